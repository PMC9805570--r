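## Training internals: batch assembly, one optimization step, and the
## epoch loops for the pretraining and joint-training stages.

# Dense views of the dataset in a fixed (canonical) cell order.
prepare_tensors <- function(data) {
  list(X = lapply(data$omics, function(o) unname(o$normalized)),
       raw = lapply(data$omics, function(o) unname(as.matrix(o$source$matrix))),
       sf = lapply(data$omics, function(o) unname(o$size_factors)),
       kinds = vapply(data$omics, function(o) o$source$omics_kind, ""),
       n = length(data$cell_ids))
}

batch_median_sigma <- function(h, scale) {
  sq <- rowSums(h^2)
  d2 <- outer(sq, sq, "+") - 2 * tcrossprod(h)
  d2[d2 < 0] <- 0
  med <- stats::median(sqrt(d2[upper.tri(d2)]))
  max(scale * med, 1e-6)
}

# One Adam step on one minibatch. `phase` is "pretrain" or "train".
train_step <- function(params, opt, tensors, idx, cfg, K, zinb_flags, gamma_m,
                       phase, warmup, lr) {
  M <- length(tensors$X)
  nb <- length(idx)
  Xclean <- lapply(tensors$X, function(x) x[idx, , drop = FALSE])
  Xb <- Xclean
  if (cfg$denoise_sd > 0)  # denoising autoencoder: corrupt encoder inputs
    Xb <- lapply(Xb, function(x) x + stats::rnorm(length(x), sd = cfg$denoise_sd))
  rawb <- lapply(tensors$raw, function(x) x[idx, , drop = FALSE])
  sfb <- lapply(tensors$sf, function(s) s[idx])

  w <- as.vector(softmax_rows(matrix(params$fusion_logits, 1)))
  enc_fw <- lapply(seq_len(M), function(m)
    encode_forward(params$towers[[m]]$enc, Xb[[m]], training = TRUE))
  zs <- lapply(enc_fw, `[[`, "z")
  fused <- Reduce(`+`, Map(function(z, wm) wm * z, zs, w))
  hd <- head_forward(params$head, fused)

  # reconstruction: loss and likelihood gradients share one pass
  dec_fw <- vector("list", M)
  zgr <- vector("list", M)
  zinb_terms <- numeric(M)
  for (m in seq_len(M)) {
    dec_fw[[m]] <- decode_forward(params$towers[[m]]$dec, zs[[m]], sfb[[m]], zinb_flags[m])
    zgr[[m]] <- zinb_loss_and_grads(rawb[[m]], dec_fw[[m]]$mu, dec_fw[[m]]$theta,
                                    if (zinb_flags[m]) dec_fw[[m]]$pi else NULL)
    zinb_terms[m] <- zgr[[m]]$loss
  }
  gm <- rep_len(gamma_m, M)
  zinb_total <- sum(gm * zinb_terms)
  gamma_eff <- if (phase == "pretrain") cfg$pretrain_gamma * gm else gm

  # pretraining only: denoising MSE reconstruction of the clean scaled
  # input from the corrupted pass, through a dedicated linear readout
  with_mse <- phase == "pretrain" && cfg$mse_weight > 0
  mse_terms <- numeric(M)
  mse_fw <- vector("list", M)
  if (with_mse) {
    for (m in seq_len(M)) {
      dcf <- dec_fw[[m]]
      xhat <- dcf$h2 %*% params$towers[[m]]$dec$Wmse +
        rep(params$towers[[m]]$dec$cmse, each = nb)
      mse_fw[[m]] <- xhat - Xclean[[m]]
      mse_terms[m] <- mean(mse_fw[[m]]^2)
    }
  }
  mse_total <- cfg$mse_weight * sum(mse_terms)

  # clustering terms on the batch
  sigma <- batch_median_sigma(hd$h, cfg$sigma_scale)
  Kmat <- gaussian_kernel(hd$h, sigma)
  l1 <- cs_ratio_sum(hd$A, Kmat)
  with_l2l3 <- phase == "train"
  l2 <- if (with_l2l3) cs_ratio_sum(simplex_corner_kernel(hd$A), Kmat) else 0
  l3 <- if (with_l2l3 && K > 1) ddc_l3(hd$A) else 0

  # contrastive term with within-batch negatives
  hard <- max.col(hd$A)
  Zh_norm <- lapply(zs, function(z) z / pmax(sqrt(rowSums(z^2)), 1e-12))
  labels_for_neg <- if (warmup) rep(NA_integer_, nb) else hard
  negs <- sample_negative_sets(labels_for_neg, M, cfg$negatives_per_anchor)
  if (cfg$delta > 0 && any(lengths(negs) > 0)) {
    ct <- contrastive_backward(zs, negs, cfg$tau)
  } else {
    ct <- list(loss = 0, dlatents = lapply(zs, function(z) z * 0))
  }
  wmin <- min(w)
  total <- if (phase == "pretrain")
    pretrain_loss(zinb_total, l1, ct$loss, w, cfg$pretrain_gamma, cfg$delta) + mse_total
  else
    total_loss(zinb_total, l1 + l2 + l3, ct$loss, w, cfg$delta)

  ## backward -------------------------------------------------------------
  ddc <- ddc_backward(hd$A, hd$h, Kmat, sigma, with_l2l3 = with_l2l3)
  hb <- head_backward(params$head, hd, ddc$dh, ddc$dA)
  dz_fused <- hb$dz

  grads <- list(towers = vector("list", M), head = hb[c("Wh", "bh", "Wa", "ba")],
                fusion_logits = numeric(M))
  cmult <- cfg$delta * wmin
  dw <- numeric(M)
  for (m in seq_len(M)) {
    db <- decode_backward(params$towers[[m]]$dec, dec_fw[[m]], zgr[[m]],
                          zinb_flags[m], gamma_eff[m],
                          mse_resid = if (with_mse) mse_fw[[m]] else NULL,
                          mse_weight = cfg$mse_weight)
    dz_m <- db$dz + w[m] * dz_fused + cmult * ct$dlatents[[m]]
    grads$towers[[m]] <- list(enc = encode_backward(params$towers[[m]]$enc, enc_fw[[m]], dz_m),
                              dec = db[setdiff(names(db), "dz")])
    dw[m] <- sum(dz_fused * zs[[m]])
  }
  grads$fusion_logits <- numeric(M)  # fusion logits are not gradient-trained

  if (!is.finite(total)) stop("non-finite training loss; aborting", call. = FALSE)
  # fusion logits get their own (larger) step size: two scalars whose
  # gradients are orders of magnitude smaller than the network's
  st1 <- adam_step(params[c("towers", "head")], grads[c("towers", "head")],
                   opt$main, lr)
  params[c("towers", "head")] <- st1$params
  # adaptive fusion weights (joint-training stage only, when the head is
  # meaningful): each omics is scored by the cosine silhouette of its
  # latents under the current predicted partition (the similarity the
  # alignment module uses); the logits track q/T by EMA. Bounded and free
  # of the winner-take-all feedback a gradient update suffers.
  if (phase == "train" && K > 1 && length(unique(hard)) > 1) {
    q <- omics_separability(Zh_norm, hard)
    target <- (q - mean(q)) / cfg$fusion_temp
    params$fusion_logits <- cfg$fusion_momentum * params$fusion_logits +
      (1 - cfg$fusion_momentum) * target
  }
  for (m in seq_len(M)) {  # running RMS statistic (momentum 0.9)
    enc <- params$towers[[m]]$enc
    params$towers[[m]]$enc$bn_ms <- 0.9 * enc$bn_ms + 0.1 * enc_fw[[m]]$bn_batch_ms
  }
  list(params = params, opt = list(main = st1$state),
       losses = c(total = total, zinb = zinb_total, l1 = l1, l2 = l2, l3 = l3,
                  contrastive = ct$loss, mse = mse_total),
       hard = hard, idx = idx, w = w)
}

# Epoch loop shared by both stages.
run_stage <- function(params, tensors, cfg, K, zinb_flags, gamma_m, phase,
                      epochs, lr, verbose = FALSE) {
  n <- tensors$n
  opt <- list(main = adam_init(params[c("towers", "head")]))
  history <- list()
  empty_streak <- integer(K)
  for (epoch in seq_len(epochs)) {
    perm <- sample.int(n)
    starts <- seq(1, n, by = cfg$batch_size)
    ep_losses <- NULL
    counts <- integer(K)
    warmup <- phase == "pretrain" && epoch <= cfg$warmup_epochs
    # calibrate the fusion weights from the very first pretraining epoch
    # (spectral initialization makes the latents meaningful immediately)
    # and again when the warm-up ends: min(w) then damps alignment toward
    # an uninformative omics throughout
    if (phase == "pretrain" && K > 1 && epoch %in% c(1, cfg$warmup_epochs + 1))
      params <- calibrate_fusion_weights(params, tensors, K, cfg)$params
    for (s in starts) {
      idx <- perm[s:min(s + cfg$batch_size - 1, n)]
      if (length(idx) < 2) next
      st <- train_step(params, opt, tensors, idx, cfg, K, zinb_flags, gamma_m,
                       phase, warmup, lr)
      params <- st$params; opt <- st$opt
      ep_losses <- rbind(ep_losses, st$losses)
      counts <- counts + tabulate(st$hard, nbins = K)
    }
    empty_streak <- ifelse(counts == 0, empty_streak + 1L, 0L)
    if (any(empty_streak >= cfg$empty_rescue_epochs)) {
      for (kk in which(empty_streak >= cfg$empty_rescue_epochs)) {
        params$head$Wa[, kk] <- stats::runif(nrow(params$head$Wa), -0.5, 0.5)
        params$head$ba[kk] <- 0
        empty_streak[kk] <- 0L
      }
    }
    mean_losses <- colMeans(ep_losses)
    history[[epoch]] <- c(phase = phase, epoch = epoch, mean_losses,
                          w_min = min(st$w))
    if (verbose && (epoch %% 10 == 0 || epoch == 1))
      message(sprintf("[%s] epoch %3d  total %.4f  zinb %.4f  ddc %.4f  contr %.4f",
                      phase, epoch, mean_losses["total"], mean_losses["zinb"],
                      mean_losses["l1"] + mean_losses["l2"] + mean_losses["l3"],
                      mean_losses["contrastive"]))
  }
  hist_df <- if (length(history)) {
    df <- as.data.frame(do.call(rbind, history), stringsAsFactors = FALSE)
    df[-1] <- lapply(df[-1], as.numeric)
    df
  } else NULL
  list(params = params, history = hist_df)
}

# Forward pass over all cells (inference mode; batch-size independent).
model_forward <- function(params, tensors) {
  M <- length(tensors$X)
  w <- as.vector(softmax_rows(matrix(params$fusion_logits, 1)))
  zs <- lapply(seq_len(M), function(m)
    encode_forward(params$towers[[m]]$enc, tensors$X[[m]])$z)
  fused <- Reduce(`+`, Map(function(z, wm) wm * z, zs, w))
  hd <- head_forward(params$head, fused)
  list(latents = zs, fused = fused, hidden = hd$h, A = hd$A,
       hard = max.col(hd$A), w = w)
}

# Separability of each omics' (normalized) latents under a partition:
# the rank-based AUC of within-cluster vs between-cluster cosine
# similarities, mapped to [-1, 1] (0 = no structure, 1 = perfect
# separation). Rank-based so scores are comparable across omics of very
# different dimensionality, unlike raw silhouette differences.
omics_separability <- function(Zh, part) {
  same <- outer(part, part, "==")
  diag(same) <- NA
  idx_same <- which(same); idx_diff <- which(!same)
  vapply(Zh, function(zh) {
    S <- tcrossprod(zh)
    w <- S[idx_same]; b <- S[idx_diff]
    r <- rank(c(w, b))
    auc <- (sum(r[seq_along(w)]) - length(w) * (length(w) + 1) / 2) /
      (as.numeric(length(w)) * length(b))
    2 * (auc - 0.5)
  }, 0)
}

# Calibrate the fusion weights from candidate partitions. Because each
# omics' latent space can hold a clean clustering in mutually misaligned
# axes (so a naive average cancels the structure), candidates are proposed
# per omics and from the fused view, each is scored by the *total*
# cross-omics silhouette consensus, and the best one sets the weights
# (w = softmax of the per-omics silhouettes over temperature). The winning
# partition is also returned so the cluster head can be warm-started on it.
calibrate_fusion_weights <- function(params, tensors, K, cfg) {
  fw <- model_forward(params, tensors)
  Zh <- lapply(fw$latents, function(z) z / pmax(sqrt(rowSums(z^2)), 1e-12))
  w <- as.vector(softmax_rows(matrix(params$fusion_logits, 1)))
  fused <- Reduce(`+`, Map(function(z, wm) wm * z, fw$latents, w))
  views <- c(fw$latents, list(fused))
  best <- NULL; best_score <- -Inf; best_q <- NULL
  for (v in views) {
    part <- tryCatch(stats::kmeans(v, centers = K, nstart = 5)$cluster,
                     error = function(e) NULL)
    if (is.null(part) || length(unique(part)) < 2) next
    q <- omics_separability(Zh, part)
    if (sum(q) > best_score) {
      best_score <- sum(q); best <- part; best_q <- q
    }
  }
  if (!is.null(best_q))
    params$fusion_logits <- (best_q - mean(best_q)) / cfg$fusion_temp
  list(params = params, partition = best)
}

# Supervised warm start of the cluster head from a partition (defaults to
# k-means on the fused latents). The targets are *soft*, distance-based
# responsibilities rather than one-hot labels: the head must stay crisp in
# cluster cores but uncertain between centers, which is what the
# entropy-based doublet detector relies on.
kmeans_head_start <- function(params, tensors, K, partition = NULL,
                              steps = 60, lr = 5e-3) {
  fw <- model_forward(params, tensors)
  if (is.null(partition))
    partition <- stats::kmeans(fw$fused, centers = K, nstart = 5)$cluster
  centers <- t(vapply(seq_len(K), function(k) {
    ix <- which(partition == k)
    if (length(ix)) colMeans(fw$fused[ix, , drop = FALSE]) else
      fw$fused[sample.int(nrow(fw$fused), 1), ]
  }, numeric(ncol(fw$fused))))
  d2 <- outer(rowSums(fw$fused^2), rowSums(centers^2), "+") -
    2 * fw$fused %*% t(centers)
  d2[d2 < 0] <- 0
  # isotropic-Gaussian E-step responsibilities: per-dimension variance v
  # estimated as (mean squared distance to own center) / D, exponent
  # -d^2 / (2 v)
  bw2 <- mean(d2[cbind(seq_len(nrow(d2)), partition)])
  v <- max(bw2 / ncol(fw$fused), 1e-8)
  target <- softmax_rows(-d2 / (2 * v))
  opt <- adam_init(params$head)
  for (s in seq_len(steps)) {
    hd <- head_forward(params$head, fw$fused)
    dA <- -(target / pmax(hd$A, 1e-10)) / nrow(target)
    hb <- head_backward(params$head, hd, 0 * hd$h, dA)
    st <- adam_step(params$head, hb[c("Wh", "bh", "Wa", "ba")], opt, lr)
    params$head <- st$params; opt <- st$state
  }
  params
}
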