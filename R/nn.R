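## Dense networks with hand-derived backpropagation.
##
## No deep-learning framework is used: the encoders, ZINB/NB decoder heads,
## fusion layer and cluster head are plain matrices, and every gradient is
## derived analytically (and verified against numerical differentiation in
## the test suite). BLAS does the heavy lifting.

elu <- function(x) {
  neg <- x < 0
  x[neg] <- expm1(x[neg])
  x
}
elu_grad <- function(x, fx) {
  g <- fx + 1
  g[x > 0] <- 1
  g
}
sigmoid <- function(x) 1 / (1 + exp(-x))
softplus <- function(x) {
  out <- log1p(exp(-abs(x)))
  out[x > 0] <- out[x > 0] + x[x > 0]
  out
}

softmax_rows <- function(logits) {
  e <- exp(logits - apply(logits, 1, max))
  e / rowSums(e)
}

glorot <- function(nin, nout) {
  s <- sqrt(6 / (nin + nout))
  matrix(stats::runif(nin * nout, -s, s), nin, nout)
}

# Rectangular identity (top-k pass-through) used by the spectral encoder
# initialization.
eye_rect <- function(nin, nout) {
  k <- min(nin, nout)
  m <- matrix(0, nin, nout)
  m[cbind(seq_len(k), seq_len(k))] <- 1
  m
}

# One omics tower: encoder p -> widths -> d, decoder d -> rev(widths) ->
# heads. `zinb` toggles the dropout head (protein uses plain NB).
# If `X` is given, the encoder is spectrally initialized: W1 holds the top
# right-singular directions of the scaled input (scaled so activations are
# small and the ELUs are quasi-linear) and the deeper layers pass the top
# components through, so the initial latents coincide with a truncated PCA
# of the input. This removes the seed lottery of random-init autoencoders:
# training starts at the linear-autoencoder optimum and refines it.
init_tower <- function(p, widths, d, zinb, X = NULL) {
  w1 <- widths[1]; w2 <- widths[2]
  if (!is.null(X)) {
    k1 <- min(w1, p, nrow(X) - 1)
    sv <- La.svd(scale(X, scale = FALSE), nu = 0, nv = k1)
    V <- t(sv$vt)
    dvals <- sv$d[seq_len(k1)]
    scl <- 0.3 * sqrt(nrow(X)) / pmax(dvals, stats::median(dvals))
    W1 <- matrix(0, p, w1)
    W1[, seq_len(k1)] <- V %*% diag(scl, k1)
    enc <- list(W1 = W1, b1 = numeric(w1),
                W2 = eye_rect(w1, w2), b2 = numeric(w2),
                W3 = eye_rect(w2, d), b3 = numeric(d))
  } else {
    enc <- list(W1 = glorot(p, w1), b1 = numeric(w1),
                W2 = glorot(w1, w2), b2 = numeric(w2),
                W3 = glorot(w2, d), b3 = numeric(d))
  }
  list(
    enc = c(enc, list(
               # scalar RMS normalization of the latent block: equalizes
               # latent scales across omics (so fusion and k-means compare
               # like with like) without whitening the per-dimension
               # variance structure. Running mean-square serves inference;
               # not updated by Adam (its "gradient" is identically zero).
               bn_ms = 1)),
    dec = c(list(V1 = glorot(d, w2), c1 = numeric(w2),
                 V2 = glorot(w2, w1), c2 = numeric(w1),
                 Wmu = glorot(w1, p), bmu = numeric(p),
                 # auxiliary readout reconstructing the scaled input by MSE
                 # during pretraining (denoising-autoencoder organization of
                 # the latent space before the likelihood refines it)
                 Wmse = glorot(w1, p), cmse = numeric(p),
                 theta_raw = numeric(p)),
            if (zinb) list(Wpi = glorot(w1, p), bpi = numeric(p))))
}

init_params <- function(cfg, feature_dims, zinb_flags, M, K, X_list = NULL) {
  d <- cfg$latent_dim
  towers <- lapply(seq_len(M), function(m)
    init_tower(feature_dims[m], cfg$encoder_widths, d, zinb_flags[m],
               X = if (cfg$spectral_init) X_list[[m]] else NULL))
  list(towers = towers,
       head = list(Wh = glorot(d, cfg$hidden_dim), bh = numeric(cfg$hidden_dim),
                   Wa = glorot(cfg$hidden_dim, K), ba = numeric(K)),
       fusion_logits = numeric(M))
}

BN_EPS <- 1e-5

encode_forward <- function(enc, X, training = FALSE) {
  a1 <- X %*% enc$W1 + rep(enc$b1, each = nrow(X))
  h1 <- elu(a1)
  a2 <- h1 %*% enc$W2 + rep(enc$b2, each = nrow(X))
  h2 <- elu(a2)
  z0 <- h2 %*% enc$W3 + rep(enc$b3, each = nrow(X))
  ms <- if (training) mean(z0^2) else enc$bn_ms
  r <- sqrt(ms + BN_EPS)
  z <- z0 / r
  list(X = X, a1 = a1, h1 = h1, a2 = a2, h2 = h2, z = z,
       bn_batch_ms = ms, bn_r = r, training = training)
}

encode_backward <- function(enc, fw, dz) {
  g <- list()
  zh <- fw$z
  if (fw$training) {
    # RMS-norm backward: z = z0 / r with r^2 the batch mean square
    dz <- (dz - zh * mean(dz * zh)) / fw$bn_r
  } else {
    dz <- dz / fw$bn_r
  }
  g$bn_ms <- 0
  g$W3 <- crossprod(fw$h2, dz); g$b3 <- colSums(dz)
  dh2 <- dz %*% t(enc$W3)
  da2 <- dh2 * elu_grad(fw$a2, fw$h2)
  g$W2 <- crossprod(fw$h1, da2); g$b2 <- colSums(da2)
  dh1 <- da2 %*% t(enc$W2)
  da1 <- dh1 * elu_grad(fw$a1, fw$h1)
  g$W1 <- crossprod(fw$X, da1); g$b1 <- colSums(da1)
  g
}

MU_CLAMP <- 12  # pre-exp mean activations clamped to +-12 for stability

decode_forward <- function(dec, z, size_factors, zinb) {
  n <- nrow(z)
  a1 <- z %*% dec$V1 + rep(dec$c1, each = n)
  h1 <- elu(a1)
  a2 <- h1 %*% dec$V2 + rep(dec$c2, each = n)
  h2 <- elu(a2)
  mr_raw <- h2 %*% dec$Wmu + rep(dec$bmu, each = n)
  mr <- pmin(pmax(mr_raw, -MU_CLAMP), MU_CLAMP)
  mu <- size_factors * exp(mr)  # recycles down columns: cell-wise scaling
  theta <- pmax(softplus(dec$theta_raw), 1e-4)
  out <- list(z = z, a1 = a1, h1 = h1, a2 = a2, h2 = h2,
              mr_raw = mr_raw, mu = mu, theta = theta)
  if (zinb) {
    pr <- h2 %*% dec$Wpi + rep(dec$bpi, each = n)
    out$pr <- pr
    out$pi <- sigmoid(pr)
  }
  out
}

# Mean ZINB NLL and its analytic gradients wrt (mu, theta, pi) in one pass.
# Delegates to the compiled kernel; the pure-R twin below is kept as an
# independent reference (the tests assert they agree).
zinb_loss_and_grads <- function(x, mu, theta_vec, pi = NULL) {
  zinb_loss_grads_cpp(x, mu, theta_vec, pi)
}

zinb_loss_and_grads_r <- function(x, mu, theta_vec, pi = NULL, lgx1 = NULL) {
  n <- nrow(x); p <- ncol(x)
  theta <- matrix(theta_vec, n, p, byrow = TRUE)
  lth <- matrix(log(theta_vec), n, p, byrow = TRUE)
  tpm <- theta + mu
  ltr <- lth - log(tpm)                 # log(theta / (theta + mu))
  if (is.null(lgx1)) lgx1 <- lgamma(x + 1)
  pos <- x > 0
  dmu <- matrix(0, n, p); dth <- matrix(0, n, p)
  dpi <- if (!is.null(pi)) matrix(0, n, p) else NULL
  ll <- theta * ltr                     # full NB log-lik at x = 0
  # x > 0 branch: NLL = -log(1 - pi) - log NB; special functions evaluated
  # only on the (sparse) nonzero entries
  if (any(pos)) {
    xx <- x[pos]; m <- mu[pos]; t <- theta[pos]; tm <- tpm[pos]
    ll[pos] <- ll[pos] + lgamma(xx + t) - lgamma(t) - lgx1[pos] +
      xx * (log(m) - log(tm))
    if (!is.null(pi)) ll[pos] <- ll[pos] + log1p(-pi[pos])
    dmu[pos] <- (xx + t) / tm - xx / m
    dth[pos] <- -(digamma(xx + t) - digamma(t) + ltr[pos] + 1 - (xx + t) / tm)
    if (!is.null(pi)) dpi[pos] <- 1 / pmax(1 - pi[pos], 1e-10)
  }
  # x == 0 branch: NLL = -log(pi + (1 - pi) * (theta/(theta+mu))^theta)
  z0 <- !pos
  if (any(z0)) {
    t <- theta[z0]; tm <- tpm[z0]
    lt <- ltr[z0]
    nb0 <- exp(ll[z0])
    p0 <- if (!is.null(pi)) pi[z0] else 0
    L0 <- pmax(p0 + (1 - p0) * nb0, 1e-12)
    ll[z0] <- log(L0)
    dnb0 <- -(1 - p0) / L0
    dmu[z0] <- dnb0 * nb0 * (-t / tm)
    dth[z0] <- dnb0 * nb0 * (lt + 1 - t / tm)
    if (!is.null(pi)) dpi[z0] <- -(1 - nb0) / L0
  }
  sc <- 1 / (n * p)  # loss is the mean over entries
  list(loss = -mean(ll),
       dmu = dmu * sc, dtheta = dth * sc, dpi = if (!is.null(dpi)) dpi * sc)
}

# `gr` is the gradient bundle from zinb_loss_and_grads on this decoder's
# outputs.
decode_backward <- function(dec, fw, gr, zinb, gamma,
                            mse_resid = NULL, mse_weight = 0) {
  dmr <- gamma * gr$dmu * fw$mu  # dmu/dmr = mu for the exp link
  dmr[abs(fw$mr_raw) > MU_CLAMP] <- 0
  g <- list()
  dh2 <- dmr %*% t(dec$Wmu)
  g$Wmu <- crossprod(fw$h2, dmr); g$bmu <- colSums(dmr)
  if (!is.null(mse_resid)) {
    dxh <- (2 * mse_weight / length(mse_resid)) * mse_resid
    dh2 <- dh2 + dxh %*% t(dec$Wmse)
    g$Wmse <- crossprod(fw$h2, dxh); g$cmse <- colSums(dxh)
  } else {
    g$Wmse <- dec$Wmse * 0; g$cmse <- dec$cmse * 0
  }
  if (zinb) {
    dpr <- gamma * gr$dpi * fw$pi * (1 - fw$pi)
    dh2 <- dh2 + dpr %*% t(dec$Wpi)
    g$Wpi <- crossprod(fw$h2, dpr); g$bpi <- colSums(dpr)
  }
  # per-feature dispersion: sum over cells, chain through softplus
  dtheta_feat <- gamma * colSums(gr$dtheta)
  g$theta_raw <- dtheta_feat * sigmoid(dec$theta_raw)
  g$theta_raw[softplus(dec$theta_raw) < 1e-4] <- 0
  da2 <- dh2 * elu_grad(fw$a2, fw$h2)
  g$V2 <- crossprod(fw$h1, da2); g$c2 <- colSums(da2)
  dh1 <- da2 %*% t(dec$V2)
  da1 <- dh1 * elu_grad(fw$a1, fw$h1)
  g$V1 <- crossprod(fw$z, da1); g$c1 <- colSums(da1)
  g$dz <- da1 %*% t(dec$V1)
  g
}

head_forward <- function(head, z) {
  n <- nrow(z)
  ah <- z %*% head$Wh + rep(head$bh, each = n)
  h <- elu(ah)
  logits <- h %*% head$Wa + rep(head$ba, each = n)
  A <- softmax_rows(logits)
  list(z = z, ah = ah, h = h, logits = logits, A = A)
}

head_backward <- function(head, fw, dh_extra, dA) {
  # softmax Jacobian: dlogits = (dA - rowSums(dA * A)) * A
  dlog <- (dA - rowSums(dA * fw$A)) * fw$A
  g <- list(Wa = crossprod(fw$h, dlog), ba = colSums(dlog))
  dh <- dlog %*% t(head$Wa) + dh_extra
  dah <- dh * elu_grad(fw$ah, fw$h)
  g$Wh <- crossprod(fw$z, dah); g$bh <- colSums(dah)
  g$dz <- dah %*% t(head$Wh)
  g
}

## DDC gradients -----------------------------------------------------------

# Gradients of cs_ratio_sum wrt the column matrix C and the kernel K.
cs_ratio_grads <- function(C, K) {
  k <- ncol(C)
  KC <- K %*% C
  num <- crossprod(C, KC)
  q <- diag(num)
  dC <- matrix(0, nrow(C), k)
  dK <- matrix(0, nrow(K), ncol(K))
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    den <- q[i] * q[j]
    if (den <= 0) next
    sden <- sqrt(den)
    a <- num[i, j]
    dC[, i] <- dC[, i] + (KC[, j] - (a / q[i]) * KC[, i]) / sden
    dC[, j] <- dC[, j] + (KC[, i] - (a / q[j]) * KC[, j]) / sden
    dK <- dK + (tcrossprod(C[, i], C[, j]) -
                  (a / 2) * (tcrossprod(C[, i]) / q[i] +
                             tcrossprod(C[, j]) / q[j])) / sden
  }
  list(dC = dC / k, dK = dK / k)
}

# Gradient of L2's corner map: dL/dA given dL/dM where
# M[a, j] = exp(-||alpha_a - e_j||).
corner_kernel_backward <- function(A, Mm, dM) {
  k <- ncol(A)
  d2 <- rowSums(A^2) - 2 * A + 1
  d2[d2 < 0] <- 0
  D <- sqrt(d2)
  W <- dM * Mm / pmax(D, 1e-12)   # chain through exp(-D) and D
  # d(-D_aj)/dalpha_a = -(alpha_a - e_j)/D_aj
  -(rowSums(W) * A - W)
}

# Map a kernel-space gradient onto h: K_ij = exp(-||h_i - h_j||^2/(2 s^2)).
kernel_backward_h <- function(h, K, dK, sigma) {
  W <- (dK + t(dK)) * K / sigma^2
  diag(W) <- 0  # diagonal is pinned at 1
  W %*% h - rowSums(W) * h
}

# Full DDC backward: gradients of (L1 + w2 * L2 + w3 * L3) wrt A and h.
ddc_backward <- function(A, h, K, sigma, with_l2l3 = TRUE) {
  g1 <- cs_ratio_grads(A, K)
  dA <- g1$dC
  dK <- g1$dK
  if (with_l2l3) {
    Mm <- simplex_corner_kernel(A)
    g2 <- cs_ratio_grads(Mm, K)
    dA <- dA + corner_kernel_backward(A, Mm, g2$dC)
    dK <- dK + g2$dK
    k <- ncol(A)
    if (k > 1)
      dA <- dA + (A %*% (matrix(1, k, k) - diag(k))) / (k * (k - 1) / 2)
  }
  dh <- kernel_backward_h(h, K, dK, sigma)
  list(dA = dA, dh = dh)
}

## Contrastive gradient ----------------------------------------------------

# Loss value and gradient wrt the raw (unnormalized) latents.
contrastive_backward <- function(latents, negatives, tau) {
  M <- length(latents)
  n <- nrow(latents[[1]])
  Zraw <- do.call(rbind, latents)
  norms <- sqrt(rowSums(Zraw^2))
  Zh <- Zraw / norms
  sims <- Zh %*% t(Zh)
  dZh <- matrix(0, nrow(Zh), ncol(Zh))
  total <- 0
  for (u in seq_len(M)) for (v in seq_len(M)) {
    if (u == v) next
    iu <- (u - 1L) * n; iv <- (v - 1L) * n
    for (i in seq_len(n)) {
      neg <- negatives[[i]]
      ai <- iu + i; bi <- iv + i
      P <- exp(sims[ai, bi] / tau)
      if (!length(neg)) next
      Eu <- exp(sims[ai, neg] / tau)
      Ev <- exp(sims[bi, neg] / tau)
      den <- P + sum(Eu) + sum(Ev)
      total <- total - log(P / den)
      # d l / d s_pos and d l / d s_neg
      gpos <- (P / den - 1) / tau
      dZh[ai, ] <- dZh[ai, ] + gpos * Zh[bi, ]
      dZh[bi, ] <- dZh[bi, ] + gpos * Zh[ai, ]
      gu <- Eu / den / tau
      gv <- Ev / den / tau
      dZh[ai, ] <- dZh[ai, ] + colSums(gu * Zh[neg, , drop = FALSE])
      dZh[bi, ] <- dZh[bi, ] + colSums(gv * Zh[neg, , drop = FALSE])
      dZh[neg, ] <- dZh[neg, ] + outer(gu, Zh[ai, ]) + outer(gv, Zh[bi, ])
    }
  }
  sc <- 1 / (n * M * (M - 1))
  # back through row normalization
  dZraw <- (dZh - rowSums(dZh * Zh) * Zh) / norms
  dlat <- lapply(seq_len(M), function(m)
    dZraw[(m - 1L) * n + seq_len(n), , drop = FALSE] * sc)
  list(loss = total * sc, dlatents = dlat)
}

## Parameter-tree utilities ------------------------------------------------

params_map2 <- function(f, a, b) {
  if (is.list(a)) {
    # match components by name where named (backward passes build their
    # gradient lists in traversal order, not parameter order)
    bb <- if (!is.null(names(a)) && !is.null(names(b))) b[names(a)] else b
    out <- mapply(function(x, y) params_map2(f, x, y), a, bb, SIMPLIFY = FALSE)
    return(out)
  }
  f(a, b)
}

params_zeros <- function(a) {
  if (is.list(a)) return(lapply(a, params_zeros))
  a * 0
}

params_global_norm <- function(a) {
  if (is.list(a)) return(sqrt(sum(vapply(a, function(x) params_global_norm(x)^2, 0))))
  sqrt(sum(a^2))
}

adam_init <- function(params) list(m = params_zeros(params), v = params_zeros(params), t = 0)

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8,
                      clip = 10) {
  gn <- params_global_norm(grads)
  if (!is.finite(gn)) stop("non-finite gradient", call. = FALSE)
  if (gn > clip) grads <- params_map2(function(g, .) g * (clip / gn), grads, grads)
  state$t <- state$t + 1
  state$m <- params_map2(function(m, g) beta1 * m + (1 - beta1) * g, state$m, grads)
  state$v <- params_map2(function(v, g) beta2 * v + (1 - beta2) * g^2, state$v, grads)
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  upd <- params_map2(function(m, v) lr * (m / bc1) / (sqrt(v / bc2) + eps),
                     state$m, state$v)
  params <- params_map2(`-`, params, upd)
  list(params = params, state = state)
}
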