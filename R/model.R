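#' Fit the joint multi-omics clustering model
#'
#' Fits omics-specific ZINB/NB autoencoders with a contrastive cross-omics
#' alignment, adaptive simplex fusion weights and a Cauchy-Schwarz
#' divergence clustering head, in three stages:
#'
#' 1. **Pretraining** minimizes `gamma * L_zinb + L1 + delta * min(w) *
#'    L_contrastive` (reconstruction, cluster separability and alignment).
#' 2. **Doublet detection** (optional) builds pseudo doublets from cluster
#'    prototypes and flags cells whose assignment entropy exceeds the
#'    empirical quantile threshold; flagged cells are excluded from the next
#'    stage.
#' 3. **Joint training** minimizes `L_zinb + (L1 + L2 + L3) + delta * min(w)
#'    * L_contrastive` and yields the final soft assignments.
#'
#' All cells (including flagged doublets) receive final assignments through
#' a forward pass. Cells are processed internally in sorted cell-id order,
#' so the result is invariant to the input row order.
#'
#' @param data A [multiomics_dataset()].
#' @param K Number of clusters (>= 1).
#' @param config A [moclust_config()].
#' @param doublets Run the automatic doublet detection stage between
#'   pretraining and joint training?
#' @param verbose Print per-epoch loss summaries?
#' @return An object of class `moclust` with components
#'   `cluster` (integer labels in `1..K`, input order),
#'   `soft_assignments` (cells x K), `fusion_weights` (simplex vector named
#'   by omics kind), `latents` (list of per-omics cells x d matrices),
#'   `fused`, `hidden`, `doublets` (a `moclust_doublets` or `NULL`),
#'   `history` (per-epoch loss components), `config`, `K`, and the model
#'   parameters. Methods: [print.moclust()], [summary.moclust()],
#'   [coef.moclust()], [predict.moclust()], [plot.moclust()],
#'   [residuals.moclust()], [logLik.moclust()].
#' @examples
#' \donttest{
#' sim <- simulate_multiomics(synth_config(n_cells = 150, n_genes = 120,
#'                                         n_proteins = 15, seed = 1))
#' fit <- moclust(sim$dataset, K = 3,
#'                config = moclust_config(pretrain_epochs = 15,
#'                                        train_epochs = 15, seed = 1),
#'                doublets = FALSE)
#' table(fit$cluster, sim$true_labels)
#' }
#' @export
moclust <- function(data, K, config = moclust_config(), doublets = TRUE,
                    verbose = FALSE) {
  stopifnot(inherits(data, "multiomics_dataset"), K >= 1)
  validate_config(config)
  cl <- match.call()

  # canonical cell order: results do not depend on input row order
  ord <- order(data$cell_ids)
  data_c <- data[ord]
  pos <- match(data$cell_ids, data_c$cell_ids)  # input row -> canonical row
  tensors <- prepare_tensors(data_c)
  M <- length(tensors$X)
  zinb_flags <- tensors$kinds != "protein"
  gamma_m <- rep_len(config$gamma_m, M)
  feature_dims <- vapply(tensors$X, ncol, 0L)

  set.seed(config$seed)
  params <- init_params(config, feature_dims, zinb_flags, M, K,
                        X_list = tensors$X)

  pre <- run_stage(params, tensors, config, K, zinb_flags, gamma_m,
                   phase = "pretrain", epochs = config$pretrain_epochs,
                   lr = config$lr_pretrain, verbose = verbose)
  params <- pre$params
  if (K > 1) {
    calib <- calibrate_fusion_weights(params, tensors, K, config)
    params <- calib$params
    if (config$kmeans_start)
      params <- kmeans_head_start(params, tensors, K, partition = calib$partition)
  }

  rna_index <- which(tensors$kinds == "rna")[1]
  if (is.na(rna_index)) rna_index <- which(tensors$kinds == "atac_activity")[1]
  if (is.na(rna_index)) rna_index <- 1L

  dbl <- NULL
  keep <- rep(TRUE, tensors$n)
  if (doublets && K > 1) {
    set.seed(config$seed + 1L)
    dbl <- tryCatch(call_doublets_core(params, tensors, config, rna_index),
                    error = function(e) {
                      warning("doublet detection skipped: ", conditionMessage(e))
                      NULL
                    })
    if (!is.null(dbl)) {
      keep <- !dbl$flags
      if (sum(keep) < max(2 * K, 10)) {
        warning("doublet filter would remove nearly all cells; ignoring flags for training")
        keep <- rep(TRUE, tensors$n)
      }
    }
  }

  tensors_train <- if (all(keep)) tensors else subset_tensors(tensors, keep)
  set.seed(config$seed + 2L)
  tr <- run_stage(params, tensors_train, config, K, zinb_flags, gamma_m,
                  phase = "train", epochs = config$train_epochs,
                  lr = config$lr_train, verbose = verbose)
  params <- tr$params

  fw <- model_forward(params, tensors)
  w <- fw$w
  names(w) <- tensors$kinds
  history <- rbind(pre$history, tr$history)

  back <- function(m) if (is.null(dim(m))) m[pos] else m[pos, , drop = FALSE]
  if (!is.null(dbl)) {
    dbl$entropy <- back(dbl$entropy)
    dbl$flags <- back(dbl$flags)
  }
  structure(list(
    call = cl, config = config, K = K, M = M,
    omics_kinds = tensors$kinds, rna_index = rna_index,
    params = params, fusion_weights = w,
    cluster = back(fw$hard), soft_assignments = back(fw$A),
    latents = lapply(fw$latents, back), fused = back(fw$fused),
    hidden = back(fw$hidden),
    entropy = back(assignment_entropy(fw$A)),
    doublets = dbl, history = history,
    cell_ids = data$cell_ids, canonical_ids = data_c$cell_ids,
    feature_ids = lapply(data$omics, function(o) o$source$feature_ids),
    tensors = tensors, canonical_pos = pos,
    labels = data$labels),
    class = "moclust")
}

subset_tensors <- function(tensors, keep) {
  list(X = lapply(tensors$X, function(x) x[keep, , drop = FALSE]),
       raw = lapply(tensors$raw, function(x) x[keep, , drop = FALSE]),
       sf = lapply(tensors$sf, function(s) s[keep]),
       kinds = tensors$kinds, n = sum(keep))
}

#' Encode one omics through its fitted encoder
#'
#' @param object A fitted [moclust()] object.
#' @param x Preprocessed cells x features matrix for the chosen omics (same
#'   feature set and preprocessing as at fit time).
#' @param omics_index Which omics' encoder to use.
#' @return Cells x d latent matrix.
#' @export
encode <- function(object, x, omics_index = 1L) {
  stopifnot(inherits(object, "moclust"))
  x <- as.matrix(x)
  enc <- object$params$towers[[omics_index]]$enc
  if (ncol(x) != nrow(enc$W1))
    stop("input has ", ncol(x), " features; encoder expects ", nrow(enc$W1),
         call. = FALSE)
  encode_forward(enc, x)$z
}

#' Decode latents into ZINB/NB parameters
#'
#' @param object A fitted [moclust()] object.
#' @param z Cells x d latent matrix.
#' @param size_factors Positive per-cell size factors scaling the mean.
#' @param omics_index Which omics' decoder to use.
#' @return List with `mu` (positive mean matrix), `theta` (positive
#'   per-feature dispersion) and, for ZINB omics, `pi` (dropout
#'   probabilities in (0,1)); protein decoders omit `pi`.
#' @export
decode_zinb <- function(object, z, size_factors = NULL, omics_index = 1L) {
  stopifnot(inherits(object, "moclust"))
  z <- as.matrix(z)
  if (is.null(size_factors)) size_factors <- rep(1, nrow(z))
  if (any(size_factors <= 0)) stop("size factors must be positive", call. = FALSE)
  if (length(size_factors) != nrow(z))
    stop("need one size factor per cell", call. = FALSE)
  zinb <- object$omics_kinds[omics_index] != "protein"
  fwd <- decode_forward(object$params$towers[[omics_index]]$dec, z, size_factors, zinb)
  out <- list(mu = fwd$mu, theta = fwd$theta)
  if (zinb) out$pi <- fwd$pi
  out
}

#' Fuse per-omics latents with simplex weights
#'
#' @param latents List of M cells x d latent matrices.
#' @param w Fusion weight vector on the simplex (nonnegative, sums to 1).
#' @return Cells x d fused matrix `sum_m w_m z^(m)`.
#' @export
fuse <- function(latents, w) {
  if (length(w) != length(latents))
    stop("need one weight per omics (", length(latents), "), got ", length(w),
         call. = FALSE)
  if (any(w < -1e-8) || abs(sum(w) - 1) > 1e-6)
    stop("fusion weights must be nonnegative and sum to 1", call. = FALSE)
  d <- dim(latents[[1]])
  for (z in latents) if (!all(dim(z) == d))
    stop("all latents must share the same shape", call. = FALSE)
  Reduce(`+`, Map(function(z, wm) wm * z, latents, w))
}

#' Cluster head: hidden representation and soft assignments
#'
#' @param object A fitted [moclust()] object.
#' @param z Cells x d fused latent matrix.
#' @return List with `h` (hidden representation feeding the kernel) and `A`
#'   (cells x K soft assignments; each row on the simplex).
#' @export
cluster_head <- function(object, z) {
  stopifnot(inherits(object, "moclust"))
  fwd <- head_forward(object$params$head, as.matrix(z))
  list(h = fwd$h, A = fwd$A)
}

#' Predict cluster assignments
#'
#' Pure forward pass (no parameter updates, no randomness): per-omics
#' latents, fusion, cluster head. Results for a subset of cells equal the
#' corresponding rows of a full-data pass.
#'
#' @param object A fitted [moclust()] object.
#' @param newdata Optional [multiomics_dataset()] with the same omics and
#'   feature sets as at fit time; defaults to the training data.
#' @param ... Unused.
#' @return A `moclust_prediction` list: `cluster`, `soft_assignments`,
#'   `latents`, `fused`, `hidden`, `entropy`, `fusion_weights`.
#' @method predict moclust
#' @export
predict.moclust <- function(object, newdata = NULL, ...) {
  tensors <- if (is.null(newdata)) {
    t0 <- object$tensors
    pos <- object$canonical_pos
    list(X = lapply(t0$X, function(x) x[pos, , drop = FALSE]),
         raw = t0$raw, sf = t0$sf, kinds = t0$kinds, n = t0$n)
  } else prepare_tensors(newdata)
  fw <- model_forward(object$params, tensors)
  w <- fw$w; names(w) <- object$omics_kinds
  structure(list(cluster = fw$hard, soft_assignments = fw$A,
                 latents = fw$latents, fused = fw$fused, hidden = fw$hidden,
                 entropy = assignment_entropy(fw$A), fusion_weights = w),
            class = "moclust_prediction")
}

#' @method print moclust
#' @export
print.moclust <- function(x, ...) {
  cat("Multi-omics joint clustering fit (moclust)\n")
  cat(sprintf("  %d cells, %d omics (%s), K = %d\n",
              length(x$cluster), x$M, paste(x$omics_kinds, collapse = " + "), x$K))
  cat("  fusion weights:",
      paste(sprintf("%s = %.3f", names(x$fusion_weights), x$fusion_weights),
            collapse = ", "), "\n")
  cat("  cluster sizes:", paste(tabulate(x$cluster, x$K), collapse = " "), "\n")
  if (!is.null(x$doublets))
    cat(sprintf("  doublets flagged: %d (F_%.2f = %.3f)\n",
                sum(x$doublets$flags), x$doublets$alpha_level, x$doublets$threshold))
  invisible(x)
}

#' Summary of a moclust fit
#' @param object A fitted [moclust()] object.
#' @param ... Unused.
#' @return A `summary.moclust` list printed with cluster sizes, weights,
#'   mean assignment entropy and final losses.
#' @method summary moclust
#' @export
summary.moclust <- function(object, ...) {
  h <- object$history
  final <- if (!is.null(h) && nrow(h)) h[nrow(h), ] else NULL
  out <- list(n = length(object$cluster), K = object$K,
              omics = object$omics_kinds,
              sizes = tabulate(object$cluster, object$K),
              fusion_weights = object$fusion_weights,
              mean_entropy = mean(object$entropy),
              final_losses = final,
              n_doublets = if (is.null(object$doublets)) NA_integer_
                           else sum(object$doublets$flags))
  class(out) <- "summary.moclust"
  out
}

#' @method print summary.moclust
#' @export
print.summary.moclust <- function(x, ...) {
  cat(sprintf("moclust fit: n = %d, K = %d (%s)\n", x$n, x$K,
              paste(x$omics, collapse = " + ")))
  cat("cluster sizes: ", paste(x$sizes, collapse = " "), "\n")
  cat("fusion weights:",
      paste(sprintf("%s = %.3f", names(x$fusion_weights), x$fusion_weights),
            collapse = ", "), "\n")
  cat(sprintf("mean assignment entropy: %.4f\n", x$mean_entropy))
  if (!is.na(x$n_doublets)) cat("doublets flagged:", x$n_doublets, "\n")
  if (!is.null(x$final_losses)) {
    fl <- x$final_losses
    cat(sprintf("final loss (%s): total %.4f  zinb %.4f  contrastive %.4f\n",
                fl$phase, as.numeric(fl$total), as.numeric(fl$zinb),
                as.numeric(fl$contrastive)))
  }
  invisible(x)
}

#' Fusion weights of a fit
#' @param object A fitted [moclust()] object.
#' @param ... Unused.
#' @return Named simplex vector of fusion weights.
#' @method coef moclust
#' @export
coef.moclust <- function(object, ...) object$fusion_weights

#' Loss curves
#'
#' Plots the per-epoch mean of each loss component for both stages.
#'
#' @param x A fitted [moclust()] object.
#' @param components Which history columns to draw.
#' @param ... Passed to [graphics::matplot()].
#' @return `x`, invisibly.
#' @method plot moclust
#' @export
plot.moclust <- function(x, components = c("total", "zinb", "l1", "contrastive"), ...) {
  h <- x$history
  if (is.null(h) || !nrow(h)) {
    warning("no training history to plot")
    return(invisible(x))
  }
  m <- as.matrix(h[, components, drop = FALSE])
  graphics::matplot(seq_len(nrow(m)), m, type = "l", lty = 1,
                    xlab = "epoch (pretrain then train)", ylab = "loss", ...)
  graphics::abline(v = sum(h$phase == "pretrain") + 0.5, lty = 3)
  graphics::legend("topright", legend = components, col = seq_along(components),
                   lty = 1, bty = "n")
  invisible(x)
}

#' Pearson residuals under the fitted ZINB/NB model
#'
#' `(x - E[x]) / sd(x)` with `E[x] = (1 - pi) mu` and
#' `Var[x] = (1 - pi) mu (1 + mu (pi + 1/theta))`.
#'
#' @param object A fitted [moclust()] object.
#' @param omics_index Which omics to compute residuals for.
#' @param ... Unused.
#' @return Cells x features matrix of Pearson residuals (input cell order).
#' @method residuals moclust
#' @export
residuals.moclust <- function(object, omics_index = 1L, ...) {
  t0 <- object$tensors
  z <- encode_forward(object$params$towers[[omics_index]]$enc,
                      t0$X[[omics_index]])$z
  zinb <- t0$kinds[omics_index] != "protein"
  fwd <- decode_forward(object$params$towers[[omics_index]]$dec, z,
                        t0$sf[[omics_index]], zinb)
  pi <- if (zinb) fwd$pi else 0
  mu <- fwd$mu
  th <- matrix(fwd$theta, nrow(mu), ncol(mu), byrow = TRUE)
  ex <- (1 - pi) * mu
  vx <- (1 - pi) * mu * (1 + mu * (pi + 1 / th))
  r <- (t0$raw[[omics_index]] - ex) / sqrt(pmax(vx, 1e-12))
  r[object$canonical_pos, , drop = FALSE]
}

#' Log-likelihood of the raw counts under the fitted decoders
#'
#' @param object A fitted [moclust()] object.
#' @param ... Unused.
#' @return A `logLik` object: summed ZINB/NB log-likelihood over all omics
#'   and entries, with `df` the total parameter count.
#' @method logLik moclust
#' @export
logLik.moclust <- function(object, ...) {
  t0 <- object$tensors
  ll <- 0
  for (m in seq_len(object$M)) {
    z <- encode_forward(object$params$towers[[m]]$enc, t0$X[[m]])$z
    zinb <- t0$kinds[m] != "protein"
    fwd <- decode_forward(object$params$towers[[m]]$dec, z, t0$sf[[m]], zinb)
    th <- matrix(fwd$theta, nrow(fwd$mu), ncol(fwd$mu), byrow = TRUE)
    pi <- if (zinb) fwd$pi else 0
    ll <- ll + sum(dzinb(t0$raw[[m]], fwd$mu, th, pi, log = TRUE))
  }
  df <- length(unlist(object$params))
  structure(ll, df = df, nobs = t0$n, class = "logLik")
}
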