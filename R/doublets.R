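#' Per-cluster prototypes
#'
#' The prototype of a cluster is the arithmetic mean of the RNA latent
#' features of its members; prototypes seed the pseudo-cell sampling of the
#' doublet detector.
#'
#' @param latents Cells x d latent matrix (transcriptomic omics).
#' @param hard_labels Integer cluster label per cell, in `1..K`.
#' @return List with `prototypes` (named list of length-d vectors, one per
#'   non-empty cluster), `members` (list of member index vectors), and
#'   `within_var` (mean within-cluster per-coordinate variance, used to set
#'   the default noise level).
#' @export
compute_prototypes <- function(latents, hard_labels) {
  latents <- as.matrix(latents)
  stopifnot(nrow(latents) == length(hard_labels))
  present <- sort(unique(hard_labels))
  if (!length(present)) stop("no cluster has any member", call. = FALSE)
  members <- lapply(present, function(k) which(hard_labels == k))
  protos <- lapply(members, function(ix) colMeans(latents[ix, , drop = FALSE]))
  names(protos) <- names(members) <- as.character(present)
  wv <- vapply(members, function(ix) {
    if (length(ix) < 2) return(NA_real_)
    mean(apply(latents[ix, , drop = FALSE], 2, stats::var))
  }, 0)
  structure(list(prototypes = protos, members = members,
                 within_var = mean(wv, na.rm = TRUE)),
            class = "moclust_prototypes")
}

#' Sample pseudo cells around prototypes
#'
#' Draws `n_per_cluster` points per cluster from an isotropic Gaussian
#' `N(P_i, eps I)` centered at each prototype.
#'
#' @param prototypes Result of [compute_prototypes()].
#' @param n_per_cluster Draws per cluster.
#' @param eps Positive per-coordinate Gaussian variance (noise level).
#' @return Named list (by cluster) of `n_per_cluster` x d matrices.
#' @export
sample_pseudo_cells <- function(prototypes, n_per_cluster = 50, eps = 0.1) {
  if (eps <= 0) stop("eps must be positive", call. = FALSE)
  lapply(prototypes$prototypes, function(P) {
    d <- length(P)
    matrix(P, n_per_cluster, d, byrow = TRUE) +
      matrix(stats::rnorm(n_per_cluster * d, sd = sqrt(eps)), n_per_cluster, d)
  })
}

#' Build pseudo doublets by cross-cluster linear fusion
#'
#' Samples `n_pairs` pairs of pseudo cells from *different* clusters and
#' mixes each pair as `lambda * z_a + (1 - lambda) * z_b`.
#'
#' @param pos_sets Named list of pseudo-cell matrices from
#'   [sample_pseudo_cells()].
#' @param lambda Mixing weight in `[0, 1]` (0.5 mixes parents equally).
#' @param n_pairs Number of pseudo doublets to generate.
#' @return `n_pairs` x d matrix of pseudo-doublet latents.
#' @export
make_pseudo_doublets <- function(pos_sets, lambda = 0.5, n_pairs = 1000) {
  nonempty <- Filter(function(m) nrow(m) > 0, pos_sets)
  if (length(nonempty) < 2)
    stop("pseudo doublets need pseudo cells from at least two clusters", call. = FALSE)
  kset <- length(nonempty)
  ci <- sample.int(kset, n_pairs, replace = TRUE)
  cj <- vapply(ci, function(i) {
    j <- sample.int(kset - 1L, 1L)
    if (j >= i) j + 1L else j
  }, 1L)
  ai <- vapply(ci, function(i) sample.int(nrow(nonempty[[i]]), 1L), 1L)
  aj <- vapply(cj, function(j) sample.int(nrow(nonempty[[j]]), 1L), 1L)
  za <- do.call(rbind, lapply(seq_len(n_pairs), function(t) nonempty[[ci[t]]][ai[t], ]))
  zb <- do.call(rbind, lapply(seq_len(n_pairs), function(t) nonempty[[cj[t]]][aj[t], ]))
  lambda * za + (1 - lambda) * zb
}

#' Shannon entropy of soft assignments
#'
#' `H = -sum_i alpha_i log alpha_i` per row, with `0 log 0 := 0`. High
#' entropy marks cells the cluster head cannot assign confidently —
#' the doublet signature exploited by the detector.
#'
#' @param A Soft assignment matrix (rows on the simplex) or a single row.
#' @return Numeric vector of entropies in `[0, log K]`.
#' @export
assignment_entropy <- function(A) {
  A <- if (is.null(dim(A))) matrix(A, 1) else as.matrix(A)
  H <- -rowSums(ifelse(A > 0, A * log(A), 0))
  pmax(H, 0)
}

#' Entropy threshold from the pseudo-doublet distribution
#'
#' The empirical `alpha_level` quantile (linear interpolation between order
#' statistics) of the pseudo-doublet entropies. With the default
#' `alpha_level = 0.05` about 95% of pseudo doublets lie above the
#' threshold.
#'
#' @param pseudo_entropies Entropies of the pseudo doublets.
#' @param alpha_level Quantile level in (0, 1) (0 and 1 give min and max).
#' @return Scalar threshold F_alpha.
#' @export
entropy_threshold <- function(pseudo_entropies, alpha_level = 0.05) {
  unname(stats::quantile(pseudo_entropies, alpha_level, type = 7))
}

#' Detect doublets from a pretrained model
#'
#' Runs the full detection pipeline: cluster prototypes from the RNA
#' latents, pseudo cells around each prototype, cross-cluster pseudo
#' doublets, entropies of their cluster-head predictions (pseudo latents are
#' fed to the head as fused representations), and finally the quantile
#' threshold applied to the real cells' assignment entropies.
#'
#' @param params Model parameter tree (internal) or a fitted `moclust`
#'   object's `$params`.
#' @param tensors Prepared data tensors (internal); or use the `moclust`
#'   method wrapper.
#' @param cfg A [moclust_config()].
#' @param rna_index Which omics holds the transcriptome latents.
#' @return A `moclust_doublets` object: per-cell `entropy`, `threshold`,
#'   `alpha_level`, logical `flags`, plus the pseudo-cell and pseudo-doublet
#'   entropy distributions.
#' @keywords internal
call_doublets_core <- function(params, tensors, cfg, rna_index = 1L) {
  fw <- model_forward(params, tensors)
  proto <- compute_prototypes(fw$latents[[rna_index]], fw$hard)
  if (length(proto$prototypes) < 2)
    stop("doublet detection needs at least two non-empty clusters", call. = FALSE)
  wv <- proto$within_var
  if (!is.finite(wv) || wv <= 0) wv <- 1
  eps <- cfg$doublet_eps_scale * wv
  pos <- sample_pseudo_cells(proto, cfg$doublet_n_per_cluster, eps)
  dbl <- make_pseudo_doublets(pos, cfg$doublet_lambda, cfg$doublet_n_pairs)
  A_dbl <- head_forward(params$head, dbl)$A
  A_pos <- head_forward(params$head, do.call(rbind, pos))$A
  pseudo_dbl_H <- assignment_entropy(A_dbl)
  pseudo_cell_H <- assignment_entropy(A_pos)
  thr <- entropy_threshold(pseudo_dbl_H, cfg$alpha_level)
  H <- assignment_entropy(fw$A)
  structure(list(entropy = H, threshold = thr, alpha_level = cfg$alpha_level,
                 flags = H > thr,
                 pseudo_doublet_entropy = pseudo_dbl_H,
                 pseudo_cell_entropy = pseudo_cell_H),
            class = "moclust_doublets")
}

#' Doublet calls for a fitted or pretrained model
#'
#' @param object A fitted [moclust()] object (its pretrained parameters and
#'   training data views are reused).
#' @param data Optional `multiomics_dataset` to score instead of the
#'   training data.
#' @param alpha_level Optional override of the quantile level.
#' @return A `moclust_doublets` object (see [call_doublets_core()]).
#' @export
call_doublets <- function(object, data = NULL, alpha_level = NULL) {
  stopifnot(inherits(object, "moclust"))
  cfg <- object$config
  if (!is.null(alpha_level)) cfg$alpha_level <- alpha_level
  tensors <- if (is.null(data)) object$tensors else prepare_tensors(data)
  set.seed(cfg$seed + 1L)
  dd <- call_doublets_core(object$params, tensors, cfg, object$rna_index)
  if (is.null(data)) {
    # training tensors are in canonical (sorted id) order; report in input order
    pos <- object$canonical_pos
    dd$entropy <- dd$entropy[pos]
    dd$flags <- dd$flags[pos]
  }
  dd
}

#' @method print moclust_doublets
#' @export
print.moclust_doublets <- function(x, ...) {
  cat(sprintf("moclust doublet call: %d/%d cells flagged (threshold F_%.2f = %.4f)\n",
              sum(x$flags), length(x$flags), x$alpha_level, x$threshold))
  invisible(x)
}
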