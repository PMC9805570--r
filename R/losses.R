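## Objective terms: ZINB/NB likelihood, contrastive alignment, and the
## Cauchy-Schwarz divergence clustering triplet. All terms are plain
## functions of matrices so they can be unit-tested against brute-force
## oracles independently of the network code.

logspace_add <- function(a, b) {
  # log(exp(a) + exp(b)), elementwise, tolerating -Inf
  m <- pmax(a, b)
  out <- m + log1p(exp(-abs(a - b)))
  out[is.infinite(m) & m < 0] <- -Inf
  out
}

#' Zero-inflated negative binomial density
#'
#' Density of the ZINB distribution: a point mass of weight `pi` at zero
#' mixed with a negative binomial parameterized by mean `mu` and dispersion
#' `theta`. With `pi = 0` this is exactly the NB density.
#'
#' @param x Nonnegative counts.
#' @param mu Positive NB mean.
#' @param theta Positive NB dispersion (inverse overdispersion: variance is
#'   `mu + mu^2/theta`).
#' @param pi Dropout weight in `[0, 1]` (default 0).
#' @param log Return log-density?
#' @return Density values, recycled to the common length.
#' @export
dzinb <- function(x, mu, theta, pi = 0, log = FALSE) {
  n <- max(length(x), length(mu), length(theta), length(pi))
  x <- rep_len(as.numeric(x), n); mu <- rep_len(as.numeric(mu), n)
  theta <- rep_len(as.numeric(theta), n); pi <- rep_len(as.numeric(pi), n)
  if (any(mu <= 0) || any(theta <= 0)) stop("mu and theta must be positive", call. = FALSE)
  if (any(pi < 0 | pi > 1)) stop("pi must lie in [0, 1]", call. = FALSE)
  lognb <- lgamma(x + theta) - lgamma(theta) - lgamma(x + 1) +
    theta * (log(theta) - log(theta + mu)) +
    x * (log(mu) - log(theta + mu))
  logpi <- ifelse(pi > 0, log(pi), -Inf)
  out <- log1p(-pi) + lognb
  at0 <- x == 0
  out[at0] <- logspace_add(logpi[at0], out[at0])
  if (log) out else exp(out)
}

#' ZINB / NB negative log-likelihood
#'
#' Mean negative log-likelihood of raw counts under a ZINB model, the
#' reconstruction loss of each omics-specific autoencoder. With `pi = NULL`
#' (or all-zero `pi`) it reduces exactly to the NB negative log-likelihood
#' used for protein counts.
#'
#' @param x Raw count matrix (cells x features), nonnegative.
#' @param mu Positive mean matrix, same shape as `x`.
#' @param theta Positive dispersion: scalar, per-feature vector of length
#'   `ncol(x)`, or full matrix.
#' @param pi Dropout probabilities in `[0,1]`: same shapes accepted as
#'   `theta`, or `NULL` for the NB special case.
#' @param gamma Scalar loss strength multiplier (default 1).
#' @return Scalar: `gamma` times the mean over entries of the negative
#'   log-likelihood.
#' @examples
#' zinb_nll(matrix(0), matrix(1), 1, 0.5)  # -log(0.5 + 0.5 * 0.5)
#' @export
zinb_nll <- function(x, mu, theta, pi = NULL, gamma = 1) {
  x <- as.matrix(x); mu <- as.matrix(mu)
  if (!all(dim(x) == dim(mu))) stop("x and mu must share a shape", call. = FALSE)
  if (any(x < 0)) stop("x must be nonnegative", call. = FALSE)
  bad <- function(v) any(!is.finite(v))
  if (bad(mu)) stop("non-finite values in the mean head", call. = FALSE)
  if (bad(theta)) stop("non-finite values in the dispersion head", call. = FALSE)
  th <- expand_param(theta, dim(x))
  if (is.null(pi)) pi <- 0
  if (bad(pi)) stop("non-finite values in the dropout head", call. = FALSE)
  pp <- expand_param(pi, dim(x))
  gamma * mean(-dzinb(x, mu, th, pp, log = TRUE))
}

expand_param <- function(p, d) {
  if (length(p) == 1) return(matrix(p, d[1], d[2]))
  if (is.matrix(p)) { stopifnot(all(dim(p) == d)); return(p) }
  if (length(p) == d[2]) return(matrix(p, d[1], d[2], byrow = TRUE))
  stop("parameter has length ", length(p),
       "; expected scalar, per-feature vector or full matrix", call. = FALSE)
}

#' Cosine similarity
#'
#' Dot product of the l2-normalized vectors; the similarity used by the
#' contrastive alignment (directions matter, magnitudes do not, which
#' tolerates scale differences between omics).
#'
#' @param u,v Nonzero numeric vectors of equal length.
#' @return Scalar in `[-1, 1]`.
#' @export
cosine_similarity <- function(u, v) {
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) stop("cosine similarity of a zero vector is undefined", call. = FALSE)
  sum(u * v) / (nu * nv)
}

l2_normalize_rows <- function(m) {
  nr <- sqrt(rowSums(m^2))
  if (any(nr == 0)) stop("cannot l2-normalize a zero row", call. = FALSE)
  m / nr
}

#' Sample cross-cluster negative sets
#'
#' For each anchor cell, the eligible negatives are all omics views of all
#' other cells currently assigned to a different cluster; one fixed-size
#' subset is sampled uniformly without replacement per anchor (shared by all
#' of that anchor's omics pairs). Latent views are indexed flat:
#' view `(cell i, omics m)` is `(m - 1) * n + i`.
#'
#' @param hard_labels Integer cluster assignment per cell (any coding), or
#'   `NULL` for the cluster-agnostic warm-up where every other cell is
#'   eligible.
#' @param n_omics Number of omics M.
#' @param negatives_per_anchor Number of views sampled per anchor.
#' @return List of integer vectors (possibly empty), one per cell.
#' @export
sample_negative_sets <- function(hard_labels, n_omics, negatives_per_anchor = 32) {
  if (is.null(hard_labels)) stop("hard_labels or n must be given", call. = FALSE)
  n <- length(hard_labels)
  lapply(seq_len(n), function(i) {
    if (all(is.na(hard_labels))) elig <- setdiff(seq_len(n), i)
    else elig <- which(hard_labels != hard_labels[i])
    if (!length(elig)) return(integer(0))
    flat <- as.vector(outer(elig, (seq_len(n_omics) - 1L) * n, `+`))
    if (length(flat) <= negatives_per_anchor) flat
    else sample(flat, negatives_per_anchor)
  })
}

#' Contrastive alignment loss
#'
#' Normalized-temperature cross-entropy over omics pairs: for each cell the
#' positive pair is its two omics views; negatives are sampled views of
#' cells assigned to other clusters. The positive term is included in the
#' denominator, so each per-pair loss is nonnegative and an empty negative
#' set contributes exactly 0. The total is averaged over `n * M * (M - 1)`
#' ordered pairs.
#'
#' @param latents List of M cells x d latent matrices (one per omics).
#' @param negatives List of flat view indices per anchor, e.g. from
#'   [sample_negative_sets()].
#' @param tau Positive temperature.
#' @return Scalar loss. If every negative set is empty the positive-only
#'   fallback (0) is returned with a warning.
#' @export
contrastive_loss <- function(latents, negatives, tau = 0.5) {
  M <- length(latents)
  stopifnot(M >= 2, tau > 0)
  n <- nrow(latents[[1]])
  Zh <- l2_normalize_rows(do.call(rbind, latents))  # (M*n) x d
  if (all(lengths(negatives) == 0))
    warning("all negative sets are empty; contrastive loss falls back to 0")
  total <- 0
  sims <- Zh %*% t(Zh)  # full view-by-view cosine similarity
  for (u in seq_len(M)) for (v in seq_len(M)) {
    if (u == v) next
    iu <- (u - 1L) * n + seq_len(n)
    iv <- (v - 1L) * n + seq_len(n)
    pos <- exp(sims[cbind(iu, iv)] / tau)
    for (i in seq_len(n)) {
      neg <- negatives[[i]]
      if (!length(neg)) next  # l = -log(1) = 0
      den <- pos[i] + sum(exp(sims[iu[i], neg] / tau)) + sum(exp(sims[iv[i], neg] / tau))
      total <- total - log(pos[i] / den)
    }
  }
  total / (n * M * (M - 1))
}

#' Gaussian kernel matrix
#'
#' @param h Cells x d_h hidden representation.
#' @param sigma Positive bandwidth.
#' @return Symmetric n x n kernel with unit diagonal,
#'   `exp(-||h_i - h_j||^2 / (2 sigma^2))`.
#' @export
gaussian_kernel <- function(h, sigma) {
  stopifnot(sigma > 0)
  h <- as.matrix(h)
  sq <- rowSums(h^2)
  d2 <- outer(sq, sq, "+") - 2 * tcrossprod(h)
  d2[d2 < 0] <- 0
  K <- exp(-d2 / (2 * sigma^2))
  diag(K) <- 1
  (K + t(K)) / 2
}

# Cauchy-Schwarz ratio sum over column pairs of C under kernel K:
# (1/k) * sum_{i<j} (c_i' K c_j) / sqrt((c_i' K c_i)(c_j' K c_j))
cs_ratio_sum <- function(C, K, warn_empty = FALSE) {
  k <- ncol(C)
  KC <- K %*% C
  num <- crossprod(C, KC)          # k x k, entries c_i' K c_j
  q <- diag(num)
  if (warn_empty && any(colSums(abs(C)) == 0))
    warning("empty (all-zero) cluster column; it contributes 0")
  total <- 0
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    den <- q[i] * q[j]
    if (den <= 0) next
    total <- total + num[i, j] / sqrt(den)
  }
  unname(total / k)
}

#' Cluster separability/compactness loss
#'
#' First Cauchy-Schwarz divergence term of the clustering objective:
#' columns of the soft assignment matrix act as unnormalized cluster
#' densities and the Gaussian kernel on the hidden representation supplies
#' the geometry. Small values mean clusters that are compact and mutually
#' separated.
#'
#' @param A Cells x K soft assignment matrix (rows on the simplex).
#' @param K Kernel matrix from [gaussian_kernel()].
#' @return Scalar `(1/k) * sum_{i<j} (a_i' K a_j) / sqrt((a_i' K a_i)(a_j' K a_j))`;
#'   pairs with a zero denominator contribute 0.
#' @export
ddc_l1 <- function(A, K) {
  A <- as.matrix(A)
  stopifnot(nrow(A) == nrow(K))
  cs_ratio_sum(A, K, warn_empty = TRUE)
}

#' Simplex-corner closeness loss
#'
#' Second Cauchy-Schwarz term: each assignment row is compared with every
#' corner of the standard simplex through `m[a, j] = exp(-||alpha_a - e_j||)`,
#' and the same CS ratio sum is taken over the columns of `m`. Minimizing it
#' pushes assignments toward crisp one-hot rows.
#'
#' @inheritParams ddc_l1
#' @return Scalar loss.
#' @export
ddc_l2 <- function(A, K) {
  A <- as.matrix(A)
  cs_ratio_sum(simplex_corner_kernel(A), K)
}

#' Distances-to-corners map used by [ddc_l2()]
#' @param A Cells x K soft assignment matrix.
#' @return Cells x K matrix with entries `exp(-||alpha_a - e_j||_2)`.
#' @export
simplex_corner_kernel <- function(A) {
  k <- ncol(A)
  # ||alpha - e_j||^2 = ||alpha||^2 - 2 alpha_j + 1
  d2 <- rowSums(A^2) - 2 * A + 1
  d2[d2 < 0] <- 0
  exp(-sqrt(d2))
}

#' Assignment-orthogonality loss
#'
#' Third clustering term: the mean of the strictly upper-triangular entries
#' of `A' A`. Zero iff distinct clusters claim disjoint sets of cells.
#'
#' @param A Cells x K soft assignment matrix.
#' @return Scalar, `sum(triu(A'A)) / (K (K - 1) / 2)`.
#' @export
ddc_l3 <- function(A) {
  A <- as.matrix(A)
  k <- ncol(A)
  if (k < 2) return(0)
  S <- crossprod(A)
  sum(S[upper.tri(S)]) / (k * (k - 1) / 2)
}

#' Total clustering loss
#'
#' Sum of the three divergence-based terms [ddc_l1()], [ddc_l2()] and
#' [ddc_l3()].
#'
#' @inheritParams ddc_l1
#' @return Scalar loss.
#' @export
cluster_loss <- function(A, K) ddc_l1(A, K) + ddc_l2(A, K) + ddc_l3(A)

#' Combined training objective
#'
#' `zinb + cluster + delta * min(w) * contrastive`: the contrastive strength
#' is automatically modulated by the weight of the least informative omics.
#'
#' @param zinb_term Summed gamma-weighted ZINB/NB reconstruction loss.
#' @param cluster_term Clustering loss.
#' @param contrastive_term Contrastive alignment loss.
#' @param w Fusion weight vector on the simplex.
#' @param delta Contrastive strength hyperparameter.
#' @return Scalar loss.
#' @export
total_loss <- function(zinb_term, cluster_term, contrastive_term, w, delta) {
  zinb_term + cluster_term + delta * min(w) * contrastive_term
}

#' Pretraining objective
#'
#' `gamma * zinb + L1 + delta * min(w) * contrastive`: during pretraining
#' only the separability term of the clustering triplet is active.
#'
#' @param zinb_term Summed ZINB/NB reconstruction loss (unweighted).
#' @param l1_term [ddc_l1()] value.
#' @param contrastive_term Contrastive alignment loss.
#' @param w Fusion weight vector.
#' @param gamma Pretraining reconstruction strength.
#' @param delta Contrastive strength.
#' @return Scalar loss.
#' @export
pretrain_loss <- function(zinb_term, l1_term, contrastive_term, w, gamma, delta) {
  gamma * zinb_term + l1_term + delta * min(w) * contrastive_term
}
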