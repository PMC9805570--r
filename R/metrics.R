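#' Normalized mutual information
#'
#' Mutual information between two labelings normalized by the arithmetic
#' mean of their entropies (the common single-cell benchmarking
#' normalization). Invariant to relabeling of either partition.
#'
#' @param labels_true,labels_pred Equal-length label vectors (any atomic
#'   type); `NA` pairs are dropped.
#' @return NMI in `[0, 1]`; 1 for identical partitions. Two one-cluster
#'   partitions (zero entropy) return 1 by convention.
#' @export
nmi <- function(labels_true, labels_pred) {
  if (length(labels_true) != length(labels_pred))
    stop("label vectors must have equal length", call. = FALSE)
  ok <- !is.na(labels_true) & !is.na(labels_pred)
  ct <- table(labels_true[ok], labels_pred[ok])
  n <- sum(ct)
  pij <- ct / n
  pi_ <- rowSums(pij); pj_ <- colSums(pij)
  mi <- sum(ifelse(pij > 0, pij * log(pij / outer(pi_, pj_)), 0))
  h <- function(p) -sum(ifelse(p > 0, p * log(p), 0))
  denom <- (h(pi_) + h(pj_)) / 2
  if (denom == 0) return(1)
  max(0, min(1, mi / denom))
}

#' Adjusted Rand index
#'
#' Pair-counting agreement between two partitions, adjusted for chance:
#' 0 in expectation for independent labelings, 1 for identical partitions.
#'
#' @inheritParams nmi
#' @return ARI in `[-1, 1]`.
#' @export
ari <- function(labels_true, labels_pred) {
  if (length(labels_true) != length(labels_pred))
    stop("label vectors must have equal length", call. = FALSE)
  ok <- !is.na(labels_true) & !is.na(labels_pred)
  ct <- table(labels_true[ok], labels_pred[ok])
  n <- sum(ct)
  ch2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(ch2(ct))
  sum_i <- sum(ch2(rowSums(ct)))
  sum_j <- sum(ch2(colSums(ct)))
  expected <- sum_i * sum_j / ch2(n)
  max_index <- (sum_i + sum_j) / 2
  if (max_index == expected) return(0)
  (sum_ij - expected) / (max_index - expected)
}

#' Clustering metric report
#'
#' @inheritParams nmi
#' @return A `metric_report` list: `nmi`, `ari`, `n_cells`, `K_true`,
#'   `K_pred` and the confusion `table`.
#' @export
evaluate_clustering <- function(labels_true, labels_pred) {
  ok <- !is.na(labels_true) & !is.na(labels_pred)
  structure(list(nmi = nmi(labels_true, labels_pred),
                 ari = ari(labels_true, labels_pred),
                 n_cells = sum(ok),
                 K_true = length(unique(labels_true[ok])),
                 K_pred = length(unique(labels_pred[ok])),
                 table = table(true = labels_true[ok], pred = labels_pred[ok])),
            class = "metric_report")
}

#' @method print metric_report
#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf("clustering vs reference (n = %d): NMI = %.4f, ARI = %.4f (K_true = %d, K_pred = %d)\n",
              x$n_cells, x$nmi, x$ari, x$K_true, x$K_pred))
  invisible(x)
}
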