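#' Select highly variable features
#'
#' Optional feature selection ahead of [multiomics_dataset()]: keeps the
#' `n_top` features with the largest scaled dispersion. Dispersion is
#' variance over mean of the depth-normalized counts, standardized within
#' ten mean-abundance bins so that highly expressed features do not
#' dominate. Off by default throughout the package; selection changes which
#' features feed the encoder, never the stored raw counts of the kept
#' features.
#'
#' @param raw An [omics_counts()] object.
#' @param n_top Number of features to keep (capped at the feature count).
#' @return An [omics_counts()] with the selected features, in decreasing
#'   scaled-dispersion order.
#' @export
select_hvg <- function(raw, n_top = 2000) {
  validate_omics_counts(raw)
  m <- as.matrix(raw$matrix)
  lib <- rowSums(m)
  if (any(lib == 0)) stop("remove zero-count cells first", call. = FALSE)
  norm <- m * (stats::median(lib) / lib)
  mu <- colMeans(norm)
  v <- apply(norm, 2, stats::var)
  disp <- ifelse(mu > 0, v / mu, 0)
  # standardize dispersion within mean-abundance bins; keep bins wide
  # enough (>= ~20 features) that co-varying signal genes cannot cancel
  # each other inside a bin
  nbins <- max(1L, min(10L, ncol(m) %/% 20L))
  bins <- cut(rank(mu, ties.method = "first"), breaks = nbins, labels = FALSE)
  z <- disp
  for (b in unique(bins)) {
    ix <- bins == b
    s <- stats::sd(disp[ix])
    z[ix] <- if (is.na(s) || s < 1e-12) 0 else (disp[ix] - mean(disp[ix])) / s
  }
  keep <- order(z, decreasing = TRUE)[seq_len(min(n_top, ncol(m)))]
  omics_counts(raw$matrix[, keep, drop = FALSE], raw$omics_kind,
               cell_ids = raw$cell_ids,
               feature_ids = raw$feature_ids[keep])
}
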