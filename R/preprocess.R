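#' Preprocess RNA or gene-activity counts
#'
#' Depth-normalizes each cell to the median library size, applies `log1p`,
#' and scales every feature to zero mean / unit variance. Size factors (cell
#' library size divided by the median library size) are retained: the raw
#' counts together with the size factors feed the ZINB reconstruction loss,
#' while the normalized matrix feeds the encoder.
#'
#' @param raw An [omics_counts()] object of kind `"rna"` or `"atac_activity"`.
#' @return A `preprocessed_omics` object: list with `normalized` (dense
#'   cells x features matrix), `size_factors` (positive, one per cell) and
#'   `source` (the untouched raw counts).
#' @examples
#' x <- omics_counts(matrix(rpois(60, 5) + 1, 6, 10), "rna")
#' p <- preprocess_rna(x)
#' range(p$size_factors)
#' @export
preprocess_rna <- function(raw) {
  validate_omics_counts(raw)
  if (!raw$omics_kind %in% c("rna", "atac_activity"))
    stop("preprocess_rna expects rna or atac_activity counts, got ", raw$omics_kind,
         call. = FALSE)
  lib <- as.numeric(Matrix::rowSums(raw$matrix))
  if (any(lib == 0))
    stop("cells with zero total counts: ",
         paste(utils::head(raw$cell_ids[lib == 0], 5), collapse = ", "),
         " (filter them out first, e.g. with filter_zero_cells())", call. = FALSE)
  med <- stats::median(lib)
  sf <- lib / med
  norm <- as.matrix(raw$matrix) * (med / lib)  # recycles down columns
  norm <- log1p(norm)
  norm <- scale_features(norm)
  structure(list(normalized = norm, size_factors = sf, source = raw),
            class = "preprocessed_omics")
}

#' Preprocess protein (ADT) counts
#'
#' Applies `log1p`, centers each cell at its mean log-count (a CLR-style
#' per-cell normalization that removes cell-level capture differences), and
#' scales every feature to zero mean / unit variance. Protein counts are
#' modelled with a plain negative binomial decoder, so the size factors are
#' fixed at 1.
#'
#' @param raw An [omics_counts()] object of kind `"protein"`.
#' @return A `preprocessed_omics` object (see [preprocess_rna()]).
#' @export
preprocess_protein <- function(raw) {
  validate_omics_counts(raw)
  if (raw$omics_kind != "protein")
    stop("preprocess_protein expects protein counts, got ", raw$omics_kind,
         call. = FALSE)
  lib <- as.numeric(Matrix::rowSums(raw$matrix))
  if (any(lib == 0))
    stop("cells with zero total counts: ",
         paste(utils::head(raw$cell_ids[lib == 0], 5), collapse = ", "),
         call. = FALSE)
  norm <- log1p(as.matrix(raw$matrix))
  norm <- norm - rowMeans(norm)
  norm <- scale_features(norm)
  structure(list(normalized = norm,
                 size_factors = rep(1, nrow(norm)),
                 source = raw),
            class = "preprocessed_omics")
}

# Per-feature z-scoring with a zero-variance guard: constant columns map to 0.
scale_features <- function(m) {
  mu <- colMeans(m)
  sdv <- apply(m, 2, stats::sd)
  sdv[is.na(sdv)] <- 0  # single-cell input: no variance estimate
  const <- sdv < 1e-12
  sdv[const] <- 1
  out <- sweep(sweep(m, 2, mu, "-"), 2, sdv, "/")
  out[, const] <- 0
  out
}

#' @method print preprocessed_omics
#' @export
print.preprocessed_omics <- function(x, ...) {
  cat(sprintf("preprocessed_omics [%s]: %d cells x %d features\n",
              x$source$omics_kind, nrow(x$normalized), ncol(x$normalized)))
  invisible(x)
}

#' Drop cells with zero counts in any omics
#'
#' Cells whose library size is zero in at least one omics cannot be
#' preprocessed; this removes them consistently from every omics.
#'
#' @param omics_list List of [omics_counts()] objects sharing cell order.
#' @return The list with zero-count cells removed from every omics.
#' @export
filter_zero_cells <- function(omics_list) {
  keep <- Reduce(`&`, lapply(omics_list, function(o)
    as.numeric(Matrix::rowSums(o$matrix)) > 0))
  lapply(omics_list, function(o)
    omics_counts(o$matrix[keep, , drop = FALSE], o$omics_kind,
                 cell_ids = o$cell_ids[keep], feature_ids = o$feature_ids))
}

#' Assemble a cell-aligned multi-omics dataset
#'
#' Bundles two or more preprocessed omics views of the same cells. Raw
#' [omics_counts()] inputs are preprocessed automatically according to their
#' kind ([preprocess_rna()] for rna/atac_activity, [preprocess_protein()] for
#' protein).
#'
#' @param omics List of `preprocessed_omics` and/or [omics_counts()] objects.
#'   All must share an identical cell id sequence.
#' @param labels Optional per-cell ground-truth labels (character/factor),
#'   used only for evaluation.
#' @return A `multiomics_dataset`: list with `omics` (list of
#'   `preprocessed_omics`), `cell_ids`, `labels`.
#' @export
multiomics_dataset <- function(omics, labels = NULL) {
  if (length(omics) < 2)
    stop("a multiomics_dataset needs at least two omics", call. = FALSE)
  omics <- lapply(omics, function(o) {
    if (inherits(o, "preprocessed_omics")) return(o)
    if (inherits(o, "omics_counts"))
      return(if (o$omics_kind == "protein") preprocess_protein(o) else preprocess_rna(o))
    stop("each omics must be an omics_counts or preprocessed_omics", call. = FALSE)
  })
  ids <- omics[[1]]$source$cell_ids
  for (o in omics[-1])
    if (!identical(o$source$cell_ids, ids))
      stop("all omics must share an identical cell_id sequence", call. = FALSE)
  if (!is.null(labels)) {
    labels <- as.character(labels)
    if (length(labels) != length(ids))
      stop("labels length ", length(labels), " != number of cells ", length(ids),
           call. = FALSE)
  }
  structure(list(omics = omics, cell_ids = ids, labels = labels),
            class = "multiomics_dataset")
}

#' @method print multiomics_dataset
#' @export
print.multiomics_dataset <- function(x, ...) {
  cat(sprintf("multiomics_dataset: %d cells, %d omics (%s)%s\n",
              length(x$cell_ids), length(x$omics),
              paste(vapply(x$omics, function(o) o$source$omics_kind, ""), collapse = " + "),
              if (is.null(x$labels)) "" else ", labelled"))
  invisible(x)
}

#' Subset a multi-omics dataset by cell
#'
#' @param x A `multiomics_dataset`.
#' @param i Logical or integer index over cells.
#' @param ... Unused.
#' @return The subsetted `multiomics_dataset` (raw counts, normalized views,
#'   size factors and labels all subsetted consistently).
#' @method [ multiomics_dataset
#' @export
`[.multiomics_dataset` <- function(x, i, ...) {
  omics <- lapply(x$omics, function(o) {
    src <- omics_counts(o$source$matrix[i, , drop = FALSE], o$source$omics_kind,
                        cell_ids = o$source$cell_ids[i],
                        feature_ids = o$source$feature_ids)
    structure(list(normalized = o$normalized[i, , drop = FALSE],
                   size_factors = o$size_factors[i],
                   source = src),
              class = "preprocessed_omics")
  })
  structure(list(omics = omics, cell_ids = x$cell_ids[i],
                 labels = if (is.null(x$labels)) NULL else x$labels[i]),
            class = "multiomics_dataset")
}
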