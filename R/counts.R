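#' Per-omics count matrix container
#'
#' An `omics_counts` object holds one omics' raw cell-by-feature count matrix
#' together with its identity metadata. It is the entry point for every
#' downstream step: preprocessing, model fitting and simulation all consume
#' or produce `omics_counts`.
#'
#' @param matrix A cells x features matrix of nonnegative counts. Dense base
#'   matrices and sparse [Matrix::dgCMatrix-class] matrices are both accepted;
#'   sparsity is preserved.
#' @param omics_kind One of `"rna"`, `"protein"`, `"atac_activity"`. RNA and
#'   protein counts must be integer-valued; ATAC gene-activity matrices are
#'   integer sums of peak counts by construction.
#' @param cell_ids Character vector of unique cell identifiers, one per row.
#'   Defaults to existing rownames, or `cell_1 ... cell_n`.
#' @param feature_ids Character vector of unique feature identifiers, one per
#'   column. Defaults to existing colnames, or `feat_1 ... feat_p`.
#'
#' @return An object of class `omics_counts`: a list with elements `matrix`,
#'   `omics_kind`, `cell_ids`, `feature_ids`.
#' @examples
#' x <- omics_counts(matrix(rpois(12, 5), 3, 4), "rna")
#' dim(x$matrix)
#' @export
omics_counts <- function(matrix, omics_kind = c("rna", "protein", "atac_activity"),
                         cell_ids = NULL, feature_ids = NULL) {
  omics_kind <- match.arg(omics_kind)
  if (!(is.matrix(matrix) || methods::is(matrix, "Matrix")))
    stop("`matrix` must be a base matrix or a Matrix::Matrix", call. = FALSE)
  if (is.null(cell_ids)) {
    cell_ids <- if (!is.null(rownames(matrix))) rownames(matrix) else
      sprintf("cell_%d", seq_len(nrow(matrix)))
  }
  if (is.null(feature_ids)) {
    feature_ids <- if (!is.null(colnames(matrix))) colnames(matrix) else
      sprintf("feat_%d", seq_len(ncol(matrix)))
  }
  cell_ids <- as.character(cell_ids)
  feature_ids <- as.character(feature_ids)
  obj <- structure(list(matrix = matrix, omics_kind = omics_kind,
                        cell_ids = cell_ids, feature_ids = feature_ids),
                   class = "omics_counts")
  validate_omics_counts(obj)
  obj
}

#' Validate an omics_counts object
#'
#' Checks the container invariants: nonnegative entries, integer counts for
#' rna/protein, unique identifiers, and dimension agreement.
#'
#' @param x An `omics_counts` object.
#' @return `x`, invisibly, if valid; otherwise an error is thrown.
#' @export
validate_omics_counts <- function(x) {
  stopifnot(inherits(x, "omics_counts"))
  m <- x$matrix
  if (nrow(m) != length(x$cell_ids))
    stop("matrix has ", nrow(m), " rows but ", length(x$cell_ids), " cell_ids", call. = FALSE)
  if (ncol(m) != length(x$feature_ids))
    stop("matrix has ", ncol(m), " columns but ", length(x$feature_ids), " feature_ids", call. = FALSE)
  if (anyDuplicated(x$cell_ids))
    stop("duplicate cell_ids: ", paste(utils::head(x$cell_ids[duplicated(x$cell_ids)], 3), collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(x$feature_ids))
    stop("duplicate feature_ids: ", paste(utils::head(x$feature_ids[duplicated(x$feature_ids)], 3), collapse = ", "),
         call. = FALSE)
  vals <- if (methods::is(m, "sparseMatrix")) m@x else as.vector(m)
  if (length(vals) && min(vals) < 0)
    stop("count matrix contains negative entries (min = ", min(vals), ")", call. = FALSE)
  if (x$omics_kind %in% c("rna", "protein") && length(vals) &&
      max(abs(vals - round(vals))) > 1e-8)
    stop(x$omics_kind, " counts must be integer-valued", call. = FALSE)
  invisible(x)
}

#' @method print omics_counts
#' @export
print.omics_counts <- function(x, ...) {
  cat(sprintf("omics_counts [%s]: %d cells x %d features (%s)\n",
              x$omics_kind, nrow(x$matrix), ncol(x$matrix),
              if (methods::is(x$matrix, "sparseMatrix")) "sparse" else "dense"))
  invisible(x)
}

#' @method dim omics_counts
#' @export
dim.omics_counts <- function(x) dim(x$matrix)

#' Read a count matrix from disk
#'
#' Reads one omics' counts from the common single-cell exchange formats and
#' returns them in cells x features orientation regardless of the on-disk
#' orientation.
#'
#' * `mtx`: a CellRanger-style triplet, either a directory containing
#'   `matrix.mtx`, `barcodes.tsv` and `features.tsv` (features in rows on
#'   disk, as CellRanger writes them) or a path to the `.mtx` file with those
#'   siblings. Sparsity is preserved.
#' * `csv`: a dense CSV/TSV with cells in rows, feature ids in the header and
#'   cell ids in the first column.
#' * `h5ad`: an AnnData file; `X` may be dense or CSR/CSC. Requires the
#'   rhdf5 package.
#'
#' @param path File or directory path.
#' @param format One of `"mtx"`, `"csv"`, `"h5ad"`.
#' @param omics_kind Passed to [omics_counts()].
#' @return An [omics_counts()] object.
#' @export
load_counts <- function(path, format = c("mtx", "csv", "h5ad"),
                        omics_kind = c("rna", "protein", "atac_activity")) {
  format <- match.arg(format)
  omics_kind <- match.arg(omics_kind)
  switch(format,
         mtx = read_counts_mtx(path, omics_kind),
         csv = read_counts_csv(path, omics_kind),
         h5ad = read_counts_h5ad(path, omics_kind))
}

read_counts_mtx <- function(path, omics_kind) {
  if (dir.exists(path)) {
    mtx <- file.path(path, "matrix.mtx")
    bc <- file.path(path, "barcodes.tsv")
    ft <- file.path(path, "features.tsv")
  } else {
    mtx <- path
    bc <- file.path(dirname(path), "barcodes.tsv")
    ft <- file.path(dirname(path), "features.tsv")
  }
  for (f in c(mtx, bc, ft)) if (!file.exists(f))
    stop("missing file: ", f, call. = FALSE)
  m <- tryCatch(Matrix::readMM(mtx),
                error = function(e) stop("cannot parse MatrixMarket file ", mtx,
                                         ": ", conditionMessage(e), call. = FALSE))
  barcodes <- readLines(bc)
  feats <- utils::read.table(ft, sep = "\t", header = FALSE,
                             stringsAsFactors = FALSE)[[1]]
  if (methods::is(m, "nMatrix")) m <- m * 1  # pattern matrix (no stored values)
  # CellRanger stores features x cells; transpose to cells x features
  m <- Matrix::t(methods::as(m, "CsparseMatrix"))
  if (nrow(m) != length(barcodes) || ncol(m) != length(feats))
    stop(sprintf("MTX shape %dx%d does not match %d barcodes x %d features",
                 nrow(m), ncol(m), length(barcodes), length(feats)), call. = FALSE)
  omics_counts(m, omics_kind, cell_ids = barcodes, feature_ids = feats)
}

read_counts_csv <- function(path, omics_kind) {
  sep <- if (grepl("\\.tsv(\\.gz)?$", path)) "\t" else ","
  df <- tryCatch(utils::read.table(path, sep = sep, header = TRUE,
                                   row.names = 1, check.names = FALSE),
                 error = function(e) stop("cannot parse delimited file ", path,
                                          ": ", conditionMessage(e), call. = FALSE))
  m <- as.matrix(df)
  if (!is.numeric(m)) stop("non-numeric entries in ", path, call. = FALSE)
  omics_counts(m, omics_kind, cell_ids = rownames(df), feature_ids = colnames(df))
}

read_counts_h5ad <- function(path, omics_kind) {
  if (!requireNamespace("rhdf5", quietly = TRUE))
    stop("h5ad support requires the rhdf5 package", call. = FALSE)
  if (!file.exists(path)) stop("missing file: ", path, call. = FALSE)
  ls <- rhdf5::h5ls(path)
  obs <- as.character(rhdf5::h5read(path, "obs/_index"))
  var <- as.character(rhdf5::h5read(path, "var/_index"))
  x_entries <- ls[ls$group == "/X", , drop = FALSE]
  if (nrow(x_entries) > 0) {
    # sparse X stored as a group of data/indices/indptr
    data <- as.numeric(rhdf5::h5read(path, "X/data"))
    indices <- as.integer(rhdf5::h5read(path, "X/indices"))
    indptr <- as.integer(rhdf5::h5read(path, "X/indptr"))
    enc <- tryCatch(rhdf5::h5readAttributes(path, "X")$`encoding-type`,
                    error = function(e) NULL)
    if (is.null(enc)) enc <- "csr_matrix"
    if (grepl("csr", enc)) {
      # anndata CSR: rows = obs (cells)
      m <- Matrix::sparseMatrix(j = indices + 1L, p = indptr, x = data,
                                dims = c(length(obs), length(var)),
                                repr = "R")
      m <- methods::as(m, "CsparseMatrix")
    } else {
      m <- Matrix::sparseMatrix(i = indices + 1L, p = indptr, x = data,
                                dims = c(length(obs), length(var)))
    }
  } else {
    m <- rhdf5::h5read(path, "X")
    # HDF5 is row-major; rhdf5 returns the transposed dense array
    m <- t(m)
    if (nrow(m) != length(obs)) m <- t(m)
  }
  omics_counts(m, omics_kind, cell_ids = obs, feature_ids = var)
}

#' Write a count matrix to disk
#'
#' Inverse of [load_counts()]; `load_counts(write_counts(x, ...))` reproduces
#' `x` exactly for all three formats.
#'
#' @param x An [omics_counts()] object.
#' @param path Target path: a directory for `mtx`, a file for `csv`/`h5ad`.
#' @param format One of `"mtx"`, `"csv"`, `"h5ad"`.
#' @return `path`, invisibly.
#' @export
write_counts <- function(x, path, format = c("mtx", "csv", "h5ad")) {
  format <- match.arg(format)
  validate_omics_counts(x)
  if (format == "mtx") {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    m <- methods::as(methods::as(x$matrix, "CsparseMatrix"), "generalMatrix")
    Matrix::writeMM(Matrix::t(m), file.path(path, "matrix.mtx"))
    writeLines(x$cell_ids, file.path(path, "barcodes.tsv"))
    writeLines(x$feature_ids, file.path(path, "features.tsv"))
  } else if (format == "csv") {
    m <- as.matrix(x$matrix)
    dimnames(m) <- list(x$cell_ids, x$feature_ids)
    utils::write.csv(m, path)
  } else {
    if (!requireNamespace("rhdf5", quietly = TRUE))
      stop("h5ad support requires the rhdf5 package", call. = FALSE)
    if (file.exists(path)) unlink(path)
    rhdf5::h5createFile(path)
    m <- methods::as(methods::as(x$matrix, "CsparseMatrix"), "generalMatrix")
    mr <- methods::as(m, "RsparseMatrix")
    rhdf5::h5createGroup(path, "X")
    rhdf5::h5write(mr@x, path, "X/data")
    rhdf5::h5write(mr@j, path, "X/indices")
    rhdf5::h5write(mr@p, path, "X/indptr")
    rhdf5::h5createGroup(path, "obs")
    rhdf5::h5createGroup(path, "var")
    rhdf5::h5write(x$cell_ids, path, "obs/_index")
    rhdf5::h5write(x$feature_ids, path, "var/_index")
    # AnnData on-disk schema attributes so standard readers accept the file
    fid <- rhdf5::H5Fopen(path)
    wattr <- function(obj, name, value, scalar = TRUE) {
      rhdf5::h5writeAttribute(value, obj, name,
                              variableLengthString = is.character(value),
                              asScalar = scalar)
    }
    gx <- rhdf5::H5Gopen(fid, "X")
    wattr(gx, "encoding-type", "csr_matrix")
    wattr(gx, "encoding-version", "0.1.0")
    wattr(gx, "shape", as.integer(dim(m)), scalar = FALSE)
    rhdf5::H5Gclose(gx)
    for (grp in c("obs", "var")) {
      gg <- rhdf5::H5Gopen(fid, grp)
      wattr(gg, "encoding-type", "dataframe")
      wattr(gg, "encoding-version", "0.2.0")
      wattr(gg, "_index", "_index")
      # zero-length column-order (no data columns): needs the low-level
      # API, h5writeAttribute cannot create empty string attributes
      tid <- rhdf5::H5Tcopy("H5T_C_S1"); rhdf5::H5Tset_size(tid, NULL)
      sid <- rhdf5::H5Screate_simple(0L)
      aid <- rhdf5::H5Acreate(gg, "column-order", tid, sid)
      rhdf5::H5Aclose(aid); rhdf5::H5Sclose(sid)
      rhdf5::H5Gclose(gg)
      gi <- rhdf5::H5Dopen(fid, paste0(grp, "/_index"))
      wattr(gi, "encoding-type", "string-array")
      wattr(gi, "encoding-version", "0.2.0")
      rhdf5::H5Dclose(gi)
    }
    rhdf5::H5Fclose(fid)
    rhdf5::h5closeAll()
  }
  invisible(path)
}
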