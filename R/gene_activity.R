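#' Genomic interval
#'
#' Minimal BED-convention interval record (0-based, half-open) used to
#' describe ATAC peaks and gene bodies.
#'
#' @param chrom Chromosome name.
#' @param start 0-based inclusive start.
#' @param end Exclusive end; must satisfy `start < end`.
#' @param strand One of `"+"`, `"-"`, `"."`.
#' @return A `genomic_interval` list.
#' @export
genomic_interval <- function(chrom, start, end, strand = ".") {
  if (!is.character(chrom) || length(chrom) != 1)
    stop("chrom must be a single string", call. = FALSE)
  start <- as.numeric(start); end <- as.numeric(end)
  if (is.na(start) || is.na(end) || start >= end)
    stop(sprintf("malformed interval %s:%s-%s (need start < end)", chrom, start, end),
         call. = FALSE)
  if (!strand %in% c("+", "-", "."))
    stop("strand must be one of '+', '-', '.'", call. = FALSE)
  structure(list(chrom = chrom, start = start, end = end, strand = strand),
            class = "genomic_interval")
}

intervals_to_granges <- function(ints) {
  chrom <- vapply(ints, function(x) x$chrom, "")
  start <- vapply(ints, function(x) x$start, 0)
  end <- vapply(ints, function(x) x$end, 0)
  strand <- vapply(ints, function(x) x$strand, "")
  strand[strand == "."] <- "*"
  # BED 0-based half-open -> GRanges 1-based closed
  GenomicRanges::GRanges(chrom, IRanges::IRanges(start + 1, end), strand = strand)
}

#' Convert ATAC peak counts to a gene-activity matrix
#'
#' Estimates per-gene transcriptional activity from chromatin accessibility:
#' for every gene, peak counts are summed over all peaks overlapping (by at
#' least 1 bp) the union of the gene body and the 2 kb region upstream of the
#' TSS. Upstream is strand-aware: lower coordinates for `+` genes, higher for
#' `-` genes. A peak overlapping two gene windows contributes its counts to
#' both. The result is treated downstream exactly like RNA counts.
#'
#' @param peaks An [omics_counts()] object whose features are ATAC peaks
#'   (cells x peaks).
#' @param peak_coords List of [genomic_interval()] of length `ncol(peaks)`.
#' @param genes Named list of [genomic_interval()] (names are gene ids) with
#'   strand `"+"` or `"-"`.
#' @param upstream Width in bp of the promoter window upstream of the TSS
#'   (default 2000).
#' @return An [omics_counts()] of kind `"atac_activity"`, cells x genes;
#'   entries are integer sums of peak counts. Genes with no overlapping peak
#'   (including genes on chromosomes absent from the peak set) get an
#'   all-zero column.
#' @export
gene_activity_from_peaks <- function(peaks, peak_coords, genes, upstream = 2000) {
  validate_omics_counts(peaks)
  if (length(peak_coords) != ncol(peaks$matrix))
    stop("peak_coords length ", length(peak_coords), " != number of peak features ",
         ncol(peaks$matrix), call. = FALSE)
  if (is.null(names(genes)))
    stop("genes must be a named list (names are gene ids)", call. = FALSE)
  strands <- vapply(genes, function(g) g$strand, "")
  if (!all(strands %in% c("+", "-")))
    stop("gene strands must be '+' or '-'", call. = FALSE)

  peak_gr <- intervals_to_granges(peak_coords)
  gene_gr <- intervals_to_granges(genes)
  # share one seqlevel universe: a chromosome present only in the genes (or
  # only in the peaks) simply yields no overlaps
  all_chr <- union(GenomeInfoDb::seqlevels(peak_gr), GenomeInfoDb::seqlevels(gene_gr))
  GenomeInfoDb::seqlevels(peak_gr) <- all_chr
  GenomeInfoDb::seqlevels(gene_gr) <- all_chr
  # extend the gene body by the promoter window on the strand-appropriate side
  win <- GenomicRanges::punion(
    gene_gr,
    GenomicRanges::flank(gene_gr, width = upstream, start = TRUE))
  hits <- GenomicRanges::findOverlaps(peak_gr, win, minoverlap = 1L,
                                      ignore.strand = TRUE)
  n_genes <- length(genes)
  ind <- Matrix::sparseMatrix(i = S4Vectors::queryHits(hits),
                              j = S4Vectors::subjectHits(hits),
                              x = 1, dims = c(length(peak_coords), n_genes))
  activity <- peaks$matrix %*% ind
  activity <- methods::as(activity, "CsparseMatrix")
  dimnames(activity) <- list(peaks$cell_ids, names(genes))
  omics_counts(activity, "atac_activity",
               cell_ids = peaks$cell_ids, feature_ids = names(genes))
}

#' Read BED intervals as genomic_interval records
#'
#' @param path Path to a BED file (>= 3 columns; column 6 used as strand when
#'   present).
#' @return Named list of [genomic_interval()]; names come from the BED name
#'   column when present, else `interval_1 ...`.
#' @export
read_bed_intervals <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE)
  n <- nrow(df)
  nm <- if (ncol(df) >= 4) as.character(df[[4]]) else sprintf("interval_%d", seq_len(n))
  strand <- if (ncol(df) >= 6) as.character(df[[6]]) else rep(".", n)
  out <- lapply(seq_len(n), function(i)
    genomic_interval(df[[1]][i], df[[2]][i], df[[3]][i], strand[i]))
  names(out) <- nm
  out
}

#' Read gene bodies from a GTF file
#'
#' Extracts `gene` records (one interval per gene) via rtracklayer and
#' converts them to BED-convention [genomic_interval()] records.
#'
#' @param path Path to a GTF/GFF file.
#' @return Named list of [genomic_interval()] keyed by gene id.
#' @export
read_gtf_genes <- function(path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE))
    stop("GTF support requires the rtracklayer package", call. = FALSE)
  gr <- rtracklayer::import(path)
  gr <- gr[gr$type == "gene"]
  ids <- if (!is.null(gr$gene_id)) gr$gene_id else as.character(seq_along(gr))
  out <- lapply(seq_along(gr), function(i)
    genomic_interval(as.character(GenomicRanges::seqnames(gr)[i]),
                     GenomicRanges::start(gr)[i] - 1,  # back to 0-based
                     GenomicRanges::end(gr)[i],
                     as.character(GenomicRanges::strand(gr)[i])))
  names(out) <- ids
  out
}
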