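test_that("count containers enforce their invariants", {
  x <- tiny_counts()
  expect_s3_class(validate_omics_counts(x), "omics_counts")
  expect_equal(dim(x), c(5L, 4L))

  m <- x$matrix; m[2, 2] <- -1
  expect_error(omics_counts(m, "rna"), "negative")
  m2 <- x$matrix * 1.0; m2[1, 1] <- 2.5
  expect_error(omics_counts(m2, "rna"), "integer")
  expect_silent(omics_counts(m2, "atac_activity"))  # activity sums may be validated laxly
  expect_error(omics_counts(x$matrix, "rna", cell_ids = rep("a", 5)), "duplicate")
})

test_that("mtx, csv and h5ad round-trip exactly, including all-zero sparse files", {
  set.seed(7)
  m <- Matrix::rsparsematrix(6, 9, density = 0.3)
  m@x <- abs(round(m@x * 10))
  m <- Matrix::drop0(m)
  x <- omics_counts(m, "rna", cell_ids = sprintf("bc%02d", 1:6),
                    feature_ids = sprintf("g%02d", 1:9))
  for (fmt in c("mtx", "csv", "h5ad")) {
    path <- file.path(tempdir(), paste0("rt_", fmt, if (fmt != "mtx") paste0(".", fmt)))
    write_counts(x, path, fmt)
    y <- load_counts(path, fmt, "rna")
    expect_equal(as.matrix(y$matrix), as.matrix(x$matrix), ignore_attr = TRUE,
                 label = fmt)
    expect_identical(y$cell_ids, x$cell_ids)
    expect_identical(y$feature_ids, x$feature_ids)
    if (fmt == "mtx") expect_s4_class(y$matrix, "sparseMatrix")
  }

  # MTX with zero stored entries -> all-zero matrix of the declared shape
  z <- omics_counts(Matrix::sparseMatrix(i = integer(0), j = integer(0),
                                         x = numeric(0), dims = c(4, 3)), "rna")
  p0 <- file.path(tempdir(), "zeromtx")
  write_counts(z, p0, "mtx")
  z2 <- load_counts(p0, "mtx", "rna")
  expect_equal(dim(z2), c(4L, 3L))
  expect_equal(sum(z2$matrix), 0)
})

test_that("a CSV containing a negative value is rejected with a validation error", {
  p <- file.path(tempdir(), "neg.csv")
  writeLines(c("id,g1,g2", "c1,3,2", "c2,-1,0"), p)
  expect_error(load_counts(p, "csv", "rna"), "negative")
})

test_that("rna preprocessing computes median-based size factors and scales features", {
  # library sizes 100, 200, 400 -> size factors 0.5, 1, 2
  m <- rbind(c(60, 40, 0), c(120, 60, 20), c(200, 100, 100))
  x <- omics_counts(m, "rna")
  p <- preprocess_rna(x)
  expect_equal(p$size_factors, c(0.5, 1, 2))
  # per-feature scaling: zero mean, unit variance (or exactly 0 for constants)
  expect_equal(unname(colMeans(p$normalized)), rep(0, 3), tolerance = 1e-12)
  expect_true(all(abs(apply(p$normalized, 2, sd) - 1) < 1e-12 |
                    apply(p$normalized, 2, sd) < 1e-12))
  # raw counts untouched
  expect_identical(p$source$matrix, m)

  # identical library sizes -> all size factors 1
  eq <- omics_counts(matrix(5L, 4, 3), "rna")
  expect_equal(preprocess_rna(eq)$size_factors, rep(1, 4))
  # feature constant after depth normalization -> all-zero scaled column
  # (equal library sizes keep the raw-constant feature constant)
  cf <- omics_counts(cbind(c(5L, 5L, 5L), c(3L, 4L, 1L), c(2L, 1L, 4L)), "rna")
  expect_equal(unname(preprocess_rna(cf)$normalized[, 1]), rep(0, 3))
})

test_that("zero-count cells are rejected with their ids, and the filter drops them", {
  m <- rbind(c(0L, 0L), c(3L, 1L))
  x <- omics_counts(m, "rna", cell_ids = c("bad_cell", "ok_cell"))
  expect_error(preprocess_rna(x), "bad_cell")
  y <- omics_counts(rbind(c(1L, 1L), c(2L, 0L)), "protein",
                    cell_ids = c("bad_cell", "ok_cell"))
  flt <- filter_zero_cells(list(x, y))
  expect_identical(flt[[1]]$cell_ids, "ok_cell")
  expect_identical(flt[[2]]$cell_ids, "ok_cell")
})

test_that("protein preprocessing yields unit size factors and cell-wise invariance", {
  x <- tiny_counts(4, 3, "protein")
  p <- preprocess_protein(x)
  expect_equal(p$size_factors, rep(1, 4))
  # two identical cells -> identical normalized rows
  m <- rbind(c(4L, 8L, 2L), c(4L, 8L, 2L), c(10L, 1L, 7L))
  p2 <- preprocess_protein(omics_counts(m, "protein"))
  expect_equal(p2$normalized[1, ], p2$normalized[2, ])
  # single cell, single feature -> 0 after scaling (zero-variance column)
  p3 <- preprocess_protein(omics_counts(matrix(9L, 1, 1), "protein"))
  expect_equal(as.vector(p3$normalized), 0)
})

test_that("multiomics_dataset validates cell alignment and subsets consistently", {
  sim <- small_sim()
  d <- sim$dataset
  expect_error(multiomics_dataset(list(sim$raw$rna)), "at least two")
  shuffled <- omics_counts(sim$raw$protein$matrix, "protein",
                           cell_ids = rev(sim$raw$protein$cell_ids),
                           feature_ids = sim$raw$protein$feature_ids)
  expect_error(multiomics_dataset(list(sim$raw$rna, shuffled)), "identical cell_id")

  sub <- d[1:10]
  expect_length(sub$cell_ids, 10)
  expect_equal(nrow(sub$omics[[1]]$normalized), 10)
  expect_equal(sub$omics[[2]]$size_factors, d$omics[[2]]$size_factors[1:10])
})

test_that("gene activity assigns peaks to gene body plus strand-aware upstream windows", {
  counts <- matrix(c(2L, 5L,
                     1L, 0L), 2, 2, byrow = TRUE)
  peaks <- omics_counts(counts, "rna",
                        feature_ids = c("peak1", "peak2"))
  peak_coords <- list(genomic_interval("chr1", 3100, 3200),
                      genomic_interval("chr2", 3100, 3200))
  genes <- list(gA = genomic_interval("chr1", 5000, 6000, "+"))
  act <- gene_activity_from_peaks(peaks, peak_coords, genes)
  # peak1 overlaps the 2 kb upstream window [3000, 5000); peak2 is on chr2
  expect_equal(as.vector(act$matrix[, "gA"]), c(2, 1))
  expect_equal(act$omics_kind, "atac_activity")

  # minus-strand gene: upstream means higher coordinates
  genes_m <- list(gB = genomic_interval("chr1", 1000, 2000, "-"))
  pc <- list(genomic_interval("chr1", 2500, 2600),  # within [2000, 4000) upstream
             genomic_interval("chr1", 500, 900))    # below the body: not assigned
  act_m <- gene_activity_from_peaks(peaks, pc, genes_m)
  expect_equal(as.vector(act_m$matrix[, "gB"]), c(2, 1))

  # no peak overlaps any window -> all-zero activity
  far <- list(gC = genomic_interval("chr9", 10, 100, "+"))
  act0 <- gene_activity_from_peaks(peaks, peak_coords, far)
  expect_equal(sum(act0$matrix), 0)

  expect_error(genomic_interval("chr1", 50, 50), "malformed")
  expect_error(gene_activity_from_peaks(peaks, peak_coords[1], genes), "length")
})

test_that("gene activity matches a brute-force overlap scan on random instances", {
  set.seed(42)
  for (rep in 1:8) {
    n_peaks <- sample(10:50, 1); n_genes <- sample(3:10, 1); n_cells <- 4
    chrs <- c("chr1", "chr2")
    peak_coords <- lapply(seq_len(n_peaks), function(i) {
      s <- sample(0:20000, 1)
      genomic_interval(sample(chrs, 1), s, s + sample(50:500, 1))
    })
    genes <- lapply(seq_len(n_genes), function(i) {
      s <- sample(0:20000, 1)
      genomic_interval(sample(chrs, 1), s, s + sample(500:3000, 1),
                       sample(c("+", "-"), 1))
    })
    names(genes) <- sprintf("g%d", seq_len(n_genes))
    cm <- matrix(rpois(n_cells * n_peaks, 2L), n_cells, n_peaks)
    peaks <- omics_counts(cm, "rna")
    act <- gene_activity_from_peaks(peaks, peak_coords, genes)
    expect_equal(unname(as.matrix(act$matrix)),
                 unname(oracle_gene_activity(cm, peak_coords, genes)))
  }
})

test_that("BED intervals parse into the 0-based half-open convention", {
  p <- file.path(tempdir(), "peaks.bed")
  writeLines(c("chr1\t100\t200\tpk1\t0\t+", "chr2\t5\t50\tpk2\t0\t-"), p)
  iv <- read_bed_intervals(p)
  expect_named(iv, c("pk1", "pk2"))
  expect_equal(iv$pk1$start, 100)
  expect_equal(iv$pk1$end, 200)
  expect_equal(iv$pk2$strand, "-")
})

test_that("highly-variable-gene selection keeps the planted signal genes", {
  set.seed(33)
  n <- 80; p <- 200
  lab <- rep(1:2, each = n / 2)
  # genes 1-10 differ strongly between clusters but keep an overall mean
  # comparable to the flat noise genes (abundance-matched DE)
  mu <- matrix(3, n, p)
  mu[lab == 1, 1:10] <- 0.5
  mu[lab == 2, 1:10] <- 5.5
  m <- matrix(rpois(n * p, as.vector(mu)), n, p)
  x <- omics_counts(m, "rna")
  sel <- select_hvg(x, 10)
  expect_length(sel$feature_ids, 10)
  expect_true(sum(sel$feature_ids %in% sprintf("feat_%d", 1:10)) >= 8)
  # raw counts of kept features are untouched
  kept <- match(sel$feature_ids, x$feature_ids)
  expect_equal(as.matrix(sel$matrix), m[, kept, drop = FALSE],
               ignore_attr = TRUE)
  expect_error(select_hvg(omics_counts(rbind(c(0L, 0L), c(1L, 2L)), "rna")),
               "zero-count")
})
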