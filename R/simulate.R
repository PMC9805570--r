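#' Configuration for the paired-omics count simulator
#'
#' The generator plants `K` cell clusters in paired RNA + protein counts.
#' Feature means are log-normal; a cluster-specific subset of features
#' (chosen per omics with probability `de_prob_*`) gets multiplied by
#' log-normal fold changes, which controls how informative each omics is
#' about the clustering. RNA counts are ZINB with log-normal cell size
#' factors and dropout; protein counts are NB. Defaults mirror a
#' desk-scale CITE-seq design with informative protein and moderately
#' informative RNA (RNA differential-expression probability 0.15, protein
#' 0.7).
#'
#' @param n_cells Number of cells.
#' @param K Number of planted clusters.
#' @param proportions Cluster proportions (default equal); must sum to 1.
#' @param n_genes,n_proteins Feature counts per omics.
#' @param de_prob_rna,de_prob_protein Per-feature probability of a
#'   cluster-specific mean shift, per omics.
#' @param lfc_scale Standard deviation of the log fold changes of DE
#'   features.
#' @param theta_rna,theta_protein NB dispersions.
#' @param dropout_rna ZINB dropout probability for RNA (protein has none).
#' @param size_factor_sd SD of the log-normal RNA cell size factors.
#' @param rna_mean_log,protein_mean_log Log-scale location of baseline
#'   feature means.
#' @param doublet_fraction Fraction of `n_cells` appended as planted
#'   doublets (cross-cluster count averages).
#' @param seed Integer seed; the generated matrices are a deterministic
#'   function of the configuration.
#' @return A `synth_config` list.
#' @export
synth_config <- function(n_cells = 600, K = 3, proportions = NULL,
                         n_genes = 1000, n_proteins = 30,
                         de_prob_rna = 0.15, de_prob_protein = 0.7,
                         lfc_scale = 1, theta_rna = 2, theta_protein = 8,
                         dropout_rna = 0.3, size_factor_sd = 0.3,
                         rna_mean_log = log(2), protein_mean_log = log(20),
                         doublet_fraction = 0, seed = 0) {
  if (is.null(proportions)) proportions <- rep(1 / K, K)
  stopifnot(length(proportions) == K, abs(sum(proportions) - 1) < 1e-8,
            de_prob_rna >= 0, de_prob_rna <= 1,
            de_prob_protein >= 0, de_prob_protein <= 1,
            dropout_rna >= 0, dropout_rna <= 1,
            theta_rna > 0, theta_protein > 0,
            doublet_fraction >= 0, doublet_fraction < 1)
  if (K > n_cells) stop("K must not exceed n_cells", call. = FALSE)
  structure(list(n_cells = n_cells, K = K, proportions = proportions,
                 n_genes = n_genes, n_proteins = n_proteins,
                 de_prob_rna = de_prob_rna, de_prob_protein = de_prob_protein,
                 lfc_scale = lfc_scale, theta_rna = theta_rna,
                 theta_protein = theta_protein, dropout_rna = dropout_rna,
                 size_factor_sd = size_factor_sd,
                 rna_mean_log = rna_mean_log, protein_mean_log = protein_mean_log,
                 doublet_fraction = doublet_fraction, seed = seed),
            class = "synth_config")
}

# cluster x features mean matrix with planted DE fold changes
make_cluster_means <- function(K, p, mean_log, de_prob, lfc_scale) {
  base <- exp(stats::rnorm(p, mean_log, 1))
  means <- matrix(base, K, p, byrow = TRUE)
  for (k in seq_len(K)) {
    de <- stats::runif(p) < de_prob
    if (any(de))
      means[k, de] <- means[k, de] * exp(stats::rnorm(sum(de), 0, lfc_scale))
  }
  means
}

rzinb_matrix <- function(mu, theta, dropout) {
  n <- length(mu)
  x <- stats::rnbinom(n, size = theta, mu = as.vector(mu))
  if (dropout > 0) x[stats::runif(n) < dropout] <- 0L
  matrix(x, nrow(mu), ncol(mu))
}

#' Simulate a paired multi-omics dataset with planted clusters
#'
#' @param config A [synth_config()].
#' @return A `synth_dataset` list:
#'   `dataset` (a preprocessed [multiomics_dataset()] with the true labels
#'   attached), `raw` (list of [omics_counts()]), `true_labels` (character;
#'   `NA` for planted doublets), `doublet_mask` (logical), and `params`
#'   (the generating configuration plus the drawn cluster means).
#' @export
simulate_multiomics <- function(config = synth_config()) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)
  n <- config$n_cells; K <- config$K

  counts_per_k <- diff(c(0, round(cumsum(config$proportions) * n)))
  labels <- sample(rep(seq_len(K), times = counts_per_k))
  mu_rna <- make_cluster_means(K, config$n_genes, config$rna_mean_log,
                               config$de_prob_rna, config$lfc_scale)
  mu_adt <- make_cluster_means(K, config$n_proteins, config$protein_mean_log,
                               config$de_prob_protein, config$lfc_scale)
  sf <- exp(stats::rnorm(n, 0, config$size_factor_sd))

  rna <- rzinb_matrix(sf * mu_rna[labels, , drop = FALSE], config$theta_rna,
                      config$dropout_rna)
  adt <- matrix(stats::rnbinom(n * config$n_proteins, size = config$theta_protein,
                               mu = as.vector(mu_adt[labels, , drop = FALSE])),
                n, config$n_proteins)

  ids <- sprintf("cell_%05d", seq_len(n))
  raw <- list(
    rna = omics_counts(rna, "rna", cell_ids = ids,
                       feature_ids = sprintf("gene_%04d", seq_len(config$n_genes))),
    protein = omics_counts(adt, "protein", cell_ids = ids,
                           feature_ids = sprintf("adt_%03d", seq_len(config$n_proteins))))
  raw <- filter_zero_cells(raw)
  kept <- match(raw$rna$cell_ids, ids)
  labels <- labels[kept]

  sdata <- structure(list(
    raw = raw,
    true_labels = as.character(labels),
    doublet_mask = rep(FALSE, length(labels)),
    params = list(config = config, mu_rna = mu_rna, mu_adt = mu_adt)),
    class = "synth_dataset")
  if (config$doublet_fraction > 0) {
    sdata <- inject_doublets(sdata, round(config$doublet_fraction * length(labels)))
  } else {
    sdata$dataset <- multiomics_dataset(sdata$raw, labels = sdata$true_labels)
  }
  sdata
}

#' @method print synth_dataset
#' @export
print.synth_dataset <- function(x, ...) {
  cat(sprintf("synth_dataset: %d cells (%d doublets), %d clusters, omics: %s\n",
              length(x$true_labels), sum(x$doublet_mask),
              length(unique(stats::na.omit(x$true_labels))),
              paste(names(x$raw), collapse = " + ")))
  invisible(x)
}

#' Append planted doublets to a simulated dataset
#'
#' Mirrors the experimental doublet construction: each doublet is the
#' per-omics average (rounded half-up) of the raw counts of a sampled pair
#' of cells from *distinct* clusters, appended as a new cell and recorded
#' in `doublet_mask`.
#'
#' @param sdata A `synth_dataset` from [simulate_multiomics()].
#' @param n_doublets Number of doublets to append.
#' @return The extended `synth_dataset` (preprocessed views rebuilt).
#' @export
inject_doublets <- function(sdata, n_doublets) {
  stopifnot(inherits(sdata, "synth_dataset"))
  labels <- sdata$true_labels
  singlet <- which(!sdata$doublet_mask)
  labs <- labels[singlet]
  if (length(unique(labs)) < 2)
    stop("doublet injection needs at least two clusters", call. = FALSE)
  tab <- table(labs)
  n_cross <- (sum(tab)^2 - sum(tab^2)) / 2
  if (n_doublets > n_cross)
    stop("requested ", n_doublets, " doublets but only ", n_cross,
         " cross-cluster pairs exist", call. = FALSE)
  pick_pair <- function() {
    repeat {
      ij <- sample(singlet, 2)
      if (labels[ij[1]] != labels[ij[2]]) return(ij)
    }
  }
  pairs <- t(vapply(seq_len(n_doublets), function(i) pick_pair(), c(1L, 1L)))
  new_raw <- lapply(sdata$raw, function(o) {
    m <- as.matrix(o$matrix)
    dbl <- floor((m[pairs[, 1], , drop = FALSE] + m[pairs[, 2], , drop = FALSE]) / 2 + 0.5)
    ids <- c(o$cell_ids, sprintf("doublet_%04d", seq_len(n_doublets)))
    omics_counts(rbind(m, dbl), o$omics_kind, cell_ids = ids,
                 feature_ids = o$feature_ids)
  })
  out <- sdata
  out$raw <- new_raw
  out$true_labels <- c(labels, rep(NA_character_, n_doublets))
  out$doublet_mask <- c(sdata$doublet_mask, rep(TRUE, n_doublets))
  out$dataset <- multiomics_dataset(out$raw, labels = out$true_labels)
  out
}
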