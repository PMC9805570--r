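# Shared fixtures and brute-force oracles. Everything is generated in code;
# no binary fixtures.

tiny_counts <- function(n = 5, p = 4, kind = "rna", seed = 11) {
  set.seed(seed)
  m <- matrix(rpois(n * p, 5) + 1L, n, p)
  omics_counts(m, kind,
               cell_ids = sprintf("c%02d", seq_len(n)),
               feature_ids = sprintf("f%02d", seq_len(p)))
}

small_sim <- function(...) {
  args <- utils::modifyList(
    list(n_cells = 120, n_genes = 80, n_proteins = 12, K = 3, seed = 5),
    list(...))
  simulate_multiomics(do.call(synth_config, args))
}

fast_config <- function(...) {
  args <- utils::modifyList(
    list(latent_dim = 8, encoder_widths = c(32, 16), hidden_dim = 8,
         pretrain_epochs = 10, train_epochs = 10, warmup_epochs = 3,
         kmeans_start = TRUE, seed = 1),
    list(...))
  do.call(moclust_config, args)
}

# random simplex-row assignment matrix
random_assignments <- function(n, k) {
  a <- matrix(rexp(n * k), n, k)
  a / rowSums(a)
}

## brute-force oracles -----------------------------------------------------

oracle_zinb_nll <- function(x, mu, theta, pi) {
  # literal mixture evaluation, entry by entry, via dnbinom
  n <- nrow(x); p <- ncol(x)
  th <- if (length(theta) == 1) matrix(theta, n, p)
        else if (is.matrix(theta)) theta else matrix(theta, n, p, byrow = TRUE)
  pp <- if (length(pi) == 1) matrix(pi, n, p) else pi
  tot <- 0
  for (i in seq_len(n)) for (j in seq_len(p)) {
    nb <- dnbinom(x[i, j], size = th[i, j], mu = mu[i, j])
    dens <- if (x[i, j] == 0) pp[i, j] + (1 - pp[i, j]) * nb else (1 - pp[i, j]) * nb
    tot <- tot - log(dens)
  }
  tot / (n * p)
}

oracle_cs_ratio <- function(C, K) {
  k <- ncol(C)
  tot <- 0
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    num <- as.numeric(t(C[, i]) %*% K %*% C[, j])
    d1 <- as.numeric(t(C[, i]) %*% K %*% C[, i])
    d2 <- as.numeric(t(C[, j]) %*% K %*% C[, j])
    if (d1 * d2 > 0) tot <- tot + num / sqrt(d1 * d2)
  }
  tot / k
}

oracle_ddc_l2 <- function(A, K) {
  n <- nrow(A); k <- ncol(A)
  m <- matrix(0, n, k)
  for (a in seq_len(n)) for (j in seq_len(k)) {
    e <- numeric(k); e[j] <- 1
    m[a, j] <- exp(-sqrt(sum((A[a, ] - e)^2)))
  }
  oracle_cs_ratio(m, K)
}

oracle_ddc_l3 <- function(A) {
  k <- ncol(A)
  s <- 0
  for (i in seq_len(k)) for (j in seq_len(k))
    if (j > i) s <- s + sum(A[, i] * A[, j])
  s / (k * (k - 1) / 2)
}

oracle_contrastive <- function(latents, negatives, tau) {
  # literal double loop over anchors and ordered omics pairs
  M <- length(latents)
  n <- nrow(latents[[1]])
  all_z <- do.call(rbind, latents)
  csim <- function(u, v) sum(u * v) / sqrt(sum(u^2) * sum(v^2))
  tot <- 0
  for (i in seq_len(n)) for (u in seq_len(M)) for (v in seq_len(M)) {
    if (u == v) next
    zu <- latents[[u]][i, ]; zv <- latents[[v]][i, ]
    num <- exp(csim(zu, zv) / tau)
    neg <- negatives[[i]]
    if (!length(neg)) next
    den <- num
    for (t in list(zu, zv)) for (jj in neg)
      den <- den + exp(csim(t, all_z[jj, ]) / tau)
    tot <- tot - log(num / den)
  }
  tot / (n * M * (M - 1))
}

oracle_ari <- function(a, b) {
  # pair-counting over all C(n,2) pairs
  n <- length(a)
  s11 <- s00 <- s10 <- s01 <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    same_a <- a[i] == a[j]; same_b <- b[i] == b[j]
    if (same_a && same_b) s11 <- s11 + 1
    else if (!same_a && !same_b) s00 <- s00 + 1
    else if (same_a) s10 <- s10 + 1
    else s01 <- s01 + 1
  }
  tot <- s11 + s00 + s10 + s01
  exp_idx <- (s11 + s10) * (s11 + s01) / tot
  max_idx <- ((s11 + s10) + (s11 + s01)) / 2
  if (max_idx == exp_idx) return(0)
  (s11 - exp_idx) / (max_idx - exp_idx)
}

oracle_gene_activity <- function(peaks_mat, peak_coords, genes, upstream = 2000) {
  # O(peaks x genes) interval scan in BED coordinates
  n <- nrow(peaks_mat)
  act <- matrix(0, n, length(genes),
                dimnames = list(NULL, names(genes)))
  for (g in seq_along(genes)) {
    gene <- genes[[g]]
    if (gene$strand == "+") {
      ws <- gene$start - upstream; we <- gene$end
    } else {
      ws <- gene$start; we <- gene$end + upstream
    }
    for (p in seq_along(peak_coords)) {
      pk <- peak_coords[[p]]
      if (pk$chrom != gene$chrom) next
      if (pk$start < we && pk$end > ws)  # >= 1 bp overlap, half-open
        act[, g] <- act[, g] + peaks_mat[, p]
    }
  }
  act
}
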