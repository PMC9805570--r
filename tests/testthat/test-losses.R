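test_that("zinb_nll reproduces hand-computed single-entry values", {
  # x = 0, mu = 1, theta = 1, pi = 0.5: -log(0.5 + 0.5 * 0.5)
  expect_equal(zinb_nll(matrix(0), matrix(1), 1, 0.5), -log(0.75), tolerance = 1e-12)
  # x = 2, mu = 2, theta = 2, pi = 0: NB pmf = 3 * 0.25 * 0.0625 -> 0.1875
  expect_equal(zinb_nll(matrix(2), matrix(2), 2, 0), -log(0.1875), tolerance = 1e-12)
})

test_that("zinb_nll with pi = 0 equals the NB likelihood exactly", {
  set.seed(1)
  x <- matrix(rpois(40, 4), 5, 8)
  mu <- matrix(rexp(40, 0.2) + 0.1, 5, 8)
  th <- rexp(8) + 0.2
  nb_direct <- -mean(dnbinom(x, size = matrix(th, 5, 8, byrow = TRUE), mu = mu, log = TRUE))
  expect_equal(zinb_nll(x, mu, th, pi = 0), nb_direct, tolerance = 1e-12)
  expect_equal(zinb_nll(x, mu, th, pi = NULL), nb_direct, tolerance = 1e-12)
})

test_that("zinb_nll matches the mixture oracle on random instances to 1e-8 relative", {
  set.seed(2)
  for (r in 1:30) {
    n <- sample(2:6, 1); p <- sample(2:6, 1)
    x <- matrix(rpois(n * p, 3), n, p)
    x[sample(n * p, n)] <- 0
    mu <- matrix(rexp(n * p, 0.3) + 0.01, n, p)
    th <- rexp(p, 0.5) + 0.05
    pim <- matrix(runif(n * p, 0, 0.9), n, p)
    expect_equal(zinb_nll(x, mu, th, pim), oracle_zinb_nll(x, mu, th, pim),
                 tolerance = 1e-8)
  }
})

test_that("zinb_nll respects gamma weighting and rejects non-finite heads", {
  x <- matrix(1); mu <- matrix(2)
  expect_equal(zinb_nll(x, mu, 1, 0, gamma = 2.5), 2.5 * zinb_nll(x, mu, 1, 0))
  expect_error(zinb_nll(x, matrix(NaN), 1, 0), "mean")
  expect_error(zinb_nll(x, mu, NA_real_, 0), "dispersion")
  expect_error(zinb_nll(x, mu, 1, Inf), "dropout")
})

test_that("NB pmf sums to 1 over its support and dzinb is a proper mixture", {
  for (mu in c(0.5, 2, 10)) for (th in c(0.2, 1, 10)) {
    expect_equal(sum(dzinb(0:10000, mu, th)), 1, tolerance = 1e-6)
    expect_equal(sum(dzinb(0:10000, mu, th, pi = 0.3)), 1, tolerance = 1e-6)
  }
  expect_equal(dzinb(0, 1, 1, 0.5), 0.75)
})

test_that("compiled zinb kernel agrees with the pure-R reference implementation", {
  set.seed(3)
  for (r in 1:10) {
    n <- sample(3:8, 1); p <- sample(2:7, 1)
    x <- matrix(rpois(n * p, 2), n, p)
    mu <- matrix(rexp(n * p, 0.4) + 0.02, n, p)
    th <- rexp(p) + 0.1
    pim <- if (r %% 2) matrix(runif(n * p), n, p) else NULL
    a <- moclust:::zinb_loss_and_grads(x, mu, th, pim)
    b <- moclust:::zinb_loss_and_grads_r(x, mu, th, pim)
    expect_equal(a$loss, b$loss, tolerance = 1e-12)
    expect_equal(a$dmu, b$dmu, tolerance = 1e-12)
    expect_equal(a$dtheta, b$dtheta, tolerance = 1e-12)
    if (!is.null(pim)) expect_equal(a$dpi, b$dpi, tolerance = 1e-12)
  }
})

test_that("cosine similarity is symmetric, scale-invariant and rejects zero vectors", {
  u <- c(1, 2, -1); v <- c(0.5, -1, 2)
  expect_equal(cosine_similarity(u, u), 1)
  expect_equal(cosine_similarity(c(1, 0), c(0, 1)), 0)
  expect_equal(cosine_similarity(2 * u, v), cosine_similarity(u, v))
  expect_equal(cosine_similarity(u, v), cosine_similarity(v, u))
  expect_error(cosine_similarity(c(0, 0), v), "zero")
})

test_that("contrastive loss reproduces the log(3) case and handles empty negative sets", {
  # one anchor, one negative view, all pairwise sims equal:
  # denominator = 3 x numerator -> loss log 3 per ordered pair
  d <- 4
  z <- matrix(rep(1, d), 1)  # all views identical -> all sims 1
  latents <- list(rbind(z, z), rbind(z, z))  # 2 cells x 2 omics, all equal
  negs <- list(2L, 1L)  # each anchor gets exactly one negative view (other cell, omics 1)
  expect_equal(contrastive_loss(latents, negs, tau = 0.5), log(3), tolerance = 1e-12)

  # empty negative sets -> 0 with a warning
  expect_warning(l0 <- contrastive_loss(latents, list(integer(0), integer(0)), 0.5),
                 "empty")
  expect_equal(l0, 0)
})

test_that("contrastive loss matches a literal double-loop oracle on random instances", {
  set.seed(4)
  for (r in 1:20) {
    n <- sample(4:10, 1); d <- sample(2:5, 1); M <- 2
    latents <- lapply(1:M, function(m) matrix(rnorm(n * d), n, d))
    labs <- sample(1:3, n, replace = TRUE)
    negs <- sample_negative_sets(labs, M, negatives_per_anchor = 5)
    tau <- runif(1, 0.2, 1)
    expect_equal(contrastive_loss(latents, negs, tau),
                 oracle_contrastive(latents, negs, tau), tolerance = 1e-10)
  }
})

test_that("negative sets exclude the anchor cell and same-cluster cells", {
  set.seed(5)
  labs <- c(1, 1, 2, 2, 3)
  negs <- sample_negative_sets(labs, n_omics = 2, negatives_per_anchor = 100)
  n <- length(labs)
  for (i in seq_along(labs)) {
    cells <- ((negs[[i]] - 1) %% n) + 1
    expect_false(i %in% cells)
    expect_true(all(labs[cells] != labs[i]))
  }
  # warm-up (NA labels): everything except the anchor cell is eligible
  negs_w <- sample_negative_sets(rep(NA_integer_, 4), 2, 100)
  expect_equal(sort(((negs_w[[1]] - 1) %% 4) + 1), c(2, 2, 3, 3, 4, 4))
})

test_that("gaussian kernel has unit diagonal and the exp(-1/2) one-sigma value", {
  h <- rbind(c(0, 0), c(1, 0), c(5, 5))
  K <- gaussian_kernel(h, sigma = 1)
  expect_equal(diag(K), rep(1, 3))
  expect_equal(K, t(K))
  expect_equal(K[1, 2], exp(-0.5))
  # sigma -> large: all entries -> 1
  expect_true(all(gaussian_kernel(h, 1e6) > 0.999999))
})

test_that("ddc_l1 reproduces hand cases and the brute-force oracle", {
  # one-hot A with block-diagonal kernel (zero cross-block) -> 0
  A <- rbind(c(1, 0), c(1, 0), c(0, 1), c(0, 1))
  K <- matrix(0, 4, 4); K[1:2, 1:2] <- 1; K[3:4, 3:4] <- 1
  expect_equal(ddc_l1(A, K), 0)
  # n = 2, k = 2, A = I, K = all ones -> 0.5
  expect_equal(ddc_l1(diag(2), matrix(1, 2, 2)), 0.5)
  set.seed(6)
  for (r in 1:25) {
    n <- sample(3:20, 1); k <- sample(2:4, 1)
    A <- random_assignments(n, k)
    K <- gaussian_kernel(matrix(rnorm(n * 3), n, 3), runif(1, 0.5, 2))
    expect_equal(ddc_l1(A, K), oracle_cs_ratio(A, K), tolerance = 1e-12)
  }
  # all-zero cluster column contributes 0, with a warning
  A0 <- cbind(c(1, 1), 0)
  expect_warning(v <- ddc_l1(A0, diag(2)), "empty")
  expect_equal(v, 0)
})

test_that("ddc_l2 uses exp(-distance-to-corner) and matches its oracle", {
  # alpha = e_1 in K = 2: m = (1, exp(-sqrt(2)))
  m <- simplex_corner_kernel(matrix(c(1, 0), 1))
  expect_equal(as.vector(m), c(1, exp(-sqrt(2))), tolerance = 1e-12)
  set.seed(7)
  for (r in 1:25) {
    n <- sample(3:20, 1); k <- sample(2:4, 1)
    A <- random_assignments(n, k)
    K <- gaussian_kernel(matrix(rnorm(n * 3), n, 3), runif(1, 0.5, 2))
    expect_equal(ddc_l2(A, K), oracle_ddc_l2(A, K), tolerance = 1e-12)
    mm <- simplex_corner_kernel(A)
    expect_true(all(mm > 0 & mm <= 1))
  }
})

test_that("ddc_l3 reproduces hand cases, its oracle and column-permutation symmetry", {
  A1 <- rbind(c(1, 0), c(0, 1))
  expect_equal(ddc_l3(A1), 0)
  A2 <- rbind(c(0.5, 0.5), c(0.5, 0.5))
  expect_equal(ddc_l3(A2), 0.5)
  set.seed(8)
  for (r in 1:25) {
    n <- sample(2:20, 1); k <- sample(2:4, 1)
    A <- random_assignments(n, k)
    expect_equal(ddc_l3(A), oracle_ddc_l3(A), tolerance = 1e-12)
    perm <- sample(k)
    expect_equal(ddc_l3(A[, perm]), ddc_l3(A), tolerance = 1e-12)
  }
})

test_that("the CS ratio term is 1 for identical cluster columns (divergence minimum)", {
  set.seed(9)
  n <- 10
  a <- rexp(n)
  A <- cbind(a, a)
  K <- gaussian_kernel(matrix(rnorm(n * 2), n, 2), 1)
  # one pair, identical columns: ratio = 1, normalized by k = 2 -> 0.5
  expect_equal(ddc_l1(A, K), 0.5, tolerance = 1e-12)
})

test_that("cluster_loss is the exact sum of its three terms and is nonnegative", {
  set.seed(10)
  for (r in 1:10) {
    n <- sample(4:15, 1); k <- sample(2:4, 1)
    A <- random_assignments(n, k)
    K <- gaussian_kernel(matrix(rnorm(n * 3), n, 3), 1)
    cl <- cluster_loss(A, K)
    expect_equal(cl, ddc_l1(A, K) + ddc_l2(A, K) + ddc_l3(A), tolerance = 1e-12)
    expect_gte(cl, 0)
  }
})

test_that("total and pretraining objectives compose exactly as written", {
  w <- c(0.3, 0.7)
  expect_equal(total_loss(2, 3, 5, w, delta = 0), 5)
  expect_equal(total_loss(2, 3, 5, w, delta = 1), 2 + 3 + 0.3 * 5)
  expect_equal(pretrain_loss(2, 1.5, 5, w, gamma = 1, delta = 0), 3.5)
  expect_equal(pretrain_loss(2, 1.5, 5, w, gamma = 0, delta = 2), 1.5 + 2 * 0.3 * 5)
  # algebraic identity: pretrain(gamma = 1) = total - (L2 + L3)
  l1 <- 1.1; l2 <- 0.4; l3 <- 0.2
  expect_equal(pretrain_loss(2, l1, 5, w, 1, 1),
               total_loss(2, l1 + l2 + l3, 5, w, 1) - (l2 + l3))
})
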