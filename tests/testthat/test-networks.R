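# The backward pass is hand-derived; these tests pin it against numerical
# differentiation of the exact training objective on a tiny instance.

test_that("every analytic gradient matches numerical differentiation", {
  set.seed(42)
  sim <- small_sim(n_cells = 30, n_genes = 20, n_proteins = 6, seed = 3)
  tensors <- moclust:::prepare_tensors(sim$dataset)
  cfg <- moclust_config(latent_dim = 4, encoder_widths = c(10, 6), hidden_dim = 5,
                        seed = 1, negatives_per_anchor = 6, spectral_init = FALSE)
  params <- moclust:::init_params(cfg, vapply(tensors$X, ncol, 0L),
                                  c(TRUE, FALSE), 2, 3)
  params$fusion_logits <- c(0.4, -0.3)  # break the min(w) tie
  idx <- seq_len(tensors$n)
  set.seed(7)
  negs <- sample_negative_sets(sample(1:3, tensors$n, TRUE), 2, 6)
  sigma <- 1.3

  # loss closure replicating one joint-training step with frozen negatives,
  # frozen kernel bandwidth and no input corruption
  loss_of <- function(params) {
    w <- as.vector(moclust:::softmax_rows(matrix(params$fusion_logits, 1)))
    enc <- lapply(1:2, function(m)
      moclust:::encode_forward(params$towers[[m]]$enc, tensors$X[[m]], training = TRUE))
    zs <- lapply(enc, `[[`, "z")
    fused <- w[1] * zs[[1]] + w[2] * zs[[2]]
    hd <- moclust:::head_forward(params$head, fused)
    zt <- 0
    for (m in 1:2) {
      zinb <- c(TRUE, FALSE)[m]
      fwd <- moclust:::decode_forward(params$towers[[m]]$dec, zs[[m]],
                                      tensors$sf[[m]], zinb)
      th <- matrix(fwd$theta, tensors$n, ncol(tensors$raw[[m]]), byrow = TRUE)
      zt <- zt + mean(-dzinb(tensors$raw[[m]], fwd$mu, th,
                             if (zinb) fwd$pi else 0, log = TRUE))
    }
    Km <- gaussian_kernel(hd$h, sigma)
    ct <- moclust:::contrastive_backward(zs, negs, cfg$tau)
    zt + moclust:::cs_ratio_sum(hd$A, Km) +
      moclust:::cs_ratio_sum(simplex_corner_kernel(hd$A), Km) +
      ddc_l3(hd$A) + cfg$delta * min(w) * ct$loss
  }

  grads <- local({
    w <- as.vector(moclust:::softmax_rows(matrix(params$fusion_logits, 1)))
    enc <- lapply(1:2, function(m)
      moclust:::encode_forward(params$towers[[m]]$enc, tensors$X[[m]], training = TRUE))
    zs <- lapply(enc, `[[`, "z")
    fused <- w[1] * zs[[1]] + w[2] * zs[[2]]
    hd <- moclust:::head_forward(params$head, fused)
    Km <- gaussian_kernel(hd$h, sigma)
    ct <- moclust:::contrastive_backward(zs, negs, cfg$tau)
    ddc <- moclust:::ddc_backward(hd$A, hd$h, Km, sigma, TRUE)
    hb <- moclust:::head_backward(params$head, hd, ddc$dh, ddc$dA)
    g <- list(towers = vector("list", 2),
              head = hb[c("Wh", "bh", "Wa", "ba")])
    for (m in 1:2) {
      zinb <- c(TRUE, FALSE)[m]
      fwd <- moclust:::decode_forward(params$towers[[m]]$dec, zs[[m]],
                                      tensors$sf[[m]], zinb)
      zg <- moclust:::zinb_loss_and_grads(tensors$raw[[m]], fwd$mu, fwd$theta,
                                          if (zinb) fwd$pi else NULL)
      db <- moclust:::decode_backward(params$towers[[m]]$dec, fwd, zg, zinb, 1)
      dz <- db$dz + w[m] * hb$dz + cfg$delta * min(w) * ct$dlatents[[m]]
      g$towers[[m]] <- list(
        enc = moclust:::encode_backward(params$towers[[m]]$enc, enc[[m]], dz),
        dec = db[setdiff(names(db), "dz")])
    }
    g
  })

  eps <- 1e-5
  check <- function(getter, setter, gmat, label, k = 4) {
    v <- getter(params)
    for (i in sample(length(v), min(k, length(v)))) {
      up <- v; up[i] <- up[i] + eps
      dn <- v; dn[i] <- dn[i] - eps
      num <- (loss_of(setter(params, up)) - loss_of(setter(params, dn))) / (2 * eps)
      expect_equal(gmat[i], num, tolerance = 1e-4,
                   label = sprintf("%s[%d] analytic", label, i))
    }
  }
  set.seed(2)
  check(function(p) p$towers[[1]]$enc$W1,
        function(p, v) { p$towers[[1]]$enc$W1[] <- v; p },
        grads$towers[[1]]$enc$W1, "enc1.W1")
  check(function(p) p$towers[[2]]$enc$W3,
        function(p, v) { p$towers[[2]]$enc$W3[] <- v; p },
        grads$towers[[2]]$enc$W3, "enc2.W3")
  check(function(p) p$towers[[1]]$dec$Wmu,
        function(p, v) { p$towers[[1]]$dec$Wmu[] <- v; p },
        grads$towers[[1]]$dec$Wmu, "dec1.Wmu")
  check(function(p) p$towers[[1]]$dec$Wpi,
        function(p, v) { p$towers[[1]]$dec$Wpi[] <- v; p },
        grads$towers[[1]]$dec$Wpi, "dec1.Wpi")
  check(function(p) p$towers[[1]]$dec$theta_raw,
        function(p, v) { p$towers[[1]]$dec$theta_raw <- v; p },
        grads$towers[[1]]$dec$theta_raw, "dec1.theta")
  check(function(p) p$towers[[2]]$dec$V1,
        function(p, v) { p$towers[[2]]$dec$V1[] <- v; p },
        grads$towers[[2]]$dec$V1, "dec2.V1")
  check(function(p) p$head$Wh,
        function(p, v) { p$head$Wh[] <- v; p },
        grads$head$Wh, "head.Wh")
  check(function(p) p$head$Wa,
        function(p, v) { p$head$Wa[] <- v; p },
        grads$head$Wa, "head.Wa")
})

test_that("decoder outputs respect their ranges over many random latents", {
  sim <- small_sim(n_cells = 40, seed = 9)
  fit <- moclust(sim$dataset, K = 3,
                 config = fast_config(pretrain_epochs = 2, train_epochs = 2, seed = 4),
                 doublets = FALSE)
  set.seed(30)
  z <- matrix(rnorm(1000 * fit$config$latent_dim), 1000)
  out <- decode_zinb(fit, z, omics_index = 1)
  expect_true(all(out$mu > 0))
  expect_true(all(out$theta > 0))
  expect_true(all(out$pi > 0 & out$pi < 1))
  # protein decoder omits the dropout head
  out2 <- decode_zinb(fit, z, omics_index = 2)
  expect_null(out2$pi)
  # size-factor linearity: doubling one cell's factor doubles its mean row
  sf <- rep(1, 3)
  a <- decode_zinb(fit, z[1:3, ], sf, 1)
  sf2 <- c(2, 1, 1)
  b <- decode_zinb(fit, z[1:3, ], sf2, 1)
  expect_equal(b$mu[1, ], 2 * a$mu[1, ], tolerance = 1e-12)
  expect_equal(b$mu[2:3, ], a$mu[2:3, ], tolerance = 1e-12)
  expect_error(decode_zinb(fit, z[1:3, ], c(1, -1, 1), 1), "positive")
})

test_that("encode is deterministic, width-checked and order-preserving", {
  sim <- small_sim(n_cells = 30, seed = 10)
  fit <- moclust(sim$dataset, K = 3,
                 config = fast_config(pretrain_epochs = 2, train_epochs = 2, seed = 5),
                 doublets = FALSE)
  x <- sim$dataset$omics[[1]]$normalized
  z1 <- encode(fit, x, 1)
  z2 <- encode(fit, x, 1)
  expect_identical(z1, z2)
  # identical cells -> identical latents; order preserved
  xx <- x[c(1, 1, 2), ]
  zz <- encode(fit, xx, 1)
  expect_equal(zz[1, ], zz[2, ])
  expect_equal(zz[3, ], encode(fit, x[2, , drop = FALSE], 1)[1, ])
  expect_error(encode(fit, x[, 1:5], 1), "features")
})

test_that("fusion is the exact simplex-weighted average", {
  z1 <- matrix(rnorm(12), 4, 3)
  z2 <- matrix(rnorm(12), 4, 3)
  expect_equal(fuse(list(z1, z2), c(0.5, 0.5)), (z1 + z2) / 2)
  expect_equal(fuse(list(z1, z2), c(1, 0)), z1)
  # convexity: identical latents are a fixed point for any simplex weight
  expect_equal(fuse(list(z1, z1), c(0.3, 0.7)), z1)
  expect_error(fuse(list(z1, z2), c(1)), "one weight per omics")
  expect_error(fuse(list(z1, z2), c(0.8, 0.8)), "sum to 1")
})

test_that("the cluster head produces simplex rows and is deterministic", {
  sim <- small_sim(n_cells = 30, seed = 11)
  fit <- moclust(sim$dataset, K = 4,
                 config = fast_config(pretrain_epochs = 2, train_epochs = 2, seed = 6),
                 doublets = FALSE)
  z <- matrix(rnorm(50 * fit$config$latent_dim), 50)
  out <- cluster_head(fit, z)
  expect_equal(rowSums(out$A), rep(1, 50), tolerance = 1e-6)
  expect_true(all(out$A >= 0 & out$A <= 1))
  expect_equal(cluster_head(fit, z)$A, out$A)
  # identical inputs give identical rows
  out2 <- cluster_head(fit, z[c(1, 1), ])
  expect_equal(out2$A[1, ], out2$A[2, ])
  # zero logits -> uniform row (softmax symmetry)
  expect_equal(as.vector(moclust:::softmax_rows(matrix(0, 1, 2))), c(0.5, 0.5))
})

test_that("fusion weights stay on the simplex throughout training", {
  sim <- small_sim(n_cells = 60, seed = 12)
  fit <- moclust(sim$dataset, K = 3, config = fast_config(seed = 7), doublets = FALSE)
  w <- coef(fit)
  expect_equal(sum(w), 1, tolerance = 1e-12)
  expect_true(all(w >= 0))
})
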