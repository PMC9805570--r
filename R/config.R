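#' Model and training configuration
#'
#' Collects every architecture, loss and optimization hyperparameter. All
#' defaults target desk-scale paired two-omics datasets (hundreds to a few
#' thousand cells); see the methods vignette for the reasoning behind each.
#'
#' @param latent_dim Common per-omics latent dimension d (fusion requires all
#'   omics to share it).
#' @param encoder_widths Hidden widths of each encoder (the decoder mirrors
#'   them).
#' @param hidden_dim Width of the hidden layer h feeding the kernel.
#' @param sigma_scale Relative Gaussian-kernel bandwidth: sigma is
#'   `sigma_scale` times the median pairwise distance among h in the batch,
#'   recomputed per batch and treated as a constant in gradients.
#' @param tau Contrastive temperature (> 0).
#' @param delta Contrastive strength (>= 0); multiplied by `min(w)` in the
#'   objective.
#' @param gamma_m Per-omics ZINB/NB loss strengths; recycled to M at fit time.
#' @param pretrain_gamma Global reconstruction strength in the pretraining
#'   objective.
#' @param negatives_per_anchor Negatives sampled per anchor cell per batch.
#' @param pretrain_epochs,train_epochs Epoch counts for the two stages.
#' @param warmup_epochs Pretraining epochs during which negatives are
#'   cluster-agnostic (all other cells) before switching to the
#'   different-cluster restriction.
#' @param batch_size Minibatch size; batches are formed over a seeded
#'   permutation of the canonical cell order.
#' @param lr_pretrain,lr_train Adam learning rates for the two stages.
#' @param denoise_sd Train-time Gaussian corruption of the (scaled) encoder
#'   inputs, the denoising-autoencoder device that forces latents to encode
#'   covarying structure rather than per-entry noise; 0 disables it.
#'   Inference is always noise-free.
#' @param mse_weight Strength of the auxiliary denoising MSE
#'   reconstruction of the scaled input during pretraining (0 disables).
#'   This is the standard deep-embedded-clustering pretraining device: it
#'   anchors the latent subspace to the leading covariance structure before
#'   the count likelihood refines it.
#' @param fusion_temp Temperature converting per-omics separability scores
#'   (rank AUC of within- vs between-cluster cosine similarities of each
#'   omics' latents under the current predicted clusters, mapped to
#'   [-1, 1]) into fusion logits; smaller values spread the weights more.
#' @param fusion_momentum EMA momentum of the fusion-logit update (per
#'   batch).
#' @param doublet_eps_scale Pseudo-cell noise level: the Gaussian variance
#'   epsilon is `doublet_eps_scale` times the mean within-cluster latent
#'   variance.
#' @param doublet_lambda Mixing weight of the pseudo-doublet linear fusion
#'   (0.5 mixes two parent clusters equally).
#' @param doublet_n_per_cluster Pseudo cells sampled per cluster.
#' @param doublet_n_pairs Number of pseudo-doublet pairs N_n.
#' @param alpha_level Quantile level of the pseudo-doublet entropy
#'   distribution used as the doublet threshold F_alpha.
#' @param empty_rescue_epochs Reinitialize a cluster head row after this many
#'   consecutive epochs without any argmax assignment.
#' @param kmeans_start Warm-start the cluster head from a k-means partition
#'   of the fused latents after pretraining (default `TRUE`; with a cold
#'   head the softmax saturates on an arbitrary crisp partition long before
#'   the divergence geometry can correct it, a known failure mode of this
#'   family of clustering heads).
#' @param spectral_init Initialize each encoder from the truncated SVD of
#'   its scaled input (initial latents then coincide with a truncated PCA),
#'   instead of random Glorot weights. Deterministic and removes the
#'   random-initialization lottery of deep count autoencoders.
#' @param seed Integer seed governing every random draw (initialization,
#'   batching, negative sampling, pseudo cells).
#' @return A `moclust_config` list.
#' @export
moclust_config <- function(latent_dim = 16,
                           encoder_widths = c(64, 32),
                           hidden_dim = 16,
                           sigma_scale = 0.15,
                           tau = 0.5,
                           delta = 0.1,
                           gamma_m = 1,
                           pretrain_gamma = 1,
                           negatives_per_anchor = 32,
                           pretrain_epochs = 40,
                           train_epochs = 40,
                           warmup_epochs = 10,
                           batch_size = 256,
                           lr_pretrain = 1e-3,
                           lr_train = 5e-4,
                           fusion_temp = 0.25,
                           fusion_momentum = 0.9,
                           denoise_sd = 1,
                           mse_weight = 1,
                           doublet_eps_scale = 0.1,
                           doublet_lambda = 0.5,
                           doublet_n_per_cluster = 50,
                           doublet_n_pairs = 1000,
                           alpha_level = 0.05,
                           empty_rescue_epochs = 10,
                           kmeans_start = TRUE,
                           spectral_init = TRUE,
                           seed = 0) {
  cfg <- list(latent_dim = latent_dim, encoder_widths = encoder_widths,
              hidden_dim = hidden_dim, sigma_scale = sigma_scale, tau = tau,
              delta = delta, gamma_m = gamma_m, pretrain_gamma = pretrain_gamma,
              negatives_per_anchor = negatives_per_anchor,
              pretrain_epochs = pretrain_epochs, train_epochs = train_epochs,
              warmup_epochs = warmup_epochs, batch_size = batch_size,
              lr_pretrain = lr_pretrain, lr_train = lr_train,
              fusion_temp = fusion_temp, fusion_momentum = fusion_momentum,
              denoise_sd = denoise_sd, mse_weight = mse_weight,
              doublet_eps_scale = doublet_eps_scale,
              doublet_lambda = doublet_lambda,
              doublet_n_per_cluster = doublet_n_per_cluster,
              doublet_n_pairs = doublet_n_pairs,
              alpha_level = alpha_level,
              empty_rescue_epochs = empty_rescue_epochs,
              kmeans_start = kmeans_start, spectral_init = spectral_init,
              seed = seed)
  validate_config(cfg)
  structure(cfg, class = "moclust_config")
}

validate_config <- function(cfg) {
  stopifnot(cfg$latent_dim >= 1, cfg$hidden_dim >= 1,
            cfg$sigma_scale > 0, cfg$tau > 0, cfg$delta >= 0,
            all(cfg$gamma_m >= 0), cfg$pretrain_gamma >= 0,
            cfg$negatives_per_anchor >= 1,
            cfg$pretrain_epochs >= 0, cfg$train_epochs >= 0,
            cfg$batch_size >= 2,
            cfg$fusion_temp > 0, cfg$fusion_momentum >= 0, cfg$fusion_momentum < 1,
            cfg$denoise_sd >= 0, cfg$mse_weight >= 0,
            cfg$doublet_eps_scale > 0,
            cfg$doublet_lambda >= 0, cfg$doublet_lambda <= 1,
            cfg$alpha_level > 0, cfg$alpha_level < 1)
  invisible(cfg)
}
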