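#' Run the end-to-end clustering pipeline from a configuration
#'
#' Drives preprocess -> pretrain -> doublet detection -> filter -> train ->
#' evaluate from a single declarative configuration, writing every artifact
#' to `out_dir`. Rerunning with the same configuration reproduces all
#' outputs byte-for-byte.
#'
#' The configuration is a list (or path to a YAML file) with entries:
#' \describe{
#'   \item{simulate}{Arguments for [synth_config()] to generate data, or}
#'   \item{data}{A named list of omics inputs, each
#'     `list(path=, format=, omics_kind=)` passed to [load_counts()].}
#'   \item{K}{Number of clusters (defaults to the simulated K).}
#'   \item{model}{Argument overrides for [moclust_config()].}
#'   \item{doublets}{Run the doublet stage (default `TRUE`).}
#'   \item{labels}{Optional path to a TSV of `cell_id<TAB>label` ground
#'     truth for evaluation.}
#' }
#'
#' @param config List or YAML file path.
#' @param out_dir Output directory (created if missing).
#' @param verbose Print progress.
#' @return The fitted [moclust()] object, invisibly. Writes `labels.tsv`,
#'   `soft_assignments.csv`, `weights.json`, `loss_history.csv`,
#'   `doublets.tsv` + `doublet_audit.json` (when the stage runs), and
#'   `metrics.json` (when ground truth is available).
#' @export
run_pipeline <- function(config, out_dir, verbose = FALSE) {
  if (is.character(config)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading a YAML pipeline config requires the yaml package", call. = FALSE)
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  truth <- NULL
  if (!is.null(config$simulate)) {
    sim <- do.call(synth_config, config$simulate)
    sdata <- simulate_multiomics(sim)
    data <- sdata$dataset
    truth <- sdata$true_labels
    K <- if (!is.null(config$K)) config$K else sim$K
  } else if (!is.null(config$data)) {
    raw <- lapply(config$data, function(d)
      load_counts(d$path, d$format, d$omics_kind))
    raw <- filter_zero_cells(raw)
    data <- multiomics_dataset(raw)
    if (is.null(config$K)) stop("config$K is required with file inputs", call. = FALSE)
    K <- config$K
    if (!is.null(config$labels)) {
      lt <- utils::read.table(config$labels, sep = "\t", header = FALSE,
                              stringsAsFactors = FALSE)
      truth <- lt[[2]][match(data$cell_ids, lt[[1]])]
    }
  } else stop("config needs either $simulate or $data", call. = FALSE)

  mcfg <- do.call(moclust_config, if (is.null(config$model)) list() else config$model)
  dbl <- if (is.null(config$doublets)) TRUE else isTRUE(config$doublets)
  fit <- moclust(data, K = K, config = mcfg, doublets = dbl, verbose = verbose)

  utils::write.table(data.frame(cell_id = fit$cell_ids, cluster = fit$cluster),
                     file.path(out_dir, "labels.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  soft <- as.data.frame(fit$soft_assignments)
  names(soft) <- sprintf("cluster_%d", seq_len(fit$K))
  utils::write.csv(cbind(cell_id = fit$cell_ids, soft),
                   file.path(out_dir, "soft_assignments.csv"), row.names = FALSE)
  writeLines(to_json(as.list(fit$fusion_weights)),
             file.path(out_dir, "weights.json"))
  utils::write.csv(fit$history, file.path(out_dir, "loss_history.csv"),
                   row.names = FALSE)
  if (!is.null(fit$doublets)) {
    utils::write.table(data.frame(cell_id = fit$cell_ids,
                                  entropy = fit$doublets$entropy,
                                  flag = fit$doublets$flags),
                       file.path(out_dir, "doublets.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    writeLines(to_json(list(threshold = fit$doublets$threshold,
                            alpha_level = fit$doublets$alpha_level,
                            pseudo_doublet_entropy = fit$doublets$pseudo_doublet_entropy)),
               file.path(out_dir, "doublet_audit.json"))
  }
  if (!is.null(truth) || !is.null(data$labels)) {
    if (is.null(truth)) truth <- data$labels
    rep <- evaluate_clustering(truth, fit$cluster)
    writeLines(to_json(list(nmi = rep$nmi, ari = rep$ari, n_cells = rep$n_cells,
                            K_true = rep$K_true, K_pred = rep$K_pred)),
               file.path(out_dir, "metrics.json"))
  }
  invisible(fit)
}

to_json <- function(x) {
  if (requireNamespace("jsonlite", quietly = TRUE))
    return(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA))
  # minimal fallback for flat lists of numbers/strings
  esc <- function(v) if (is.character(v)) paste0('"', v, '"') else format(v, digits = 15)
  items <- vapply(names(x), function(nm) {
    v <- x[[nm]]
    val <- if (length(v) == 1) esc(v) else paste0("[", paste(esc(v), collapse = ","), "]")
    paste0('"', nm, '":', val)
  }, "")
  paste0("{", paste(items, collapse = ","), "}")
}
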