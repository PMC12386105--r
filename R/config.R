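#' Run configuration
#'
#' Collects every tunable of the pipeline with its default. Defaults follow
#' the method's reference settings: edge significance threshold 0.05, loss
#' weights `lambda1 = 0.1`, `lambda2 = 1e-7`, at most 10 modules, learning
#' rate 0.01, 200 epochs, contrastive temperature `tau = 0.1`, and `k = 7`
#' modules in the final voting ensemble.
#'
#' @param p_edge significance threshold for cooperation-network edges.
#' @param lambda1 weight of the functional-consistency loss.
#' @param lambda2 weight of the difference-prompt (contrastive) loss.
#' @param max_modules maximum number of modules extracted by the greedy search.
#' @param learning_rate Adam step size for graph auto-encoder training.
#' @param epochs number of training epochs.
#' @param tau temperature of the contrastive difference-prompt loss.
#' @param k number of top-AUC modules kept for the voting ensemble.
#' @param hidden_dims integer vector of the two encoder layer widths.
#' @param discr_dim output width of the linear discriminator.
#' @param edge_threshold decoder probability above which an edge enters the
#'   enhanced network.
#' @param svm_C soft-margin cost for every linear SVM fit.
#' @param t_test_variant `"welch"` (default) or `"student"`.
#' @param neg_sample_ratio negatives sampled per positive edge each epoch.
#' @param use_neg_sampling if `FALSE`, the reconstruction loss uses the full
#'   adjacency matrix every epoch.
#' @param seed master seed; fixes every stochastic step of a run.
#' @param use_knowledge ablation switch: drop disease-association attributes
#'   and the functional-consistency loss.
#' @param use_difference_prompt ablation switch: drop the contrastive loss.
#' @param use_gae ablation switch: skip auto-encoder enhancement and search
#'   modules directly on the binary cooperation network.
#' @param standardize z-score features on the training samples before SVM fits.
#' @param normalize_discriminator L2-normalize discriminator outputs before
#'   the contrastive dot product.
#' @param auc_mode `"cv"` (internal stratified cross-validation, default) or
#'   `"resub"` (resubstitution) for module AUC during search.
#' @param cv_folds_internal folds for the internal module-AUC estimate.
#' @param variance_prefilter keep only this many highest-variance features
#'   before pair enumeration; 0 (default) disables the filter.
#'
#' @return an object of class `kenmir_config` (a named list).
#' @export
run_config <- function(p_edge = 0.05,
                       lambda1 = 0.1,
                       lambda2 = 1e-7,
                       max_modules = 10,
                       learning_rate = 0.01,
                       epochs = 200,
                       tau = 0.1,
                       k = 7,
                       hidden_dims = c(64L, 32L),
                       discr_dim = 16L,
                       edge_threshold = 0.5,
                       svm_C = 1.0,
                       t_test_variant = c("welch", "student"),
                       neg_sample_ratio = 1.0,
                       use_neg_sampling = TRUE,
                       seed = 1L,
                       use_knowledge = TRUE,
                       use_difference_prompt = TRUE,
                       use_gae = TRUE,
                       standardize = TRUE,
                       normalize_discriminator = TRUE,
                       auc_mode = c("cv", "resub"),
                       cv_folds_internal = 5L,
                       variance_prefilter = 0L) {
  t_test_variant <- match.arg(t_test_variant)
  auc_mode <- match.arg(auc_mode)
  stopifnot(length(hidden_dims) == 2L)
  cfg <- list(
    p_edge = p_edge, lambda1 = lambda1, lambda2 = lambda2,
    max_modules = as.integer(max_modules), learning_rate = learning_rate,
    epochs = as.integer(epochs), tau = tau, k = as.integer(k),
    hidden_dims = as.integer(hidden_dims), discr_dim = as.integer(discr_dim),
    edge_threshold = edge_threshold, svm_C = svm_C,
    t_test_variant = t_test_variant, neg_sample_ratio = neg_sample_ratio,
    use_neg_sampling = isTRUE(use_neg_sampling), seed = as.integer(seed),
    use_knowledge = isTRUE(use_knowledge),
    use_difference_prompt = isTRUE(use_difference_prompt),
    use_gae = isTRUE(use_gae), standardize = isTRUE(standardize),
    normalize_discriminator = isTRUE(normalize_discriminator),
    auc_mode = auc_mode, cv_folds_internal = as.integer(cv_folds_internal),
    variance_prefilter = as.integer(variance_prefilter)
  )
  validate_config(cfg)
  structure(cfg, class = "kenmir_config")
}

#' @keywords internal
validate_config <- function(cfg) {
  if (cfg$lambda1 < 0 || cfg$lambda2 < 0)
    stop("loss weights lambda1/lambda2 must be nonnegative", call. = FALSE)
  if (cfg$p_edge <= 0 || cfg$p_edge >= 1)
    stop("p_edge must lie strictly between 0 and 1", call. = FALSE)
  if (cfg$tau <= 0) stop("temperature tau must be positive", call. = FALSE)
  if (cfg$k > cfg$max_modules)
    stop("k must not exceed max_modules", call. = FALSE)
  if (cfg$epochs < 0) stop("epochs must be >= 0", call. = FALSE)
  if (cfg$neg_sample_ratio <= 0 && cfg$use_neg_sampling)
    stop("neg_sample_ratio must be positive when sampling is enabled",
         call. = FALSE)
  invisible(cfg)
}

#' Load a run configuration from YAML or JSON
#'
#' Unknown keys are an error, so typos cannot silently fall back to defaults.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file whose keys are
#'   arguments of [run_config()].
#' @return a `kenmir_config`.
#' @export
load_config <- function(path) {
  vals <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(vals)) vals <- list()
  known <- names(formals(run_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  do.call(run_config, vals)
}

#' Build a run manifest
#'
#' Records enough provenance (config hash, seed, package and R versions,
#' input checksums) to tell whether two runs were set up identically.
#'
#' @param config a `kenmir_config`.
#' @param inputs named list of objects (or file paths) whose checksums to
#'   record.
#' @return named list; serialize with [jsonlite::write_json()].
#' @export
run_manifest <- function(config, inputs = list()) {
  checksum <- function(x) {
    if (is.character(x) && length(x) == 1 && file.exists(x)) {
      fnv1a(readLines(x, warn = FALSE))
    } else object_hash(x)
  }
  list(
    config_hash = object_hash(unclass(config)),
    seed = config$seed,
    package_version = as.character(utils::packageVersion("kenmir")),
    r_version = as.character(getRversion()),
    input_checksums = lapply(inputs, checksum),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
}
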