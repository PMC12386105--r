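# End-to-end orchestration: cooperation network -> auto-encoder enhancement
# -> greedy module search -> top-k selection -> voting ensemble; plus the
# repeated stratified cross-validation harness.

#' Run the full biomarker-identification pipeline on training data
#'
#' Builds the cooperation network, enhances it with the graph auto-encoder
#' (skipped under `use_gae = FALSE`, in which case module search runs
#' directly on the binary cooperation network), finds modules greedily,
#' keeps the `k` best by AUC, and fits the voting ensemble. Only the given
#' (training) samples are ever used for fitting.
#'
#' @param data training [expression_dataset()].
#' @param knowledge a [knowledge_table()]; aligned internally.
#' @param config a [run_config()].
#' @param coop optionally, a precomputed [build_cooperation_network()]
#'   result for `data` (the network topology does not depend on the ablation
#'   flags, so it can be shared across ablation runs).
#' @param out_dir if given, intermediate artifacts (edge lists, latent
#'   matrix, loss trace, module file, manifest) are written there.
#' @return list of class `kenmir_fit` with elements `coop`, `gnet`, `gae`
#'   (`NULL` under `use_gae = FALSE`), `all_modules`, `modules` (top-k),
#'   `ensemble`, `config`, `manifest`.
#' @export
run_pipeline <- function(data, knowledge, config = run_config(),
                         coop = NULL, out_dir = NULL) {
  if (is.null(coop))
    coop <- build_cooperation_network(data, knowledge, config)
  ids <- coop$graph$node_ids
  # attributes depend on the knowledge ablation flag; derive them here so a
  # shared `coop` stays valid across ablation variants
  coop$attributes <- if (config$use_knowledge) {
    cbind(coop$knowledge$assoc, t(data$values[, ids, drop = FALSE]))
  } else {
    t(data$values[, ids, drop = FALSE])
  }

  gae <- NULL
  if (config$use_gae) {
    gae <- train_gae(coop, knowledge, data, config)
    gnet <- build_enhanced_network(gae$Z, ids, config$edge_threshold,
                                   candidates = coop$graph)
  } else {
    gnet <- coop$graph
  }

  all_modules <- with_seed(derive_seed(config$seed, 202L),
                           find_modules(gnet, data, config))
  modules <- select_top_k(all_modules, config$k)
  ensemble <- fit_ensemble(data, modules, config)
  manifest <- run_manifest(config, inputs = list(expression = data$values,
                                                 labels = data$labels,
                                                 knowledge = knowledge$assoc))
  fit <- structure(list(coop = coop, gnet = gnet, gae = gae,
                        all_modules = all_modules, modules = modules,
                        ensemble = ensemble, config = config,
                        manifest = manifest),
                   class = "kenmir_fit")
  if (!is.null(out_dir)) save_artifacts(fit, out_dir)
  fit
}

#' @export
print.kenmir_fit <- function(x, ...) {
  cat("kenmir_fit\n  ")
  print(x$coop$graph)
  cat("  enhanced: ")
  print(x$gnet)
  cat("  ")
  print(x$modules)
  invisible(x)
}

#' @keywords internal
save_artifacts <- function(fit, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_graph(fit$coop$graph, file.path(out_dir, "cooperation_network.tsv"))
  write_graph(fit$gnet, file.path(out_dir, "enhanced_network.tsv"))
  write_modules(fit$modules, file.path(out_dir, "modules.gmt"))
  if (!is.null(fit$gae)) {
    zdf <- data.frame(node_id = rownames(fit$gae$Z),
                      apply(fit$gae$Z, 2, format_num), check.names = FALSE)
    utils::write.table(zdf, file.path(out_dir, "latent.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(fit$gae$trace, file.path(out_dir, "loss_trace.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  write_ensemble(fit$ensemble, file.path(out_dir, "ensemble.json"))
  jsonlite::write_json(fit$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' @keywords internal
confusion_metrics <- function(tp, fp, tn, fn) {
  c(accuracy = 100 * (tp + tn) / (tp + fp + tn + fn),
    sensitivity = if (tp + fn > 0) 100 * tp / (tp + fn) else NA_real_,
    specificity = if (tn + fp > 0) 100 * tn / (tn + fp) else NA_real_)
}

#' Repeated stratified cross-validation of the full pipeline
#'
#' For each repeat, samples are split into stratified folds; the entire
#' pipeline (network, auto-encoder, modules, ensemble) is refit on each
#' training split, and held-out folds alone provide the confusion counts.
#' Metrics are reported in percent as mean and SD over all repeat x fold
#' evaluations. Folds are reduced (with a message) when a class has fewer
#' samples than folds. Folds on which no module is found fall back to
#' predicting the training majority class, with a message.
#'
#' @param data an [expression_dataset()].
#' @param knowledge a [knowledge_table()].
#' @param config a [run_config()]; per-fold seeds derive from `config$seed`.
#' @param folds,repeats cross-validation layout.
#' @return object of class `evaluation_report`: `per_fold` data.frame of
#'   confusion counts and metrics, `summary` data.frame (metric, mean, sd).
#' @export
cross_validate <- function(data, knowledge, config = run_config(),
                           folds = 10L, repeats = 10L) {
  y <- data$labels
  n1 <- sum(y == 1L); n0 <- sum(y == 0L)
  eff_folds <- min(folds, n1, n0)
  if (eff_folds < folds)
    message("folds reduced to ", eff_folds, " (smallest class has ",
            min(n1, n0), " samples)")
  rows <- list()
  for (r in seq_len(repeats)) {
    fold_of <- integer(length(y))
    with_seed(derive_seed(config$seed, 1000L + r), {
      for (cls in c(0L, 1L)) {
        idx <- sample(which(y == cls))
        fold_of[idx] <- rep_len(seq_len(eff_folds), length(idx))
      }
    })
    for (f in seq_len(eff_folds)) {
      tr_idx <- which(fold_of != f)
      te_idx <- which(fold_of == f)
      train <- subset_dataset(data, samples = tr_idx)
      test <- subset_dataset(data, samples = te_idx)
      cfg <- config
      cfg$seed <- derive_seed(config$seed, 100L * r + f)
      pred <- tryCatch({
        fit <- run_pipeline(train, knowledge, cfg)
        predict(fit$ensemble, test)$label
      }, error = function(e) {
        message("fold ", f, " repeat ", r, ": ", conditionMessage(e),
                "; predicting training majority class")
        maj <- as.integer(sum(train$labels == 1L) > sum(train$labels == 0L))
        rep(maj, length(te_idx))
      })
      truth <- test$labels
      tp <- sum(pred == 1L & truth == 1L)
      fp <- sum(pred == 1L & truth == 0L)
      tn <- sum(pred == 0L & truth == 0L)
      fn <- sum(pred == 0L & truth == 1L)
      met <- confusion_metrics(tp, fp, tn, fn)
      rows[[length(rows) + 1L]] <-
        data.frame(repeat_i = r, fold = f, tp = tp, fp = fp, tn = tn,
                   fn = fn, accuracy = met["accuracy"],
                   sensitivity = met["sensitivity"],
                   specificity = met["specificity"], row.names = NULL)
    }
  }
  per_fold <- do.call(rbind, rows)
  summarize <- function(v) c(mean = mean(v, na.rm = TRUE),
                             sd = stats::sd(v, na.rm = TRUE))
  summ <- rbind(accuracy = summarize(per_fold$accuracy),
                sensitivity = summarize(per_fold$sensitivity),
                specificity = summarize(per_fold$specificity))
  summary_df <- data.frame(metric = rownames(summ), mean = summ[, "mean"],
                           sd = summ[, "sd"], row.names = NULL)
  structure(list(per_fold = per_fold, summary = summary_df,
                 folds = eff_folds, repeats = repeats),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("evaluation_report: %d-fold CV x %d repeat(s)\n",
              x$folds, x$repeats))
  for (i in seq_len(nrow(x$summary)))
    cat(sprintf("  %-12s %6.2f%% +/- %.2f\n", x$summary$metric[i],
                x$summary$mean[i], x$summary$sd[i]))
  invisible(x)
}
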