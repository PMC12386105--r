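#' Fit the per-module voting ensemble
#'
#' One standardized linear SVM per selected module, each restricted to its
#' module's feature columns and fitted on all training samples. The ensemble
#' predicts by majority vote of the base classifiers.
#'
#' @param data the training [expression_dataset()].
#' @param modules a [module_set()] (typically from [select_top_k()]).
#' @param config a [run_config()].
#' @return object of class `voting_ensemble`.
#' @export
fit_ensemble <- function(data, modules, config = run_config()) {
  if (n_modules(modules) == 0L)
    stop("cannot fit an ensemble without modules", call. = FALSE)
  classifiers <- lapply(modules$modules, function(m) {
    x <- data$values[, m$members, drop = FALSE]
    if (config$standardize) {
      std <- standardize_columns(x)
      xs <- std$x; center <- std$center; scale <- std$scale
    } else {
      xs <- x
      center <- rep(0, ncol(x)); scale <- rep(1, ncol(x))
    }
    fit <- linear_svm_fit(xs, data$labels, C = config$svm_C)
    list(members = m$members, auc = m$auc, fit = fit,
         center = center, scale = scale)
  })
  structure(list(classifiers = classifiers, k = length(classifiers)),
            class = "voting_ensemble")
}

#' @export
print.voting_ensemble <- function(x, ...) {
  cat(sprintf("voting_ensemble: %d base linear SVM(s)\n", x$k))
  invisible(x)
}

#' Predict sample labels by majority voting
#'
#' Every base classifier votes with the sign of its decision score; the
#' majority label wins. An exact tie (possible for even `k`) falls back to
#' the sign of the mean decision score, reported with a message.
#'
#' @param object a `voting_ensemble`.
#' @param samples an [expression_dataset()] (labels may be placeholders)
#'   containing every feature the ensemble uses.
#' @param ... unused.
#' @return data.frame with `sample_id`, predicted `label`, `votes_case`,
#'   `votes_control`, `mean_score`.
#' @export
predict.voting_ensemble <- function(object, samples, ...) {
  needed <- unique(unlist(lapply(object$classifiers, `[[`, "members")))
  missing <- setdiff(needed, colnames(samples$values))
  if (length(missing))
    stop("sample data lack feature(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  n <- nrow(samples$values)
  scores <- sapply(object$classifiers, function(cl) {
    x <- samples$values[, cl$members, drop = FALSE]
    xs <- sweep(sweep(x, 2, cl$center, "-"), 2, cl$scale, "/")
    linear_svm_score(cl$fit, xs)
  })
  scores <- matrix(scores, nrow = n)
  votes <- scores > 0
  votes_case <- rowSums(votes)
  votes_control <- object$k - votes_case
  mean_score <- rowMeans(scores)
  label <- ifelse(votes_case > votes_control, 1L,
                  ifelse(votes_case < votes_control, 0L,
                         as.integer(mean_score > 0)))
  if (any(votes_case == votes_control))
    message(sum(votes_case == votes_control),
            " tied vote(s) resolved by mean decision score")
  data.frame(sample_id = rownames(samples$values), label = label,
             votes_case = votes_case, votes_control = votes_control,
             mean_score = mean_score, stringsAsFactors = FALSE)
}

#' Save a fitted voting ensemble as JSON
#'
#' The ensemble is a small collection of linear weights and standardization
#' parameters, so JSON keeps artifacts human-readable and diffable.
#'
#' @param ensemble a `voting_ensemble`.
#' @param path output path.
#' @export
write_ensemble <- function(ensemble, path) {
  obj <- lapply(ensemble$classifiers, function(cl)
    list(members = cl$members, auc = cl$auc,
         w = unname(cl$fit$w), b = cl$fit$b, C = cl$fit$C,
         center = unname(cl$center), scale = unname(cl$scale)))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a voting ensemble saved by [write_ensemble()]
#' @param path JSON path.
#' @return a `voting_ensemble`.
#' @export
read_ensemble <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  classifiers <- lapply(obj, function(cl)
    list(members = as.character(cl$members), auc = cl$auc,
         fit = list(w = as.numeric(cl$w), b = cl$b, C = cl$C),
         center = as.numeric(cl$center), scale = as.numeric(cl$scale)))
  structure(list(classifiers = classifiers, k = length(classifiers)),
            class = "voting_ensemble")
}
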