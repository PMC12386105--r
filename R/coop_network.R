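# Cooperation-network construction: edges mark miRNA pairs whose joint
# linear-SVM combination ("artificial combinatorial feature") differs
# significantly between the case and control groups.

#' Fit the pairwise separating hyperplane for two features
#'
#' A soft-margin linear SVM on the two-column submatrix (f_i, f_j) against
#' the sample labels yields the hyperplane
#' `alpha * f_i + beta * f_j + gamma = 0`; its left-hand side is the
#' artificial combinatorial feature of the pair. Features are z-scored on
#' the training samples before fitting (disable with `standardize = FALSE`);
#' the standardization parameters are stored so the combinatorial feature is
#' evaluated on the same scale.
#'
#' @param data an [expression_dataset()].
#' @param i,j feature indices (or ids).
#' @param C soft-margin cost.
#' @param standardize z-score the two columns before fitting.
#' @return object of class `pair_hyperplane` with `alpha`, `beta`, `gamma`,
#'   the indices and the standardization used; `NULL` (with a message) when
#'   either feature has zero variance, in which case the pair is skipped.
#' @export
fit_pair_hyperplane <- function(data, i, j, C = 1.0, standardize = TRUE) {
  if (is.character(i)) i <- match(i, colnames(data$values))
  if (is.character(j)) j <- match(j, colnames(data$values))
  x <- data$values[, c(i, j), drop = FALSE]
  if (any(apply(x, 2, stats::sd) == 0)) {
    message("zero-variance feature in pair (", i, ", ", j, "); pair skipped")
    return(NULL)
  }
  if (standardize) {
    std <- standardize_columns(x)
    xs <- std$x; center <- std$center; scale <- std$scale
  } else {
    xs <- x; center <- c(0, 0); scale <- c(1, 1)
  }
  fit <- linear_svm_fit(xs, data$labels, C = C)
  structure(list(i = i, j = j, alpha = fit$w[1], beta = fit$w[2],
                 gamma = fit$b, center = center, scale = scale),
            class = "pair_hyperplane")
}

#' Evaluate the artificial combinatorial feature of a pair
#'
#' Per-sample scalar `alpha * f_i(s) + beta * f_j(s) + gamma`, computed on
#' the same (standardized) scale the hyperplane was fitted on.
#'
#' @param h a `pair_hyperplane`.
#' @param data an [expression_dataset()] containing the pair's features.
#' @return numeric vector, one value per sample.
#' @export
combinatorial_feature <- function(h, data) {
  fi <- (data$values[, h$i] - h$center[1]) / h$scale[1]
  fj <- (data$values[, h$j] - h$center[2]) / h$scale[2]
  drop(h$alpha * fi + h$beta * fj + h$gamma)
}

#' Two-sample t-test p-value for a combinatorial feature
#'
#' Two-sided Welch (default) or pooled-variance Student t-test of the values
#' between the two label groups. Degenerate inputs (zero variance in both
#' groups) yield p = 1 when the group means agree (no evidence) and p = 0
#' when they differ (perfect separation); both cases are reported with a
#' message.
#'
#' @param values per-sample numeric vector.
#' @param labels binary labels (0/1).
#' @param variant `"welch"` or `"student"`.
#' @return p-value in `[0, 1]`.
#' @export
edge_significance <- function(values, labels, variant = c("welch", "student")) {
  variant <- match.arg(variant)
  a <- values[labels == 1L]
  b <- values[labels == 0L]
  if (length(a) < 2L || length(b) < 2L)
    stop("each group needs at least 2 samples", call. = FALSE)
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    if (mean(a) == mean(b)) {
      message("degenerate t-test (both groups constant, equal means): p = 1")
      return(1)
    }
    message("degenerate t-test (both groups constant, distinct means): p = 0")
    return(0)
  }
  stats::t.test(a, b, var.equal = (variant == "student"))$p.value
}

#' Build the miRNA cooperation network
#'
#' Enumerates all m(m-1)/2 feature pairs; for each, fits the pairwise
#' hyperplane, evaluates the combinatorial feature, and t-tests it between
#' groups. An edge joins f_i and f_j iff the p-value is below
#' `config$p_edge`. Node attributes concatenate the disease-association
#' profile d(f_i) (length p, dropped under `use_knowledge = FALSE`) with the
#' expression profile s(f_i) (length n).
#'
#' @param data an [expression_dataset()] (training samples only).
#' @param knowledge a [knowledge_table()]; aligned to the data features
#'   internally.
#' @param config a [run_config()].
#' @return object of class `cooperation_network`: `graph` (binary
#'   [weighted_graph()]), `attributes` (m x (p + n) matrix), `pvalues`
#'   (symmetric m x m matrix, `NA` diagonal and skipped pairs).
#' @export
build_cooperation_network <- function(data, knowledge, config = run_config()) {
  m <- n_features(data)
  if (m < 2L) stop("need at least 2 features to form pairs", call. = FALSE)
  if (config$variance_prefilter > 0L && config$variance_prefilter < m) {
    v <- apply(data$values, 2, stats::var)
    keep <- order(v, decreasing = TRUE)[seq_len(config$variance_prefilter)]
    data <- subset_dataset(data, features = sort(keep))
    m <- n_features(data)
  }
  ids <- colnames(data$values)
  kn <- align_knowledge(knowledge, ids)

  y <- data$labels
  if (config$standardize) {
    xs <- standardize_columns(data$values)$x
  } else {
    xs <- data$values
  }
  sds <- apply(data$values, 2, stats::sd)

  pv <- matrix(NA_real_, m, m, dimnames = list(ids, ids))
  adj <- matrix(0, m, m, dimnames = list(ids, ids))
  skipped <- 0L
  for (i in seq_len(m - 1L)) {
    for (j in (i + 1L):m) {
      if (sds[i] == 0 || sds[j] == 0) {
        skipped <- skipped + 1L
        next
      }
      fit <- linear_svm_fit(xs[, c(i, j), drop = FALSE], y, C = config$svm_C)
      fcom <- drop(xs[, c(i, j), drop = FALSE] %*% fit$w + fit$b)
      p <- suppressMessages(
        edge_significance(fcom, y, variant = config$t_test_variant))
      pv[i, j] <- pv[j, i] <- p
      if (p < config$p_edge) adj[i, j] <- adj[j, i] <- 1
    }
  }
  if (skipped > 0L)
    message(skipped, " pair(s) skipped for zero feature variance")

  attrs <- if (config$use_knowledge) {
    cbind(kn$assoc, t(data$values))
  } else {
    t(data$values)
  }
  rownames(attrs) <- ids
  structure(list(graph = weighted_graph(adj, ids), attributes = attrs,
                 pvalues = pv, knowledge = kn),
            class = "cooperation_network")
}

#' @export
print.cooperation_network <- function(x, ...) {
  cat("cooperation_network\n  ")
  print(x$graph)
  cat(sprintf("  attributes: %d x %d\n",
              nrow(x$attributes), ncol(x$attributes)))
  invisible(x)
}
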