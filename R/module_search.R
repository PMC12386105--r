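# Greedy AUC-guided module identification on the enhanced network, followed
# by top-k selection. A module starts at the most influential node (largest
# weighted degree), repeatedly pulls in the neighbor behind the heaviest
# outgoing edge, and keeps it when the module AUC improves — or, to escape
# local optima, with probability 1 - exp((AUC - 1)/cmn) when it does not.

#' Weighted degree of a node
#'
#' The node's influence: the sum of the weights of its incident edges.
#'
#' @param graph a [weighted_graph()].
#' @param node node id.
#' @return nonnegative scalar.
#' @export
node_importance <- function(graph, node) {
  if (!(node %in% graph$node_ids))
    stop("unknown node '", node, "'", call. = FALSE)
  sum(graph$weights[node, ])
}

#' Discriminative AUC of a feature subset
#'
#' Fits a standardized linear SVM on the member columns and scores samples;
#' AUC comes from the rank (Mann-Whitney) formula with ties counted 0.5.
#' Default mode is seeded stratified internal cross-validation
#' (`config$cv_folds_internal` folds, reduced when a class is smaller):
#' held-out decision scores from all folds are pooled before the AUC is
#' taken, which guards against trivially overfit AUC = 1 modules.
#' `auc_mode = "resub"` scores the training samples directly.
#'
#' The fold assignment is derived deterministically from `config$seed` and
#' the member set, so the estimate does not depend on evaluation order.
#'
#' @param data an [expression_dataset()].
#' @param members character vector of feature ids (non-empty, all present).
#' @param config a [run_config()].
#' @return AUC in `[0, 1]`.
#' @export
module_auc <- function(data, members, config = run_config()) {
  members <- as.character(members)
  if (length(members) == 0L) stop("empty member set", call. = FALSE)
  missing <- setdiff(members, colnames(data$values))
  if (length(missing))
    stop("feature(s) not in data: ", paste(missing, collapse = ", "),
         call. = FALSE)
  x <- data$values[, members, drop = FALSE]
  y <- data$labels

  if (config$auc_mode == "resub") {
    xs <- if (config$standardize) standardize_columns(x)$x else x
    fit <- linear_svm_fit(xs, y, C = config$svm_C)
    return(auc_score(linear_svm_score(fit, xs), y))
  }

  n1 <- sum(y == 1L); n0 <- sum(y == 0L)
  folds <- max(2L, min(config$cv_folds_internal, n1, n0))
  hash <- sum(utf8ToInt(paste(sort(members), collapse = ","))) %% 1000003L
  fold_of <- integer(length(y))
  with_seed(derive_seed(config$seed, 7L + hash), {
    for (cls in c(0L, 1L)) {
      idx <- sample(which(y == cls))
      fold_of[idx] <- rep_len(seq_len(folds), length(idx))
    }
  })
  scores <- numeric(length(y))
  for (f in seq_len(folds)) {
    tr <- fold_of != f
    te <- !tr
    if (config$standardize) {
      std <- standardize_columns(x[tr, , drop = FALSE])
      xtr <- std$x
      xte <- sweep(sweep(x[te, , drop = FALSE], 2, std$center, "-"),
                   2, std$scale, "/")
    } else {
      xtr <- x[tr, , drop = FALSE]
      xte <- x[te, , drop = FALSE]
    }
    fit <- linear_svm_fit(xtr, y[tr], C = config$svm_C)
    scores[te] <- linear_svm_score(fit, xte)
  }
  auc_score(scores, y)
}

#' Probabilistic acceptance of a non-improving extension
#'
#' `Prob_t = 1 - exp((AUC_cmn - 1) / cmn)` where `cmn` counts the nodes of
#' the candidate module (current members plus the candidate). Strictly
#' decreasing in the AUC and zero exactly at AUC = 1.
#'
#' @param auc_cmn AUC of the candidate module, in `[0, 1]`.
#' @param cmn candidate module size (>= 1).
#' @return probability in `[0, 1)`.
#' @export
acceptance_probability <- function(auc_cmn, cmn) {
  if (cmn < 1) stop("cmn must be a positive integer", call. = FALSE)
  1 - exp((auc_cmn - 1) / cmn)
}

#' Grow one module from a seed node
#'
#' Starts from `{seed_node}`. Each step finds the maximum-weight edge from
#' the module to the outside; its outside endpoint is the candidate (ties on
#' edge weight go to the candidate whose addition gives the largest AUC,
#' residual ties to the lexicographically smallest id). The candidate is
#' accepted when it strictly improves the module AUC, otherwise with
#' probability [acceptance_probability()]; a rejection — or no outgoing edge
#' — ends the extension.
#'
#' @param graph a [weighted_graph()].
#' @param data an [expression_dataset()].
#' @param seed_node starting node id.
#' @param config a [run_config()].
#' @param runif_fn uniform sampler used for the probabilistic gate; defaults
#'   to the ambient RNG (seed it for reproducibility).
#' @return list with `members` (character) and `auc`.
#' @export
grow_module <- function(graph, data, seed_node, config = run_config(),
                        runif_fn = stats::runif) {
  if (!(seed_node %in% graph$node_ids))
    stop("unknown seed node '", seed_node, "'", call. = FALSE)
  members <- seed_node
  auc_cur <- module_auc(data, members, config)
  W <- graph$weights
  repeat {
    outside <- setdiff(graph$node_ids, members)
    if (length(outside) == 0L) break
    sub <- W[members, outside, drop = FALSE]
    wmax <- max(sub)
    if (wmax <= 0) break
    cand <- outside[apply(sub, 2, max) == wmax]
    if (length(cand) > 1L) {
      cand_auc <- vapply(cand, function(cn)
        module_auc(data, c(members, cn), config), numeric(1))
      cand <- cand[cand_auc == max(cand_auc)]
      cand <- sort(cand)[1]
      auc_cmn <- max(cand_auc)
    } else {
      auc_cmn <- module_auc(data, c(members, cand), config)
    }
    if (auc_cmn > auc_cur) {
      accept <- TRUE
    } else {
      prob <- acceptance_probability(auc_cmn, length(members) + 1L)
      accept <- runif_fn(1) < prob
    }
    if (!accept) break
    members <- c(members, cand)
    auc_cur <- auc_cmn
  }
  list(members = members, auc = auc_cur)
}

#' Find disjoint modules by repeated greedy growth
#'
#' Seeds each module at the non-isolated node with the largest weighted
#' degree (ties to the lexicographically smallest id), grows it with
#' [grow_module()], removes its nodes and incident edges, and repeats until
#' no edges remain or `config$max_modules` modules are found.
#'
#' @inheritParams grow_module
#' @return a [module_set()] (empty for an edgeless graph).
#' @export
find_modules <- function(graph, data, config = run_config(),
                         runif_fn = stats::runif) {
  mods <- list()
  g <- graph
  while (length(mods) < config$max_modules) {
    deg <- rowSums(g$weights)
    cands <- g$node_ids[deg > 0]
    if (length(cands) == 0L) break
    seed_node <- sort(cands[deg[cands] == max(deg[cands])])[1]
    grown <- grow_module(g, data, seed_node, config, runif_fn)
    mods[[length(mods) + 1L]] <- grown
    keep <- setdiff(g$node_ids, grown$members)
    if (length(keep) == 0L) break
    g <- weighted_graph(g$weights[keep, keep, drop = FALSE], keep)
  }
  module_set(mods, source_graph_id = "greedy-search")
}

#' Keep the k highest-AUC modules
#'
#' Sorted AUC-descending; ties go to the smaller module, then to the
#' lexicographically first member. When fewer than `k` modules are
#' available all are kept, with a warning.
#'
#' @param modules a [module_set()].
#' @param k number of key modules to keep (>= 1).
#' @return a [module_set()] with at most `k` modules.
#' @export
select_top_k <- function(modules, k) {
  if (n_modules(modules) == 0L)
    stop("no modules found; nothing to select", call. = FALSE)
  if (k < 1) stop("k must be >= 1", call. = FALSE)
  ms <- modules$modules
  aucs <- vapply(ms, `[[`, numeric(1), "auc")
  sizes <- vapply(ms, function(m) length(m$members), integer(1))
  firsts <- vapply(ms, function(m) sort(m$members)[1], character(1))
  ord <- order(-aucs, sizes, firsts)
  if (length(ms) < k)
    warning("only ", length(ms), " module(s) available; k = ", k,
            call. = FALSE)
  module_set(ms[ord[seq_len(min(k, length(ms)))]],
             source_graph_id = modules$source_graph_id)
}
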