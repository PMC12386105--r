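#' Undirected weighted graph
#'
#' Carrier for both the binary cooperation network and the weighted enhanced
#' network: a symmetric nonnegative weight matrix with zero diagonal.
#'
#' @param weights symmetric numeric matrix, zero diagonal, entries >= 0.
#' @param node_ids node identifiers; default rownames.
#' @return object of class `weighted_graph`.
#' @export
weighted_graph <- function(weights, node_ids = rownames(weights)) {
  weights <- as.matrix(weights)
  if (is.null(node_ids)) node_ids <- paste0("f", seq_len(nrow(weights)))
  node_ids <- as.character(node_ids)
  if (nrow(weights) != ncol(weights) || length(node_ids) != nrow(weights))
    stop("weight matrix must be square and match node_ids", call. = FALSE)
  if (!isSymmetric(unname(weights), tol = 1e-12))
    stop("weight matrix must be symmetric", call. = FALSE)
  if (any(diag(weights) != 0))
    stop("weight matrix must have a zero diagonal", call. = FALSE)
  if (any(weights < 0)) stop("edge weights must be nonnegative", call. = FALSE)
  dimnames(weights) <- list(node_ids, node_ids)
  structure(list(node_ids = node_ids, weights = weights),
            class = "weighted_graph")
}

#' @export
print.weighted_graph <- function(x, ...) {
  cat(sprintf("weighted_graph: %d nodes, %d edges\n",
              length(x$node_ids), sum(x$weights[upper.tri(x$weights)] > 0)))
  invisible(x)
}

#' Edge list of a weighted graph
#'
#' Each undirected edge once, with `node_a < node_b` lexicographically.
#' @param graph a `weighted_graph`.
#' @return data.frame with columns `node_a`, `node_b`, `weight`.
#' @export
graph_edges <- function(graph) {
  w <- graph$weights
  idx <- which(upper.tri(w) & w > 0, arr.ind = TRUE)
  if (nrow(idx) == 0)
    return(data.frame(node_a = character(), node_b = character(),
                      weight = numeric(), stringsAsFactors = FALSE))
  a <- graph$node_ids[idx[, 1]]
  b <- graph$node_ids[idx[, 2]]
  swap <- a > b
  tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
  df <- data.frame(node_a = a, node_b = b, weight = w[idx],
                   stringsAsFactors = FALSE)
  df[order(df$node_a, df$node_b), , drop = FALSE]
}

#' Write a graph as a three-column edge-list TSV
#'
#' Columns `node_a`, `node_b`, `weight`; each undirected edge appears once
#' with `node_a < node_b` lexicographically; weights carry 15 significant
#' digits so a read round-trips exactly.
#'
#' @param graph a `weighted_graph`.
#' @param path output path.
#' @export
write_graph <- function(graph, path) {
  stopifnot(inherits(graph, "weighted_graph"))
  df <- graph_edges(graph)
  df$weight <- format_num(df$weight)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an edge-list TSV back into a `weighted_graph`
#'
#' @param path edge-list path as written by [write_graph()].
#' @param node_ids full node set (isolated nodes are not recoverable from an
#'   edge list); defaults to the ids appearing in the file.
#' @return a `weighted_graph`.
#' @export
read_graph <- function(path, node_ids = NULL) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE,
                          colClasses = c("character", "character", "numeric"))
  if (is.null(node_ids)) node_ids <- sort(unique(c(df$node_a, df$node_b)))
  w <- matrix(0, length(node_ids), length(node_ids),
              dimnames = list(node_ids, node_ids))
  if (nrow(df)) {
    unknown <- setdiff(c(df$node_a, df$node_b), node_ids)
    if (length(unknown))
      stop("edge endpoint(s) not in node_ids: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    w[cbind(df$node_a, df$node_b)] <- df$weight
    w[cbind(df$node_b, df$node_a)] <- df$weight
  }
  weighted_graph(w, node_ids)
}

#' Module set
#'
#' Disjoint feature subsets with their AUC scores, ordered AUC-descending.
#'
#' @param modules list of `list(members = <character>, auc = <numeric>)`.
#' @param source_graph_id provenance tag (free text).
#' @return object of class `module_set`.
#' @export
module_set <- function(modules = list(), source_graph_id = "") {
  all_members <- unlist(lapply(modules, `[[`, "members"))
  if (anyDuplicated(all_members))
    stop("modules must be pairwise disjoint", call. = FALSE)
  aucs <- vapply(modules, `[[`, numeric(1), "auc")
  if (any(aucs < 0 | aucs > 1)) stop("AUC must lie in [0, 1]", call. = FALSE)
  modules <- modules[order(-aucs)]
  structure(list(modules = modules, source_graph_id = source_graph_id),
            class = "module_set")
}

#' @export
print.module_set <- function(x, ...) {
  cat(sprintf("module_set: %d module(s)\n", length(x$modules)))
  for (i in seq_along(x$modules)) {
    m <- x$modules[[i]]
    cat(sprintf("  M_%d (AUC %.3f): %s\n", i, m$auc,
                paste(m$members, collapse = ", ")))
  }
  invisible(x)
}

#' @rdname module_set
#' @param x a `module_set`.
#' @export
n_modules <- function(x) length(x$modules)

#' Write modules as GMT-style lines
#'
#' One line per module, AUC-descending: module id, AUC as the description
#' field, then the member feature ids, all tab-separated.
#'
#' @param modules a `module_set`.
#' @param path output path.
#' @export
write_modules <- function(modules, path) {
  stopifnot(inherits(modules, "module_set"))
  lines <- vapply(seq_along(modules$modules), function(i) {
    m <- modules$modules[[i]]
    paste(c(paste0("M_", i), format_num(m$auc), m$members), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a GMT-style module file written by [write_modules()]
#' @param path module file path.
#' @return a `module_set`.
#' @export
read_modules <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  mods <- lapply(lines, function(l) {
    parts <- strsplit(l, "\t", fixed = TRUE)[[1]]
    list(members = parts[-(1:2)], auc = as.numeric(parts[2]))
  })
  module_set(mods)
}
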