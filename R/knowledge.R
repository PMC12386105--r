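#' miRNA-disease association table
#'
#' Binary `m x p` matrix: entry (i, t) is 1 when miRNA i is reported to be
#' associated with disease t, as exported from curated databases.
#'
#' @param assoc binary matrix, miRNAs in rows, diseases in columns.
#' @param feature_ids,disease_ids identifiers; default to dimnames.
#' @return an object of class `knowledge_table`.
#' @export
knowledge_table <- function(assoc, feature_ids = rownames(assoc),
                            disease_ids = colnames(assoc)) {
  assoc <- as.matrix(assoc)
  if (is.null(feature_ids)) feature_ids <- paste0("f", seq_len(nrow(assoc)))
  if (is.null(disease_ids)) disease_ids <- paste0("d", seq_len(ncol(assoc)))
  feature_ids <- as.character(feature_ids)
  disease_ids <- as.character(disease_ids)
  if (ncol(assoc) < 1L) stop("empty disease set", call. = FALSE)
  if (anyDuplicated(feature_ids))
    stop("duplicate feature id(s) in knowledge table", call. = FALSE)
  if (anyDuplicated(disease_ids))
    stop("duplicate disease id(s) in knowledge table", call. = FALSE)
  bad <- which(!(assoc %in% c(0, 1)))
  if (length(bad)) {
    idx <- arrayInd(bad[1], dim(assoc))
    stop(sprintf("non-binary entry '%s' at miRNA '%s', disease '%s'",
                 assoc[bad[1]], feature_ids[idx[1]], disease_ids[idx[2]]),
         call. = FALSE)
  }
  storage.mode(assoc) <- "double"
  dimnames(assoc) <- list(feature_ids, disease_ids)
  structure(list(assoc = assoc), class = "knowledge_table")
}

#' @export
print.knowledge_table <- function(x, ...) {
  cat(sprintf("knowledge_table: %d miRNAs x %d diseases (%d associations)\n",
              nrow(x$assoc), ncol(x$assoc), sum(x$assoc)))
  invisible(x)
}

#' Align a knowledge table to a feature list
#'
#' Rows are reordered to `features`; miRNAs without a database record receive
#' an all-zero association profile (a warning reports how many), so
#' expression-side features are never dropped for lack of knowledge coverage.
#'
#' @param knowledge a `knowledge_table`.
#' @param features ordered character vector of feature ids.
#' @return a `knowledge_table` whose rows are exactly `features`, in order.
#' @export
align_knowledge <- function(knowledge, features) {
  features <- as.character(features)
  m <- matrix(0, length(features), ncol(knowledge$assoc),
              dimnames = list(features, colnames(knowledge$assoc)))
  present <- intersect(features, rownames(knowledge$assoc))
  m[present, ] <- knowledge$assoc[present, , drop = FALSE]
  absent <- setdiff(features, rownames(knowledge$assoc))
  if (length(absent))
    warning(length(absent), " feature(s) absent from the knowledge table; ",
            "assigned all-zero association profiles", call. = FALSE)
  knowledge_table(m)
}

#' Read a miRNA-disease association table and align it to a feature list
#'
#' @param path TSV/CSV with a header of disease ids and a first column of
#'   miRNA ids; entries must be 0/1.
#' @param features ordered feature ids to align rows to (see
#'   [align_knowledge()]).
#' @param sep field separator; guessed from the extension when `NULL`.
#' @return a `knowledge_table` aligned to `features`.
#' @export
read_knowledge <- function(path, features, sep = NULL) {
  sep <- sep %||% guess_sep(path)
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           check.names = FALSE, stringsAsFactors = FALSE)
  ids <- as.character(tab[[1]])
  mat <- as.matrix(tab[, -1, drop = FALSE])
  storage.mode(mat) <- "double"
  rownames(mat) <- ids
  align_knowledge(knowledge_table(mat), features)
}

#' Write a knowledge table
#' @param knowledge a `knowledge_table`.
#' @param path output path.
#' @export
write_knowledge <- function(knowledge, path) {
  df <- data.frame(mirna_id = rownames(knowledge$assoc), knowledge$assoc,
                   check.names = FALSE)
  utils::write.table(df, path, sep = guess_sep(path), quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a probe-to-accession mapping table
#'
#' Two columns: probe id, miRNA accession. A probe listed with more than one
#' distinct accession is treated as multi-mapped downstream; several probes
#' may map to the same accession.
#'
#' @param path TSV/CSV path with a header row.
#' @param sep field separator; guessed from the extension when `NULL`.
#' @return data.frame of class `mapping_table` with columns `probe_id`,
#'   `accession`.
#' @export
read_mapping <- function(path, sep = NULL) {
  sep <- sep %||% guess_sep(path)
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           check.names = FALSE, stringsAsFactors = FALSE)
  mapping_table(tab[[1]], tab[[2]])
}

#' @rdname read_mapping
#' @param probe_id,accession character vectors of equal length.
#' @export
mapping_table <- function(probe_id, accession) {
  df <- data.frame(probe_id = as.character(probe_id),
                   accession = as.character(accession),
                   stringsAsFactors = FALSE)
  df <- unique(df)
  structure(df, class = c("mapping_table", "data.frame"))
}
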