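#' Labeled expression dataset
#'
#' The central container: an `n` samples x `m` features real matrix plus a
#' binary group label per sample (case = 1, control = 0).
#'
#' @param values numeric matrix, samples in rows, features in columns.
#' @param labels binary vector (0/1), one entry per sample.
#' @param feature_ids,sample_ids identifiers; default to dimnames.
#' @return an object of class `expression_dataset` with elements `values`
#'   (dimnamed matrix) and `labels` (named integer vector).
#' @export
expression_dataset <- function(values, labels,
                               feature_ids = colnames(values),
                               sample_ids = rownames(values)) {
  values <- as.matrix(values)
  if (is.null(feature_ids)) feature_ids <- paste0("f", seq_len(ncol(values)))
  if (is.null(sample_ids)) sample_ids <- paste0("s", seq_len(nrow(values)))
  feature_ids <- as.character(feature_ids)
  sample_ids <- as.character(sample_ids)
  if (length(feature_ids) != ncol(values) || length(sample_ids) != nrow(values))
    stop("id lists do not match the value matrix dimensions", call. = FALSE)
  if (anyNA(values)) {
    idx <- which(is.na(values), arr.ind = TRUE)[1, ]
    stop(sprintf("missing value at sample '%s', feature '%s'",
                 sample_ids[idx[1]], feature_ids[idx[2]]), call. = FALSE)
  }
  if (anyDuplicated(feature_ids))
    stop("duplicate feature id(s): ",
         paste(unique(feature_ids[duplicated(feature_ids)]), collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(sample_ids))
    stop("duplicate sample id(s): ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "),
         call. = FALSE)
  labels <- as.integer(labels)
  if (length(labels) != nrow(values))
    stop("labels length does not match the number of samples", call. = FALSE)
  if (anyNA(labels) || !all(labels %in% c(0L, 1L)))
    stop("labels must be binary (case = 1, control = 0)", call. = FALSE)
  if (sum(labels == 0L) < 2L || sum(labels == 1L) < 2L)
    stop("each label class needs at least 2 samples", call. = FALSE)
  dimnames(values) <- list(sample_ids, feature_ids)
  names(labels) <- sample_ids
  structure(list(values = values, labels = labels),
            class = "expression_dataset")
}

#' @export
print.expression_dataset <- function(x, ...) {
  cat(sprintf("expression_dataset: %d samples x %d features (%d cases, %d controls)\n",
              nrow(x$values), ncol(x$values),
              sum(x$labels == 1L), sum(x$labels == 0L)))
  invisible(x)
}

#' Number of samples / features
#' @rdname expression_dataset
#' @param x an `expression_dataset`.
#' @export
n_samples <- function(x) nrow(x$values)

#' @rdname expression_dataset
#' @export
n_features <- function(x) ncol(x$values)

#' Subset an expression dataset by samples and/or features
#' @keywords internal
subset_dataset <- function(data, samples = NULL, features = NULL) {
  v <- data$values
  l <- data$labels
  if (!is.null(samples)) {
    v <- v[samples, , drop = FALSE]
    l <- l[samples]
  }
  if (!is.null(features)) v <- v[, features, drop = FALSE]
  structure(list(values = v, labels = l), class = "expression_dataset")
}

#' Read a labeled expression table
#'
#' Expects a delimited file (TSV by extension default, CSV for `.csv`) with a
#' header row of feature ids and a first column of sample ids. Labels come
#' either from a column of the same file (`label_spec` = its name) or from a
#' two-column sidecar file (sample_id, label) passed as an existing path.
#' With `transposed = TRUE` the file holds features in rows and samples in
#' columns.
#'
#' @param path expression table path.
#' @param label_spec label column name or path to a sidecar label file.
#' @param transposed set when the file is features x samples.
#' @param sep field separator; guessed from the extension when `NULL`.
#' @return an [expression_dataset()].
#' @export
read_expression <- function(path, label_spec, transposed = FALSE, sep = NULL) {
  sep <- sep %||% guess_sep(path)
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           check.names = FALSE, stringsAsFactors = FALSE)
  row_ids <- as.character(tab[[1]])
  mat <- as.matrix(tab[, -1, drop = FALSE])
  storage.mode(mat) <- "double"
  rownames(mat) <- row_ids
  # data.frame subsetting mangles duplicated header names; restore them so
  # duplicate ids are caught by validation rather than silently renamed
  hdr <- strsplit(readLines(path, n = 1L), sep, fixed = TRUE)[[1]]
  colnames(mat) <- hdr[-1]
  if (transposed) mat <- t(mat)

  labels_from_file <- is.character(label_spec) && file.exists(label_spec) &&
    label_spec != "" && !(label_spec %in% colnames(mat))
  if (labels_from_file) {
    lt <- utils::read.table(label_spec, header = TRUE, sep = guess_sep(label_spec),
                            check.names = FALSE, stringsAsFactors = FALSE)
    lab <- stats::setNames(as.integer(lt[[2]]), as.character(lt[[1]]))
    missing <- setdiff(rownames(mat), names(lab))
    if (length(missing))
      stop("no label for sample(s): ", paste(missing, collapse = ", "),
           call. = FALSE)
    labels <- lab[rownames(mat)]
  } else {
    if (!(label_spec %in% colnames(mat)))
      stop("label column '", label_spec, "' not found", call. = FALSE)
    lab_col <- which(colnames(mat) == label_spec)[1]
    labels <- as.integer(mat[, lab_col])
    mat <- mat[, -lab_col, drop = FALSE]
  }
  expression_dataset(mat, labels)
}

#' Write an expression dataset (inverse of [read_expression()])
#' @param data an `expression_dataset`.
#' @param path output path; labels go into a `label` column.
#' @export
write_expression <- function(data, path) {
  sep <- guess_sep(path)
  m <- cbind(data$values, label = data$labels)
  df <- data.frame(sample_id = rownames(data$values),
                   apply(m, 2, format_num), check.names = FALSE)
  # numbers are pre-formatted to 15 significant digits
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}
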