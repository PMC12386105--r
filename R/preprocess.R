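#' Collapse probe-level rows to miRNA accessions
#'
#' Applies the standard microarray cleanup rules ahead of network analysis:
#' probes mapping to more than one accession are removed; probes with no
#' mapping entry are removed; when several probes map to the same accession
#' only the one with the highest mean expression across all samples is kept
#' (ties broken by input order, with a message); surviving features are
#' renamed to their accessions.
#'
#' Means are taken on the values as provided (no log transform).
#'
#' @param probes an [expression_dataset()] whose features are probe ids.
#' @param mapping a [mapping_table()].
#' @return an `expression_dataset` whose features are accessions.
#' @export
collapse_probes <- function(probes, mapping) {
  parts <- collapse_probes_impl(probes, mapping)
  if (length(parts$keep) == 0L)
    stop("no probe survives mapping and collapsing", call. = FALSE)
  out <- probes$values[, parts$keep, drop = FALSE]
  colnames(out) <- parts$accession
  expression_dataset(out, probes$labels)
}

#' @keywords internal
collapse_probes_impl <- function(probes, mapping) {
  probe_ids <- colnames(probes$values)
  n_acc <- tapply(mapping$accession, mapping$probe_id,
                  function(a) length(unique(a)))
  multimapped <- probe_ids[probe_ids %in% names(n_acc)[n_acc > 1]]
  unmapped <- setdiff(probe_ids, mapping$probe_id)
  candidates <- setdiff(probe_ids, c(multimapped, unmapped))

  acc_of <- stats::setNames(mapping$accession, mapping$probe_id)
  acc <- acc_of[candidates]
  keep <- character(0)
  dup_discarded <- 0L
  for (a in unique(acc)) {
    grp <- candidates[acc == a]          # input order preserved
    if (length(grp) > 1L) {
      means <- colMeans(probes$values[, grp, drop = FALSE])
      best <- grp[which.max(means)]      # which.max keeps the first on ties
      if (sum(means == max(means)) > 1L)
        message("mean tie among probes for accession '", a,
                "'; kept first in input order: ", best)
      dup_discarded <- dup_discarded + length(grp) - 1L
    } else best <- grp
    keep <- c(keep, best)
  }
  # keep input order of the surviving probes
  keep <- probe_ids[probe_ids %in% keep]
  list(keep = keep, accession = unname(acc_of[keep]),
       multimapped = multimapped, unmapped = unmapped,
       duplicates_discarded = dup_discarded)
}

#' Summarize what probe collapsing would remove and retain
#'
#' @inheritParams collapse_probes
#' @return named list of counts: `input`, `removed_multimapped`,
#'   `removed_unmapped`, `duplicates_discarded`, `retained`. The categories
#'   always sum back to `input`.
#' @export
preprocess_report <- function(probes, mapping) {
  parts <- collapse_probes_impl(probes, mapping)
  list(input = ncol(probes$values),
       removed_multimapped = length(parts$multimapped),
       removed_unmapped = length(parts$unmapped),
       duplicates_discarded = parts$duplicates_discarded,
       retained = length(parts$keep))
}
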