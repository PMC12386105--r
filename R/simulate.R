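# Synthetic two-group benchmark with planted cooperative modules and a
# matching disease-association knowledge table. Module features are
# equicorrelated Gaussians shifted upward in cases; knowledge rows of a
# module share a disease block, satisfying the premise that functionally
# similar miRNAs associate with similar diseases, with independent flip
# noise on every entry.

#' Specify a synthetic benchmark
#'
#' Defaults describe the reference benchmark used throughout the test suite:
#' 30 samples per group, 120 features, three planted modules of 8 features
#' with within-module correlation 0.6 and case mean-shift 1.5, 20 diseases,
#' 5% knowledge flip noise.
#'
#' @param n_per_group samples per class.
#' @param m total number of features.
#' @param modules list of `list(size, rho, delta)` per planted module:
#'   size, equicorrelation in `[0, 1)`, case mean shift `>= 0`.
#' @param p number of diseases.
#' @param knowledge_flip probability of flipping each knowledge entry,
#'   in `[0, 0.5)`.
#' @param noise_sd standard deviation of background features.
#' @param background_assoc_rate density of 1-entries in background
#'   knowledge rows before flips.
#' @param seed integer seed; fully determines the draw.
#' @return object of class `simulation_spec`.
#' @export
simulation_spec <- function(n_per_group = 30L, m = 120L,
                            modules = rep(list(list(size = 8L, rho = 0.6,
                                                    delta = 1.5)), 3),
                            p = 20L, knowledge_flip = 0.05, noise_sd = 1,
                            background_assoc_rate = 0.05, seed = 0L) {
  sizes <- vapply(modules, `[[`, numeric(1), "size")
  rhos <- vapply(modules, `[[`, numeric(1), "rho")
  deltas <- vapply(modules, `[[`, numeric(1), "delta")
  if (sum(sizes) > m)
    stop("module sizes exceed the number of features", call. = FALSE)
  if (any(rhos < 0 | rhos >= 1))
    stop("within-module correlation must lie in [0, 1)", call. = FALSE)
  if (any(deltas < 0)) stop("mean shifts must be >= 0", call. = FALSE)
  if (knowledge_flip < 0 || knowledge_flip >= 0.5)
    stop("knowledge_flip must lie in [0, 0.5)", call. = FALSE)
  if (noise_sd <= 0) stop("noise_sd must be positive", call. = FALSE)
  structure(list(n_per_group = as.integer(n_per_group), m = as.integer(m),
                 modules = modules, p = as.integer(p),
                 knowledge_flip = knowledge_flip, noise_sd = noise_sd,
                 background_assoc_rate = background_assoc_rate,
                 seed = as.integer(seed)),
            class = "simulation_spec")
}

#' Draw a synthetic dataset with known ground truth
#'
#' Module features are equicorrelated multivariate normal (pairwise
#' correlation `rho`, unit variance) with mean `+delta` in cases and 0 in
#' controls; background features are independent `N(0, noise_sd^2)` in both
#' groups. Each planted module owns a distinct block of diseases: its
#' members carry 1s on that block; background rows are sparse Bernoulli.
#' Every knowledge entry is then flipped independently with probability
#' `knowledge_flip`.
#'
#' @param spec a [simulation_spec()].
#' @return list with `data` (an [expression_dataset()], cases first),
#'   `knowledge` (a [knowledge_table()]), and `truth` (list: `membership` —
#'   named vector, `NA` for background; `differential` — named logical;
#'   `true_assoc` — pre-flip association matrix; `module_members` — list of
#'   feature-id vectors).
#' @export
simulate_dataset <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  with_seed(spec$seed, {
    n <- 2L * spec$n_per_group
    labels <- rep(c(1L, 0L), each = spec$n_per_group)
    feature_ids <- sprintf("MIMAT%07d", seq_len(spec$m))
    sample_ids <- sprintf("%s%03d", ifelse(labels == 1L, "case", "ctrl"),
                          c(seq_len(spec$n_per_group),
                            seq_len(spec$n_per_group)))
    values <- matrix(NA_real_, n, spec$m,
                     dimnames = list(sample_ids, feature_ids))
    membership <- stats::setNames(rep(NA_integer_, spec$m), feature_ids)
    differential <- stats::setNames(logical(spec$m), feature_ids)

    pos <- 1L
    module_members <- list()
    for (t in seq_along(spec$modules)) {
      md <- spec$modules[[t]]
      cols <- pos:(pos + md$size - 1L)
      g <- stats::rnorm(n)                       # shared module factor
      e <- matrix(stats::rnorm(n * md$size), n, md$size)
      x <- sqrt(md$rho) * g + sqrt(1 - md$rho) * e
      x[labels == 1L, ] <- x[labels == 1L, ] + md$delta
      values[, cols] <- x
      membership[cols] <- t
      differential[cols] <- md$delta > 0
      module_members[[t]] <- feature_ids[cols]
      pos <- pos + md$size
    }
    if (pos <= spec$m) {
      bg <- pos:spec$m
      values[, bg] <- matrix(stats::rnorm(n * length(bg), sd = spec$noise_sd),
                             n, length(bg))
    }

    nmod <- length(spec$modules)
    block <- max(1L, spec$p %/% (nmod + 1L))
    true_assoc <- matrix(0, spec$m, spec$p,
                         dimnames = list(feature_ids,
                                         sprintf("disease%02d",
                                                 seq_len(spec$p))))
    for (t in seq_len(nmod)) {
      dblock <- ((t - 1L) * block + 1L):(t * block)
      true_assoc[module_members[[t]], dblock] <- 1
    }
    bg_rows <- feature_ids[is.na(membership)]
    if (length(bg_rows))
      true_assoc[bg_rows, ] <- matrix(
        stats::rbinom(length(bg_rows) * spec$p, 1,
                      spec$background_assoc_rate),
        length(bg_rows), spec$p)
    flips <- matrix(stats::runif(spec$m * spec$p) < spec$knowledge_flip,
                    spec$m, spec$p)
    assoc <- abs(true_assoc - flips)

    list(data = expression_dataset(values, labels),
         knowledge = knowledge_table(assoc),
         truth = list(membership = membership, differential = differential,
                      true_assoc = true_assoc,
                      module_members = module_members))
  })
}

#' Score module recovery against the planted ground truth
#'
#' For each planted module, the best Jaccard index over the found modules;
#' the mean over planted modules summarizes recovery.
#'
#' @param found a [module_set()].
#' @param truth the `truth` element of [simulate_dataset()].
#' @return list with `per_module` (numeric vector) and `mean`.
#' @export
score_recovery <- function(found, truth) {
  jaccard <- function(a, b) {
    u <- length(union(a, b))
    if (u == 0) return(0)
    length(intersect(a, b)) / u
  }
  per <- vapply(truth$module_members, function(planted) {
    if (n_modules(found) == 0L) return(0)
    max(vapply(found$modules, function(m) jaccard(planted, m$members),
               numeric(1)))
  }, numeric(1))
  list(per_module = per, mean = mean(per))
}
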