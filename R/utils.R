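# Internal helpers shared across the package.

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate code under a temporary RNG seed
#'
#' Saves the global RNG state, seeds it, evaluates `code`, and restores the
#' previous state so callers are unaffected.
#' @keywords internal
with_seed <- function(seed, code) {
  has_state <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_state) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_state) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

#' Derive a child seed from a master seed
#'
#' Deterministic, keeps the result in [0, 2^31 - 2] so it is always a valid
#' 32-bit integer seed.
#' @keywords internal
derive_seed <- function(seed, i) {
  as.integer((as.numeric(seed) %% 2147483647 + 7919 * as.numeric(i)) %% 2147483647)
}

#' FNV-1a hash of a character scalar, as hex
#' @keywords internal
fnv1a <- function(x) {
  bytes <- utf8ToInt(paste(x, collapse = "\n"))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), as.integer(b))
    # 32-bit multiply by the FNV prime, done in doubles to avoid overflow
    h <- (h * 16777619) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

#' Stable hash of an arbitrary R object (via its deparsed form)
#' @keywords internal
object_hash <- function(x) fnv1a(paste(deparse(x), collapse = ""))

#' Numeric formatting with round-trip precision for TSV output
#'
#' Shortest representation of 15 significant digits when that parses back
#' exactly, otherwise the full 17 digits.
#' @keywords internal
format_num <- function(x) {
  s <- sprintf("%.15g", x)
  bad <- as.numeric(s) != x
  s[bad] <- sprintf("%.17g", x[bad])
  s
}

#' Guess the field separator from a file extension
#' @keywords internal
guess_sep <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

#' Standardize columns of a matrix (z-score); zero-variance columns are
#' centered only (scale treated as 1).
#' Returns list(x, center, scale).
#' @keywords internal
standardize_columns <- function(x, center = NULL, scale = NULL) {
  if (is.null(center)) center <- colMeans(x)
  if (is.null(scale)) {
    scale <- apply(x, 2, stats::sd)
    scale[!is.finite(scale) | scale == 0] <- 1
  }
  xs <- sweep(sweep(x, 2, center, "-"), 2, scale, "/")
  list(x = xs, center = center, scale = scale)
}
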