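# Linear soft-margin SVM wrapper around e1071, with a fixed orientation:
# decision scores f(x) = x . w + b are positive for the case class (label 1).
# e1071 orients decision values toward the first factor level, so the raw
# (w, rho) pair is sign-flipped to this convention.

#' Fit a linear SVM with class-1-positive orientation
#'
#' @param x numeric matrix (samples x features), already standardized if the
#'   caller wants standardization.
#' @param y binary labels (0/1).
#' @param C soft-margin cost.
#' @return list with `w` (weight vector), `b` (intercept); score is
#'   `x %*% w + b`, positive toward label 1.
#' @keywords internal
linear_svm_fit <- function(x, y, C = 1.0, tolerance = 1e-6) {
  x <- as.matrix(x)
  yf <- factor(y, levels = c(0L, 1L))
  fit <- e1071::svm(x, yf, kernel = "linear", cost = C, scale = FALSE,
                    tolerance = tolerance)
  w <- unname(drop(t(fit$coefs) %*% fit$SV))
  b <- unname(-fit$rho)
  # positive raw score predicts the class seen first in the data,
  # fit$levels[fit$labels[1]]; flip so positive => class "1"
  if (fit$levels[fit$labels[1]] == "0") {
    w <- -w
    b <- -b
  }
  list(w = w, b = b, C = C)
}

#' Decision scores of a fitted linear SVM
#' @keywords internal
linear_svm_score <- function(fit, x) {
  drop(as.matrix(x) %*% fit$w + fit$b)
}

#' Primal objective 0.5 ||w||^2 + C * sum(hinge) of a fitted linear SVM
#' @keywords internal
linear_svm_objective <- function(fit, x, y) {
  s <- linear_svm_score(fit, x)
  ypm <- ifelse(y == 1, 1, -1)
  0.5 * sum(fit$w^2) + fit$C * sum(pmax(0, 1 - ypm * s))
}

#' Rank-based AUC (Mann-Whitney) with ties counted 0.5
#'
#' @param scores numeric decision scores, larger meaning more case-like.
#' @param labels binary labels (0/1).
#' @return AUC in `[0, 1]`.
#' @export
auc_score <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1L)
  n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) stop("AUC needs both classes", call. = FALSE)
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
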