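# Independent oracles used to validate the implementation paths.

# Primal objective of the soft-margin linear SVM obtained from the dual QP,
# solved with kernlab's interior-point solver (independent of e1071/libsvm).
qp_svm_objective <- function(X, y, C) {
  ypm <- ifelse(y == 1, 1, -1)
  n <- length(ypm)
  H <- (ypm %o% ypm) * tcrossprod(X) + diag(1e-12, n)
  sol <- kernlab::ipop(c = matrix(rep(-1, n)), H = H,
                       A = matrix(ypm, 1), b = 0,
                       l = matrix(rep(0, n)), u = matrix(rep(C, n)),
                       r = 0, sigf = 12, maxiter = 400)
  a <- kernlab::primal(sol)
  # dual objective at the optimum equals the primal optimum (strong duality)
  sum(a) - 0.5 * drop(t(a) %*% H %*% a)
}

# Textbook two-sample t-test p-values (Welch and pooled-variance Student).
ttest_pvalue_manual <- function(a, b, variant = "welch") {
  na <- length(a); nb <- length(b)
  va <- stats::var(a); vb <- stats::var(b)
  if (variant == "welch") {
    se2 <- va / na + vb / nb
    t <- (mean(a) - mean(b)) / sqrt(se2)
    df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  } else {
    sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
    t <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
    df <- na + nb - 2
  }
  2 * stats::pt(-abs(t), df)
}

# O(n^2) Mann-Whitney pair counting with ties worth 1/2.
auc_paircount <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

# Naive double-loop supervised-contrastive loss.
lmp_naive <- function(Z, labels, DL, tau, normalize = TRUE) {
  U <- Z %*% DL
  if (normalize) U <- U / pmax(sqrt(rowSums(U^2)), 1e-12)
  m <- nrow(U)
  total <- 0
  for (i in seq_len(m)) {
    A <- setdiff(seq_len(m), i)
    B <- A[labels[A] == labels[i]]
    if (length(B) == 0) next
    denom <- sum(exp(sapply(A, function(a) sum(U[i, ] * U[a, ]) / tau)))
    s <- 0
    for (b in B)
      s <- s + log(exp(sum(U[i, ] * U[b, ]) / tau) / denom)
    total <- total - s / length(B)
  }
  total
}

# Central finite-difference gradient of the total GAE loss for one block.
fd_gradient <- function(params, block, eps, loss_fn) {
  g <- params[[block]] * 0
  for (i in seq_along(params[[block]])) {
    pp <- params
    pp[[block]][i] <- pp[[block]][i] + eps
    lp <- loss_fn(pp)
    pp[[block]][i] <- pp[[block]][i] - 2 * eps
    lm <- loss_fn(pp)
    g[i] <- (lp - lm) / (2 * eps)
  }
  g
}
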