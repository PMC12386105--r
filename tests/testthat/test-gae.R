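test_that("normalized adjacency matches hand arithmetic and stays symmetric", {
  expect_equal(normalized_adjacency(matrix(0, 1, 1)), matrix(1, 1, 1))
  expect_equal(normalized_adjacency(matrix(c(0, 1, 1, 0), 2, 2)),
               matrix(0.5, 2, 2))
  set.seed(5)
  A <- matrix(0, 8, 8)
  A[upper.tri(A)] <- rbinom(28, 1, 0.4)
  A <- A + t(A)
  Ah <- normalized_adjacency(A)
  expect_true(isSymmetric(Ah))
  expect_lte(max(abs(eigen(Ah, symmetric = TRUE)$values)), 1 + 1e-12)
})

test_that("encoder and decoder reproduce hand-computed examples", {
  A <- matrix(c(0, 1, 1, 0), 2, 2)
  Ah <- normalized_adjacency(A)
  params <- list(W0 = matrix(1), W1 = matrix(1))
  Z <- gae_encode(Ah, matrix(c(2, 0), 2, 1), params)
  expect_equal(Z, matrix(1, 2, 1))

  expect_equal(gae_encode(Ah, matrix(0, 2, 1), params), matrix(0, 2, 1))

  expect_equal(gae_decode(matrix(0, 2, 1)), matrix(0.5, 2, 2))
  expect_equal(gae_decode(matrix(1, 2, 1)),
               matrix(plogis(1), 2, 2), tolerance = 1e-12)
  set.seed(6)
  Zr <- matrix(rnorm(12), 4, 3)
  expect_true(isSymmetric(gae_decode(Zr)))

  expect_error(gae_encode(Ah, matrix(0, 3, 1), params), "dimension")
})

test_that("encoder is permutation-equivariant", {
  set.seed(8)
  m <- 6
  A <- matrix(0, m, m); A[upper.tri(A)] <- rbinom(15, 1, 0.5); A <- A + t(A)
  X <- matrix(rnorm(m * 3), m, 3)
  params <- list(W0 = matrix(rnorm(6), 3, 2), W1 = matrix(rnorm(4), 2, 2))
  Z <- gae_encode(normalized_adjacency(A), X, params)
  perm <- sample(m)
  Zp <- gae_encode(normalized_adjacency(A[perm, perm]), X[perm, ], params)
  expect_equal(Zp, Z[perm, ], tolerance = 1e-12)
})

test_that("reconstruction loss covers exact, uniform, and sampled cases", {
  A <- matrix(c(0, 1, 1, 0), 2, 2)
  expect_equal(reconstruction_loss(A, A), 0)
  expect_equal(reconstruction_loss(A, matrix(0.5, 2, 2)), 0.25)
  s1 <- plogis(1)
  expect_equal(reconstruction_loss(A, matrix(s1, 2, 2)),
               (2 * s1^2 + 2 * (1 - s1)^2) / 4, tolerance = 1e-12)
  expect_equal(reconstruction_loss(A, matrix(s1, 2, 2)), 0.3034,
               tolerance = 1e-4)
  # sampled entries restrict the average to those pairs
  entries <- rbind(c(1L, 2L))
  expect_equal(reconstruction_loss(A, matrix(0.2, 2, 2), entries), 0.64)
  # no-edge graph: sampler falls back to the full matrix with a message
  expect_message(e0 <- kenmir:::sample_rec_entries(matrix(0, 3, 3)),
                 "no edges")
  expect_null(e0)
})

test_that("GIP kernel similarity matches the closed form and kernel axioms", {
  S <- gip_similarity(rbind(c(1, 0), c(0, 1)))
  expect_equal(S[1, 2], exp(-2), tolerance = 1e-12)
  expect_equal(diag(S), c(1, 1))

  v <- rbind(a = c(1, 1, 0), b = c(1, 1, 0), c = c(0, 0, 1))
  Sv <- gip_similarity(v)
  expect_equal(Sv["a", "b"], 1)           # identical profiles
  set.seed(11)
  R <- matrix(rnorm(40), 8, 5)
  SR <- gip_similarity(R)
  expect_true(isSymmetric(SR))
  expect_true(all(SR > 0 & SR <= 1 + 1e-12))
  expect_equal(diag(SR), rep(1, 8))

  expect_error(gip_similarity(matrix(0, 3, 2)), "zero")
})

test_that("functional consistency loss is the squared Frobenius difference", {
  GS <- matrix(c(1, exp(-2), exp(-2), 1), 2, 2)
  expect_equal(functional_consistency_loss(GS, GS), 0)
  expect_equal(functional_consistency_loss(GS, matrix(1, 2, 2)),
               2 * (1 - exp(-2))^2, tolerance = 1e-12)
  expect_error(functional_consistency_loss(GS, matrix(1, 3, 3)), "shape")
})

test_that("pseudo-labels mark differential features and partition the set", {
  d <- expression_dataset(cbind(f1 = c(1, 2, 3, 4, 5, 6),
                                f2 = c(1, 2, 3, 1, 2, 3),
                                f3 = rep(0, 6)),
                          c(1, 1, 1, 0, 0, 0))
  pl <- suppressMessages(assign_pseudo_labels(d))
  expect_identical(unname(pl), c("y0", "y1", "y1"))
  expect_length(pl, n_features(d))
})

test_that("difference-prompt loss matches symmetry and the naive double loop", {
  # identical representations: every softmax term is 1/2, loss = 3 log 2
  Z <- matrix(1, 3, 2)
  DL <- matrix(rnorm(4), 2, 2)
  expect_equal(difference_prompt_loss(Z, rep("y0", 3), DL, tau = 0.1),
               3 * log(2), tolerance = 1e-9)

  set.seed(13)
  for (i in 1:5) {
    Z <- matrix(rnorm(5 * 3), 5, 3)
    DL <- matrix(rnorm(3 * 2), 3, 2)
    lab <- sample(c("y0", "y1"), 5, replace = TRUE)
    for (norm in c(TRUE, FALSE)) {
      expect_equal(
        suppressMessages(difference_prompt_loss(Z, lab, DL, 0.1, norm)),
        lmp_naive(Z, lab, DL, 0.1, norm), tolerance = 1e-9)
    }
  }

  # singleton pseudo-label class: that node's term is skipped
  Z <- matrix(rnorm(8), 4, 2)
  lab <- c("y0", "y0", "y0", "y1")
  expect_message(l <- difference_prompt_loss(Z, lab, DL <- diag(2), 0.1),
                 "singleton")
  expect_equal(l, lmp_naive(Z, lab, DL, 0.1), tolerance = 1e-9)

  expect_error(difference_prompt_loss(matrix(1, 1, 2), "y0", diag(2), 0.1),
               "at least 2")
})

test_that("losses are invariant under consistent node relabeling", {
  set.seed(14)
  m <- 7
  A <- matrix(0, m, m); A[upper.tri(A)] <- rbinom(21, 1, 0.5); A <- A + t(A)
  Z <- matrix(rnorm(m * 3), m, 3)
  GS <- gip_similarity(matrix(rbinom(m * 4, 1, 0.5) + 0.1, m, 4))
  lab <- sample(c("y0", "y1"), m, replace = TRUE)
  DL <- matrix(rnorm(6), 3, 2)
  perm <- sample(m)
  expect_equal(reconstruction_loss(A, gae_decode(Z)),
               reconstruction_loss(A[perm, perm], gae_decode(Z[perm, ])),
               tolerance = 1e-12)
  expect_equal(functional_consistency_loss(GS, gip_similarity(Z)),
               functional_consistency_loss(GS[perm, perm],
                                           gip_similarity(Z[perm, ])),
               tolerance = 1e-12)
  expect_equal(suppressMessages(difference_prompt_loss(Z, lab, DL, 0.1)),
               suppressMessages(
                 difference_prompt_loss(Z[perm, ], lab[perm], DL, 0.1)),
               tolerance = 1e-9)
})

test_that("total loss combines components under ablation flags", {
  comp <- c(0.3034, 1.4953, 2.0794)
  expect_equal(total_loss(comp, 0, 0), 0.3034)
  expect_equal(total_loss(comp, 0.1, 1e-7),
               0.3034 + 0.1 * 1.4953 + 1e-7 * 2.0794, tolerance = 1e-12)
  expect_equal(total_loss(comp, 0.1, 1e-7, use_difference_prompt = FALSE),
               0.3034 + 0.1 * 1.4953)
  expect_equal(total_loss(comp, 0.1, 1e-7, use_knowledge = FALSE,
                          use_difference_prompt = FALSE), 0.3034)
  expect_error(total_loss(comp, -0.1, 0), "nonnegative")
})

test_that("analytic gradients agree with central finite differences", {
  set.seed(21)
  m <- 10; p <- 4; n <- 8
  A <- matrix(0, m, m); A[upper.tri(A)] <- rbinom(45, 1, 0.35); A <- A + t(A)
  X <- cbind(matrix(rbinom(m * p, 1, 0.4), m, p), matrix(rnorm(m * n), m, n))
  Ahat <- normalized_adjacency(A)
  GS <- gip_similarity(X[, 1:p] + matrix(runif(m * p), m, p) * 0.01)
  plab <- sample(c("y0", "y1"), m, replace = TRUE)
  cfg <- run_config(lambda1 = 0.5, lambda2 = 0.7, hidden_dims = c(6, 4),
                    discr_dim = 3, seed = 1)
  params <- gae_init_params(ncol(X), cfg$hidden_dims, cfg$discr_dim)
  res <- kenmir:::gae_loss_grad(params, Ahat, X, A, NULL, GS, plab, cfg)
  loss_fn <- function(pp)
    kenmir:::gae_loss_grad(pp, Ahat, X, A, NULL, GS, plab, cfg)$l_total
  for (block in c("W0", "W1", "DL")) {
    num <- fd_gradient(params, block, 1e-5, loss_fn)
    rel <- max(abs(num - res$grads[[block]])) / max(abs(num))
    expect_lt(rel, 1e-4)
  }
})

test_that("training descends, is deterministic, and honors epochs = 0", {
  sim <- simulate_dataset(simulation_spec(
    n_per_group = 15, m = 60,
    modules = rep(list(list(size = 6, rho = 0.6, delta = 1.5)), 3),
    p = 12, seed = 3))
  cfg <- run_config(seed = 3, hidden_dims = c(16, 8), discr_dim = 4)
  net <- suppressMessages(suppressWarnings(
    build_cooperation_network(sim$data, sim$knowledge, cfg)))

  g1 <- suppressMessages(train_gae(net, sim$knowledge, sim$data, cfg))
  g2 <- suppressMessages(train_gae(net, sim$knowledge, sim$data, cfg))
  expect_identical(g1$trace, g2$trace)
  expect_identical(g1$Z, g2$Z)
  expect_equal(nrow(g1$trace), cfg$epochs)
  expect_true(all(g1$trace$l_rec >= 0 & g1$trace$l_fc >= 0 &
                    g1$trace$l_mp >= 0))
  expect_lt(g1$trace$l_total[cfg$epochs], g1$trace$l_total[1])

  cfg0 <- run_config(seed = 3, hidden_dims = c(16, 8), discr_dim = 4,
                     epochs = 0)
  g0 <- suppressMessages(train_gae(net, sim$knowledge, sim$data, cfg0))
  expect_equal(nrow(g0$trace), 0)
  X <- kenmir:::standardize_columns(net$attributes)$x
  expect_equal(unname(g0$Z),
               unname(gae_encode(normalized_adjacency(net$graph$weights),
                                 X, g0$params)),
               tolerance = 1e-12)
})

test_that("enhanced network thresholds decoder probabilities", {
  g <- build_enhanced_network(matrix(1, 2, 1), c("a", "b"), theta = 0.5)
  expect_equal(g$weights["a", "b"], plogis(1), tolerance = 1e-6)

  # orthogonal representations: probability 0.5 kept at the default theta
  Z0 <- rbind(c(1, 0), c(0, 1))
  g0 <- build_enhanced_network(Z0, c("a", "b"), theta = 0.5)
  expect_equal(g0$weights["a", "b"], 0.5)

  set.seed(15)
  Zr <- matrix(rnorm(12), 6, 2)
  gr <- build_enhanced_network(Zr, letters[1:6], theta = 0.5)
  expect_true(isSymmetric(gr$weights))
  expect_true(all(gr$weights >= 0 & gr$weights < 1))

  # candidate restriction: no edge outside the candidate set
  cand <- weighted_graph(matrix(c(0, 1, 0, 1, 0, 0, 0, 0, 0), 3, 3,
                                byrow = TRUE), c("a", "b", "c"))
  gm <- build_enhanced_network(matrix(1, 3, 1), c("a", "b", "c"),
                               candidates = cand)
  expect_gt(gm$weights["a", "b"], 0)
  expect_equal(gm$weights["a", "c"], 0)
  expect_equal(gm$weights["b", "c"], 0)
})
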