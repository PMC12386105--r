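test_that("node importance is the weighted degree", {
  w <- matrix(0, 4, 4, dimnames = rep(list(letters[1:4]), 2))
  w["a", "b"] <- w["b", "a"] <- 0.6
  w["a", "c"] <- w["c", "a"] <- 0.7
  g <- weighted_graph(w)
  expect_equal(node_importance(g, "a"), 1.3)
  expect_equal(node_importance(g, "d"), 0)
  # handshake identity
  tot <- sum(vapply(g$node_ids, node_importance, numeric(1), graph = g))
  expect_equal(tot, 2 * sum(graph_edges(g)$weight))
  expect_error(node_importance(g, "zz"), "unknown node")
})

test_that("acceptance probability follows the closed form", {
  for (c_ in 1:6) expect_equal(acceptance_probability(1, c_), 0)
  expect_equal(acceptance_probability(0.5, 2), 1 - exp(-0.25),
               tolerance = 1e-12)
  expect_equal(acceptance_probability(0.9, 10), 1 - exp(-0.01),
               tolerance = 1e-12)
  # strictly decreasing in the AUC, zero only at AUC = 1
  aucs <- seq(0, 1, by = 0.1)
  probs <- vapply(aucs, acceptance_probability, numeric(1), cmn = 3)
  expect_true(all(diff(probs) < 0))
  expect_true(all(probs[aucs < 1] > 0))
  expect_error(acceptance_probability(0.5, 0), "positive")
})

test_that("rank AUC equals brute-force pair counting, including ties", {
  set.seed(31)
  for (i in 1:10) {
    n <- 30
    labels <- rbinom(n, 1, 0.5)
    if (length(unique(labels)) < 2) labels[1:2] <- c(0, 1)
    scores <- round(rnorm(n), 1)        # rounding forces ties
    expect_equal(auc_score(scores, labels), auc_paircount(scores, labels),
                 tolerance = 1e-12)
  }
  expect_equal(auc_score(rep(1, 6), c(1, 1, 1, 0, 0, 0)), 0.5)
})

test_that("module AUC is perfect for a clean separator and 0.5 for a constant", {
  d <- expression_dataset(cbind(f1 = c(10, 11, 12, 13, -10, -11, -12, -13),
                                f2 = rnorm(8),
                                f3 = rep(2, 8)),
                          c(1, 1, 1, 1, 0, 0, 0, 0))
  cfg <- run_config(seed = 2, cv_folds_internal = 4L)
  expect_equal(module_auc(d, "f1", cfg), 1)
  expect_equal(module_auc(d, "f3", cfg), 0.5)   # constant scores, all ties
  expect_error(module_auc(d, "nope", cfg), "nope")
  expect_error(module_auc(d, character(0), cfg), "empty")

  # resubstitution mode agrees with a direct standardized fit
  cfg_r <- run_config(seed = 2, auc_mode = "resub")
  xs <- kenmir:::standardize_columns(d$values[, c("f1", "f2")])$x
  fit <- kenmir:::linear_svm_fit(xs, d$labels, C = 1)
  expect_equal(module_auc(d, c("f1", "f2"), cfg_r),
               auc_score(kenmir:::linear_svm_score(fit, xs), d$labels),
               tolerance = 1e-12)
})

test_that("module growth follows max-weight edges through the accept gate", {
  set.seed(41)
  n <- 40
  y <- rep(c(1L, 0L), each = n / 2)
  # a and b carry independent signal; c is pure noise
  vals <- cbind(a = rnorm(n) + 1.2 * y,
                b = rnorm(n) + 1.2 * y,
                c = rnorm(n))
  d <- expression_dataset(vals, y)
  w <- matrix(0, 3, 3, dimnames = rep(list(c("a", "b", "c")), 2))
  w["a", "b"] <- w["b", "a"] <- 0.9
  w["b", "c"] <- w["c", "b"] <- 0.8
  g <- weighted_graph(w)
  cfg <- run_config(seed = 41)

  auc_a <- module_auc(d, "a", cfg)
  auc_ab <- module_auc(d, c("a", "b"), cfg)
  auc_abc <- module_auc(d, c("a", "b", "c"), cfg)
  expect_gt(auc_ab, auc_a)      # fixture premise: b helps
  expect_lt(auc_abc, auc_ab)    # fixture premise: c hurts

  # forced rejection at the probabilistic gate: growth stops after b
  res_rej <- grow_module(g, d, "a", cfg, runif_fn = function(n) rep(1, n))
  expect_identical(res_rej$members, c("a", "b"))
  expect_equal(res_rej$auc, auc_ab)

  # forced acceptance: search continues through the non-improving step
  res_acc <- grow_module(g, d, "a", cfg, runif_fn = function(n) rep(0, n))
  expect_identical(res_acc$members, c("a", "b", "c"))
  expect_equal(res_acc$auc, auc_abc)

  # isolated seed terminates immediately with its own AUC
  g_iso <- weighted_graph(matrix(0, 3, 3), c("a", "b", "c"))
  res_iso <- grow_module(g_iso, d, "c", cfg)
  expect_identical(res_iso$members, "c")
  expect_equal(res_iso$auc, module_auc(d, "c", cfg))
})

test_that("module discovery separates disconnected components and caps counts", {
  set.seed(43)
  n <- 40
  y <- rep(c(1L, 0L), each = n / 2)
  vals <- sapply(1:6, function(i) rnorm(n) + 1.0 * y)
  colnames(vals) <- c("a1", "a2", "a3", "b1", "b2", "b3")
  d <- expression_dataset(vals, y)
  w <- matrix(0, 6, 6, dimnames = rep(list(colnames(vals)), 2))
  for (pair in list(c("a1", "a2"), c("a2", "a3"), c("a1", "a3"),
                    c("b1", "b2"), c("b2", "b3"), c("b1", "b3")))
    w[pair[1], pair[2]] <- w[pair[2], pair[1]] <- runif(1, 0.6, 0.9)
  g <- weighted_graph(w)
  cfg <- run_config(seed = 43)

  # always-accept gate: each module absorbs its whole component
  ms <- find_modules(g, d, cfg, runif_fn = function(n) rep(0, n))
  expect_identical(n_modules(ms), 2L)
  sets <- lapply(ms$modules, function(m) sort(m$members))
  expect_true(any(vapply(sets, identical, logical(1),
                         c("a1", "a2", "a3"))))
  expect_true(any(vapply(sets, identical, logical(1),
                         c("b1", "b2", "b3"))))

  # modules are disjoint and within the graph's node set
  all_members <- unlist(lapply(ms$modules, `[[`, "members"))
  expect_identical(anyDuplicated(all_members), 0L)
  expect_true(all(all_members %in% g$node_ids))

  # cap at one module
  cfg1 <- run_config(seed = 43, max_modules = 1, k = 1)
  expect_identical(n_modules(find_modules(g, d, cfg1)), 1L)

  # edgeless graph yields no modules
  g0 <- weighted_graph(matrix(0, 3, 3), c("x", "y", "z"))
  expect_identical(n_modules(find_modules(g0, d, cfg)), 0L)
})

test_that("top-k selection orders by AUC with deterministic tie-breaks", {
  mods <- list(
    list(members = c("x1", "x2", "x3"), auc = 0.8),
    list(members = c("y1"), auc = 0.8),
    list(members = c("a1"), auc = 0.8),
    list(members = c("z1", "z2"), auc = 0.95),
    list(members = c("w1"), auc = 0.4))
  ms <- module_set(mods)
  top <- select_top_k(ms, 3)
  expect_identical(n_modules(top), 3L)
  expect_equal(top$modules[[1]]$auc, 0.95)
  # AUC tie: smaller module first, then lexicographic first member
  expect_identical(top$modules[[2]]$members, "a1")
  expect_identical(top$modules[[3]]$members, "y1")

  expect_warning(all3 <- select_top_k(module_set(mods[1:3]), 7), "only 3")
  expect_identical(n_modules(all3), 3L)
  expect_error(select_top_k(module_set(), 7), "no modules")
})

test_that("the voting ensemble stores per-module fits and votes by majority", {
  d <- toy_dataset(n_per_group = 10, m = 4, delta = 2, seed = 44)
  ms <- module_set(list(list(members = c("f1", "f2"), auc = 0.9),
                        list(members = "f3", auc = 0.7)))
  cfg <- run_config(seed = 44, k = 2)
  ens <- fit_ensemble(d, ms, cfg)
  expect_identical(ens$k, 2L)
  expect_identical(lapply(ens$classifiers, `[[`, "members"),
                   list(c("f1", "f2"), "f3"))

  # single-module ensemble is its base classifier
  ens1 <- fit_ensemble(d, module_set(list(list(members = "f1", auc = 0.9))),
                       run_config(seed = 44, k = 1))
  p1 <- suppressMessages(predict(ens1, d))
  cl <- ens1$classifiers[[1]]
  xs <- sweep(sweep(d$values[, "f1", drop = FALSE], 2, cl$center, "-"),
              2, cl$scale, "/")
  expect_identical(p1$label,
                   as.integer(kenmir:::linear_svm_score(cl$fit, xs) > 0))

  # missing feature is reported by name
  d_missing <- expression_dataset(d$values[, c("f1", "f2", "f4")], d$labels)
  expect_error(predict(ens, d_missing), "f3")
})

test_that("tied votes fall back to the sign of the mean decision score", {
  mk_cl <- function(feature, w) {
    list(members = feature, auc = 0.9,
         fit = list(w = w, b = 0, C = 1), center = 0, scale = 1)
  }
  ens <- structure(list(classifiers = list(mk_cl("f1", 1), mk_cl("f2", 1)),
                        k = 2L), class = "voting_ensemble")
  samples <- expression_dataset(
    cbind(f1 = c(1, 1, 5, -5), f2 = c(-2, 2, 1, -1)),
    c(0, 1, 1, 0))
  expect_message(pred <- predict(ens, samples), "tied")
  expect_identical(pred$label, c(0L, 1L, 1L, 0L))  # ties: means -0.5, +1.5
  expect_identical(pred$votes_case + pred$votes_control, rep(2, 4))
})
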