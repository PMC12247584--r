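test_that("edge selection is exact partial correlation with disjoint masks", {
  set.seed(21)
  n <- 20
  X <- matrix(rnorm(n * 5), n, 5)
  y <- rnorm(n)
  X[, 3] <- y  # perfectly correlated edge
  sel <- select_edges(X, y, NULL, alpha = 1e-12)
  expect_true(sel$pos_mask[3])
  expect_false(any(sel$pos_mask & sel$neg_mask))

  # with covariates, equals the residualize-then-Pearson oracle
  n <- 60
  X <- matrix(rnorm(n * 150), n, 150)
  Z <- matrix(rnorm(n * 3), n, 3)
  y <- 0.2 * Z[, 1] + rnorm(n)
  sel2 <- select_edges(X, y, Z, alpha = 0.05)
  orc <- oracle_select_edges(X, y, Z, 0.05)
  expect_equal(sel2$pos_mask, orc$pos)
  expect_equal(sel2$neg_mask, orc$neg)
  expect_equal(sel2$r, orc$r, tolerance = 1e-10)

  # constant edges are unselectable but not fatal
  X[, 7] <- 1
  sel3 <- select_edges(X, y, Z, alpha = 0.05)
  expect_true(7 %in% sel3$unselectable)
  expect_false(sel3$pos_mask[7] || sel3$neg_mask[7])
})

test_that("null selection rate matches the nominal alpha", {
  set.seed(22)
  n <- 60; E <- 1000; alpha <- 0.05
  X <- matrix(rnorm(n * E), n, E)
  y <- rnorm(n)
  sel <- select_edges(X, y, NULL, alpha)
  frac <- (sum(sel$pos_mask) + sum(sel$neg_mask)) / E
  expect_lt(abs(frac - alpha), 3 * sqrt(alpha * (1 - alpha) / E))
})

test_that("summed strengths equal the loop-based oracle", {
  set.seed(23)
  X <- matrix(rnorm(5 * 8), 5, 8)
  pos <- c(TRUE, FALSE, TRUE, rep(FALSE, 5))
  neg <- c(FALSE, TRUE, FALSE, TRUE, rep(FALSE, 4))
  ss <- summed_strengths(X, pos, neg)
  for (s in 1:5) {
    ps <- 0; ns <- 0
    for (e in 1:8) {
      if (pos[e]) ps <- ps + X[s, e]
      if (neg[e]) ns <- ns + X[s, e]
    }
    expect_equal(ss$pos_sum[s], ps, tolerance = 1e-12)
    expect_equal(ss$neg_sum[s], ns, tolerance = 1e-12)
  }
  empty <- summed_strengths(X[1, ], rep(FALSE, 8), rep(FALSE, 8))
  expect_equal(c(empty$pos_sum, empty$neg_sum), c(0, 0))
})

test_that("LOOCV recovers a noiseless planted signal and is pessimistic on noise", {
  set.seed(24)
  n <- 100; E <- 50
  X <- matrix(rnorm(n * E), n, E)
  y <- 2 * X[, 10]  # noiseless linear function of one edge
  res <- cbpm_loocv(X, y, NULL, cbpm_config(selection_alpha = 0.001))
  expect_gt(res$r_obs_pred, 0.95)
  expect_true(all(res$pos_masks[10, ]))

  # pure-noise performance is centered at or below zero across seeds
  rs <- sapply(1:10, function(s) {
    set.seed(300 + s)
    Xn <- matrix(rnorm(40 * 100), 40, 100)
    yn <- rnorm(40)
    cbpm_loocv(Xn, yn, NULL, cbpm_config())$r_obs_pred
  })
  expect_lt(mean(rs, na.rm = TRUE), 0.1)
})

test_that("folds with no selected edges fall back to the training mean", {
  set.seed(25)
  n <- 10; E <- 6
  X <- matrix(1, n, E)  # constant edges: nothing selectable
  y <- rnorm(n)
  res <- cbpm_loocv(X, y, NULL, cbpm_config())
  expect_true(all(res$fold_fallback))
  expect_equal(res$status, "degenerate")
  for (i in 1:n) expect_equal(res$predicted[i], mean(y[-i]), tolerance = 1e-12)
})

test_that("permutation p follows the proportion convention with ties as better", {
  fakenull <- c(0.5, 0.2, 0.2, -0.1)
  obs <- 0.2
  # convention check on the arithmetic the test function uses
  expect_equal(mean(fakenull >= obs), 0.75)

  set.seed(26)
  n <- 60; E <- 80
  X <- matrix(rnorm(n * E), n, E)
  y <- 3 * X[, 5] + 0.2 * rnorm(n)   # strong signal: observed beats all nulls
  pt <- cbpm_permutation_test(X, y, NULL, cbpm_config(n_permutations = 30, seed = 2))
  expect_equal(pt$p_perm, 0)
  expect_equal(pt$p_perm_add_one, 1 / 31)
  expect_equal(length(pt$null_r), 30)
  # reproducible under the same seed
  pt2 <- cbpm_permutation_test(X, y, NULL, cbpm_config(n_permutations = 30, seed = 2))
  expect_identical(pt$null_r, pt2$null_r)
})

test_that("stricter alphas never select more edges and alpha = 1 runs", {
  set.seed(27)
  n <- 50; E <- 120
  X <- matrix(rnorm(n * E), n, E)
  y <- 0.8 * X[, 3] + rnorm(n)
  counts <- sapply(c(0.001, 0.01, 0.1, 1), function(a) {
    res <- cbpm_loocv(X, y, NULL, cbpm_config(selection_alpha = a))
    sum(res$pos_masks[, 1]) + sum(res$neg_masks[, 1])
  })
  expect_true(all(diff(counts) >= 0))
  # at alpha = 1 every non-constant edge is selected by sign alone
  expect_equal(counts[4], E)
})

test_that("model form variants restrict the strength terms", {
  set.seed(28)
  n <- 60; E <- 40
  X <- matrix(rnorm(n * E), n, E)
  y <- 1.5 * X[, 2] - 1.5 * X[, 9] + 0.5 * rnorm(n)
  pos_only <- cbpm_loocv(X, y, NULL, cbpm_config(model_form = "pos_only"))
  expect_equal(sum(pos_only$neg_masks), 0)
  neg_only <- cbpm_loocv(X, y, NULL, cbpm_config(model_form = "neg_only"))
  expect_equal(sum(neg_only$pos_masks), 0)
})

test_that("lesioning a k-ROI network removes exactly its incident edges", {
  atlas <- make_atlas(c(NetA = 4, DefaultC = 3, DefaultA = 3), hippocampus_size = 2)
  R <- nrow(atlas)
  map <- edge_index_map(R)
  for (net in c("NetA", "Hipp")) {
    rois <- which(atlas$network == net)
    keep <- !(map$i %in% rois | map$j %in% rois)
    k <- length(rois)
    expect_equal(sum(keep), (R - k) * (R - k - 1) / 2)
  }
})
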