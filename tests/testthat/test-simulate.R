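# configuration used by several blocks: tiny cohort, configurable noise
quiet_spec <- function(edge_loads = 0, behav_loads = 0) {
  list(
    age = list(dist = "uniform", min = 18, max = 50,
               behavior_loading = behav_loads, edge_loading = edge_loads),
    sex = list(dist = "bernoulli", prob = 0.5,
               behavior_loading = 0, edge_loading = 0),
    fd = list(dist = "normal", mean = 0.14, sd = 0.04,
              behavior_loading = 0, edge_loading = 0),
    cattell = list(dist = "normal", mean = 36.35, sd = 4.23,
                   behavior_loading = 0, edge_loading = 0),
    acer = list(dist = "normal", mean = 96.54, sd = 3.63,
                behavior_loading = 0, edge_loading = 0)
  )
}

small_sizes <- c(NetA = 4L, DefaultC = 3L, DefaultA = 3L)

test_that("with no variation sources every connectome equals the group mean", {
  cfg <- simulation_config(n_subjects = 5, network_sizes = small_sizes,
                           hippocampus_size = 2, subject_noise_sd = 0,
                           confound_spec = quiet_spec(), seed = 3)
  coh <- simulate_cohort(cfg)
  atlas <- coh$atlas
  map <- edge_index_map(nrow(atlas))
  same_net <- atlas$network[map$i] == atlas$network[map$j]
  expected_z <- ifelse(same_net, cfg$within_z, cfg$between_z)
  for (cn in coh$connectomes) {
    ev <- vectorize_connectome(cn)
    expect_equal(ev$values, fisher_z_inv(expected_z), tolerance = 1e-12)
  }
})

test_that("identical config and seed reproduce identical outputs", {
  cfg <- simulation_config(n_subjects = 8, network_sizes = small_sizes,
                           hippocampus_size = 2, seed = 42)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$subjects, b$subjects)
  expect_identical(a$connectomes[[3]]$matrix, b$connectomes[[3]]$matrix)
})

test_that("a planted edge's behavior correlation matches a Monte-Carlo oracle", {
  # oracle: direct draw from the stated generative model at n = 50,000
  beta <- 0.3
  sigma <- 0.1
  set.seed(99)
  b <- rnorm(50000)
  z <- 0.35 + beta * b + rnorm(50000, 0, sigma)
  r_oracle <- cor(atanh(tanh(z)), b)

  edges <- data.frame(i = 2, j = 1, beta = beta)
  cfg <- simulation_config(n_subjects = 500, network_sizes = small_sizes,
                           hippocampus_size = 2, signal_edges = edges,
                           subject_noise_sd = sigma,
                           confound_spec = quiet_spec(),
                           behavior_noise_sd = 1, seed = 7)
  coh <- simulate_cohort(cfg)
  X <- cohort_edge_matrix(coh$connectomes)
  map <- attr(X, "edge_map")
  k <- map$k[map$i == 2 & map$j == 1]
  b_lat <- attr(coh$subjects, "behavior_latent")
  r_hat <- cor(fisher_z(X[, k]), b_lat)
  expect_lt(abs(r_hat - r_oracle), 0.1)
})

test_that("invalid signal edges are rejected", {
  expect_error(simulation_config(network_sizes = small_sizes, hippocampus_size = 0,
                                 signal_edges = data.frame(i = 1, j = 1, beta = 0.2)),
               "distinct")
  expect_error(simulation_config(network_sizes = small_sizes, hippocampus_size = 0,
                                 signal_edges = data.frame(i = 1, j = 99, beta = 0.2)),
               "in-range")
})

test_that("time series from an identity target have near-zero correlations", {
  target <- diag(10)
  sim <- simulate_timeseries(target, run_length = 5000, seed = 5)
  r <- cor(sim$ts$values)
  expect_lt(max(abs(r[upper.tri(r)])), 0.05)
})

test_that("a planted pairwise correlation is recovered from a long run", {
  target <- diag(6)
  target[1, 2] <- target[2, 1] <- 0.6
  sim <- simulate_timeseries(target, run_length = 5000, seed = 8)
  expect_lt(abs(cor(sim$ts$values[, 1], sim$ts$values[, 2]) - 0.6), 0.05)
})

test_that("regressing zero-loading confounds barely moves the connectome", {
  target <- random_correlation(8, seed = 2)
  sim <- simulate_timeseries(target, run_length = 600, global_loading = 0,
                             motion_loading = 0, seed = 2)
  with_conf <- process_run(sim$ts, sim$confounds)
  without_conf <- process_run(sim$ts, NULL)
  expect_lt(mean(abs(with_conf$matrix - without_conf$matrix)), 0.03)
})

test_that("degenerate run lengths are refused", {
  expect_error(simulate_timeseries(diag(10), run_length = 11, seed = 1),
               "n_rois")
})

test_that("non-PSD targets are repaired by eigenvalue clipping", {
  m <- diag(3)
  m[1, 2] <- m[2, 1] <- 0.9
  m[1, 3] <- m[3, 1] <- 0.9
  m[2, 3] <- m[3, 2] <- -0.9
  rep_m <- nearest_psd(m)
  expect_gte(min(eigen(rep_m, symmetric = TRUE)$values), 0)
  expect_gt(attr(rep_m, "psd_adjustment"), 0)
  expect_equal(diag(rep_m), rep(1, 3))
  # already-PSD input passes through with zero adjustment
  ok <- nearest_psd(diag(3))
  expect_equal(attr(ok, "psd_adjustment"), 0)
})
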