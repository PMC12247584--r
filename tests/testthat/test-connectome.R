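test_that("spike regressors flag timepoints exceeding either threshold", {
  s <- build_spike_regressors(fd = c(0.1, 0.7, 0.1), dvars = c(1, 1, 3))
  expect_equal(dim(s), c(3, 2))
  expect_equal(s[, 1], c(0, 1, 0))
  expect_equal(s[, 2], c(0, 0, 1))

  expect_equal(ncol(build_spike_regressors(c(0.1, 0.2), c(1, 1))), 0)

  # strictly-greater-than rule: 0.61 flagged, 0.6 itself not
  expect_equal(ncol(build_spike_regressors(0.61, 0)), 1)
  expect_equal(ncol(build_spike_regressors(0.6, 0)), 0)
  expect_error(build_spike_regressors(c(0.1, 0.2), 1), "length")
})

test_that("task regressor is the HRF-convolved onset train", {
  expect_equal(build_task_regressor(numeric(0), 50, 2), numeric(50))

  # single onset at t = 0: proportional to the sampled HRF, peak near 5 s
  tr <- 1
  x <- build_task_regressor(0, 40, tr)
  expect_equal(x, hrf_double_gamma((0:39) * tr))
  expect_equal((which.max(x) - 1) * tr, 5, tolerance = 1)

  # linearity: two well-separated onsets are the sum of shifted copies
  x2 <- build_task_regressor(c(0, 20), 60, tr)
  single <- build_task_regressor(0, 60, tr)
  shifted <- c(numeric(20), single[1:40])
  expect_equal(x2, single + shifted, tolerance = 1e-12)

  expect_warning(build_task_regressor(c(1, 500), 50, 2), "dropped")
})

test_that("confound regression produces residuals orthogonal to the design", {
  set.seed(1)
  Tn <- 80
  conf <- matrix(rnorm(Tn * 3), Tn, 3, dimnames = list(NULL, c("a", "b", "c")))
  ts <- roi_timeseries(matrix(rnorm(Tn * 4), Tn, 4), sampling_interval = 2)

  # column equal to a confound regresses to ~0
  ts2 <- ts
  ts2$values[, 1] <- conf[, 2]
  out <- regress_confounds(ts2, conf)
  expect_lt(max(abs(out$values[, 1])), 1e-10)

  # intercept-only = mean centering
  cen <- regress_confounds(ts, NULL)
  expect_equal(cen$values, scale(ts$values, scale = FALSE), ignore_attr = TRUE)

  # OLS normal equations: residuals orthogonal to every design column
  res <- regress_confounds(ts, conf)
  expect_lt(max(abs(crossprod(conf, res$values))), 1e-8)
})

test_that("degenerate confound designs are pruned or rejected by name", {
  set.seed(2)
  Tn <- 40
  ts <- roi_timeseries(matrix(rnorm(Tn * 3), Tn, 3), sampling_interval = 2)
  conf <- cbind(good = rnorm(Tn), flat = rep(1, Tn))
  expect_warning(regress_confounds(ts, conf), "flat")
  dup <- cbind(a = conf[, "good"], b = conf[, "good"] * 2)
  expect_error(suppressWarnings(regress_confounds(ts, dup)), "b")
})

test_that("band-pass preserves the passband and kills DC and fast components", {
  # passband sinusoid at 0.05 Hz, TR 1.97 s
  Tn <- 1024
  tt <- (0:(Tn - 1)) * 1.97
  ts <- roi_timeseries(cbind(sin(2 * pi * 0.05 * tt), cos(2 * pi * 0.05 * tt)),
                       sampling_interval = 1.97)
  out <- bandpass(ts)
  core <- 100:(Tn - 100)  # avoid the filtfilt edge transients
  gain <- sd(out$values[core, 1]) / sd(ts$values[core, 1])
  expect_lt(abs(gain - 1), 0.05)

  # constant column is removed entirely
  flat <- roi_timeseries(cbind(rep(3, 256), sin(2 * pi * 0.05 * (1:256) * 1.97)),
                         sampling_interval = 1.97)
  expect_lt(max(abs(bandpass(flat)$values[, 1])), 1e-8)

  # 0.4 Hz stopband sinusoid at TR 1 s: attenuated by at least 80%
  tt1 <- 0:1023
  fast <- roi_timeseries(cbind(sin(2 * pi * 0.4 * tt1), rnorm(1024)),
                         sampling_interval = 1)
  outf <- bandpass(fast)
  expect_lt(sd(outf$values[core, 1]) / sd(fast$values[core, 1]), 0.2)

  expect_error(bandpass(ts, high_hz = 0.3), "Nyquist")
})

test_that("correlation connectome matches the textbook formula", {
  set.seed(3)
  v <- matrix(rnorm(18), 6, 3)
  v[, 3] <- -v[, 1]
  ts <- roi_timeseries(v, c("r1", "r2", "r3"), 2, "rest")
  cn <- correlation_connectome(ts)
  expect_equal(cn$matrix["r1", "r3"], -1)
  expect_equal(diag(cn$matrix), c(r1 = 1, r2 = 1, r3 = 1))

  # hand oracle for r(r1, r2): sum formula
  x <- v[, 1]; y <- v[, 2]
  r_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(cn$matrix["r1", "r2"], r_hand, tolerance = 1e-12)

  v[, 2] <- 0
  expect_error(correlation_connectome(roi_timeseries(v, c("r1", "r2", "r3"), 2)),
               "r2")
})

test_that("Fisher-z averaging obeys its closed form and invariances", {
  set.seed(4)
  m1 <- random_correlation(5, seed = 10)
  m2 <- random_correlation(5, seed = 11)
  c1 <- connectome(m1); c2 <- connectome(m2)

  # k identical connectomes average to themselves exactly
  same <- average_connectomes(list(c1, c1, c1))
  expect_equal(same$matrix, c1$matrix, tolerance = 1e-12)

  # scalar closed form on one edge
  avg <- average_connectomes(list(c1, c2))
  expect_equal(avg$matrix[2, 1], oracle_fisher_mean(c(m1[2, 1], m2[2, 1])),
               tolerance = 1e-12)

  # permutation invariance and single-run idempotence
  expect_equal(average_connectomes(list(c2, c1))$matrix, avg$matrix)
  expect_equal(average_connectomes(list(c1))$matrix, c1$matrix, tolerance = 1e-12)

  # raw mode averages correlations directly
  raw <- average_connectomes(list(c1, c2), method = "raw")
  expect_equal(raw$matrix[2, 1], mean(c(m1[2, 1], m2[2, 1])), tolerance = 1e-12)

  c3 <- connectome(random_correlation(4, seed = 12))
  expect_error(average_connectomes(list(c1, c3)), "mismatch")
})

test_that("QC rules follow the strict motion and age thresholds", {
  run_fd <- data.frame(
    subject_id = rep(c("s1", "s2", "s3"), each = 3),
    run_id = rep(c("r1", "r2", "r3"), 3),
    mean_fd = c(0.31, 0.32, 0.10,   # s1: two bad runs
                0.31, 0.10, 0.10,   # s2: one bad run
                0.10, 0.10, 0.10))  # s3: clean
  ages <- c(s1 = 30, s2 = 30, s3 = 55)
  qc <- qc_filter(run_fd, ages)
  expect_equal(qc$retained, "s2")
  expect_equal(qc$exclusions$reason[qc$exclusions$subject_id == "s1"], "motion")
  expect_equal(qc$exclusions$reason[qc$exclusions$subject_id == "s3"], "age")
  # the retained subject's single bad run is flagged for dropping
  expect_equal(qc$dropped_runs$run_id, "r1")

  # boundary value 0.3 passes (strictly greater than)
  qc2 <- qc_filter(data.frame(subject_id = "s4", run_id = "r1", mean_fd = 0.3),
                   c(s4 = 25))
  expect_equal(qc2$retained, "s4")

  # missing age falls under listwise deletion
  qc3 <- qc_filter(data.frame(subject_id = "s5", run_id = "r1", mean_fd = 0.1),
                   c(s1 = 20))
  expect_equal(qc3$exclusions$reason, "missing")
})

test_that("pipeline estimates converge to the target correlation as T grows", {
  target <- random_correlation(8, seed = 20)
  err <- sapply(c(500, 2000), function(Tn) {
    sim <- simulate_timeseries(target, run_length = Tn, sampling_interval = 2,
                               seed = 21)
    conn <- process_run(sim$ts, sim$confounds)
    mean(abs(conn$matrix - target)[upper.tri(target)])
  })
  expect_lt(err[2], err[1])
  expect_lt(err[2], 2 / sqrt(2000 - 3))
})
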