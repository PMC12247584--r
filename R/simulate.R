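#' Default nuisance-covariate specification
#'
#' Each covariate carries a marginal distribution, a loading on the latent
#' behavior (approximately its correlation with behavior when the total
#' behavior variance is near 1), and a loading on connectome edges (additive
#' shift, Fisher-z units per SD of the covariate, applied to every edge).
#' Marginal means/SDs follow the magnitudes typical of an adult community
#' sample: age uniform 18-50, sex Bernoulli(0.5) coded 1 = female / 0 = male,
#' mean framewise displacement ~ 0.14 mm, fluid-intelligence and
#' cognitive-screen totals near 36 and 96.
#'
#' @return named list of covariate specs.
#' @export
default_confound_spec <- function() {
  list(
    age = list(dist = "uniform", min = 18, max = 50,
               behavior_loading = -0.13, edge_loading = -0.05),
    sex = list(dist = "bernoulli", prob = 0.5,
               behavior_loading = 0.14, edge_loading = 0),
    fd = list(dist = "normal", mean = 0.14, sd = 0.04,
              behavior_loading = -0.10, edge_loading = -0.10),
    cattell = list(dist = "normal", mean = 36.35, sd = 4.23,
                   behavior_loading = 0.35, edge_loading = 0),
    acer = list(dist = "normal", mean = 96.54, sd = 3.63,
                behavior_loading = 0.40, edge_loading = 0)
  )
}

#' Simulation configuration
#'
#' Bundles and validates every parameter of the synthetic cohort generator.
#'
#' @param n_subjects cohort size (default 243, the analyzed sample size).
#' @param network_sizes cortical parcel counts per network (default: the
#'   400-parcel 17-network preset).
#' @param hippocampus_size number of hippocampal ROIs (default 6).
#' @param n_runs functional runs per subject (default 3: rest, movie,
#'   sensorimotor).
#' @param run_length timepoints per run (default 261).
#' @param sampling_interval TR in seconds (default 1.97).
#' @param signal_edges data.frame with columns `i`, `j`, `beta`: planted
#'   edge-behavior effects, `beta` in Fisher-z units per SD of behavior.
#' @param behavior_noise_sd SD of the behavior residual not explained by the
#'   covariates (default 0.82, putting total behavior variance near 1 under
#'   the default covariate loadings).
#' @param confound_spec see [default_confound_spec()].
#' @param subject_noise_sd SD of per-subject, per-edge Fisher-z noise.
#' @param within_z,between_z group-mean edge strength (Fisher-z) for
#'   same-network and cross-network edges.
#' @param emo_fraction fraction of subjects with the optional emotional
#'   memory score (default 0.5).
#' @param seed integer master seed.
#' @return a validated `simulation_config` list.
#' @export
simulation_config <- function(n_subjects = 243,
                              network_sizes = schaefer17_sizes(),
                              hippocampus_size = 6,
                              n_runs = 3,
                              run_length = 261,
                              sampling_interval = 1.97,
                              signal_edges = NULL,
                              behavior_noise_sd = 0.82,
                              confound_spec = default_confound_spec(),
                              subject_noise_sd = 0.1,
                              within_z = 0.35,
                              between_z = 0.05,
                              emo_fraction = 0.5,
                              seed = 1L) {
  counts <- c(n_subjects, network_sizes, hippocampus_size + 1, n_runs, run_length)
  if (any(counts <= 0)) stop("invalid config: all counts must be positive", call. = FALSE)
  if (behavior_noise_sd < 0 || subject_noise_sd < 0) {
    stop("invalid config: noise SDs must be non-negative", call. = FALSE)
  }
  n_roi <- sum(network_sizes) + hippocampus_size
  if (!is.null(signal_edges)) {
    signal_edges <- as.data.frame(signal_edges)
    if (!all(c("i", "j", "beta") %in% names(signal_edges))) {
      stop("signal_edges needs columns i, j, beta", call. = FALSE)
    }
    ok <- signal_edges$i != signal_edges$j &
      signal_edges$i >= 1 & signal_edges$i <= n_roi &
      signal_edges$j >= 1 & signal_edges$j <= n_roi
    if (!all(ok)) stop("invalid config: signal edges must reference distinct in-range ROIs",
                       call. = FALSE)
    # normalize to lower-triangle orientation
    swap <- signal_edges$i < signal_edges$j
    tmp <- signal_edges$i[swap]
    signal_edges$i[swap] <- signal_edges$j[swap]
    signal_edges$j[swap] <- tmp
  }
  structure(list(n_subjects = n_subjects, network_sizes = network_sizes,
                 hippocampus_size = hippocampus_size, n_runs = n_runs,
                 run_length = run_length, sampling_interval = sampling_interval,
                 signal_edges = signal_edges, behavior_noise_sd = behavior_noise_sd,
                 confound_spec = confound_spec, subject_noise_sd = subject_noise_sd,
                 within_z = within_z, between_z = between_z,
                 emo_fraction = emo_fraction, seed = as.integer(seed)),
            class = "simulation_config")
}

#' Pick random edges to carry a planted behavior effect
#'
#' @param atlas an `atlas_labels` table.
#' @param n_edges how many edges to plant.
#' @param beta effect size, Fisher-z per SD of behavior (recycled).
#' @param networks optional character vector: restrict both endpoints to
#'   ROIs of these networks.
#' @param seed RNG seed.
#' @return data.frame `i`, `j`, `beta` suitable for [simulation_config()].
#' @export
plant_signal_edges <- function(atlas, n_edges, beta = 0.3, networks = NULL, seed = 1L) {
  rois <- if (is.null(networks)) atlas$roi_id else atlas$roi_id[atlas$network %in% networks]
  if (length(rois) < 2) stop("not enough ROIs to plant edges", call. = FALSE)
  pairs <- t(utils::combn(sort(rois), 2))
  if (n_edges > nrow(pairs)) stop("more signal edges requested than available pairs", call. = FALSE)
  set.seed(derive_seed(seed, "plant_edges"))
  pick <- sample(nrow(pairs), n_edges)
  data.frame(i = pairs[pick, 2], j = pairs[pick, 1],
             beta = rep_len(beta, n_edges))
}

# Draw one covariate column plus its standardized latent (population scale).
draw_covariate <- function(spec, n) {
  switch(spec$dist,
    uniform = {
      x <- stats::runif(n, spec$min, spec$max)
      mu <- (spec$min + spec$max) / 2
      sdev <- (spec$max - spec$min) / sqrt(12)
      list(x = x, u = (x - mu) / sdev)
    },
    bernoulli = {
      x <- stats::rbinom(n, 1, spec$prob)
      list(x = x, u = (x - spec$prob) / sqrt(spec$prob * (1 - spec$prob)))
    },
    normal = {
      x <- stats::rnorm(n, spec$mean, spec$sd)
      list(x = x, u = (x - spec$mean) / spec$sd)
    },
    stop("unknown covariate distribution: ", spec$dist, call. = FALSE)
  )
}

#' Simulate a subject cohort of connectomes and behavior
#'
#' Generates, for each subject: nuisance covariates with configured loadings,
#' a behavior score driven by those covariates plus noise, and a connectome
#' built on the Fisher-z scale as group-mean block structure + planted
#' edge-behavior effects (`beta` x standardized behavior on the configured
#' signal edges) + uniform covariate shifts + subject noise, symmetrized and
#' back-transformed to correlations.
#'
#' Identical config and seed reproduce identical output.
#'
#' @param config a [simulation_config()].
#' @return list with `connectomes` (named list of [connectome()]),
#'   `subjects` (data.frame: ids, memory scores, covariates), `atlas`, and
#'   `config`.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(derive_seed(config$seed, "cohort"))
  n <- config$n_subjects
  atlas <- make_atlas(config$network_sizes, config$hippocampus_size)
  n_roi <- nrow(atlas)
  map <- edge_index_map(n_roi)
  E <- nrow(map)

  # covariates and behavior
  cov_draw <- lapply(config$confound_spec, draw_covariate, n = n)
  U <- vapply(cov_draw, `[[`, numeric(n), "u")
  lambdas <- vapply(config$confound_spec, `[[`, numeric(1), "behavior_loading")
  b <- as.numeric(U %*% lambdas) + stats::rnorm(n, 0, config$behavior_noise_sd)
  b_sd_pop <- sqrt(sum(lambdas^2) + config$behavior_noise_sd^2)
  b_std <- b / b_sd_pop

  # memory scores on the observed scale
  mem_narr <- 15.28 + 3.50 * b_std
  split_noise <- stats::rnorm(n, 0, 1)
  immediate <- mem_narr + split_noise
  delayed <- mem_narr - split_noise
  emo_latent <- 0.44 * b_std + sqrt(1 - 0.44^2) * stats::rnorm(n)
  mem_emo <- 52.98 + 23.98 * emo_latent
  has_emo <- seq_len(n) %in% sample(n, round(config$emo_fraction * n))
  mem_emo[!has_emo] <- NA_real_

  # group-mean Fisher-z edge strengths from network blocks
  same_net <- atlas$network[map$i] == atlas$network[map$j]
  z0 <- ifelse(same_net, config$within_z, config$between_z)

  # planted effects
  beta_vec <- numeric(E)
  if (!is.null(config$signal_edges)) {
    k <- match(paste(config$signal_edges$i, config$signal_edges$j),
               paste(map$i, map$j))
    beta_vec[k] <- config$signal_edges$beta
  }

  gammas <- vapply(config$confound_spec, `[[`, numeric(1), "edge_loading")
  cov_shift <- as.numeric(U %*% gammas)  # per-subject, applied to all edges

  connectomes <- vector("list", n)
  ids <- sprintf("sub-%03d", seq_len(n))
  n_extreme <- 0
  for (s in seq_len(n)) {
    z <- z0 + beta_vec * b_std[s] + cov_shift[s] +
      stats::rnorm(E, 0, config$subject_noise_sd)
    if (!all(is.finite(z))) stop("non-finite connectome entries generated", call. = FALSE)
    n_extreme <- n_extreme + sum(abs(z) > 5)
    m <- matrix(0, n_roi, n_roi)
    m[cbind(map$i, map$j)] <- fisher_z_inv(z)
    m <- m + t(m)
    diag(m) <- 1
    connectomes[[s]] <- connectome(m, atlas$roi_name, scale = "pearson_r",
                                   source = paste0(ids[s], ":synthetic"))
  }
  names(connectomes) <- ids
  if (n_extreme / (n * E) > 0.01) {
    warning("more than 1% of simulated edges have |z| > 5 (correlations at the boundary)",
            call. = FALSE)
  }

  subjects <- data.frame(
    subject_id = ids,
    immediate = immediate, delayed = delayed,
    mem_narr = mem_narr, mem_emo = mem_emo,
    age = cov_draw$age$x, sex = cov_draw$sex$x, fd = cov_draw$fd$x,
    cattell = cov_draw$cattell$x, acer = cov_draw$acer$x,
    stringsAsFactors = FALSE
  )
  attr(subjects, "behavior_latent") <- b_std

  list(connectomes = connectomes, subjects = subjects, atlas = atlas,
       config = config)
}

#' Nearest positive semidefinite repair by eigenvalue clipping
#'
#' Symmetrizes, clips eigenvalues at a small positive floor, and rescales to
#' unit diagonal. The Frobenius norm of the adjustment is attached as
#' attribute `"psd_adjustment"`.
#'
#' @param m square symmetric matrix (a correlation target).
#' @param floor smallest allowed eigenvalue.
#' @return repaired correlation matrix.
#' @export
nearest_psd <- function(m, floor = 1e-8) {
  m <- (m + t(m)) / 2
  e <- eigen(m, symmetric = TRUE)
  if (min(e$values) >= floor) {
    attr(m, "psd_adjustment") <- 0
    return(m)
  }
  vals <- pmax(e$values, floor)
  rep_m <- e$vectors %*% (vals * t(e$vectors))
  d <- sqrt(diag(rep_m))
  rep_m <- rep_m / tcrossprod(d)
  rep_m <- (rep_m + t(rep_m)) / 2
  diag(rep_m) <- 1
  attr(rep_m, "psd_adjustment") <- norm(rep_m - m, "F")
  rep_m
}

#' Simulate an ROI time series with a known population correlation
#'
#' Draws `run_length` iid multivariate-normal samples whose population
#' correlation equals the (PSD-repaired) target, then adds confound time
#' courses — motion-like random-walk drifts and an AR(1) global signal —
#' with the given loadings. The matched confound table (motion parameters,
#' derivatives, quadratics, component regressors, FD, DVARS, global signal)
#' is returned alongside.
#'
#' @param target a [connectome()] or correlation matrix (population target).
#' @param run_length timepoints T; must be at least `n_rois + 2`.
#' @param sampling_interval TR, seconds.
#' @param global_loading additive loading of the global-signal time course on
#'   every ROI (0 = no contamination).
#' @param motion_loading loading of the motion drifts on ROI signals, via
#'   random per-ROI weights (0 = none).
#' @param run_type,subject_id passed to [roi_timeseries()].
#' @param seed RNG seed.
#' @return list with `ts` ([roi_timeseries()]), `confounds` (list matching
#'   [process_run()]), and `psd_adjustment` (Frobenius norm of the PSD
#'   repair).
#' @export
simulate_timeseries <- function(target, run_length, sampling_interval = 1.97,
                                global_loading = 0, motion_loading = 0,
                                run_type = "rest", subject_id = "sub-sim",
                                seed = 1L) {
  m <- if (inherits(target, "connectome")) target$matrix else as.matrix(target)
  ids <- if (inherits(target, "connectome")) target$roi_ids else
    (colnames(m) %||% as.character(seq_len(ncol(m))))
  R <- ncol(m)
  if (run_length < R + 2) {
    stop("run_length must be at least n_rois + 2 for a defined correlation estimate",
         call. = FALSE)
  }
  repaired <- nearest_psd(m)
  adj <- attr(repaired, "psd_adjustment")
  set.seed(derive_seed(seed, "timeseries"))
  L <- chol(repaired + diag(1e-10, R))
  Y <- matrix(stats::rnorm(run_length * R), run_length, R) %*% L

  motion6 <- apply(matrix(stats::rnorm(run_length * 6, 0, 0.02), run_length, 6), 2, cumsum)
  colnames(motion6) <- c("trans_x", "trans_y", "trans_z", "rot_x", "rot_y", "rot_z")
  deriv <- rbind(0, diff(motion6))
  colnames(deriv) <- paste0(colnames(motion6), "_d1")
  quad <- cbind(motion6^2, deriv^2)
  colnames(quad) <- paste0(c(colnames(motion6), colnames(deriv)), "_sq")
  components <- matrix(stats::rnorm(run_length * 6), run_length, 6,
                       dimnames = list(NULL, paste0("comp", 1:6)))
  gs <- as.numeric(stats::filter(stats::rnorm(run_length), 0.5, "recursive"))
  fd <- c(0, rowSums(abs(diff(motion6[, 1:3]))) * 2) + 0.05
  dvars <- abs(stats::rnorm(run_length, 1, 0.4))

  if (global_loading != 0) Y <- Y + global_loading * gs
  if (motion_loading != 0) {
    W <- matrix(stats::rnorm(6 * R, 0, 1), 6, R)
    Y <- Y + motion_loading * motion6 %*% W
  }
  colnames(Y) <- ids

  list(ts = roi_timeseries(Y, ids, sampling_interval, run_type, subject_id),
       confounds = list(motion6 = motion6, motion_derivatives = deriv,
                        motion_quadratics = quad, components = components,
                        fd = fd, dvars = dvars, global_signal = gs),
       psd_adjustment = adj)
}
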