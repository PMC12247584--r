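#' ROI time-series container
#'
#' One run's T x R matrix of ROI signals, with sampling interval and run type.
#'
#' @param values numeric T x R matrix, all finite, T >= 2, R >= 2.
#' @param roi_ids unique identifiers aligned to columns (defaults to column
#'   names or 1..R).
#' @param sampling_interval repetition time in seconds.
#' @param run_type one of `"rest"`, `"movie"`, `"sensorimotor"`.
#' @param subject_id optional subject identifier.
#' @return an object of class `roi_timeseries`.
#' @export
roi_timeseries <- function(values, roi_ids = NULL, sampling_interval,
                           run_type = c("rest", "movie", "sensorimotor"),
                           subject_id = NA_character_) {
  run_type <- match.arg(run_type)
  values <- as.matrix(values)
  if (!all(is.finite(values))) stop("time series contains non-finite entries", call. = FALSE)
  if (nrow(values) < 2 || ncol(values) < 2) {
    stop("time series must have at least 2 timepoints and 2 ROIs", call. = FALSE)
  }
  if (is.null(roi_ids)) roi_ids <- colnames(values) %||% as.character(seq_len(ncol(values)))
  roi_ids <- as.character(roi_ids)
  if (length(roi_ids) != ncol(values) || anyDuplicated(roi_ids)) {
    stop("roi_ids must be unique and aligned to columns", call. = FALSE)
  }
  if (!is.numeric(sampling_interval) || sampling_interval <= 0) {
    stop("sampling_interval must be a positive number of seconds", call. = FALSE)
  }
  colnames(values) <- roi_ids
  structure(list(values = values, roi_ids = roi_ids,
                 sampling_interval = sampling_interval,
                 run_type = run_type, subject_id = subject_id),
            class = "roi_timeseries")
}

#' @export
print.roi_timeseries <- function(x, ...) {
  cat(sprintf("<roi_timeseries> %d timepoints x %d ROIs, TR = %gs, run_type = %s\n",
              nrow(x$values), ncol(x$values), x$sampling_interval, x$run_type))
  invisible(x)
}

#' Connectome container
#'
#' Symmetric R x R connectivity matrix keyed to ROI identifiers.
#'
#' @param matrix symmetric numeric matrix; on the `pearson_r` scale entries
#'   must lie in \[-1, 1\] and the diagonal is forced to exactly 1; on the
#'   `fisher_z` scale the diagonal is undefined and stored as 0.
#' @param roi_ids identifiers aligned to rows/columns.
#' @param scale `"pearson_r"` or `"fisher_z"`.
#' @param source character vector of run ids that contributed.
#' @return an object of class `connectome`.
#' @export
connectome <- function(matrix, roi_ids = NULL, scale = c("pearson_r", "fisher_z"),
                       source = character()) {
  scale <- match.arg(scale)
  m <- as.matrix(matrix)
  if (nrow(m) != ncol(m)) stop("connectome matrix must be square", call. = FALSE)
  if (!all(is.finite(m))) stop("connectome contains non-finite entries", call. = FALSE)
  if (max(abs(m - t(m))) > 1e-10) stop("connectome matrix is not symmetric", call. = FALSE)
  m <- (m + t(m)) / 2
  if (is.null(roi_ids)) roi_ids <- colnames(m) %||% as.character(seq_len(ncol(m)))
  roi_ids <- as.character(roi_ids)
  if (length(roi_ids) != ncol(m) || anyDuplicated(roi_ids)) {
    stop("roi_ids must be unique and match matrix dimension", call. = FALSE)
  }
  if (scale == "pearson_r") {
    off <- m[row(m) != col(m)]
    if (length(off) && (min(off) < -1 || max(off) > 1)) {
      stop("pearson_r connectome entries must lie in [-1, 1]", call. = FALSE)
    }
    diag(m) <- 1
  } else {
    diag(m) <- 0
  }
  dimnames(m) <- list(roi_ids, roi_ids)
  structure(list(matrix = m, roi_ids = roi_ids, scale = scale,
                 source = as.character(source)),
            class = "connectome")
}

#' @export
print.connectome <- function(x, ...) {
  cat(sprintf("<connectome> %d x %d (%s), %d source run(s)\n",
              nrow(x$matrix), ncol(x$matrix), x$scale, length(x$source)))
  invisible(x)
}

#' Motion/artifact spike regressors
#'
#' One indicator column per flagged timepoint. A timepoint is flagged when
#' framewise displacement exceeds `fd_threshold` (mm) or standardized DVARS
#' exceeds `dvars_threshold`; both comparisons are strict (`>`), so boundary
#' values are not flagged.
#'
#' @param fd framewise displacement per timepoint, mm.
#' @param dvars standardized DVARS per timepoint.
#' @param fd_threshold default 0.6 mm.
#' @param dvars_threshold default 2.
#' @return a T x m 0/1 matrix, m = number of flagged timepoints (possibly 0).
#' @export
build_spike_regressors <- function(fd, dvars, fd_threshold = 0.6, dvars_threshold = 2) {
  if (length(fd) != length(dvars)) stop("fd and dvars must have equal length", call. = FALSE)
  if (fd_threshold <= 0 || dvars_threshold <= 0) {
    stop("spike thresholds must be positive", call. = FALSE)
  }
  flagged <- which(fd > fd_threshold | dvars > dvars_threshold)
  out <- matrix(0, nrow = length(fd), ncol = length(flagged))
  if (length(flagged)) {
    out[cbind(flagged, seq_along(flagged))] <- 1
    colnames(out) <- paste0("spike_t", flagged)
  }
  out
}

#' Canonical double-gamma hemodynamic response function
#'
#' Difference of two gamma densities: response peaking at 5 s, undershoot
#' peaking at 15 s, peak-to-undershoot ratio 6.
#'
#' @param t time in seconds (non-negative).
#' @return HRF values at `t`.
#' @export
hrf_double_gamma <- function(t) {
  h <- stats::dgamma(t, shape = 6, rate = 1) -
    stats::dgamma(t, shape = 16, rate = 1) / 6
  h[t < 0] <- 0
  h
}

#' Task-activation regressor from stimulus onsets
#'
#' Places unit impulses at the samples nearest each onset and convolves with
#' the canonical double-gamma HRF, truncated to the run length. Onsets at or
#' beyond the run end are dropped with a warning.
#'
#' @param onsets stimulus onsets in seconds from run start (non-negative).
#' @param n_timepoints run length T.
#' @param sampling_interval TR in seconds.
#' @return numeric vector of length T.
#' @export
build_task_regressor <- function(onsets, n_timepoints, sampling_interval) {
  if (length(onsets) && any(onsets < 0)) stop("onsets must be non-negative", call. = FALSE)
  onsets <- sort(onsets)
  run_end <- n_timepoints * sampling_interval
  late <- onsets >= run_end
  if (any(late)) {
    warning(sum(late), " onset(s) at or beyond run end dropped", call. = FALSE)
    onsets <- onsets[!late]
  }
  out <- numeric(n_timepoints)
  if (!length(onsets)) return(out)
  tgrid <- (seq_len(n_timepoints) - 1) * sampling_interval
  hrf <- hrf_double_gamma(tgrid)
  for (o in onsets) {
    k <- round(o / sampling_interval) + 1
    if (k > n_timepoints) next
    span <- k:n_timepoints
    out[span] <- out[span] + hrf[seq_along(span)]
  }
  out
}

# Prune intercept-redundant columns from a confound design: constant columns
# and exact duplicates, each pruning logged as a warning.
prune_design <- function(design) {
  if (is.null(design) || ncol(design) == 0) return(design)
  keep <- rep(TRUE, ncol(design))
  nm <- colnames(design) %||% paste0("c", seq_len(ncol(design)))
  const <- apply(design, 2, function(x) max(x) - min(x) == 0)
  if (any(const)) {
    warning("pruning constant confound column(s): ", paste(nm[const], collapse = ", "),
            call. = FALSE)
    keep[const] <- FALSE
  }
  # exact duplicates among the survivors
  if (sum(keep) > 1) {
    idx <- which(keep)
    seen <- list()
    for (j in idx) {
      key <- paste(design[, j], collapse = "\r")
      if (!is.null(seen[[key]])) {
        warning("pruning duplicate confound column: ", nm[j], call. = FALSE)
        keep[j] <- FALSE
      } else {
        seen[[key]] <- j
      }
    }
  }
  design[, keep, drop = FALSE]
}

#' Ordinary least-squares confound regression
#'
#' Replaces every ROI column by its OLS residual against an intercept plus the
#' given confound columns. Constant and duplicate confound columns are pruned
#' with a warning; a design that is still rank deficient is an error naming
#' the collinear columns.
#'
#' @param ts a [roi_timeseries()].
#' @param confounds numeric matrix with T rows (or NULL/zero columns for
#'   intercept-only mean centering).
#' @return a `roi_timeseries` of residuals.
#' @export
regress_confounds <- function(ts, confounds = NULL) {
  stopifnot(inherits(ts, "roi_timeseries"))
  Tn <- nrow(ts$values)
  if (!is.null(confounds)) {
    confounds <- as.matrix(confounds)
    if (nrow(confounds) != Tn) stop("confound design must have T rows", call. = FALSE)
    confounds <- prune_design(confounds)
  }
  X <- cbind(intercept = rep(1, Tn), confounds)
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    bad <- colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]]
    stop("rank-deficient confound design; collinear column(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  resid <- qr.resid(qx, ts$values)
  out <- ts
  out$values <- resid
  out
}

#' Zero-phase band-pass filter
#'
#' Second-order Butterworth band-pass applied forward and backward
#' (`signal::filtfilt`), so the effective magnitude response is squared and
#' the phase is zero. Each column is mean-centered first; the default corner
#' frequencies are 0.008 Hz (high-pass) and 0.1 Hz (low-pass).
#'
#' @param ts a [roi_timeseries()].
#' @param low_hz high-pass corner frequency.
#' @param high_hz low-pass corner frequency; must be below Nyquist.
#' @param order Butterworth prototype order (default 2).
#' @return filtered `roi_timeseries` with (approximately) zero-mean columns.
#' @export
bandpass <- function(ts, low_hz = 0.008, high_hz = 0.1, order = 2) {
  stopifnot(inherits(ts, "roi_timeseries"))
  nyq <- 1 / (2 * ts$sampling_interval)
  if (!(low_hz > 0 && low_hz < high_hz)) {
    stop("band edges must satisfy 0 < low_hz < high_hz", call. = FALSE)
  }
  if (high_hz >= nyq) {
    stop(sprintf("high_hz (%g) must be below the Nyquist frequency (%g Hz)", high_hz, nyq),
         call. = FALSE)
  }
  filt <- signal::butter(order, c(low_hz, high_hz) / nyq, type = "pass")
  vals <- scale(ts$values, center = TRUE, scale = FALSE)
  out <- apply(vals, 2, function(col) signal::filtfilt(filt, col))
  out <- matrix(out, nrow = nrow(vals), dimnames = dimnames(ts$values))
  res <- ts
  res$values <- out
  res
}

#' Pearson ROI-to-ROI connectome from a time series
#'
#' @param ts a [roi_timeseries()]; every column must have nonzero variance.
#' @return a [connectome()] on the `pearson_r` scale.
#' @export
correlation_connectome <- function(ts) {
  stopifnot(inherits(ts, "roi_timeseries"))
  v <- apply(ts$values, 2, stats::sd)
  if (any(v == 0)) {
    stop("zero-variance ROI column(s): ", paste(ts$roi_ids[v == 0], collapse = ", "),
         call. = FALSE)
  }
  m <- stats::cor(ts$values)
  m <- (m + t(m)) / 2
  m[m > 1] <- 1
  m[m < -1] <- -1
  connectome(m, ts$roi_ids, scale = "pearson_r",
             source = paste0(ts$subject_id, ":", ts$run_type))
}

#' Average per-run connectomes into a generalized connectome
#'
#' By default each edge is Fisher z-transformed, averaged arithmetically
#' across runs, and transformed back to a correlation; `method = "raw"`
#' averages the correlations directly (sensitivity variant). The diagonal is
#' restored to 1.
#'
#' @param runs list of [connectome()] objects with identical ROI ids/order.
#' @param method `"fisher"` (default) or `"raw"`.
#' @return a generalized [connectome()] on the `pearson_r` scale.
#' @export
average_connectomes <- function(runs, method = c("fisher", "raw")) {
  method <- match.arg(method)
  if (!length(runs)) stop("at least one connectome is required", call. = FALSE)
  stopifnot(all(vapply(runs, inherits, logical(1), "connectome")))
  ids <- runs[[1]]$roi_ids
  for (r in runs) {
    if (!identical(r$roi_ids, ids)) stop("connectomes have mismatched ROI sets/order", call. = FALSE)
    if (r$scale != "pearson_r") stop("averaging expects pearson_r connectomes", call. = FALSE)
  }
  mats <- lapply(runs, function(r) r$matrix)
  # per-edge values are sorted before summation so the average is exactly
  # invariant to run order despite floating-point non-associativity
  sorted_mean <- function(mlist) {
    Z <- vapply(mlist, as.numeric, numeric(length(mlist[[1]])))
    if (is.null(dim(Z))) Z <- matrix(Z, nrow = 1)
    sorted <- matrix(Z[order(row(Z), Z)], nrow = nrow(Z), byrow = TRUE)
    matrix(rowSums(sorted) / ncol(sorted), nrow(mlist[[1]]), ncol(mlist[[1]]))
  }
  if (method == "fisher") {
    avg <- fisher_z_inv(sorted_mean(lapply(mats, fisher_z)))
  } else {
    avg <- sorted_mean(mats)
  }
  diag(avg) <- 1
  connectome(avg, ids, scale = "pearson_r",
             source = unlist(lapply(runs, `[[`, "source")))
}

#' Motion- and age-based participant quality control
#'
#' A run is bad when its mean framewise displacement exceeds `run_threshold`
#' (strictly). A subject is excluded when the number of bad runs exceeds
#' `max_bad_runs`, when age falls outside `age_range` (strictly outside), or
#' when age is missing (listwise deletion). Bad runs of retained subjects are
#' flagged for dropping from the generalized average.
#'
#' @param run_fd data.frame with columns `subject_id`, `run_id`, `mean_fd`.
#' @param ages named numeric vector (names = subject ids); `NA` = missing.
#' @param run_threshold mean-FD cutoff per run, mm (default 0.3).
#' @param max_bad_runs largest tolerated number of bad runs (default 1, i.e.
#'   exclusion at 2 or more).
#' @param age_range inclusive age bounds (default 18-50).
#' @return list with `retained` (subject ids), `exclusions` (data.frame
#'   `subject_id`, `reason`), and `dropped_runs` (data.frame `subject_id`,
#'   `run_id`).
#' @export
qc_filter <- function(run_fd, ages, run_threshold = 0.3, max_bad_runs = 1,
                      age_range = c(18, 50)) {
  need <- c("subject_id", "run_id", "mean_fd")
  if (!all(need %in% names(run_fd))) {
    stop("run_fd must have columns subject_id, run_id, mean_fd", call. = FALSE)
  }
  subjects <- unique(as.character(run_fd$subject_id))
  excl <- list()
  dropped <- list()
  retained <- character()
  for (s in subjects) {
    rows <- run_fd[run_fd$subject_id == s, , drop = FALSE]
    bad <- rows$mean_fd > run_threshold
    age <- if (s %in% names(ages)) ages[[s]] else NA_real_
    if (sum(bad) > max_bad_runs) {
      excl[[s]] <- "motion"
    } else if (is.na(age)) {
      excl[[s]] <- "missing"
    } else if (age < age_range[1] || age > age_range[2]) {
      excl[[s]] <- "age"
    } else {
      retained <- c(retained, s)
      if (any(bad)) {
        dropped[[s]] <- data.frame(subject_id = s, run_id = rows$run_id[bad],
                                   stringsAsFactors = FALSE)
      }
    }
  }
  exclusions <- if (length(excl)) {
    data.frame(subject_id = names(excl), reason = unlist(excl),
               row.names = NULL, stringsAsFactors = FALSE)
  } else {
    data.frame(subject_id = character(), reason = character(), stringsAsFactors = FALSE)
  }
  dropped_runs <- if (length(dropped)) {
    do.call(rbind, c(dropped, list(make.row.names = FALSE)))
  } else {
    data.frame(subject_id = character(), run_id = character(), stringsAsFactors = FALSE)
  }
  list(retained = retained, exclusions = exclusions, dropped_runs = dropped_runs)
}

#' Denoise one run and compute its connectome
#'
#' Applies the fixed pipeline order: spike/task/confound regression, then
#' band-pass filtering, then Pearson correlation. The confound design
#' concatenates the six motion parameters, their derivatives and quadratics,
#' up to the first six component regressors, framewise displacement, the
#' global signal (if `gsr`), spike regressors, and (for sensorimotor runs
#' only) the HRF-convolved task regressor.
#'
#' @param ts a [roi_timeseries()].
#' @param confounds list with elements `motion6`, `motion_derivatives`,
#'   `motion_quadratics`, `components`, `fd`, `dvars`, `global_signal`
#'   (any may be NULL).
#' @param events optional numeric vector of task onsets (seconds); used only
#'   when `ts$run_type == "sensorimotor"`.
#' @param gsr include global signal regression (default TRUE).
#' @param fd_spike,dvars_spike spike-flagging thresholds.
#' @param low_hz,high_hz band-pass corners.
#' @return a per-run [connectome()].
#' @export
process_run <- function(ts, confounds = NULL, events = NULL, gsr = TRUE,
                        fd_spike = 0.6, dvars_spike = 2,
                        low_hz = 0.008, high_hz = 0.1) {
  stopifnot(inherits(ts, "roi_timeseries"))
  Tn <- nrow(ts$values)
  design <- NULL
  if (!is.null(confounds)) {
    comp <- confounds$components
    if (!is.null(comp)) comp <- as.matrix(comp)[, seq_len(min(6, ncol(as.matrix(comp)))), drop = FALSE]
    parts <- list(confounds$motion6, confounds$motion_derivatives,
                  confounds$motion_quadratics, comp)
    parts <- Filter(Negate(is.null), lapply(parts, function(p) if (is.null(p)) NULL else as.matrix(p)))
    design <- if (length(parts)) do.call(cbind, parts) else NULL
    if (!is.null(confounds$fd)) design <- cbind(design, fd = confounds$fd)
    if (gsr && !is.null(confounds$global_signal)) {
      design <- cbind(design, global_signal = confounds$global_signal)
    }
    if (!is.null(confounds$fd) && !is.null(confounds$dvars)) {
      spikes <- build_spike_regressors(confounds$fd, confounds$dvars, fd_spike, dvars_spike)
      if (ncol(spikes)) design <- cbind(design, spikes)
    }
  }
  if (identical(ts$run_type, "sensorimotor") && !is.null(events) && length(events)) {
    design <- cbind(design, task = build_task_regressor(events, Tn, ts$sampling_interval))
  }
  cleaned <- regress_confounds(ts, design)
  filtered <- bandpass(cleaned, low_hz = low_hz, high_hz = high_hz)
  correlation_connectome(filtered)
}
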