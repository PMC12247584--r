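# Delimited-table dialect used for every artifact: UTF-8, tab-separated,
# header row, '.' decimal, NA token "NA", numbers at 10 significant digits.

#' Write / read a square connectivity matrix
#'
#' Tab-delimited with a ROI-id header row, 10 significant digits.
#'
#' @param conn a [connectome()] (or plain matrix for `write_matrix`).
#' @param path file path.
#' @export
write_connectome <- function(conn, path) {
  m <- if (inherits(conn, "connectome")) conn$matrix else as.matrix(conn)
  df <- as.data.frame(signif(m, 10))
  colnames(df) <- colnames(m) %||% as.character(seq_len(ncol(m)))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE, na = "NA")
  if (inherits(conn, "connectome")) {
    meta <- list(scale = conn$scale, source = conn$source, roi_ids = conn$roi_ids)
    jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE)
  }
  invisible(path)
}

#' @rdname write_connectome
#' @export
read_connectome <- function(path) {
  df <- utils::read.delim(path, sep = "\t", check.names = FALSE)
  m <- as.matrix(df)
  meta_path <- paste0(path, ".json")
  scale <- "pearson_r"
  src <- character()
  if (file.exists(meta_path)) {
    meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
    scale <- meta$scale
    src <- meta$source
  }
  connectome(m, colnames(m), scale = scale, source = src)
}

# flatten a confound list into one table for writing
confounds_to_table <- function(cf) {
  cbind(as.data.frame(cf$motion6), as.data.frame(cf$motion_derivatives),
        as.data.frame(cf$motion_quadratics), as.data.frame(cf$components),
        fd = cf$fd, dvars = cf$dvars, global_signal = cf$global_signal)
}

#' Read a confound table into the grouped confound list
#'
#' Rebuilds the grouped confound structure consumed by [process_run()] from
#' a flat confounds table, using the column-name provenance (motion columns,
#' `_d1` derivatives, `_sq` quadratics, `comp*` components, `fd`, `dvars`,
#' `global_signal`).
#'
#' @param path path to a tab-delimited confounds table.
#' @return list with elements `motion6`, `motion_derivatives`,
#'   `motion_quadratics`, `components`, `fd`, `dvars`, `global_signal`.
#' @export
read_confounds <- function(path) {
  table_to_confounds(utils::read.delim(path, check.names = FALSE))
}

# rebuild the confound list from a table using the column-name provenance
table_to_confounds <- function(df) {
  nm <- names(df)
  motion_cols <- c("trans_x", "trans_y", "trans_z", "rot_x", "rot_y", "rot_z")
  list(
    motion6 = as.matrix(df[, intersect(motion_cols, nm), drop = FALSE]),
    motion_derivatives = as.matrix(df[, grep("_d1$", nm, value = TRUE), drop = FALSE]),
    motion_quadratics = as.matrix(df[, grep("_sq$", nm, value = TRUE), drop = FALSE]),
    components = as.matrix(df[, grep("^comp", nm, value = TRUE), drop = FALSE]),
    fd = df$fd, dvars = df$dvars, global_signal = df$global_signal
  )
}

#' Write a simulated cohort to disk as a run manifest
#'
#' Generates per-run ROI time series from each subject's simulated
#' connectome, writes one time-series table and one confounds table per
#' subject-run (plus an onsets table for sensorimotor runs), the
#' behavior/covariate table (`subjects.csv`), the atlas (`atlas.tsv`), and a
#' `manifest.json` index mapping subjects to runs and file paths.
#'
#' @param cohort output of [simulate_cohort()].
#' @param dir output directory (created if needed).
#' @param global_loading,motion_loading confound contamination passed to
#'   [simulate_timeseries()].
#' @return the manifest path, invisibly.
#' @export
write_cohort <- function(cohort, dir, global_loading = 0.2, motion_loading = 0.5) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- cohort$config
  run_types <- rep_len(c("rest", "movie", "sensorimotor"), cfg$n_runs)
  atlas_path <- file.path(dir, "atlas.tsv")
  write_atlas(cohort$atlas, atlas_path)
  subjects_path <- file.path(dir, "subjects.csv")
  utils::write.table(cohort$subjects, subjects_path, sep = ",", quote = FALSE,
                     row.names = FALSE, na = "NA")

  index <- list()
  for (sid in names(cohort$connectomes)) {
    runs <- list()
    for (r in seq_len(cfg$n_runs)) {
      seed_r <- derive_seed(cfg$seed, paste0(sid, "_run", r))
      sim <- simulate_timeseries(cohort$connectomes[[sid]],
                                 run_length = cfg$run_length,
                                 sampling_interval = cfg$sampling_interval,
                                 global_loading = global_loading,
                                 motion_loading = motion_loading,
                                 run_type = run_types[r], subject_id = sid,
                                 seed = seed_r)
      ts_path <- file.path(dir, sprintf("%s_run-%d_timeseries.tsv", sid, r))
      cf_path <- file.path(dir, sprintf("%s_run-%d_confounds.tsv", sid, r))
      utils::write.table(as.data.frame(signif(sim$ts$values, 10)), ts_path,
                         sep = "\t", quote = FALSE, row.names = FALSE, na = "NA")
      utils::write.table(signif(confounds_to_table(sim$confounds), 10), cf_path,
                         sep = "\t", quote = FALSE, row.names = FALSE, na = "NA")
      run <- list(run_id = sprintf("run-%d", r), run_type = run_types[r],
                  timeseries = basename(ts_path), confounds = basename(cf_path))
      if (run_types[r] == "sensorimotor") {
        ev_path <- file.path(dir, sprintf("%s_run-%d_events.tsv", sid, r))
        onsets <- seq(10, (cfg$run_length - 10) * cfg$sampling_interval, by = 40)
        utils::write.table(data.frame(onset_s = onsets), ev_path, sep = "\t",
                           quote = FALSE, row.names = FALSE)
        run$events <- basename(ev_path)
      }
      runs[[length(runs) + 1]] <- run
    }
    index[[sid]] <- runs
  }

  manifest <- list(atlas = basename(atlas_path), subjects = basename(subjects_path),
                   sampling_interval = cfg$sampling_interval,
                   seed = cfg$seed,
                   options = list(global_loading = global_loading,
                                  motion_loading = motion_loading),
                   runs = index)
  manifest_path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest_path)
}

#' Load a run manifest
#'
#' @param path path to `manifest.json`.
#' @return the manifest list with an added `dir` element.
#' @export
read_manifest <- function(path) {
  manifest <- jsonlite::read_json(path, simplifyVector = FALSE)
  manifest$dir <- dirname(normalizePath(path))
  manifest
}

#' Validate the inputs referenced by a manifest
#'
#' Report-only consistency checks: every referenced file exists, time series
#' and confound tables agree on T, the atlas covers the time-series ROI
#' columns, and the behavior table carries the expected schema.
#'
#' @param manifest a loaded manifest (see [read_manifest()]) or a path.
#' @return data.frame of violations (`context`, `violation`); zero rows when
#'   everything is consistent.
#' @export
validate_inputs <- function(manifest) {
  if (is.character(manifest)) manifest <- read_manifest(manifest)
  dir <- manifest$dir
  bad <- list()
  note <- function(context, violation) {
    bad[[length(bad) + 1]] <<- data.frame(context = context, violation = violation,
                                          stringsAsFactors = FALSE)
  }
  atlas_path <- file.path(dir, manifest$atlas)
  subjects_path <- file.path(dir, manifest$subjects)
  atlas <- NULL
  if (!file.exists(atlas_path)) note("atlas", paste0("missing file: ", manifest$atlas))
  else atlas <- read_atlas(atlas_path)
  if (!file.exists(subjects_path)) {
    note("subjects", paste0("missing file: ", manifest$subjects))
  } else {
    subj <- utils::read.csv(subjects_path)
    need <- c("subject_id", "age", "sex", "fd")
    miss <- setdiff(need, names(subj))
    if (length(miss)) note("subjects", paste0("missing column(s): ", paste(miss, collapse = ", ")))
  }
  for (sid in names(manifest$runs)) {
    for (run in manifest$runs[[sid]]) {
      ctx <- paste0(sid, "/", run$run_id)
      ts_path <- file.path(dir, run$timeseries)
      cf_path <- file.path(dir, run$confounds)
      if (!file.exists(ts_path)) { note(ctx, paste0("missing file: ", run$timeseries)); next }
      if (!file.exists(cf_path)) { note(ctx, paste0("missing file: ", run$confounds)); next }
      ts <- utils::read.delim(ts_path, check.names = FALSE)
      cf <- utils::read.delim(cf_path, check.names = FALSE)
      if (nrow(ts) != nrow(cf)) {
        note(ctx, sprintf("timepoint mismatch: %d in time series vs %d in confounds",
                          nrow(ts), nrow(cf)))
      }
      if (!is.null(atlas) && ncol(ts) != nrow(atlas)) {
        note(ctx, sprintf("atlas covers %d ROIs but time series has %d columns",
                          nrow(atlas), ncol(ts)))
      }
      if (!is.null(run$events) && !file.exists(file.path(dir, run$events))) {
        note(ctx, paste0("missing file: ", run$events))
      }
    }
  }
  if (length(bad)) do.call(rbind, bad) else
    data.frame(context = character(), violation = character(), stringsAsFactors = FALSE)
}

#' Run the full analysis pipeline on a manifest
#'
#' Stages, in order: input validation (missing files abort before any
#' compute), motion/age participant QC, per-run denoising and connectome
#' estimation, Fisher-z cross-run averaging into generalized connectomes,
#' network summaries, covariate-adjusted brain-behavior models, and
#' (optionally) CBPM with permutation inference. All tabular artifacts and a
#' provenance record (options snapshot, seed, output checksums) are written
#' under `out_dir`; a rerun with identical inputs reproduces identical
#' outputs.
#'
#' @param manifest_path path to `manifest.json`.
#' @param out_dir output directory.
#' @param gsr include global signal regression (default TRUE).
#' @param average `"fisher"` or `"raw"` cross-run averaging.
#' @param drop_bad_runs drop a retained subject's high-motion runs from the
#'   generalized average (default TRUE).
#' @param fd_spike,dvars_spike spike-flagging thresholds.
#' @param run_cbpm run the CBPM stage (default TRUE).
#' @param cbpm a [cbpm_config()] for that stage.
#' @return invisible list of the main in-memory results.
#' @export
run_pipeline <- function(manifest_path, out_dir, gsr = TRUE,
                         average = c("fisher", "raw"), drop_bad_runs = TRUE,
                         fd_spike = 0.6, dvars_spike = 2,
                         run_cbpm = TRUE, cbpm = cbpm_config()) {
  average <- match.arg(average)
  manifest <- read_manifest(manifest_path)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  report <- validate_inputs(manifest)
  missing <- grepl("^missing file", report$violation)
  if (any(missing)) {
    stop("manifest references missing file(s): ",
         paste(report$context[missing], collapse = ", "), call. = FALSE)
  }

  atlas <- read_atlas(file.path(manifest$dir, manifest$atlas))
  subjects <- utils::read.csv(file.path(manifest$dir, manifest$subjects))

  # --- QC stage: per-run mean FD from the confound tables ---------------
  fd_rows <- list()
  for (sid in names(manifest$runs)) {
    for (run in manifest$runs[[sid]]) {
      cf <- utils::read.delim(file.path(manifest$dir, run$confounds), check.names = FALSE)
      fd_rows[[length(fd_rows) + 1]] <- data.frame(
        subject_id = sid, run_id = run$run_id, mean_fd = mean(cf$fd),
        stringsAsFactors = FALSE)
    }
  }
  run_fd <- do.call(rbind, fd_rows)
  ages <- stats::setNames(subjects$age, subjects$subject_id)
  qc <- qc_filter(run_fd, ages)
  utils::write.table(qc$exclusions, file.path(out_dir, "exclusions.csv"),
                     sep = ",", quote = FALSE, row.names = FALSE)

  # --- connectome stage --------------------------------------------------
  connectomes <- list()
  for (sid in qc$retained) {
    runs <- manifest$runs[[sid]]
    per_run <- list()
    for (run in runs) {
      if (drop_bad_runs &&
          nrow(qc$dropped_runs) &&
          any(qc$dropped_runs$subject_id == sid & qc$dropped_runs$run_id == run$run_id)) {
        next
      }
      ts_tab <- utils::read.delim(file.path(manifest$dir, run$timeseries), check.names = FALSE)
      cf <- table_to_confounds(utils::read.delim(file.path(manifest$dir, run$confounds),
                                                 check.names = FALSE))
      events <- NULL
      if (!is.null(run$events)) {
        events <- utils::read.delim(file.path(manifest$dir, run$events))$onset_s
      }
      ts <- roi_timeseries(as.matrix(ts_tab), colnames(ts_tab),
                           manifest$sampling_interval, run$run_type, sid)
      per_run[[length(per_run) + 1]] <- process_run(ts, cf, events, gsr = gsr,
                                                    fd_spike = fd_spike,
                                                    dvars_spike = dvars_spike)
    }
    if (!length(per_run)) next
    gen <- average_connectomes(per_run, method = average)
    connectomes[[sid]] <- gen
    write_connectome(gen, file.path(out_dir, paste0(sid, "_connectome.tsv")))
  }

  # --- summaries, scores, models ----------------------------------------
  summaries <- summarize_cohort(connectomes, atlas)
  utils::write.table(as.data.frame(lapply(summaries, function(x)
    if (is.numeric(x)) signif(x, 10) else x)),
    file.path(out_dir, "summaries.csv"), sep = ",", quote = FALSE, row.names = FALSE)
  subjects <- build_scores(subjects)
  models <- run_association_models(subjects, summaries)
  models$beta <- signif(models$beta, 10)
  models$raw_beta <- signif(models$raw_beta, 10)
  models$se <- signif(models$se, 10)
  models$t <- signif(models$t, 10)
  models$p <- signif(models$p, 10)
  utils::write.table(models, file.path(out_dir, "models.csv"),
                     sep = ",", quote = FALSE, row.names = FALSE, na = "NA")

  # --- CBPM stage --------------------------------------------------------
  cbpm_out <- NULL
  if (run_cbpm) {
    d <- merge(subjects, summaries, by = "subject_id")
    d <- d[match(names(connectomes), d$subject_id), ]
    X <- cohort_edge_matrix(connectomes)
    covs <- d[, intersect(cbpm$covariates, names(d)), drop = FALSE]
    cbpm_out <- cbpm_permutation_test(X, d$mem_narr, covs, cbpm)
    res <- cbpm_out$observed
    jsonlite::write_json(list(r_obs_pred = res$r_obs_pred, p_perm = cbpm_out$p_perm,
                              p_perm_add_one = cbpm_out$p_perm_add_one,
                              status = res$status,
                              n_fallback_folds = sum(res$fold_fallback),
                              n_consensus_pos = sum(res$consensus_pos),
                              n_consensus_neg = sum(res$consensus_neg)),
                         file.path(out_dir, "cbpm_result.json"),
                         auto_unbox = TRUE, digits = NA)
    utils::write.table(data.frame(null_r = signif(cbpm_out$null_r, 10)),
                       file.path(out_dir, "null_distribution.csv"),
                       sep = ",", quote = FALSE, row.names = FALSE)
    map <- attr(X, "edge_map")
    freq_pos <- rowMeans(res$pos_masks)
    freq_neg <- rowMeans(res$neg_masks)
    sel <- freq_pos > 0 | freq_neg > 0
    consensus <- data.frame(edge = map$k[sel], roi_i = map$i[sel], roi_j = map$j[sel],
                            sign = ifelse(freq_pos[sel] >= freq_neg[sel], "positive", "negative"),
                            fold_selection_frequency = signif(pmax(freq_pos, freq_neg)[sel], 10))
    utils::write.table(consensus, file.path(out_dir, "consensus_edges.csv"),
                       sep = ",", quote = FALSE, row.names = FALSE)
  }

  # --- provenance --------------------------------------------------------
  options_snapshot <- list(gsr = gsr, average = average, drop_bad_runs = drop_bad_runs,
                           fd_spike = fd_spike, dvars_spike = dvars_spike,
                           run_cbpm = run_cbpm,
                           cbpm = unclass(cbpm), seed = manifest$seed)
  outputs <- list.files(out_dir, full.names = TRUE)
  outputs <- outputs[!grepl("provenance", outputs)]
  prov <- list(options = options_snapshot,
               checksums = as.list(tools::md5sum(sort(outputs))))
  jsonlite::write_json(prov, file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, pretty = TRUE)

  invisible(list(qc = qc, connectomes = connectomes, summaries = summaries,
                 models = models, cbpm = cbpm_out, validation = report))
}
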