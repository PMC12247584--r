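#!/usr/bin/env Rscript
# Stage 2: participant QC and connectome estimation.
#
# Applies the motion/age exclusion rules (a run is bad when its mean FD
# exceeds 0.3 mm; a subject is excluded at two or more bad runs, out-of-range
# or missing age), then denoises every retained run (confound + spike + task
# regression, 0.008-0.1 Hz zero-phase band-pass, Pearson correlation) and
# Fisher-z-averages runs into one generalized connectome per subject.

library(genconn)

manifest <- read_manifest("results/cohort/manifest.json")
out_dir <- "results/connectomes"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

report <- validate_inputs(manifest)
stopifnot(nrow(report) == 0)

subjects <- read.csv(file.path(manifest$dir, manifest$subjects))

# per-run mean FD for QC
fd_rows <- do.call(rbind, lapply(names(manifest$runs), function(sid) {
  do.call(rbind, lapply(manifest$runs[[sid]], function(run) {
    cf <- read.delim(file.path(manifest$dir, run$confounds), check.names = FALSE)
    data.frame(subject_id = sid, run_id = run$run_id, mean_fd = mean(cf$fd))
  }))
}))
qc <- qc_filter(fd_rows, setNames(subjects$age, subjects$subject_id))
write.csv(qc$exclusions, file.path(out_dir, "exclusions.csv"), row.names = FALSE)
cat("QC retained", length(qc$retained), "of", length(unique(fd_rows$subject_id)),
    "subjects\n")
if (nrow(qc$exclusions)) print(table(qc$exclusions$reason))

for (sid in qc$retained) {
  per_run <- list()
  for (run in manifest$runs[[sid]]) {
    if (any(qc$dropped_runs$subject_id == sid & qc$dropped_runs$run_id == run$run_id)) next
    ts_tab <- read.delim(file.path(manifest$dir, run$timeseries), check.names = FALSE)
    cf <- read_confounds(file.path(manifest$dir, run$confounds))
    events <- if (!is.null(run$events)) {
      read.delim(file.path(manifest$dir, run$events))$onset_s
    }
    ts <- roi_timeseries(as.matrix(ts_tab), colnames(ts_tab),
                         manifest$sampling_interval, run$run_type, sid)
    per_run[[length(per_run) + 1]] <- process_run(ts, cf, events, gsr = TRUE)
  }
  gen <- average_connectomes(per_run, method = "fisher")
  write_connectome(gen, file.path(out_dir, paste0(sid, "_connectome.tsv")))
}

cat("Wrote", length(qc$retained), "generalized connectomes to", out_dir, "\n")
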