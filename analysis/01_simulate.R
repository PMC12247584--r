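#!/usr/bin/env Rscript
# Stage 1: simulate a demonstration cohort and write it to disk as a run
# manifest (per-run ROI time series + confounds, behavior table, atlas).
#
# The cohort is a scaled-down analogue of the study sample: 120 subjects,
# a 30-ROI atlas (17-network-style labels collapsed to 5 cortical networks
# plus 2 hippocampal ROIs), 2 runs per subject, and 20 planted edge-behavior
# effects (beta = 0.35 Fisher-z per SD of behavior) confined to one
# designated network so the later lesion stage has a known target.

library(genconn)

out_dir <- "results/cohort"
seed <- 20260919L

sizes <- c(SigNet = 8L, NetB = 5L, DefaultC = 5L, DefaultA = 5L, NetC = 5L)
atlas <- make_atlas(sizes, hippocampus_size = 2)
edges <- plant_signal_edges(atlas, n_edges = 20, beta = 0.35,
                            networks = "SigNet", seed = seed)

cfg <- simulation_config(
  n_subjects = 120, network_sizes = sizes, hippocampus_size = 2,
  n_runs = 2, run_length = 150, sampling_interval = 1.97,
  signal_edges = edges, seed = seed
)
cohort <- simulate_cohort(cfg)
manifest <- write_cohort(cohort, out_dir)

# keep the planted-edge list so stage 5/6 can score recovery
write.table(edges, file.path(out_dir, "planted_edges.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

cat("Simulated", cfg$n_subjects, "subjects x", cfg$n_runs, "runs over",
    nrow(atlas), "ROIs\n")
cat("Planted", nrow(edges), "signal edges inside 'SigNet'\n")
cat("Manifest written to", manifest, "\n")
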