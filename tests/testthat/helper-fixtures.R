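# Shared fixtures, memoized so expensive cohorts and permutation runs are
# built once per test session.

.fixture_env <- new.env(parent = emptyenv())

memoize <- function(key, builder) {
  if (is.null(.fixture_env[[key]])) .fixture_env[[key]] <- builder()
  .fixture_env[[key]]
}

# 64-ROI atlas whose "SigNet" network hosts every planted signal edge.
planted_atlas_sizes <- function() {
  c(SigNet = 12L, NetB = 9L, NetC = 9L, DefaultC = 8L, DefaultA = 8L,
    NetD = 8L, NetE = 8L)
}

# Planted cohort at the study scale: n = 243 subjects, 64 ROIs (2016 edges),
# 50 signal edges at beta = 0.3 (Fisher-z per SD of behavior), all inside
# SigNet; nuisance covariates (age, sex, fd) load on behavior and edges.
planted_cohort <- function() {
  memoize("planted_cohort", function() {
    atlas <- make_atlas(planted_atlas_sizes(), hippocampus_size = 2)
    edges <- plant_signal_edges(atlas, n_edges = 50, beta = 0.3,
                                networks = "SigNet", seed = 1)
    cfg <- simulation_config(n_subjects = 243,
                             network_sizes = planted_atlas_sizes(),
                             hippocampus_size = 2,
                             signal_edges = edges, seed = 1)
    coh <- simulate_cohort(cfg)
    X <- cohort_edge_matrix(coh$connectomes)
    list(cohort = coh, X = X, edges = edges,
         covariates = coh$subjects[, c("age", "sex", "fd")],
         y = coh$subjects$mem_narr, atlas = coh$atlas)
  })
}

# Full CBPM permutation run on the planted cohort (100 permutations),
# shared between the signal-recovery and lesion checks.
planted_permutation <- function() {
  memoize("planted_permutation", function() {
    fx <- planted_cohort()
    cbpm_permutation_test(fx$X, fx$y, fx$covariates,
                          cbpm_config(selection_alpha = 0.01,
                                      n_permutations = 100, seed = 1))
  })
}

# Small written cohort (manifest on disk) shared by the io and end-to-end
# determinism tests.
demo_manifest <- function() {
  memoize("demo_manifest", function() {
    cfg <- simulation_config(n_subjects = 10,
                             network_sizes = c(NetA = 5, DefaultC = 4, DefaultA = 4, NetB = 5),
                             hippocampus_size = 2, n_runs = 2, run_length = 80,
                             seed = 17)
    coh <- simulate_cohort(cfg)
    dir <- file.path(tempdir(), "genconn-demo-cohort")
    write_cohort(coh, dir)
  })
}

# Small null cohort generator for calibration experiments: no planted
# signal, nuisance covariates correlated with both edges and behavior.
null_cohort <- function(seed, n_subjects = 60) {
  cfg <- simulation_config(n_subjects = n_subjects,
                           network_sizes = c(NetA = 11L, DefaultC = 8L, DefaultA = 8L),
                           hippocampus_size = 6, seed = seed)
  simulate_cohort(cfg)
}
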