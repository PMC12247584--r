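#!/usr/bin/env Rscript
# Stage 3: network-level connectivity summaries.
#
# For every generalized connectome, the four study summaries on the Pearson
# scale: within (DMN-C internal), between (DMN-C to DMN-A), extra (DMN-C to
# the rest of cortex), and hipp (all hippocampal connections).

library(genconn)

atlas <- read_atlas("results/cohort/atlas.tsv")
paths <- list.files("results/connectomes", pattern = "_connectome\\.tsv$",
                    full.names = TRUE)
connectomes <- lapply(paths, read_connectome)
names(connectomes) <- sub("_connectome\\.tsv$", "", basename(paths))

summaries <- summarize_cohort(connectomes, atlas)
write.csv(summaries, "results/summaries.csv", row.names = FALSE)

cat("Summaries for", nrow(summaries), "subjects (cohort means):\n")
print(round(colMeans(summaries[, -1]), 4))
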