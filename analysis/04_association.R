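#!/usr/bin/env Rscript
# Stage 4: covariate-adjusted brain-behavior models.
#
# Standardized-beta OLS of narrative recall (and the composite memory score)
# on each network summary, unadjusted and with the two covariate sets:
# {age, sex, mean FD} and additionally {fluid intelligence, cognitive screen}.

library(genconn)

subjects <- build_scores(read.csv("results/cohort/subjects.csv"))
summaries <- read.csv("results/summaries.csv")

models <- run_association_models(subjects, summaries)
write.csv(models, "results/models.csv", row.names = FALSE)

cat("Fit", nrow(models), "models; narrative-recall rows:\n")
narr <- models[models$y == "mem_narr", c("x", "covariate_set", "beta", "se", "t", "df", "p")]
narr[, 3:7] <- round(narr[, 3:7], 3)
print(narr, row.names = FALSE)
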