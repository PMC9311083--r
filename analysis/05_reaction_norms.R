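#!/usr/bin/env Rscript
# Per-sex mean-standardised reaction-norm slopes against temperature for the
# synthetic dataset, for the female-vs-male slope scatter. Run
# 03_synthetic_dataset.R first.

suppressPackageStartupMessages({
  library(sexplast)
  library(tidyr)
  library(dplyr)
})

groups <- read_dataset("results/synthetic_groups.csv")$groups
out <- norm_slopes(groups)
write.csv(out$slopes, "results/reaction_norm_slopes.csv", row.names = FALSE)

wide <- out$slopes |>
  select(study_id, experiment_id, sex, slope) |>
  pivot_wider(names_from = sex, values_from = slope)
cat("slopes estimated for", nrow(wide), "experiments;",
    nrow(out$exclusions), "exclusions.\n")
cat(sprintf("female-male slope correlation: %.3f\n", cor(wide$F, wide$M)))
cat(sprintf("mean |slope|: females %.4f, males %.4f per degree C\n",
            mean(abs(wide$F)), mean(abs(wide$M))))
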