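#!/usr/bin/env Rscript
# How does sexual dimorphism in plasticity (b_SD = b_f - b_m) affect
# steady-state population growth under directional environmental change?
# Sweeps the three reference parameterisations (symmetric "black", female-
# favoured "orange", male-favoured "blue") under both demographic modes and
# tabulates each curve's optimum.

suppressPackageStartupMessages({
  library(sexplast)
  library(dplyr)
})

dir.create("results", showWarnings = FALSE)
eta <- 0.05
grid <- seq(-1.5, 1.5, length.out = 301)
curves <- list(black = figure1_params("black"),
               orange = figure1_params("orange"),
               blue = figure1_params("blue"))

tabs <- lapply(c("female_dominance", "codominance"), function(demog) {
  sweep_figure1(curves, grid, eta, demog) |> mutate(demography = demog)
})
curves_tab <- bind_rows(tabs)
write.csv(curves_tab, "results/figure1_curves.csv", row.names = FALSE)

optima <- bind_rows(lapply(names(curves), function(id) {
  bind_rows(lapply(c("female_dominance", "codominance"), function(demog) {
    tibble::tibble(curve = id, demography = demog,
                   b_sd_hat = optimal_bsd(curves[[id]], eta, demog),
                   b_sd_hat_numeric = optimal_bsd_numeric(curves[[id]], eta, demog),
                   r_eq_at_opt = growth_at_bsd(curves[[id]],
                                               optimal_bsd(curves[[id]], eta, demog),
                                               eta, demog))
  }))
}))
write.csv(optima, "results/figure1_optima.csv", row.names = FALSE)

cat("Optimal sexual dimorphism in plasticity (eta = 0.05, r_mf = 0.5):\n")
print(as.data.frame(optima), digits = 4, row.names = FALSE)
cat("\nUnder female demographic dominance the symmetric curve peaks at",
    "b_SD = 1/3 (female-biased plasticity); under co-dominance it peaks at",
    "exactly 0. Asymmetries in B and V_A shift the optima in the expected",
    "directions (orange right, blue left).\n")
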