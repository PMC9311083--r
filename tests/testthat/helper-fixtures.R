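# Shared fixtures built in code.

# a minimal valid group-summary table: one experiment, both sexes, two levels
toy_groups <- function(trait_class = "longevity",
                       temps = c(18, 25),
                       means = c(F_cold = 10, F_warm = 8, M_cold = 10, M_warm = 8),
                       sds = c(2, 2, 2, 2), ns = c(10L, 10L, 10L, 10L),
                       study = "s1", experiment = "e1", species = "sp one") {
  tibble::tibble(
    study_id = study, experiment_id = experiment, species = species,
    trait_class = trait_class, trait_name = trait_class,
    treatment_type = "rearing",
    treatment_level_id = rep(c("cold", "warm"), 2),
    temperature = rep(temps, 2),
    sex = c("F", "F", "M", "M"),
    mean = unname(means), sd = unname(sds), n = unname(ns)
  )
}

# random valid theory parameter set (stable dynamics, non-singular r_mf)
random_theory_params <- function() {
  theory_params(
    B_f = stats::runif(1, 0.5, 1.5), B_m = stats::runif(1, 0.5, 1.5),
    b_f = stats::runif(1, 0, 1), b_m = stats::runif(1, 0, 1),
    V_A_f = stats::runif(1, 0.2, 0.8), V_A_m = stats::runif(1, 0.2, 0.8),
    r_mf = stats::runif(1, -0.85, 0.85),
    gamma_f = stats::runif(1, 0.5, 1.5), gamma_m = stats::runif(1, 0.5, 1.5),
    gamma_b_f = 0, gamma_b_m = 0,
    r_max = 0.05
  )
}

# independent dense-grid argmax used to check the closed-form optimum
grid_argmax_bsd <- function(params, eta, demography, lo = -3, hi = 3,
                            n = 20001) {
  grid <- seq(lo, hi, length.out = n)
  vals <- vapply(grid, function(s) growth_at_bsd(params, s, eta, demography),
                 numeric(1))
  grid[which.max(vals)]
}
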