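#' Quadratic cost of plasticity
#'
#' Fitness penalty paid by a sex for maintaining a reaction norm of slope
#' `b`: `cost = gamma_b * b^2 / 2`. All growth-rate functions route the cost
#' through this single function so its placement can be adjusted in one
#' place.
#'
#' @param b Reaction-norm slope.
#' @param gamma_b Cost coefficient (>= 0).
#' @return The growth-rate penalty (>= 0).
#' @export
plasticity_cost <- function(b, gamma_b) gamma_b * b^2 / 2

# Steady-state per-sex scaled lags under directional change.
# Solves the two-sex steady state: the mean breeding value of each sex must
# advance by K_s * eta per generation, with the response
#   dz_f = (V_f * g_f L_f + C * g_m L_m) / 2,  C = r * sqrt(V_f V_m),
# giving  g_s L_s = 2 eta (K_s - r c_s K_t) / (V_s (1 - r^2)),
# where c_f = sqrt(V_f/V_m) (and its inverse for males). Returns the
# selection-scaled lags x_s = gamma_s * L_s.
scaled_lags_directional <- function(params, eta) {
  K <- effective_rates(params)
  r <- params$r_mf
  cf <- sqrt(params$V_A_f / params$V_A_m)
  denom <- 1 - r^2
  x_f <- 2 * eta * (K[["K_f"]] - r * cf * K[["K_m"]]) / (params$V_A_f * denom)
  x_m <- 2 * eta * (K[["K_m"]] - r / cf * K[["K_f"]]) / (params$V_A_m * denom)
  c(f = x_f, m = x_m)
}

growth_outcome <- function(params, r_eq, load_f, load_m) {
  K <- effective_rates(params)
  structure(list(
    r_eq = r_eq,
    K_f = K[["K_f"]], K_m = K[["K_m"]],
    alpha = alpha_ratio(params),
    lag_load_f = load_f, lag_load_m = load_m,
    persists = r_eq > 0
  ), class = "growth_outcome")
}

#' @export
print.growth_outcome <- function(x, ...) {
  cat(sprintf("Steady-state intrinsic growth r_eq = %.6g (%s)\n", x$r_eq,
              if (x$persists) "population may persist" else "population declines"))
  cat(sprintf("  K_f = %.4g, K_m = %.4g, alpha = %.4g\n", x$K_f, x$K_m, x$alpha))
  cat(sprintf("  loads: female %.6g, male %.6g\n", x$lag_load_f, x$lag_load_m))
  invisible(x)
}

#' Steady-state growth under directional environmental change
#'
#' Long-run intrinsic growth rate of a two-sex population tracking optima
#' that move linearly in time. Each sex carries a lag load
#' `(gamma_s/2) * L_s^2` from the steady-state lag `L_s` of its trait mean
#' behind its optimum, plus any cost of plasticity. Under female demographic
#' dominance the growth rate is reduced by the full female load; under
#' co-dominance by half of each sex's load. Equivalent closed form (female
#' dominance):
#' `r_eq = r_max - (2/gamma_f) * (eta*K_f/V_A_f)^2 * ((1 - r_mf*alpha)/(1 - r_mf^2))^2`.
#'
#' @param params A [theory_params()] object.
#' @param eta Per-generation rate of directional environmental change.
#' @param demography `"female_dominance"` (growth depends on female
#'   adaptation only) or `"codominance"` (equally on both sexes).
#' @return A `growth_outcome` list: `r_eq`, effective rates `K_f`/`K_m`,
#'   `alpha`, per-sex load terms that sum to `r_max - r_eq`, and a
#'   `persists` flag (`r_eq > 0`).
#' @examples
#' p <- figure1_params("black")
#' growth_directional(p, eta = 0.05, "female_dominance")
#' @export
growth_directional <- function(params, eta,
                               demography = c("female_dominance", "codominance")) {
  stopifnot(inherits(params, "theory_params"))
  demography <- match.arg(demography)
  check_singular(params)
  if (!is.finite(eta)) stop("'eta' must be finite", call. = FALSE)

  x <- scaled_lags_directional(params, eta)
  # lag load of sex s: (gamma_s/2) L_s^2 = x_s^2 / (2 gamma_s)
  load_f <- x[["f"]]^2 / (2 * params$gamma_f)
  load_m <- x[["m"]]^2 / (2 * params$gamma_m)
  cost_f <- plasticity_cost(params$b_f, params$gamma_b_f)
  cost_m <- plasticity_cost(params$b_m, params$gamma_b_m)

  if (demography == "female_dominance") {
    lf <- load_f + cost_f
    lm <- 0
  } else {
    lf <- (load_f + cost_f) / 2
    lm <- (load_m + cost_m) / 2
  }
  growth_outcome(params, params$r_max - lf - lm, lf, lm)
}

#' Mean steady-state growth under cyclic environmental change
#'
#' For cycles slow relative to the pace of evolution the growth/dimorphism
#' relation is the same as under directional change and the computation
#' delegates to [growth_directional()] with the regime's `eta`. For fast
#' cycles evolution cannot track the oscillating optima and the trait means
#' stay put, so each sex's mean load over a cycle is proportional to its
#' effective mistracking: `r_bar_eq = r_max - (gamma_f/4) * A * K_f^2` under
#' female dominance, and
#' `r_max - (gamma_f/8) * A * K_f^2 - (gamma_m/8) * A * K_m^2` under
#' co-dominance. Fast-cycle growth is maximised by perfect per-sex tracking
#' (`b_f = B_f`, `b_m = B_m`).
#'
#' @param params A [theory_params()] object.
#' @param regime An [env_regime()] with mode `"cyclic_slow"` or
#'   `"cyclic_fast"`.
#' @inheritParams growth_directional
#' @return A `growth_outcome` list (see [growth_directional()]).
#' @export
growth_cyclic <- function(params, regime,
                          demography = c("female_dominance", "codominance")) {
  stopifnot(inherits(params, "theory_params"), inherits(regime, "env_regime"))
  demography <- match.arg(demography)
  if (regime$mode == "directional")
    stop("use growth_directional() for the directional regime", call. = FALSE)
  if (regime$mode == "cyclic_slow")
    return(growth_directional(params, regime$eta, demography))

  check_singular(params)
  K <- effective_rates(params)
  A <- regime$A
  cost_f <- plasticity_cost(params$b_f, params$gamma_b_f)
  cost_m <- plasticity_cost(params$b_m, params$gamma_b_m)
  if (demography == "female_dominance") {
    lf <- params$gamma_f / 4 * A * K[["K_f"]]^2 + cost_f
    lm <- 0
  } else {
    lf <- params$gamma_f / 8 * A * K[["K_f"]]^2 + cost_f / 2
    lm <- params$gamma_m / 8 * A * K[["K_m"]]^2 + cost_m / 2
  }
  growth_outcome(params, params$r_max - lf - lm, lf, lm)
}
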