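#' Configuration for the deterministic two-sex forward simulator
#'
#' The simulator iterates the infinite-population mean dynamics of the
#' two-sex model: fixed reaction norms shift each sex's phenotype with the
#' environment, Gaussian stabilising selection pulls the sex-specific trait
#' means toward moving optima, and the between-generation response follows
#' the two-sex breeder's equation with the fixed G-matrix
#' `[[V_A_f, C], [C, V_A_m]]`, `C = r_mf * sqrt(V_A_f * V_A_m)`. It is
#' noise-free by construction and serves as an independent numerical oracle
#' for the closed-form steady states.
#'
#' @param params A [theory_params()] object.
#' @param regime An [env_regime()].
#' @param demography `"female_dominance"` or `"codominance"`.
#' @param generations Number of generations to iterate.
#' @param burn_in Generations discarded before averaging growth (default
#'   40\% of `generations`).
#' @param tol Convergence tolerance on the difference between the mean
#'   growth of the last two averaging windows.
#' @param include_variance_load If `TRUE`, additionally subtract the
#'   standing-variance load `(gamma_s/2) V_A_s` terms from the growth rate.
#'   These terms do not depend on the dimorphism in plasticity and are
#'   absorbed into `r_max` by default (`FALSE`).
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(params, regime,
                       demography = c("female_dominance", "codominance"),
                       generations = 5000L,
                       burn_in = NULL, tol = 1e-6,
                       include_variance_load = FALSE) {
  stopifnot(inherits(params, "theory_params"), inherits(regime, "env_regime"))
  demography <- match.arg(demography)
  generations <- as.integer(generations)
  if (is.null(burn_in)) burn_in <- as.integer(floor(0.4 * generations))
  burn_in <- as.integer(burn_in)
  if (generations <= burn_in || burn_in < 0)
    stop("need generations > burn_in >= 0", call. = FALSE)
  structure(list(params = params, regime = regime, demography = demography,
                 generations = generations, burn_in = burn_in, tol = tol,
                 include_variance_load = include_variance_load),
            class = "sim_config")
}

env_at <- function(regime, t) {
  switch(regime$mode,
    directional = regime$eta * t,
    cyclic_slow = regime$eta * t,
    cyclic_fast = sqrt(regime$A) * sin(2 * pi * t / regime$period)
  )
}

sim_growth_rate <- function(p, lag_f, lag_m, demography, include_variance_load) {
  load_f <- p$gamma_f / 2 * lag_f^2 + plasticity_cost(p$b_f, p$gamma_b_f)
  load_m <- p$gamma_m / 2 * lag_m^2 + plasticity_cost(p$b_m, p$gamma_b_m)
  if (include_variance_load) {
    load_f <- load_f + p$gamma_f / 2 * p$V_A_f
    load_m <- load_m + p$gamma_m / 2 * p$V_A_m
  }
  if (demography == "female_dominance") p$r_max - load_f
  else p$r_max - load_f / 2 - load_m / 2
}

#' Iterate the two-sex mean-trait recursion
#'
#' Runs the deterministic recursion for `config$generations` generations
#' starting from mean breeding values at the time-zero optima. Each
#' generation: the environment `env(t)` sets the sex-specific optima
#' `theta_s = B_s * env` and phenotypes `z_s = zbar_s + b_s * env`; the
#' directional selection gradient on each sex is `gamma_s * (theta_s - z_s)`;
#' the next generation's mean breeding values follow the two-sex breeder's
#' equation (half the G-weighted average of the two gradients).
#'
#' @param config A [sim_config()] object.
#' @param keep_trajectory If `FALSE`, only the per-generation growth rates
#'   are retained (cheaper for steady-state estimation).
#' @return A tibble with columns `generation`, `env`, `zbar_f`, `zbar_m`,
#'   `lag_f`, `lag_m`, `r` (or just `generation`, `r` when
#'   `keep_trajectory = FALSE`).
#' @export
simulate_dynamics <- function(config, keep_trajectory = TRUE) {
  stopifnot(inherits(config, "sim_config"))
  p <- config$params
  G11 <- p$V_A_f
  G22 <- p$V_A_m
  G12 <- p$r_mf * sqrt(G11 * G22)
  n <- config$generations
  z_f <- p$B_f * env_at(config$regime, 0) - p$b_f * env_at(config$regime, 0)
  z_m <- p$B_m * env_at(config$regime, 0) - p$b_m * env_at(config$regime, 0)

  r_vec <- numeric(n)
  if (keep_trajectory) {
    envs <- zf_v <- zm_v <- lf_v <- lm_v <- numeric(n)
  }
  for (t in seq_len(n)) {
    e <- env_at(config$regime, t - 1)
    lag_f <- p$B_f * e - (z_f + p$b_f * e)
    lag_m <- p$B_m * e - (z_m + p$b_m * e)
    if (abs(lag_f) > 1e6 || abs(lag_m) > 1e6)
      stop(sprintf("simulation diverged at generation %d (|lag| > 1e6); ",
                   t), "check that gamma * V_A is not too large", call. = FALSE)
    r_vec[t] <- sim_growth_rate(p, lag_f, lag_m, config$demography,
                                config$include_variance_load)
    if (keep_trajectory) {
      envs[t] <- e; zf_v[t] <- z_f; zm_v[t] <- z_m
      lf_v[t] <- lag_f; lm_v[t] <- lag_m
    }
    beta_f <- p$gamma_f * lag_f
    beta_m <- p$gamma_m * lag_m
    z_f <- z_f + (G11 * beta_f + G12 * beta_m) / 2
    z_m <- z_m + (G12 * beta_f + G22 * beta_m) / 2
  }
  if (keep_trajectory) {
    tibble::tibble(generation = seq_len(n) - 1L, env = envs,
                   zbar_f = zf_v, zbar_m = zm_v,
                   lag_f = lf_v, lag_m = lm_v, r = r_vec)
  } else {
    tibble::tibble(generation = seq_len(n) - 1L, r = r_vec)
  }
}

#' Steady-state growth rate from forward simulation
#'
#' Mean intrinsic growth rate after burn-in. For cyclic regimes the average
#' is taken over the largest whole number of cycles that fits after
#' burn-in, so the estimate is unbiased by partial cycles. Convergence is
#' assessed by comparing the mean growth over the last two windows (each
#' 10\% of the run); a gap above `config$tol` flags non-convergence.
#'
#' @param config A [sim_config()] object. For directional change use at
#'   least a few thousand generations; for cyclic regimes at least ~50 full
#'   cycles.
#' @return A list with `r_eq` (the estimate), `converged`, and
#'   `convergence_gap`.
#' @export
steady_state_growth <- function(config) {
  traj <- simulate_dynamics(config, keep_trajectory = FALSE)
  r <- traj$r
  n <- length(r)
  post <- r[(config$burn_in + 1L):n]
  if (config$regime$mode == "cyclic_fast") {
    per <- config$regime$period
    ncyc <- floor(length(post) / per)
    if (ncyc < 1) stop("fewer than one full cycle after burn-in", call. = FALSE)
    post <- post[seq_len(ncyc * per)]
  }
  w <- max(10L, floor(0.1 * n))
  w <- min(w, floor(length(post) / 2))
  last <- mean(post[(length(post) - w + 1L):length(post)])
  prev <- mean(post[(length(post) - 2L * w + 1L):(length(post) - w)])
  gap <- abs(last - prev)
  list(r_eq = mean(post), converged = gap <= config$tol, convergence_gap = gap)
}
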