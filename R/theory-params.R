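#' Parameter set for the two-sex moving-optimum model
#'
#' Bundles every parameter of the two-sex quantitative-genetic model of
#' population growth under environmental change: how fast each sex's
#' phenotypic optimum moves per unit of environmental change (`B_f`, `B_m`),
#' the fixed sex-specific reaction-norm slopes (`b_f`, `b_m`), sex-specific
#' additive genetic variances and their cross-sex correlation, the strengths
#' of stabilising selection, optional quadratic costs of plasticity, and the
#' maximum intrinsic growth rate attained by a perfectly adapted population.
#'
#' Two derived quantities are used throughout: the average reaction norm
#' `b_bar = (b_f + b_m)/2` and the sexual dimorphism in plasticity
#' `b_sd = b_f - b_m` (positive values mean females are the more plastic sex).
#'
#' @param B_f,B_m Rate of change of the female/male optimum per unit
#'   environmental change (trait units / env unit).
#' @param b_f,b_m Female/male reaction-norm slopes (trait units / env unit).
#'   Plasticity is adaptive yet imperfect when `0 < b_s/B_s < 1`.
#' @param V_A_f,V_A_m Sex-specific additive genetic variances (trait units^2);
#'   must be positive.
#' @param r_mf Cross-sex additive genetic correlation, in `[-1, 1]`. Values
#'   with `|r_mf| = 1` are accepted at construction but rejected by the growth
#'   functions, whose denominators contain `(1 - r_mf^2)`.
#' @param gamma_f,gamma_m Sex-specific strengths of stabilising selection on
#'   the trait mean (1 / trait units^2); must be positive.
#' @param gamma_b_f,gamma_b_m Sex-specific costs of plasticity (>= 0; zero
#'   means plasticity is free).
#' @param r_max Maximum intrinsic growth rate (per generation), i.e. the
#'   growth rate of a population whose trait means sit on their optima.
#'
#' @return An object of class `theory_params` (a named list).
#' @seealso [growth_directional()], [growth_cyclic()], [optimal_bsd()]
#' @examples
#' p <- theory_params(b_f = 0.6, b_m = 0.4)
#' b_sd(p) # 0.2: female-biased plasticity
#' @export
theory_params <- function(B_f = 1, B_m = 1, b_f = 0.5, b_m = 0.5,
                          V_A_f = 0.5, V_A_m = 0.5, r_mf = 0.5,
                          gamma_f = 1, gamma_m = 1,
                          gamma_b_f = 0, gamma_b_m = 0,
                          r_max = 0.05) {
  p <- list(B_f = B_f, B_m = B_m, b_f = b_f, b_m = b_m,
            V_A_f = V_A_f, V_A_m = V_A_m, r_mf = r_mf,
            gamma_f = gamma_f, gamma_m = gamma_m,
            gamma_b_f = gamma_b_f, gamma_b_m = gamma_b_m,
            r_max = r_max)
  for (nm in names(p)) {
    if (!is.numeric(p[[nm]]) || length(p[[nm]]) != 1L || !is.finite(p[[nm]]))
      stop("'", nm, "' must be a single finite number", call. = FALSE)
  }
  if (V_A_f <= 0 || V_A_m <= 0)
    stop("additive genetic variances must be positive", call. = FALSE)
  if (gamma_f <= 0 || gamma_m <= 0)
    stop("strengths of stabilising selection must be positive", call. = FALSE)
  if (abs(r_mf) > 1)
    stop("'r_mf' must lie in [-1, 1]", call. = FALSE)
  if (gamma_b_f < 0 || gamma_b_m < 0)
    stop("costs of plasticity must be non-negative", call. = FALSE)
  structure(p, class = "theory_params")
}

#' @export
print.theory_params <- function(x, ...) {
  cat("Two-sex moving-optimum model parameters\n")
  cat(sprintf("  optima:      B_f = %g, B_m = %g\n", x$B_f, x$B_m))
  cat(sprintf("  plasticity:  b_f = %g, b_m = %g (b_bar = %g, b_sd = %g)\n",
              x$b_f, x$b_m, b_bar(x), b_sd(x)))
  cat(sprintf("  genetics:    V_A_f = %g, V_A_m = %g, r_mf = %g\n",
              x$V_A_f, x$V_A_m, x$r_mf))
  cat(sprintf("  selection:   gamma_f = %g, gamma_m = %g; costs %g / %g\n",
              x$gamma_f, x$gamma_m, x$gamma_b_f, x$gamma_b_m))
  cat(sprintf("  r_max = %g\n", x$r_max))
  invisible(x)
}

#' Average reaction norm and sexual dimorphism in plasticity
#'
#' `b_bar()` returns the sex-averaged reaction-norm slope `(b_f + b_m)/2`;
#' `b_sd()` returns the dimorphism `b_f - b_m`.
#'
#' @param params A [theory_params()] object.
#' @return A single number.
#' @export
b_bar <- function(params) (params$b_f + params$b_m) / 2

#' @rdname b_bar
#' @export
b_sd <- function(params) params$b_f - params$b_m

#' Effective rates of change of the sex-specific optima
#'
#' The effective rate of change of each sex's optimum is the rate of change
#' of the optimum in excess of the plastic response: `K_f = B_f - b_f`,
#' `K_m = B_m - b_m`. It is the residual burden that evolution (rather than
#' plasticity) must track.
#'
#' @param params A [theory_params()] object.
#' @return Named numeric vector `c(K_f, K_m)`.
#' @examples
#' effective_rates(theory_params(B_f = 1, b_f = 0.6, B_m = 1, b_m = 0.4))
#' @export
effective_rates <- function(params) {
  stopifnot(inherits(params, "theory_params"))
  c(K_f = params$B_f - params$b_f, K_m = params$B_m - params$b_m)
}

#' Variance-weighted ratio of effective male vs. female optimum change
#'
#' `alpha = K_m * sqrt(V_A_f) / (K_f * sqrt(V_A_m))` quantifies the relative
#' contribution of selection on males versus females to the population's
#' evolutionary response. Undefined (`NaN`/`Inf`) when `K_f = 0`; the growth
#' functions avoid the ratio internally and remain well defined there.
#'
#' @param params A [theory_params()] object.
#' @return A single number (possibly non-finite when `K_f = 0`).
#' @export
alpha_ratio <- function(params) {
  K <- effective_rates(params)
  (K[["K_m"]] * sqrt(params$V_A_f)) / (K[["K_f"]] * sqrt(params$V_A_m))
}

#' Environmental change regime
#'
#' @param mode `"directional"` (linear trend), `"cyclic_slow"` (cycles slow
#'   relative to evolution, which behave like directional change), or
#'   `"cyclic_fast"` (cycles fast relative to evolution).
#' @param eta Per-generation rate of directional environmental change
#'   (env units / generation); used by `directional` and `cyclic_slow`.
#' @param A Amplitude term of the environmental cycle as it enters the
#'   fast-cycle load (the squared amplitude of the sinusoidal environment:
#'   the simulator realises `env(t) = sqrt(A) * sin(2*pi*t/period)`).
#' @param period Generations per cycle; only used to realise cycles in the
#'   simulator. Must be `>= 2` for cyclic modes.
#' @return An object of class `env_regime`.
#' @export
env_regime <- function(mode = c("directional", "cyclic_slow", "cyclic_fast"),
                       eta = 0, A = 0, period = NULL) {
  mode <- match.arg(mode)
  if (!is.finite(eta)) stop("'eta' must be finite", call. = FALSE)
  if (A < 0) stop("'A' must be non-negative", call. = FALSE)
  if (mode %in% c("cyclic_slow", "cyclic_fast")) {
    if (is.null(period)) period <- 20
    if (period < 2) stop("'period' must be >= 2 for cyclic regimes", call. = FALSE)
  }
  structure(list(mode = mode, eta = eta, A = A, period = period),
            class = "env_regime")
}

# shared guards for the (1 - r_mf^2) denominators
check_singular <- function(params) {
  if (abs(params$r_mf) >= 1)
    stop("|r_mf| = 1 is a singularity of the model (denominators contain 1 - r_mf^2)",
         call. = FALSE)
  invisible(params)
}
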