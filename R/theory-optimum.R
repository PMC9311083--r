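#' Evaluate steady-state growth as a function of dimorphism in plasticity
#'
#' Replaces the reaction norms in `params` by `b_f = b_bar + b_sd/2`,
#' `b_m = b_bar - b_sd/2` (holding the sex-averaged plasticity `b_bar`
#' fixed) and evaluates [growth_directional()].
#'
#' @param params A [theory_params()] object (its `b_f`, `b_m` supply `b_bar`).
#' @param b_sd Sexual dimorphism in plasticity to impose.
#' @inheritParams growth_directional
#' @return The steady-state growth rate `r_eq` (a number).
#' @export
growth_at_bsd <- function(params, b_sd, eta,
                          demography = c("female_dominance", "codominance")) {
  demography <- match.arg(demography)
  bb <- b_bar(params)
  p <- params
  p$b_f <- bb + b_sd / 2
  p$b_m <- bb - b_sd / 2
  growth_directional(p, eta, demography)$r_eq
}

#' Optimal sexual dimorphism in plasticity (closed form)
#'
#' The value of `b_sd = b_f - b_m` that maximises steady-state growth under
#' directional environmental change, holding the average plasticity `b_bar`
#' fixed. Because the steady-state growth rate is an exact quadratic in
#' `b_sd`, the maximiser has a closed form; it must (and in the tests does)
#' agree with direct numerical maximisation of the growth curve.
#'
#' Under female dominance, with `Q = eta / (V_A_f (1 - r_mf^2))`,
#' `c = sqrt(V_A_f / V_A_m)` and `P = 2 Q^2 (1 + r_mf c) / gamma_f`:
#' \deqn{\hat b_{SD} = \frac{P[(B_f - \bar b) - r c (B_m - \bar b)] -
#'   \gamma_{b,f} \bar b / 2}{P (1 + r c)/2 + \gamma_{b,f}/4}.}
#' With no cost, equal optima and equal variances this simplifies to
#' `2 (B_f - b_bar) (1 - r_mf) / (1 + r_mf)`, which is strictly positive
#' (female-biased plasticity pays) whenever plasticity is adaptive yet
#' imperfect and `0 < r_mf < 1`. Under co-dominance the symmetric analogue
#' applies; the co-dominant form assumes equal costs in the two sexes
#' (`gamma_b_f == gamma_b_m`) and in the fully symmetric cost-free case
#' gives exactly 0.
#'
#' @inheritParams growth_at_bsd
#' @return The maximising `b_sd` (a number).
#' @examples
#' optimal_bsd(figure1_params("black"), eta = 0.05, "female_dominance") # 1/3
#' @export
optimal_bsd <- function(params, eta,
                        demography = c("female_dominance", "codominance")) {
  stopifnot(inherits(params, "theory_params"))
  demography <- match.arg(demography)
  check_singular(params)
  r <- params$r_mf
  cf <- sqrt(params$V_A_f / params$V_A_m)
  bb <- b_bar(params)
  d_f <- params$B_f - bb
  d_m <- params$B_m - bb
  Qf <- eta / (params$V_A_f * (1 - r^2))
  Qm <- eta / (params$V_A_m * (1 - r^2))

  if (demography == "female_dominance") {
    P <- 2 * Qf^2 * (1 + r * cf) / params$gamma_f
    num <- P * (d_f - r * cf * d_m) - params$gamma_b_f * bb / 2
    den <- P * (1 + r * cf) / 2 + params$gamma_b_f / 4
  } else {
    if (params$gamma_b_f != params$gamma_b_m)
      stop("the co-dominance closed form assumes equal plasticity costs in the sexes ",
           "(gamma_b_f == gamma_b_m); use optimal_bsd_numeric() otherwise",
           call. = FALSE)
    gb <- params$gamma_b_f
    tf <- Qf^2 * (1 + r * cf) / params$gamma_f
    tm <- Qm^2 * (1 + r / cf) / params$gamma_m
    num <- 2 * tf * (d_f - r * cf * d_m) - 2 * tm * (d_m - r / cf * d_f)
    den <- tf * (1 + r * cf) + tm * (1 + r / cf) + gb / 2
  }
  if (den == 0)
    stop("degenerate optimum: the growth rate does not depend on b_sd ",
         "(eta and the plasticity costs are all zero)", call. = FALSE)
  num / den
}

#' Optimal dimorphism by golden-section search
#'
#' Deterministic golden-section maximisation of [growth_at_bsd()] over a
#' bracket of `+/- 10` in units of the mean optimum rate
#' `B_bar = (B_f + B_m)/2` (or `+/- 10` when `B_bar = 0`). Serves as the
#' independent numerical check of the [optimal_bsd()] closed form.
#'
#' @inheritParams growth_at_bsd
#' @param tol Absolute tolerance on the bracket width (default `1e-8`).
#' @return The maximising `b_sd` (a number).
#' @export
optimal_bsd_numeric <- function(params, eta,
                                demography = c("female_dominance", "codominance"),
                                tol = 1e-8) {
  demography <- match.arg(demography)
  scale <- max(abs((params$B_f + params$B_m) / 2), 1)
  lo <- -10 * scale
  hi <- 10 * scale
  f <- function(s) growth_at_bsd(params, s, eta, demography)
  gr <- (sqrt(5) - 1) / 2
  x1 <- hi - gr * (hi - lo)
  x2 <- lo + gr * (hi - lo)
  f1 <- f(x1)
  f2 <- f(x2)
  while (hi - lo > tol) {
    if (f1 >= f2) {
      hi <- x2; x2 <- x1; f2 <- f1
      x1 <- hi - gr * (hi - lo); f1 <- f(x1)
    } else {
      lo <- x1; x1 <- x2; f1 <- f2
      x2 <- lo + gr * (hi - lo); f2 <- f(x2)
    }
  }
  (lo + hi) / 2
}

#' Reference parameterisations of the theory's illustrative growth curves
#'
#' Three curve settings sharing `eta = 0.05`, `b_bar = 0.5`, `r_max = 0.05`,
#' mean additive variance `0.5`, mean optimum rate `1`, equal stabilising
#' selection in the sexes and no cost of plasticity. `"black"` is fully
#' symmetric (`B_f = B_m = 1`, `V_A_f = V_A_m = 0.5`); `"orange"` has a
#' faster-moving female optimum and more male genetic variance
#' (`B_f - B_m = 0.2`, `V_A_f - V_A_m = -0.1`); `"blue"` is the mirror image
#' (`B_f - B_m = -0.2`, `V_A_f - V_A_m = 0.1`). The strength of stabilising
#' selection is not pinned down by these settings and defaults to
#' `gamma_f = gamma_m = 1` (it cancels from the cost-free optima).
#'
#' @param curve `"black"`, `"orange"` or `"blue"`.
#' @param r_mf Cross-sex genetic correlation (default 0.5).
#' @param gamma Common strength of stabilising selection (default 1).
#' @return A [theory_params()] object.
#' @export
figure1_params <- function(curve = c("black", "orange", "blue"),
                           r_mf = 0.5, gamma = 1) {
  curve <- match.arg(curve)
  dB <- switch(curve, black = 0, orange = 0.2, blue = -0.2)
  dV <- switch(curve, black = 0, orange = -0.1, blue = 0.1)
  theory_params(
    B_f = 1 + dB / 2, B_m = 1 - dB / 2,
    b_f = 0.5, b_m = 0.5,
    V_A_f = 0.5 + dV / 2, V_A_m = 0.5 - dV / 2,
    r_mf = r_mf, gamma_f = gamma, gamma_m = gamma,
    gamma_b_f = 0, gamma_b_m = 0, r_max = 0.05
  )
}

#' Sweep steady-state growth curves over a grid of dimorphism values
#'
#' Evaluates [growth_at_bsd()] for each named parameter set over a grid of
#' `b_sd` values, producing a tidy table suitable for plotting growth
#' against sexual dimorphism in plasticity (the shaded `b_sd > 0` half of
#' the axis is female-biased plasticity).
#'
#' @param param_list Named list of [theory_params()] objects, one per curve.
#' @param b_sd_grid Numeric grid of dimorphism values.
#' @inheritParams growth_at_bsd
#' @return A tibble with columns `curve_id`, `b_sd`, `r_eq`, `persists`,
#'   `female_biased`.
#' @examples
#' sweep_figure1(list(black = figure1_params("black")),
#'               seq(-1, 1, 0.5), eta = 0.05, "female_dominance")
#' @export
sweep_figure1 <- function(param_list, b_sd_grid, eta,
                          demography = c("female_dominance", "codominance")) {
  demography <- match.arg(demography)
  stopifnot(is.list(param_list), length(param_list) > 0)
  if (is.null(names(param_list)) || any(names(param_list) == ""))
    names(param_list) <- paste0("curve", seq_along(param_list))
  out <- lapply(names(param_list), function(id) {
    p <- param_list[[id]]
    r <- vapply(b_sd_grid, function(s) growth_at_bsd(p, s, eta, demography),
                numeric(1))
    tibble::tibble(curve_id = id, b_sd = b_sd_grid, r_eq = r,
                   persists = r > 0, female_biased = b_sd_grid > 0)
  })
  dplyr::bind_rows(out)
}
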