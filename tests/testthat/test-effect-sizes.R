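test_that("Hedges' d and its variance match independent hand computation", {
  # identical groups: d = 0 regardless of n
  expect_equal(hedges_d(5, 1, 8, 5, 1, 12)$d, 0)

  # m1 = 10, m2 = 8, sd = 2, n = 10 each: d = (1 - 3/71) * 1
  h <- hedges_d(10, 2, 10, 8, 2, 10)
  J <- 1 - 3 / (4 * 18 - 1)
  expect_equal(h$d, J * (10 - 8) / 2, tolerance = 1e-12)
  expect_equal(h$d, 0.957746478873239, tolerance = 1e-12)
  expect_equal(h$V, 20 / 100 + h$d^2 / 36, tolerance = 1e-12)

  # unequal groups, independent arithmetic
  m1 <- 3.2; s1 <- 1.1; n1 <- 7; m2 <- 2.5; s2 <- 0.9; n2 <- 13
  sp <- sqrt(((n1 - 1) * s1^2 + (n2 - 1) * s2^2) / (n1 + n2 - 2))
  J2 <- 1 - 3 / (4 * (n1 + n2 - 2) - 1)
  h2 <- hedges_d(m1, s1, n1, m2, s2, n2)
  expect_equal(h2$d, J2 * (m1 - m2) / sp, tolerance = 1e-12)
  expect_equal(h2$V, (n1 + n2) / (n1 * n2) + h2$d^2 / (2 * (n1 + n2 - 2)),
               tolerance = 1e-12)
})

test_that("Hedges' d point estimate agrees with metafor's SMD", {
  skip_if_not_installed("metafor")
  es <- metafor::escalc(measure = "SMD", m1i = 10, sd1i = 2, n1i = 10,
                        m2i = 8, sd2i = 2, n2i = 10)
  # metafor applies the exact Gamma-function small-sample correction; we use
  # the standard 1 - 3/(4m - 1) approximation. The uncorrected standardised
  # differences must agree exactly, the corrections to their O(m^-2) gap.
  m <- 18
  J_approx <- 1 - 3 / (4 * m - 1)
  J_exact <- exp(lgamma(m / 2) - log(sqrt(m / 2)) - lgamma((m - 1) / 2))
  d_mine <- hedges_d(10, 2, 10, 8, 2, 10)$d
  expect_equal(d_mine / J_approx, as.numeric(es$yi) / J_exact,
               tolerance = 1e-12)
  expect_equal(d_mine, as.numeric(es$yi), tolerance = 5e-4)
})

test_that("lnCVR matches the bias-corrected formula and metafor's CVR", {
  # equal CVs and equal n: exactly zero
  expect_equal(lncvr(10, 2, 20, 5, 1, 20)$lncvr, 0)

  # CV ratio 2 with equal n: corrections cancel, lnCVR = ln 2
  lv <- lncvr(10, 2, 20, 10, 1, 20)
  expect_equal(lv$lncvr, log(2), tolerance = 1e-12)
  expect_equal(lv$V, 4 / 2000 + 1 / 38 + 1 / 2000 + 1 / 38, tolerance = 1e-12)

  # unequal n: correction terms persist
  lv2 <- lncvr(12, 3, 8, 9, 2, 15)
  expect_equal(lv2$lncvr,
               log((3 / 12) / (2 / 9)) + 1 / (2 * 7) - 1 / (2 * 14),
               tolerance = 1e-12)

  skip_if_not_installed("metafor")
  es <- metafor::escalc(measure = "CVR", m1i = 12, sd1i = 3, n1i = 8,
                        m2i = 9, sd2i = 2, n2i = 15)
  expect_equal(lv2$lncvr, as.numeric(es$yi), tolerance = 1e-12)
  expect_equal(lv2$V, as.numeric(es$vi), tolerance = 1e-12)
})

test_that("swapping operand order negates d and lnCVR", {
  a <- hedges_d(10, 2, 9, 8.5, 1.5, 14)
  b <- hedges_d(8.5, 1.5, 14, 10, 2, 9)
  expect_equal(a$d, -b$d, tolerance = 1e-12)
  expect_equal(a$V, b$V, tolerance = 1e-12) # V depends on d only through d^2
  la <- lncvr(10, 2, 9, 8.5, 1.5, 14)
  lb <- lncvr(8.5, 1.5, 14, 10, 2, 9)
  expect_equal(la$lncvr, -lb$lncvr, tolerance = 1e-12)
})

test_that("d is invariant to rescaling the trait", {
  c0 <- 37.4
  a <- hedges_d(10, 2, 9, 8.5, 1.5, 14)
  b <- hedges_d(10 * c0, 2 * c0, 9, 8.5 * c0, 1.5 * c0, 14)
  expect_equal(a$d, b$d, tolerance = 1e-12)
})

test_that("direction conventions order operands by trait class", {
  # cold-minus-warm classes: the colder treatment is the minuend
  expect_identical(direction_convention("development_time", 18, 25), "a")
  expect_identical(direction_convention("development_time", 25, 18), "b")
  # warm-minus-cold classes: the warmer treatment is the minuend
  expect_identical(direction_convention("heat_resistance", 18, 25), "b")
  expect_identical(direction_convention("cold_resistance", 25, 18), "a")
  # unorderable without temperatures or override
  expect_identical(direction_convention("size", 20, 20), NA_character_)
  expect_identical(direction_convention("size", NA, NA), NA_character_)
  # duration-manipulation override
  expect_identical(direction_convention("size", NA, NA, "a_colder"), "a")
  expect_identical(direction_convention("gene_expression", NA, NA, "a_colder"), "b")
  expect_error(direction_convention("not_a_class", 18, 25), "unknown trait class")
})

test_that("longevity measured cold vs warm with longer life when cold gives d > 0", {
  g <- toy_groups(trait_class = "longevity",
                  means = c(10, 8, 10, 8)) # longer lifespan at 18 than 25
  eff <- compute_effects(g, kinds = "hedges_d")$effects
  expect_true(all(eff$value > 0))
  expect_equal(sort(eff$sex), c("F", "M"))
})

test_that("pairwise contrast enumeration gives C(L,2) effects per sex", {
  make_levels <- function(L) {
    tibble::tibble(
      study_id = "s", experiment_id = "e", species = "sp",
      trait_class = "size", trait_name = "mass", treatment_type = "rearing",
      treatment_level_id = rep(paste0("L", 1:L), each = 2),
      temperature = rep(seq(15, by = 3, length.out = L), each = 2),
      sex = rep(c("F", "M"), L),
      mean = stats::rnorm(2 * L, 10), sd = 1, n = 10L)
  }
  set.seed(9)
  for (L in 2:4) {
    eff <- compute_effects(make_levels(L), kinds = "hedges_d")$effects
    expect_equal(nrow(eff), 2 * choose(L, 2))
  }
})

test_that("exclusion rules are reason-coded and accounting balances", {
  set.seed(10)
  g <- tibble::tibble(
    study_id = "s", experiment_id = "e", species = "sp",
    trait_class = "survival", trait_name = "surv", treatment_type = "acute",
    treatment_level_id = rep(paste0("L", 1:3), each = 2),
    temperature = rep(c(15, 20, 25), each = 2),
    sex = rep(c("F", "M"), 3),
    mean = c(5, 5, 6, 6, 7, 7),
    sd = c(1, 1, 1, 0, 1, 1),          # male sd zero at L2
    n = c(10L, 2L, 10L, 10L, 10L, 2L)) # tiny male n at L1 and L3
  res <- compute_effects(g, kinds = "hedges_d")
  # females: all 3 contrasts; males: L1-L2 and L2-L3 hit the zero sd,
  # L1-L3 has pooled n = 4 < 5
  expect_equal(nrow(res$effects[res$effects$sex == "F", ]), 3)
  expect_equal(nrow(res$effects[res$effects$sex == "M", ]), 0)
  expect_setequal(res$exclusions$reason[res$exclusions$sex == "M"],
                  c("zero_sd", "pooled_n_lt_5"))
  # candidate contrasts = effects + exclusions
  expect_equal(nrow(res$effects) + nrow(res$exclusions), 2 * choose(3, 2))
})

test_that("zero means are excluded from lnCVR but not from d", {
  g <- toy_groups(means = c(0, 8, 10, 8))
  res <- compute_effects(g)
  expect_equal(nrow(res$effects[res$effects$kind == "hedges_d", ]), 2)
  lcv <- res$exclusions[res$exclusions$reason == "zero_mean", ]
  expect_setequal(unique(lcv$kind), c("lncvr_treatment", "lncvr_sex"))
})

test_that("sex-axis lnCVR uses the male CV as numerator", {
  g <- toy_groups(sds = c(1, 1, 2, 2)) # males twice as variable
  res <- compute_effects(g, kinds = "lncvr_sex")
  expect_equal(nrow(res$effects), 2) # one per level
  expect_true(all(res$effects$value > 0))
  expect_equal(res$effects$value[1], log(2), tolerance = 1e-12) # equal n, means
})

test_that("computed d is unbiased on synthetic data with known true effect", {
  # all hierarchy variances zero and a common true d: the mean computed d
  # over many contrasts converges on the truth
  cfg <- synth_config(seed = 99, n_species = 50, studies_per_species = 2,
                      experiments_per_study = 15, levels_per_experiment = 2,
                      d_female = 1, d_sex_male = 0,
                      sigma2_species = 0, sigma2_phylo = 0, sigma2_study = 0,
                      sigma2_experiment = 0, sigma2_resid_f = 0,
                      sigma2_resid_m = 0, n_range = c(100L, 100L))
  g <- synth_generate(cfg)
  eff <- compute_effects(g$groups, kinds = "hedges_d")$effects
  expect_gte(nrow(eff), 3000)
  expect_lt(abs(mean(eff$value) - 1), 0.02)
})

test_that("funnel censoring drops only small standardised effects", {
  eff <- tibble::tibble(study_id = "s", experiment_id = as.character(1:100),
                        value = seq(0.01, 2, length.out = 100), V = 0.04)
  kept <- censor_funnel(eff, threshold = 1.5, prob = 1)
  expect_true(all(abs(kept$value) / sqrt(kept$V) >= 1.5))
  set.seed(1)
  kept2 <- censor_funnel(eff, threshold = 1.5, prob = 0.5)
  expect_gt(nrow(kept2), nrow(kept))
})
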