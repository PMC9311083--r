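# trait classes whose d is computed colder-minus-warmer (positive d = larger
# trait value in the cold: slower development, longer life, larger size,
# longer survival) vs. warmer-minus-colder (resistance/expression traits,
# positive d = larger value in the warm).
COLD_MINUS_WARM <- c("development_time", "longevity", "size", "survival")
WARM_MINUS_COLD <- c("cold_resistance", "heat_resistance", "gene_expression")

#' Trait classes recognised by the pipeline
#' @return Character vector of the seven trait classes.
#' @export
trait_classes <- function() c(COLD_MINUS_WARM, WARM_MINUS_COLD)

#' Hedges' d for two group summaries
#'
#' Bias-corrected standardised mean difference `d = J * (m1 - m2) / s_pool`,
#' with the pooled standard deviation on `n1 + n2 - 2` degrees of freedom
#' and small-sample correction `J = 1 - 3 / (4*(n1 + n2 - 2) - 1)`. The
#' sampling variance is the large-sample form
#' `V = (n1 + n2)/(n1*n2) + d^2 / (2*(n1 + n2 - 2))`. Group 1 is the
#' minuend; use [direction_convention()] to order groups by trait class.
#'
#' @param m1,sd1,n1 Mean, standard deviation and sample size of group 1.
#' @param m2,sd2,n2 Mean, standard deviation and sample size of group 2.
#' @return List with `d` and `V`.
#' @examples
#' hedges_d(10, 2, 10, 8, 2, 10) # d = (1 - 3/71) * 1
#' @export
hedges_d <- function(m1, sd1, n1, m2, sd2, n2) {
  if (sd1 <= 0 || sd2 <= 0)
    stop("Hedges' d requires positive standard deviations in both groups",
         call. = FALSE)
  if (n1 + n2 < 5)
    stop("pooled sample size below 5", call. = FALSE)
  df <- n1 + n2 - 2
  s_pool <- sqrt(((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / df)
  J <- 1 - 3 / (4 * df - 1)
  d <- J * (m1 - m2) / s_pool
  V <- (n1 + n2) / (n1 * n2) + d^2 / (2 * df)
  list(d = d, V = V)
}

#' Log coefficient-of-variation ratio for two group summaries
#'
#' `lnCVR = ln(CV1/CV2)` with the small-sample bias correction
#' `+ 1/(2*(n1-1)) - 1/(2*(n2-1))`, and sampling variance
#' `V = sd1^2/(n1*m1^2) + 1/(2*(n1-1)) + sd2^2/(n2*m2^2) + 1/(2*(n2-1))`.
#' Group 1 is the numerator.
#'
#' @inheritParams hedges_d
#' @return List with `lncvr` and `V`.
#' @export
lncvr <- function(m1, sd1, n1, m2, sd2, n2) {
  if (m1 == 0 || m2 == 0)
    stop("lnCVR is undefined when a group mean is zero", call. = FALSE)
  if (sd1 <= 0 || sd2 <= 0)
    stop("lnCVR requires positive standard deviations", call. = FALSE)
  if (n1 + n2 < 5)
    stop("pooled sample size below 5", call. = FALSE)
  y <- log((sd1 / abs(m1)) / (sd2 / abs(m2))) +
    1 / (2 * (n1 - 1)) - 1 / (2 * (n2 - 1))
  V <- sd1^2 / (n1 * m1^2) + 1 / (2 * (n1 - 1)) +
    sd2^2 / (n2 * m2^2) + 1 / (2 * (n2 - 1))
  list(lncvr = y, V = V)
}

#' Order a pair of treatment levels by the trait-class direction convention
#'
#' Decides which of two treatment levels is the minuend (numerator) of a
#' contrast. For `development_time`, `longevity`, `size` and `survival` the
#' colder treatment is the minuend (positive d = larger trait value when
#' cold); for `cold_resistance`, `heat_resistance` and `gene_expression` the
#' warmer treatment is (positive d = larger value when warm). Levels are
#' ordered by their temperatures; when temperatures are missing or equal
#' (e.g. designs manipulating exposure duration at one temperature), an
#' explicit `direction_override` — `"a_colder"` or `"b_colder"` — must say
#' which level counts as colder, otherwise the pair is unorderable.
#'
#' @param trait_class One of [trait_classes()].
#' @param temp_a,temp_b Temperatures (degrees C) of levels a and b; may be `NA`.
#' @param direction_override Optional `"a_colder"` or `"b_colder"`.
#' @return `"a"` or `"b"` naming the minuend level, or `NA_character_` if
#'   the pair is unorderable.
#' @export
direction_convention <- function(trait_class, temp_a, temp_b,
                                 direction_override = NA_character_) {
  if (!trait_class %in% trait_classes())
    stop("unknown trait class: ", trait_class, call. = FALSE)
  colder <- if (!is.na(temp_a) && !is.na(temp_b) && temp_a != temp_b) {
    if (temp_a < temp_b) "a" else "b"
  } else if (!is.na(direction_override) &&
             direction_override %in% c("a_colder", "b_colder")) {
    if (direction_override == "a_colder") "a" else "b"
  } else {
    return(NA_character_)
  }
  warmer <- if (colder == "a") "b" else "a"
  if (trait_class %in% COLD_MINUS_WARM) colder else warmer
}

required_group_cols <- function() {
  c("study_id", "experiment_id", "species", "trait_class", "trait_name",
    "treatment_type", "treatment_level_id", "temperature", "sex",
    "mean", "sd", "n")
}

check_groups <- function(groups) {
  miss <- setdiff(required_group_cols(), names(groups))
  if (length(miss))
    stop("missing required columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (!"direction_override" %in% names(groups))
    groups$direction_override <- NA_character_
  groups
}

# one exclusion record
excl_row <- function(study, exp, species, trait_class, kind, sex, la, lb, reason) {
  tibble::tibble(study_id = study, experiment_id = exp, species = species,
                 trait_class = trait_class, kind = kind, sex = sex,
                 level_1 = la, level_2 = lb, reason = reason)
}

#' Compute all pairwise effect sizes for a dataset of group summaries
#'
#' Enumerates, within each experiment, every unordered pair of treatment
#' levels and computes per-sex Hedges' d and lnCVR (treatment axis), plus the
#' male-vs-female lnCVR at each level (sex axis; male CV in the numerator,
#' so positive values mean males are more variable). Contrast operands are
#' ordered by [direction_convention()]. Contrasts failing the exclusion
#' rules — zero standard deviation, pooled sample size below 5, zero mean
#' (lnCVR only), or an unorderable level pair — are reported in a reason-coded
#' exclusions table, so that candidate contrasts = effects + exclusions
#' exactly.
#'
#' @param groups A group-summary table (see [read_dataset()] for the schema).
#' @param kinds Which effect kinds to compute; any of `"hedges_d"`,
#'   `"lncvr_treatment"`, `"lncvr_sex"`.
#' @return A list with `effects` (tibble: kind, grouping keys, sex, levels,
#'   temperatures, value, V, n1, n2) and `exclusions` (tibble with a
#'   `reason` column).
#' @export
compute_effects <- function(groups,
                            kinds = c("hedges_d", "lncvr_treatment", "lncvr_sex")) {
  groups <- check_groups(groups)
  kinds <- match.arg(kinds, several.ok = TRUE)
  effects <- list()
  excl <- list()
  eff_i <- 0L
  exc_i <- 0L

  add_eff <- function(row) { eff_i <<- eff_i + 1L; effects[[eff_i]] <<- row }
  add_exc <- function(row) { exc_i <<- exc_i + 1L; excl[[exc_i]] <<- row }

  for (exp_df in split(groups, interaction(groups$study_id,
                                           groups$experiment_id, drop = TRUE))) {
    study <- exp_df$study_id[1]
    exp_id <- exp_df$experiment_id[1]
    species <- exp_df$species[1]
    tclass <- exp_df$trait_class[1]
    ttype <- exp_df$treatment_type[1]
    override <- exp_df$direction_override[1]
    levels <- unique(exp_df$treatment_level_id)

    level_row <- function(level, sex) {
      rows <- exp_df[exp_df$treatment_level_id == level & exp_df$sex == sex, ]
      if (nrow(rows) != 1L) NULL else rows
    }

    # treatment-axis contrasts (within sex, across level pairs)
    if (length(levels) >= 2 && any(c("hedges_d", "lncvr_treatment") %in% kinds)) {
      pairs <- utils::combn(levels, 2, simplify = FALSE)
      for (pr in pairs) {
        for (sex in intersect(c("F", "M"), unique(exp_df$sex))) {
          ga <- level_row(pr[1], sex)
          gb <- level_row(pr[2], sex)
          if (is.null(ga) || is.null(gb)) {
            for (k in intersect(kinds, c("hedges_d", "lncvr_treatment")))
              add_exc(excl_row(study, exp_id, species, tclass, k, sex,
                               pr[1], pr[2], "missing_group"))
            next
          }
          minuend <- direction_convention(tclass, ga$temperature, gb$temperature,
                                          override)
          if (is.na(minuend)) {
            for (k in intersect(kinds, c("hedges_d", "lncvr_treatment")))
              add_exc(excl_row(study, exp_id, species, tclass, k, sex,
                               pr[1], pr[2], "unorderable_levels"))
            next
          }
          g1 <- if (minuend == "a") ga else gb
          g2 <- if (minuend == "a") gb else ga
          common <- function(kind, value, V) tibble::tibble(
            kind = kind, study_id = study, experiment_id = exp_id,
            species = species, trait_class = tclass, treatment_type = ttype,
            sex = sex, level_1 = g1$treatment_level_id,
            level_2 = g2$treatment_level_id,
            temp_1 = g1$temperature, temp_2 = g2$temperature,
            value = value, V = V, n1 = g1$n, n2 = g2$n)
          reason <- function(g1, g2, need_mean = FALSE) {
            if (g1$sd <= 0 || g2$sd <= 0) "zero_sd"
            else if (g1$n + g2$n < 5) "pooled_n_lt_5"
            else if (need_mean && (g1$mean == 0 || g2$mean == 0)) "zero_mean"
            else NA_character_
          }
          if ("hedges_d" %in% kinds) {
            rs <- reason(g1, g2)
            if (is.na(rs)) {
              h <- hedges_d(g1$mean, g1$sd, g1$n, g2$mean, g2$sd, g2$n)
              add_eff(common("hedges_d", h$d, h$V))
            } else add_exc(excl_row(study, exp_id, species, tclass, "hedges_d",
                                    sex, pr[1], pr[2], rs))
          }
          if ("lncvr_treatment" %in% kinds) {
            rs <- reason(g1, g2, need_mean = TRUE)
            if (is.na(rs)) {
              lv <- lncvr(g1$mean, g1$sd, g1$n, g2$mean, g2$sd, g2$n)
              add_eff(common("lncvr_treatment", lv$lncvr, lv$V))
            } else add_exc(excl_row(study, exp_id, species, tclass,
                                    "lncvr_treatment", sex, pr[1], pr[2], rs))
          }
        }
      }
    }

    # sex-axis lnCVR at each level (male numerator)
    if ("lncvr_sex" %in% kinds) {
      for (level in levels) {
        gm <- level_row(level, "M")
        gf <- level_row(level, "F")
        if (is.null(gm) || is.null(gf)) {
          add_exc(excl_row(study, exp_id, species, tclass, "lncvr_sex",
                           NA_character_, level, level, "missing_group"))
          next
        }
        rs <- if (gm$sd <= 0 || gf$sd <= 0) "zero_sd"
        else if (gm$n + gf$n < 5) "pooled_n_lt_5"
        else if (gm$mean == 0 || gf$mean == 0) "zero_mean"
        else NA_character_
        if (is.na(rs)) {
          lv <- lncvr(gm$mean, gm$sd, gm$n, gf$mean, gf$sd, gf$n)
          add_eff(tibble::tibble(
            kind = "lncvr_sex", study_id = study, experiment_id = exp_id,
            species = species, trait_class = tclass, treatment_type = ttype,
            sex = NA_character_, level_1 = level, level_2 = level,
            temp_1 = gm$temperature, temp_2 = gf$temperature,
            value = lv$lncvr, V = lv$V, n1 = gm$n, n2 = gf$n))
        } else add_exc(excl_row(study, exp_id, species, tclass, "lncvr_sex",
                                NA_character_, level, level, rs))
      }
    }
  }

  empty_eff <- tibble::tibble(
    kind = character(), study_id = character(), experiment_id = character(),
    species = character(), trait_class = character(), treatment_type = character(),
    sex = character(), level_1 = character(), level_2 = character(),
    temp_1 = numeric(), temp_2 = numeric(), value = numeric(), V = numeric(),
    n1 = integer(), n2 = integer())
  empty_exc <- excl_row(character(), character(), character(), character(),
                        character(), character(), character(), character(),
                        character())
  list(
    effects = if (eff_i) dplyr::bind_rows(effects) else empty_eff,
    exclusions = if (exc_i) dplyr::bind_rows(excl) else empty_exc
  )
}

#' Censor an effects table to mimic publication bias
#'
#' Drops effects whose standardised magnitude `|value| / sqrt(V)` falls
#' below `threshold`, each with probability `prob`. Used to create
#' asymmetric funnels for validating the publication-bias refit.
#'
#' @param effects An effects tibble from [compute_effects()].
#' @param threshold Censoring threshold on `|value|/SE` (default 1.5).
#' @param prob Probability that a sub-threshold effect is dropped.
#' @return The censored effects tibble.
#' @export
censor_funnel <- function(effects, threshold = 1.5, prob = 1) {
  z <- abs(effects$value) / sqrt(effects$V)
  drop <- z < threshold & stats::runif(nrow(effects)) < prob
  effects[!drop, , drop = FALSE]
}
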