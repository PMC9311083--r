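#' Mean-standardised reaction-norm slopes per experiment and sex
#'
#' For every experiment whose treatment levels were exposed to distinct
#' temperatures, divides each sex's level means by that sex's across-level
#' mean (so traits on different scales become comparable) and regresses the
#' standardised means against temperature (degrees C) by ordinary least
#' squares, levels weighted equally. The per-sex slope is the sex's thermal
#' reaction norm; a female-vs-male scatter of these slopes visualises
#' sexual dimorphism in plasticity.
#'
#' Experiments are excluded, with a reason code, when the levels do not
#' carry distinct temperatures for every level (e.g. designs manipulating
#' exposure duration), when fewer than two levels are present, or when a
#' sex's across-level mean is zero (standardisation undefined).
#'
#' @param groups A group-summary table (see [read_dataset()]).
#' @return A list with `slopes` (tibble: study_id, experiment_id, species,
#'   trait_class, treatment_type, sex, slope, n_levels) and `exclusions`
#'   (tibble with reason codes).
#' @examples
#' g <- tibble::tibble(
#'   study_id = "s", experiment_id = "e", species = "sp",
#'   trait_class = "size", trait_name = "mass", treatment_type = "rearing",
#'   treatment_level_id = c("a", "b", "a", "b"),
#'   temperature = c(18, 28, 18, 28), sex = c("F", "F", "M", "M"),
#'   mean = c(12, 8, 12, 8), sd = 1, n = 10L)
#' norm_slopes(g)$slopes$slope # -0.04 per degree C for both sexes
#' @export
norm_slopes <- function(groups) {
  groups <- check_groups(groups)
  slopes <- list()
  excl <- list()
  si <- ei <- 0L
  for (exp_df in split(groups, interaction(groups$study_id,
                                           groups$experiment_id, drop = TRUE))) {
    keys <- exp_df[1, c("study_id", "experiment_id", "species",
                        "trait_class", "treatment_type")]
    add_exc <- function(sex, reason) {
      ei <<- ei + 1L
      excl[[ei]] <<- tibble::tibble(keys, sex = sex, reason = reason)
    }
    lv <- unique(exp_df[, c("treatment_level_id", "temperature")])
    if (nrow(lv) < 2) { add_exc(NA_character_, "lt_2_levels"); next }
    if (any(is.na(lv$temperature)) ||
        length(unique(lv$temperature)) < nrow(lv)) {
      add_exc(NA_character_, "non_temperature_levels"); next
    }
    for (sex in c("F", "M")) {
      sdf <- exp_df[exp_df$sex == sex, ]
      if (nrow(sdf) < 2) { add_exc(sex, "missing_sex"); next }
      grand <- mean(sdf$mean)
      if (grand == 0) { add_exc(sex, "zero_mean"); next }
      std <- sdf$mean / grand
      tt <- sdf$temperature
      slope <- sum((tt - mean(tt)) * (std - mean(std))) / sum((tt - mean(tt))^2)
      si <- si + 1L
      slopes[[si]] <- tibble::tibble(keys, sex = sex, slope = slope,
                                     n_levels = nrow(sdf))
    }
  }
  empty_slopes <- tibble::tibble(study_id = character(),
                                 experiment_id = character(),
                                 species = character(), trait_class = character(),
                                 treatment_type = character(), sex = character(),
                                 slope = numeric(), n_levels = integer())
  empty_excl <- tibble::tibble(study_id = character(), experiment_id = character(),
                               species = character(), trait_class = character(),
                               treatment_type = character(), sex = character(),
                               reason = character())
  list(slopes = if (si) dplyr::bind_rows(slopes) else empty_slopes,
       exclusions = if (ei) dplyr::bind_rows(excl) else empty_excl)
}
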