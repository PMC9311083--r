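#' Read and validate a group-summary dataset
#'
#' Reads a UTF-8 CSV in the group-summary schema (one row per
#' study x experiment x treatment level x sex) and validates it row by row.
#' Required columns: `study_id`, `experiment_id`, `species`, `trait_class`,
#' `trait_name`, `treatment_type`, `treatment_level_id`, `temperature`
#' (degrees C, may be empty), `sex` (`F`/`M`), `mean`, `sd` (>= 0), `n`
#' (integer >= 1). An optional `direction_override` column
#' (`a_colder`/`b_colder`) orders two-level designs without distinct
#' temperatures. Malformed rows are rejected with a reason, never silently
#' dropped; missing required columns are a hard error.
#'
#' @param path Path to the CSV file.
#' @return A list with `groups` (validated tibble of accepted rows) and
#'   `report` (list: `read`, `accepted`, `rejected`, `reasons` tally;
#'   `read = accepted + rejected` always).
#' @export
read_dataset <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  miss <- setdiff(required_group_cols(), names(raw))
  if (length(miss))
    stop("missing required columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (!"direction_override" %in% names(raw))
    raw$direction_override <- rep(NA_character_, nrow(raw))
  n_read <- nrow(raw)

  suppressWarnings({
    raw$mean <- as.numeric(raw$mean)
    raw$sd <- as.numeric(raw$sd)
    raw$temperature <- as.numeric(raw$temperature)
    n_num <- as.numeric(raw$n)
  })
  reason <- rep(NA_character_, n_read)
  flag <- function(bad, code) reason[bad & is.na(reason)] <<- code
  flag(is.na(raw$mean), "missing_mean")
  flag(is.na(raw$sd), "missing_sd")
  flag(!is.na(raw$sd) & raw$sd < 0, "negative_sd")
  flag(is.na(n_num) | n_num < 1 | n_num != round(n_num), "bad_n")
  flag(!raw$sex %in% c("F", "M"), "bad_sex")
  flag(!raw$trait_class %in% trait_classes(), "bad_trait_class")
  flag(is.na(raw$study_id) | raw$study_id == "" |
         is.na(raw$experiment_id) | raw$experiment_id == "" |
         is.na(raw$treatment_level_id) | raw$treatment_level_id == "",
       "missing_key")
  dup <- duplicated(raw[, c("study_id", "experiment_id",
                            "treatment_level_id", "sex")])
  flag(dup, "duplicate_cell")

  ok <- is.na(reason)
  groups <- tibble::as_tibble(raw[ok, , drop = FALSE])
  groups$n <- as.integer(n_num[ok])
  report <- list(read = n_read, accepted = sum(ok), rejected = sum(!ok),
                 reasons = if (any(!ok)) table(reason[!ok]) else table(character()),
                 schema_version = "1")
  list(groups = groups, report = report)
}

#' Write a group-summary dataset
#'
#' Writes the schema accepted by [read_dataset()] as a UTF-8 CSV with a
#' period decimal separator. Accepted rows round-trip exactly (up to
#' numeric printing at full precision).
#'
#' @param groups A group-summary tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(groups, path) {
  utils::write.csv(as.data.frame(groups), path, row.names = FALSE,
                   fileEncoding = "UTF-8", quote = TRUE)
  invisible(path)
}
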