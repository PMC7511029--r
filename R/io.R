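#' File formats
#'
#' The package reads and writes plain UTF-8 comma-separated files with a
#' mandatory header row and unquoted numerics:
#'
#' * `women.csv`: `woman_id, state_id, district_id, dob_cmc, interview_cmc,
#'   currently_married, using_any_method, weight`
#' * `births.csv`: `woman_id, birth_cmc`
#' * `district_estimates.csv`: `district_id, state_id, tfr, tfr_ci_low,
#'   tfr_ci_high, cpr, total_births_window`
#' * `averted.csv`: `district_id, state_id, method, group, tfr, cpr, tfrp,
#'   ba, pib`
#' * `state_aggregates.csv`: `unit_id, method, n_districts,
#'   n_below_replacement, n_cpr_above_50, total_births, ba_total, pib`
#'
#' All dates are century month codes (see [cmc()]); logical flags are
#' written as `TRUE`/`FALSE`. Floats are written at full precision;
#' `write_estimates(report = TRUE)` rounds to 2 decimals for reporting.
#'
#' @name avertr-formats
NULL

women_cols <- c("woman_id", "state_id", "district_id", "dob_cmc",
                "interview_cmc", "currently_married", "using_any_method",
                "weight")
births_cols <- c("woman_id", "birth_cmc")

check_columns <- function(df, wanted, what) {
  missing <- setdiff(wanted, names(df))
  if (length(missing) > 0)
    abort(sprintf("%s is missing column(s): %s", what,
                  paste(missing, collapse = ", ")),
          class = "avertr_schema_error")
}

#' Validate woman-level microdata
#'
#' Checks referential integrity and the record invariants: interview after
#' birth of the woman, completed age 15-49 at interview, nonnegative
#' weights, every birth after the mother's tenth birthday and not after her
#' interview. Validation is total: every offending row is enumerated, none
#' are silently dropped.
#'
#' @param women,births Tibbles in the microdata schema
#'   (see [avertr-formats]).
#' @return Invisibly `TRUE` when valid; otherwise aborts with a message
#'   listing each violation and its row number(s).
#' @export
validate_microdata <- function(women, births) {
  check_columns(women, women_cols, "women table")
  check_columns(births, births_cols, "births table")
  problems <- character()
  row_msg <- function(rows, msg) {
    sprintf("%s (rows %s)", msg,
            paste(head(rows, 10), collapse = ", "))
  }

  orphan <- which(!births$woman_id %in% women$woman_id)
  if (length(orphan) > 0)
    problems <- c(problems,
                  row_msg(orphan, "births reference unknown woman_id"))

  bad_order <- which(women$interview_cmc <= women$dob_cmc)
  if (length(bad_order) > 0)
    problems <- c(problems, row_msg(bad_order, "interview_cmc <= dob_cmc"))

  age <- age_completed_years(women$dob_cmc, women$interview_cmc)
  bad_age <- which(age < 15 | age > 49)
  if (length(bad_age) > 0)
    problems <- c(problems,
                  row_msg(bad_age, "age at interview outside 15-49"))

  bad_w <- which(women$weight < 0 | is.na(women$weight))
  if (length(bad_w) > 0)
    problems <- c(problems, row_msg(bad_w, "negative or missing weight"))

  if (nrow(births) > 0 && length(orphan) == 0) {
    mother <- women[match(births$woman_id, women$woman_id), ]
    too_young <- which(births$birth_cmc <= mother$dob_cmc + 120L)
    if (length(too_young) > 0)
      problems <- c(problems,
                    row_msg(too_young, "birth before mother aged 10"))
    after <- which(births$birth_cmc > mother$interview_cmc)
    if (length(after) > 0)
      problems <- c(problems, row_msg(after, "birth after interview"))
  }

  if (length(problems) > 0)
    abort(c("microdata validation failed:", problems),
          class = "avertr_validation_error")
  invisible(TRUE)
}

#' Read woman-level microdata from CSV
#'
#' Reads the two-file microdata schema and validates it (see
#' [validate_microdata()]). An empty births file (header only) is a valid
#' childless population.
#'
#' @param women_path,births_path Paths to `women.csv` and `births.csv`.
#' @return List with typed `women` and `births` tibbles.
#' @export
read_microdata <- function(women_path, births_path) {
  women <- readr::read_csv(
    women_path,
    col_types = readr::cols(
      woman_id = readr::col_double(),
      state_id = readr::col_integer(),
      district_id = readr::col_integer(),
      dob_cmc = readr::col_integer(),
      interview_cmc = readr::col_integer(),
      currently_married = readr::col_logical(),
      using_any_method = readr::col_logical(),
      weight = readr::col_double()
    )
  )
  births <- readr::read_csv(
    births_path,
    col_types = readr::cols(
      woman_id = readr::col_double(),
      birth_cmc = readr::col_integer()
    )
  )
  check_columns(women, women_cols, "women table")
  check_columns(births, births_cols, "births table")
  validate_microdata(women, births)
  list(women = women, births = births)
}

#' Write an estimates table to CSV
#'
#' Writes any of the package's result tables with a fixed column order.
#' With `report = TRUE` numeric columns are rounded to 2 decimals, the
#' precision used in published summary tables; the default keeps full
#' precision so that write-then-read is the identity up to float text
#' representation.
#'
#' @param records A tibble of results (district estimates, averted results
#'   or aggregates).
#' @param path Output CSV path.
#' @param report Round numerics to 2 decimals for reporting.
#' @return The input, invisibly.
#' @export
write_estimates <- function(records, path, report = FALSE) {
  out <- records
  if (report)
    out <- dplyr::mutate(out, dplyr::across(
      dplyr::where(~ is.double(.x)), ~ round(.x, 2)))
  readr::write_csv(out, path)
  invisible(records)
}
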