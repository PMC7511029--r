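#' Woman-years of exposure and births by district and age group
#'
#' Splits each woman's reference window (the `window_months` months
#' strictly preceding her interview month, excluding the interview month
#' itself) across the seven 5-year age groups of her own life, computed
#' from her date of birth in exact integer-month arithmetic. The overlap in
#' months divided by 12, times her sampling weight, accrues as woman-years
#' of exposure; months where she is under 15 or over 49 completed years
#' contribute nothing. Each birth inside the window accrues the mother's
#' weight to the births count of her age group at the birth month (completed
#' years; an exact multiple of 5 goes to the older group). Births whose
#' mother is outside 15-49 at the birth fall outside the rate schedule and
#' are not attributed.
#'
#' @param women,births Validated microdata tibbles (see [avertr-formats]).
#' @param window_months Reference window length in months (default 36, the
#'   three years preceding the survey).
#' @return Tibble with one row per district x age group: `district_id`,
#'   `age_group`, `exposure` (weighted woman-years), `births` (weighted
#'   count).
#' @export
compute_exposure <- function(women, births, window_months = 36L) {
  stopifnot(window_months >= 1)
  gm <- window_group_months(women$dob_cmc, women$interview_cmc, window_months)
  exposure <- gm |>
    dplyr::mutate(
      district_id = women$district_id[.data$i],
      weight = women$weight[.data$i],
      age_group = factor(age_group_labels[.data$g],
                         levels = age_group_labels)
    ) |>
    dplyr::group_by(.data$district_id, .data$age_group, .drop = FALSE) |>
    dplyr::summarise(exposure = sum(.data$months / 12 * .data$weight),
                     .groups = "drop")

  if (nrow(births) > 0) {
    b <- births |>
      dplyr::inner_join(
        dplyr::select(women, "woman_id", "district_id", "dob_cmc",
                      "interview_cmc", "weight"),
        by = "woman_id"
      ) |>
      dplyr::filter(
        .data$birth_cmc >= .data$interview_cmc - window_months,
        .data$birth_cmc <= .data$interview_cmc - 1L
      ) |>
      dplyr::mutate(
        age_group = age_group(age_completed_years(.data$dob_cmc,
                                                  .data$birth_cmc))
      ) |>
      dplyr::filter(!is.na(.data$age_group)) |>
      dplyr::group_by(.data$district_id, .data$age_group, .drop = FALSE) |>
      dplyr::summarise(births = sum(.data$weight), .groups = "drop")
    exposure <- dplyr::left_join(exposure, b,
                                 by = c("district_id", "age_group"))
    exposure$births[is.na(exposure$births)] <- 0
  } else {
    exposure$births <- 0
  }
  dplyr::filter(exposure, !is.na(.data$district_id))
}

#' Total fertility rate from an exposure table
#'
#' Direct-method TFR: `5 * sum(births_a / exposure_a)` over the seven
#' 5-year groups, age-specific rates in births per woman-year. Groups with
#' neither births nor exposure contribute zero; births in a group with zero
#' exposure are an estimation error (a rate cannot be formed).
#'
#' @param exposure Output of [compute_exposure()].
#' @return Tibble `district_id`, `tfr`.
#' @export
compute_tfr <- function(exposure) {
  bad <- dplyr::filter(exposure, .data$births > 0, .data$exposure <= 0)
  if (nrow(bad) > 0)
    abort(sprintf(
      "births with zero exposure in district %s, age group %s",
      bad$district_id[1], as.character(bad$age_group[1])),
      class = "avertr_estimation_error")
  exposure |>
    dplyr::group_by(.data$district_id) |>
    dplyr::summarise(
      tfr = 5 * sum(ifelse(.data$exposure > 0,
                           .data$births / .data$exposure, 0)),
      .groups = "drop"
    )
}

#' Confidence interval for the TFR
#'
#' Model-based interval from independent Poisson birth counts per age
#' group: with rates `r_a = births_a / exposure_a` the TFR is
#' `5 * sum(r_a)`, the delta-method variance of `log TFR` is
#' `sum(r_a^2 / births_a) / sum(r_a)^2` (groups without births carry no
#' variance information and are excluded), and the interval is
#' `TFR * exp(±z * SE(log TFR))`. Districts with no births at all get the
#' degenerate interval `(0, 0)` with a warning.
#'
#' @param exposure Output of [compute_exposure()].
#' @param level Confidence level (default 0.95).
#' @return Tibble `district_id`, `tfr`, `tfr_ci_low`, `tfr_ci_high`.
#' @export
compute_tfr_ci <- function(exposure, level = 0.95) {
  z <- qnorm(1 - (1 - level) / 2)
  tfr <- compute_tfr(exposure)
  vartab <- exposure |>
    dplyr::filter(.data$births > 0) |>
    dplyr::mutate(rate = .data$births / .data$exposure) |>
    dplyr::group_by(.data$district_id) |>
    dplyr::summarise(
      var_num = sum(.data$rate^2 / .data$births),
      rate_sum = sum(.data$rate),
      .groups = "drop"
    )
  out <- dplyr::left_join(tfr, vartab, by = "district_id") |>
    dplyr::mutate(
      se_log = ifelse(is.na(.data$var_num), NA_real_,
                      sqrt(.data$var_num) / .data$rate_sum),
      tfr_ci_low = ifelse(is.na(.data$se_log), 0,
                          .data$tfr * exp(-z * .data$se_log)),
      tfr_ci_high = ifelse(is.na(.data$se_log), 0,
                           .data$tfr * exp(z * .data$se_log))
    )
  if (anyNA(out$se_log))
    warn(sprintf(
      "no births in district(s) %s: TFR interval undefined, returned (0, 0)",
      paste(out$district_id[is.na(out$se_log)], collapse = ", ")))
  dplyr::select(out, "district_id", "tfr", "tfr_ci_low", "tfr_ci_high")
}

#' District-level observed TFR, CI, CPR and window births
#'
#' One-stop estimator: runs [compute_exposure()], [compute_tfr_ci()] and
#' [compute_cpr()] and assembles the per-district estimates table that the
#' counterfactual stage consumes. `total_births_window` is the weighted
#' count of births attributed in the window (mothers aged 15-49 at birth),
#' the same births that enter the TFR.
#'
#' @inheritParams compute_exposure
#' @param ci_level Confidence level for the TFR interval.
#' @return Tibble `district_id`, `state_id`, `tfr`, `tfr_ci_low`,
#'   `tfr_ci_high`, `cpr`, `total_births_window`.
#' @export
estimate_districts <- function(women, births, window_months = 36L,
                               ci_level = 0.95) {
  exposure <- compute_exposure(women, births, window_months)
  ci <- compute_tfr_ci(exposure, ci_level)
  totals <- exposure |>
    dplyr::group_by(.data$district_id) |>
    dplyr::summarise(total_births_window = sum(.data$births),
                     .groups = "drop")
  states <- dplyr::distinct(women, .data$district_id, .data$state_id)
  ci |>
    dplyr::left_join(states, by = "district_id") |>
    dplyr::left_join(totals, by = "district_id") |>
    dplyr::left_join(compute_cpr(women), by = "district_id") |>
    dplyr::select("district_id", "state_id", "tfr", "tfr_ci_low",
                  "tfr_ci_high", "cpr", "total_births_window")
}
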