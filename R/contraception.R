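#' Contraceptive prevalence rate per district
#'
#' CPR is the weighted percentage of currently married women aged 15-49
#' using any contraceptive method (couple-level use is collapsed into the
#' single `using_any_method` flag). Women outside union are excluded from
#' both numerator and denominator; their `using_any_method` flag, if set,
#' is ignored. A district with no currently married women has an undefined
#' CPR, returned as `NA` with a warning so it can be excluded downstream
#' rather than silently dropped.
#'
#' @param women Validated women tibble (see [avertr-formats]).
#' @return Tibble `district_id`, `cpr` (percent, `NA` when undefined),
#'   `n_married` (weighted denominator).
#' @examples
#' w <- tibble::tibble(
#'   woman_id = 1:3, state_id = 1L, district_id = 1L,
#'   dob_cmc = 1000L, interview_cmc = 1393L,
#'   currently_married = TRUE,
#'   using_any_method = c(TRUE, FALSE, TRUE),
#'   weight = c(1, 1, 2)
#' )
#' compute_cpr(w) # 75 percent
#' @export
compute_cpr <- function(women) {
  out <- women |>
    dplyr::group_by(.data$district_id) |>
    dplyr::summarise(
      n_married = sum(.data$weight[.data$currently_married]),
      cpr = if (sum(.data$weight[.data$currently_married]) > 0) {
        100 * sum(.data$weight[.data$currently_married &
                                 .data$using_any_method]) /
          sum(.data$weight[.data$currently_married])
      } else NA_real_,
      .groups = "drop"
    ) |>
    dplyr::select("district_id", "cpr", "n_married")
  if (anyNA(out$cpr))
    warn(sprintf(
      "district(s) %s have no currently married women: CPR undefined (NA)",
      paste(out$district_id[is.na(out$cpr)], collapse = ", ")))
  out
}
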