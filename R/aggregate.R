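#' Roll district births averted up to state or national level
#'
#' Births averted are summed over the districts of each unit and the
#' aggregate percentage increase in births is recomputed as
#' `100 * ba_total / total_births` — a births-weighted mean of the
#' district PIBs, not their plain average. Alongside, the table reports
#' how many districts sit below replacement fertility (`tfr <
#' tfr_replacement`, strict, default 2.1) and how many have CPR above
#' `cpr_cut` (strict, default 50); note these reporting thresholds are
#' distinct from the 2.2/50 stratification of the fitting stage.
#'
#' @param averted Per-district results from [run_method1()] /
#'   [run_method2()] / [estimate_births_averted()].
#' @param estimates District estimates from [estimate_districts()]
#'   (supplies `state_id`, `tfr`, `cpr`, `total_births_window`).
#' @param level `"state"` or `"national"`.
#' @param tfr_replacement,cpr_cut Reporting thresholds for the two counts.
#' @return Tibble with `unit_id`, `method`, `n_districts`,
#'   `n_below_replacement`, `n_cpr_above_50`, `total_births`, `ba_total`,
#'   `pib`.
#' @export
aggregate_averted <- function(averted, estimates,
                              level = c("state", "national"),
                              tfr_replacement = 2.1, cpr_cut = 50) {
  level <- match.arg(level)
  missing_ids <- setdiff(averted$district_id, estimates$district_id)
  if (length(missing_ids) > 0)
    abort(sprintf("averted district(s) %s have no matching estimate",
                  paste(head(missing_ids, 5), collapse = ", ")),
          class = "avertr_consistency_error")
  joined <- averted |>
    dplyr::select("district_id", "method", "ba") |>
    dplyr::inner_join(
      dplyr::select(estimates, "district_id", "state_id", "tfr", "cpr",
                    "total_births_window"),
      by = "district_id"
    ) |>
    dplyr::mutate(unit_id = if (level == "national") "national"
                  else as.character(.data$state_id))
  joined |>
    dplyr::group_by(.data$unit_id, .data$method) |>
    dplyr::summarise(
      n_districts = dplyr::n(),
      n_below_replacement = sum(.data$tfr < .env$tfr_replacement),
      n_cpr_above_50 = sum(.data$cpr > .env$cpr_cut),
      total_births = sum(.data$total_births_window),
      ba_total = sum(.data$ba),
      pib = 100 * sum(.data$ba) / sum(.data$total_births_window),
      .groups = "drop"
    )
}
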