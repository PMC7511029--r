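#' PIB distribution summaries by replacement-fertility stratum
#'
#' Summarises the district distribution of the percentage increase in
#' births (PIB) separately for districts above and at-or-below replacement
#' fertility (default split at TFR 2.1) and per estimation method:
#' quartiles by the linear-interpolation (type-7) definition, mean, n, and
#' the skew direction read off `sign(mean - median)` (`"left"` when mean <
#' median, the pattern expected for below-replacement districts where a
#' few low-CPR districts trail the bulk). Empty strata are omitted with a
#' warning.
#'
#' @param averted Per-district results carrying `district_id`, `method`,
#'   `pib`.
#' @param estimates District estimates carrying `district_id`, `tfr`.
#' @param split_tfr Replacement-level TFR used to split the strata.
#' @return Tibble: `stratum`, `method`, `n`, `p25`, `median`, `p75`,
#'   `mean`, `skew`.
#' @export
pib_distribution <- function(averted, estimates, split_tfr = 2.1) {
  stopifnot(nrow(averted) > 0)
  joined <- averted |>
    dplyr::select("district_id", "method", "pib") |>
    dplyr::inner_join(dplyr::select(estimates, "district_id", "tfr"),
                      by = "district_id") |>
    dplyr::mutate(stratum = ifelse(.data$tfr > .env$split_tfr,
                                   "above_replacement",
                                   "below_replacement"))
  out <- joined |>
    dplyr::group_by(.data$stratum, .data$method) |>
    dplyr::summarise(
      n = dplyr::n(),
      p25 = quantile(.data$pib, 0.25, type = 7, names = FALSE),
      median = median(.data$pib),
      p75 = quantile(.data$pib, 0.75, type = 7, names = FALSE),
      mean = mean(.data$pib),
      skew = dplyr::case_when(
        mean(.data$pib) < median(.data$pib) ~ "left",
        mean(.data$pib) > median(.data$pib) ~ "right",
        TRUE ~ "symmetric"
      ),
      .groups = "drop"
    )
  present <- unique(out$stratum)
  absent <- setdiff(c("above_replacement", "below_replacement"), present)
  if (length(absent) > 0)
    warn(sprintf("stratum %s is empty and omitted",
                 paste(absent, collapse = ", ")))
  out
}

#' Coefficient of variation of births-averted estimates
#'
#' `100 * sd(x) / mean(x)` with the sample (n - 1) standard deviation;
#' used to compare the dispersion of the two methods' births-averted
#' estimates relative to their level. Undefined (NA, with a warning) when
#' the mean is zero.
#'
#' @param ba_values Numeric vector, length >= 2.
#' @return CV in percent.
#' @examples
#' cv_of_ba(c(90, 110)) # ~14.14
#' @export
cv_of_ba <- function(ba_values) {
  stopifnot(length(ba_values) >= 2)
  m <- mean(ba_values)
  if (m == 0) {
    warn("mean of ba_values is zero: CV undefined")
    return(NA_real_)
  }
  100 * sd(ba_values) / m
}
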