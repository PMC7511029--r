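#' Century-month-code helpers
#'
#' Dates are carried as century month codes (CMC), the DHS standard
#' encoding: `CMC = (year - 1900) * 12 + month`, so January 1900 is CMC 1.
#' All exposure and age arithmetic in the package is integer-month
#' arithmetic on CMCs, which keeps exposure splitting exact.
#'
#' @param year Calendar year (e.g. 2016).
#' @param month Calendar month, 1-12.
#' @return `cmc()` returns the integer CMC; `cmc_year()` and `cmc_month()`
#'   invert it.
#' @examples
#' cmc(2016, 1) # 1393
#' cmc_year(1393)
#' @export
cmc <- function(year, month) {
  stopifnot(all(month >= 1), all(month <= 12))
  as.integer((year - 1900L) * 12L + month)
}

#' @rdname cmc
#' @param x An integer CMC.
#' @export
cmc_year <- function(x) as.integer(1900L + (x - 1L) %/% 12L)

#' @rdname cmc
#' @export
cmc_month <- function(x) as.integer((x - 1L) %% 12L + 1L)

#' Completed age in years from two CMCs
#'
#' Completed years between a date of birth and a reference month:
#' `floor((ref_cmc - dob_cmc) / 12)`.
#'
#' @param dob_cmc Date of birth, CMC.
#' @param ref_cmc Reference month, CMC.
#' @return Integer completed years.
#' @export
age_completed_years <- function(dob_cmc, ref_cmc) {
  as.integer((ref_cmc - dob_cmc) %/% 12L)
}

# Reproductive-age 5-year groups, 15-19 ... 45-49
age_group_starts <- seq(15L, 45L, by = 5L)

age_group_labels <- paste(age_group_starts, age_group_starts + 4L, sep = "-")

#' Five-year age-group label for a completed age
#'
#' Ages are assigned by completed years; an exact multiple of five goes to
#' the older group (age 20 falls in 20-24). Ages outside 15-49 return `NA`.
#'
#' @param age Completed age in years.
#' @return Factor with levels `"15-19"` ... `"45-49"`.
#' @export
age_group <- function(age) {
  idx <- ifelse(age >= 15L & age <= 49L, (age - 15L) %/% 5L + 1L, NA_integer_)
  factor(age_group_labels[idx], levels = age_group_labels)
}
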