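#' Plot a TFR-CPR fit
#'
#' Scatter of log TFR against CPR, points shaded by robust weight (for an
#' IRLS fit) with the fitted line overlaid — the standard diagnostic for
#' spotting which districts the robust fit down-weighted.
#'
#' @param object A `tfr_cpr_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot tfr_cpr_fit
#' @export
autoplot.tfr_cpr_fit <- function(object, ...) {
  df <- object$data
  df$weight <- object$robust_weights
  ggplot2::ggplot(df, ggplot2::aes(x = .data$cpr, y = .data$logtfr)) +
    ggplot2::geom_point(ggplot2::aes(alpha = .data$weight)) +
    ggplot2::geom_abline(intercept = object$beta0_hat,
                         slope = object$beta1_hat, colour = "#D55E00") +
    ggplot2::scale_alpha_continuous(limits = c(0, 1), name = "robust\nweight") +
    ggplot2::labs(
      x = "CPR (% of currently married women 15-49)",
      y = "log TFR",
      title = sprintf("log TFR = %.3f %+.4f CPR (%s)",
                      object$beta0_hat, object$beta1_hat,
                      toupper(object$kind))
    ) +
    ggplot2::theme_minimal()
}

#' Box plots of PIB by replacement-fertility stratum and method
#'
#' The sensitivity-analysis figure: district PIB distributions side by
#' side for districts above and at-or-below replacement fertility, one box
#' per estimation method.
#'
#' @param averted Per-district averted results (`district_id`, `method`,
#'   `pib`).
#' @param estimates District estimates (`district_id`, `tfr`).
#' @param split_tfr Replacement-level TFR split.
#' @return A ggplot object.
#' @export
plot_pib_distribution <- function(averted, estimates, split_tfr = 2.1) {
  joined <- averted |>
    dplyr::select("district_id", "method", "pib") |>
    dplyr::inner_join(dplyr::select(estimates, "district_id", "tfr"),
                      by = "district_id") |>
    dplyr::mutate(
      stratum = ifelse(.data$tfr > .env$split_tfr,
                       sprintf("TFR > %.1f", split_tfr),
                       sprintf("TFR ≤ %.1f", split_tfr)),
      method = paste("Method", .data$method)
    )
  ggplot2::ggplot(joined,
                  ggplot2::aes(x = .data$stratum, y = .data$pib,
                               fill = .data$method)) +
    ggplot2::geom_boxplot() +
    ggplot2::labs(x = NULL, y = "Percentage increase in births (PIB)",
                  fill = NULL) +
    ggplot2::theme_minimal()
}
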