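#' Log-linear TFR-CPR regression fits
#'
#' The counterfactual construction rests on the district-level model
#' `log TFR_i = beta0 + beta1 * CPR_i + eps_i`. [fit_ols()] solves it by
#' closed-form least squares. [fit_robust()] re-fits it by iteratively
#' reweighted least squares so that high-residual districts (outliers) are
#' down-weighted: starting from the OLS solution, residuals are scaled by
#' the MAD-based robust scale `median(|e - median(e)|) / 0.6745`, a Huber
#' stage (k = 1.345) iterates weighted least squares to convergence, then a
#' Tukey bisquare stage (c = 4.685) does the same; the scale is refreshed
#' each iteration. Convergence is declared when the largest coefficient
#' change falls below `tol`.
#'
#' @param districts Tibble with at least `tfr` and `cpr` columns (all
#'   `tfr > 0`, `cpr` in percent) and ideally `district_id`; rows with `NA`
#'   in either variable are refused.
#' @param huber_k,bisquare_c Tuning constants of the two weight functions.
#' @param tol Convergence tolerance on the maximum coefficient change.
#' @param max_iter Maximum IRLS iterations per stage.
#' @return An object of class `tfr_cpr_fit`: a list with `beta0_hat`,
#'   `beta1_hat`, per-district `residuals` (`log tfr - (b0 + b1 cpr)`) and
#'   `robust_weights` (all 1 for OLS), `kind` (`"ols"` or `"irls"`),
#'   `n_obs`, `converged`, `n_iter`, `scale`, and the model frame `data`.
#'   Supports [tidy()], [glance()], [autoplot()] and `predict()`.
#' @examples
#' d <- tibble::tibble(cpr = c(10, 30, 50, 70),
#'                     tfr = exp(1.199 - 0.0083 * c(10, 30, 50, 70)))
#' fit_ols(d)$beta1_hat # -0.0083
#' @export
fit_ols <- function(districts) {
  xy <- fit_frame(districts)
  b <- ls_solve(xy$cpr, xy$logtfr, rep(1, nrow(xy)))
  new_tfr_cpr_fit(b, xy, rep(1, nrow(xy)), kind = "ols",
                  converged = TRUE, n_iter = 0L, scale = NA_real_)
}

#' @rdname fit_ols
#' @export
fit_robust <- function(districts, huber_k = 1.345, bisquare_c = 4.685,
                       tol = 1e-8, max_iter = 50L) {
  xy <- fit_frame(districts)
  x <- xy$cpr
  y <- xy$logtfr
  b <- ls_solve(x, y, rep(1, length(x)))
  scale <- NA_real_
  total_iter <- 0L
  converged <- TRUE

  for (stage in c("huber", "bisquare")) {
    wfun <- if (stage == "huber") {
      function(u) pmin(1, huber_k / pmax(abs(u), .Machine$double.eps))
    } else {
      function(u) ifelse(abs(u) < bisquare_c, (1 - (u / bisquare_c)^2)^2, 0)
    }
    stage_converged <- FALSE
    for (it in seq_len(max_iter)) {
      r <- y - b[1] - b[2] * x
      scale <- mad_scale(r)
      if (scale <= 0) { # residuals (essentially) identical: nothing to weight
        stage_converged <- TRUE
        break
      }
      w <- wfun(r / scale)
      if (sum(w > 0) < 2 || length(unique(x[w > 0])) < 2)
        abort("robust weighting left fewer than 2 distinct design points",
              class = "avertr_estimation_error")
      b_new <- ls_solve(x, y, w)
      total_iter <- total_iter + 1L
      if (max(abs(b_new - b)) < tol) {
        b <- b_new
        stage_converged <- TRUE
        break
      }
      b <- b_new
    }
    if (!stage_converged) converged <- FALSE
  }
  if (!converged)
    warn(sprintf("robust fit did not converge in %d iterations per stage",
                 max_iter))
  r <- y - b[1] - b[2] * x
  final_scale <- mad_scale(r)
  w <- if (final_scale > 0) {
    u <- r / final_scale
    ifelse(abs(u) < bisquare_c, (1 - (u / bisquare_c)^2)^2, 0)
  } else rep(1, length(r))
  new_tfr_cpr_fit(b, xy, w, kind = "irls", converged = converged,
                  n_iter = total_iter, scale = final_scale)
}

# MAD about the median, scaled to be consistent for a normal sample
mad_scale <- function(r) median(abs(r - median(r))) / 0.6745

# weighted least squares of y on (1, x), closed form from normal equations
ls_solve <- function(x, y, w) {
  sw <- sum(w)
  xbar <- sum(w * x) / sw
  ybar <- sum(w * y) / sw
  sxx <- sum(w * (x - xbar)^2)
  if (sxx <= 0)
    abort("degenerate design: all CPR values equal",
          class = "avertr_estimation_error")
  b1 <- sum(w * (x - xbar) * (y - ybar)) / sxx
  c(ybar - b1 * xbar, b1)
}

fit_frame <- function(districts) {
  stopifnot(is.data.frame(districts),
            all(c("tfr", "cpr") %in% names(districts)))
  if (nrow(districts) < 3)
    abort("need at least 3 districts to fit the TFR-CPR regression",
          class = "avertr_estimation_error")
  if (anyNA(districts$tfr) || anyNA(districts$cpr))
    abort("NA in tfr or cpr: exclude flagged districts before fitting",
          class = "avertr_estimation_error")
  if (any(districts$tfr <= 0))
    abort("all tfr must be > 0 to take logs",
          class = "avertr_estimation_error")
  tibble::tibble(
    district_id = if ("district_id" %in% names(districts))
      districts$district_id else seq_len(nrow(districts)),
    cpr = districts$cpr,
    tfr = districts$tfr,
    logtfr = log(districts$tfr)
  )
}

new_tfr_cpr_fit <- function(b, xy, w, kind, converged, n_iter, scale) {
  structure(
    list(
      beta0_hat = unname(b[1]),
      beta1_hat = unname(b[2]),
      residuals = xy$logtfr - b[1] - b[2] * xy$cpr,
      robust_weights = w,
      kind = kind,
      n_obs = nrow(xy),
      converged = converged,
      n_iter = n_iter,
      scale = scale,
      data = xy
    ),
    class = "tfr_cpr_fit"
  )
}

#' @export
print.tfr_cpr_fit <- function(x, ...) {
  cat(sprintf(
    "<tfr_cpr_fit> %s on %d districts\n  log TFR = %.4f %+.5f * CPR\n",
    toupper(x$kind), x$n_obs, x$beta0_hat, x$beta1_hat))
  if (x$kind == "irls")
    cat(sprintf("  %d IRLS iterations, scale %.4g, converged: %s\n",
                x$n_iter, x$scale, x$converged))
  invisible(x)
}

#' @export
predict.tfr_cpr_fit <- function(object, newdata = NULL, ...) {
  cpr <- if (is.null(newdata)) object$data$cpr else newdata$cpr
  exp(object$beta0_hat + object$beta1_hat * cpr)
}

#' Tidy a TFR-CPR fit
#'
#' @param x A `tfr_cpr_fit`.
#' @param ... Unused.
#' @return [tidy()]: one row per coefficient (`term`, `estimate`).
#'   [glance()]: one-row model summary (`kind`, `n_obs`, `n_iter`,
#'   `converged`, `scale`, `min_weight`).
#' @method tidy tfr_cpr_fit
#' @export
tidy.tfr_cpr_fit <- function(x, ...) {
  tibble::tibble(
    term = c("(Intercept)", "cpr"),
    estimate = c(x$beta0_hat, x$beta1_hat)
  )
}

#' @rdname tidy.tfr_cpr_fit
#' @method glance tfr_cpr_fit
#' @export
glance.tfr_cpr_fit <- function(x, ...) {
  tibble::tibble(
    kind = x$kind, n_obs = x$n_obs, n_iter = x$n_iter,
    converged = x$converged, scale = x$scale,
    min_weight = min(x$robust_weights)
  )
}

#' Classify a district into the four TFR-CPR strata
#'
#' The stratified method partitions districts into four groups by whether
#' TFR is at or below the national level (default 2.2) and whether CPR is
#' below 50 percent: group 1 low TFR & low CPR, group 2 high TFR & low
#' CPR, group 3 low TFR & high CPR, group 4 high TFR & high CPR. Ties go
#' to "low" for TFR (`tfr <= threshold`) and "high" for CPR
#' (`cpr >= threshold`), so (2.2, 50) lands in group 3.
#'
#' @param tfr,cpr Numeric vectors (births per woman; percent).
#' @param tfr_threshold,cpr_threshold Stratum boundaries.
#' @return Integer vector in 1..4.
#' @export
classify_group <- function(tfr, cpr, tfr_threshold = 2.2,
                           cpr_threshold = 50) {
  low_tfr <- tfr <= tfr_threshold
  low_cpr <- cpr < cpr_threshold
  ifelse(low_tfr & low_cpr, 1L,
         ifelse(!low_tfr & low_cpr, 2L,
                ifelse(low_tfr & !low_cpr, 3L, 4L)))
}

#' Potential TFR in the absence of contraception
#'
#' Given a fitted slope `beta1_hat` of log TFR on CPR, the counterfactual
#' TFR a district would experience with zero contraceptive use preserves
#' the district's own residual: `log TFRP = beta0_hat + eps_hat`, which is
#' algebraically `log TFR + c * CPR` with correction slope
#' `c = -beta1_hat`. A district with `cpr = 0` is unchanged.
#'
#' @param tfr,cpr Observed district values.
#' @param fit A `tfr_cpr_fit`, or a bare numeric `beta1_hat`.
#' @return Potential TFR (births per woman), same length as `tfr`.
#' @export
potential_tfr <- function(tfr, cpr, fit) {
  beta1 <- if (inherits(fit, "tfr_cpr_fit")) fit$beta1_hat else fit
  stopifnot(is.numeric(beta1), length(beta1) == 1)
  exp(log(tfr) - beta1 * cpr)
}

#' Births averted and percentage increase in births
#'
#' `pib()` is the percentage increase in births a district would see in
#' the absence of contraception, `100 * (tfrp - tfr) / tfr`; under the
#' log-linear fit it equals `100 * (exp(c * cpr) - 1)`. `births_averted()`
#' applies that relative excess to the observed births in the reference
#' window, `ba = (tfrp - tfr) / tfr * total_births`, and is carried in
#' whatever unit `total_births` is in (this package reports thousands, as
#' summary tables in this literature do).
#'
#' @param tfr Observed TFR (> 0).
#' @param tfrp Potential TFR from [potential_tfr()].
#' @param total_births Births in the reference window.
#' @return Numeric vector.
#' @export
births_averted <- function(tfr, tfrp, total_births) {
  if (any(tfr <= 0))
    abort("births_averted undefined for tfr <= 0",
          class = "avertr_estimation_error")
  (tfrp - tfr) / tfr * total_births
}

#' @rdname births_averted
#' @export
pib <- function(tfr, tfrp) {
  if (any(tfr <= 0))
    abort("pib undefined for tfr <= 0", class = "avertr_estimation_error")
  100 * (tfrp - tfr) / tfr
}

averted_table <- function(districts, fit, group, method) {
  tfrp <- potential_tfr(districts$tfr, districts$cpr, fit)
  tibble::tibble(
    district_id = districts$district_id,
    state_id = if ("state_id" %in% names(districts))
      districts$state_id else NA_integer_,
    method = method,
    group = group,
    tfr = districts$tfr,
    cpr = districts$cpr,
    tfrp = tfrp,
    ba = births_averted(districts$tfr, tfrp,
                        districts$total_births_window),
    pib = pib(districts$tfr, tfrp)
  )
}

#' Births averted by stratified (Method 1) or pooled (Method 2) fits
#'
#' [run_method1()] classifies districts into the four TFR-CPR strata,
#' fits one robust regression per stratum and applies each stratum's own
#' correction slope to its districts. [run_method2()] fits a single pooled
#' robust regression and applies its slope everywhere.
#' [estimate_births_averted()] runs either or both. A stratum whose fitted
#' slope comes out positive yields negative PIB; the functions warn and
#' report it rather than truncating.
#'
#' @param districts Tibble with `district_id`, `tfr`, `cpr`,
#'   `total_births_window` (and ideally `state_id`).
#' @inheritParams classify_group
#' @param ... Passed to [fit_robust()].
#' @return Tibble of per-district results: `district_id`, `state_id`,
#'   `method` (`"1"` or `"2"`), `group` (`1`-`4` or `"pooled"`), `tfr`,
#'   `cpr`, `tfrp`, `ba`, `pib`; the fitted `tfr_cpr_fit` object(s) are
#'   attached as attribute `"fits"`.
#' @export
run_method1 <- function(districts, tfr_threshold = 2.2, cpr_threshold = 50,
                        ...) {
  grp <- classify_group(districts$tfr, districts$cpr,
                        tfr_threshold, cpr_threshold)
  sizes <- table(factor(grp, levels = 1:4))
  small <- names(sizes)[sizes > 0 & sizes < 3]
  if (length(small) > 0)
    abort(sprintf("group(s) %s have fewer than 3 districts; cannot fit",
                  paste(small, collapse = ", ")),
          class = "avertr_estimation_error")
  fits <- list()
  out <- purrr::map(sort(unique(grp)), function(g) {
    sub <- districts[grp == g, ]
    fit <- fit_robust(sub, ...)
    fits[[as.character(g)]] <<- fit
    if (fit$beta1_hat > 0)
      warn(sprintf(
        "group %d fitted a positive slope (%.4g): negative PIB reported",
        g, fit$beta1_hat))
    averted_table(sub, fit, group = as.character(g), method = "1")
  })
  res <- dplyr::arrange(dplyr::bind_rows(out), .data$district_id)
  attr(res, "fits") <- fits
  res
}

#' @rdname run_method1
#' @export
run_method2 <- function(districts, ...) {
  fit <- fit_robust(districts, ...)
  if (fit$beta1_hat > 0)
    warn(sprintf("pooled fit has a positive slope (%.4g): negative PIB",
                 fit$beta1_hat))
  res <- averted_table(districts, fit, group = "pooled", method = "2")
  res <- dplyr::arrange(res, .data$district_id)
  attr(res, "fits") <- list(pooled = fit)
  res
}

#' @rdname run_method1
#' @param method `"1"`, `"2"` or `"both"`.
#' @export
estimate_births_averted <- function(districts, method = c("both", "1", "2"),
                                    tfr_threshold = 2.2, cpr_threshold = 50,
                                    ...) {
  method <- match.arg(method)
  parts <- list()
  fits <- list()
  if (method %in% c("1", "both")) {
    m1 <- run_method1(districts, tfr_threshold, cpr_threshold, ...)
    fits <- c(fits, setNames(attr(m1, "fits"),
                             paste0("group", names(attr(m1, "fits")))))
    parts <- c(parts, list(m1))
  }
  if (method %in% c("2", "both")) {
    m2 <- run_method2(districts, ...)
    fits <- c(fits, attr(m2, "fits"))
    parts <- c(parts, list(m2))
  }
  res <- dplyr::bind_rows(parts)
  attr(res, "fits") <- fits
  res
}
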