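test_that("OLS recovers a noise-free generating line essentially exactly", {
  d <- line_districts(cpr = seq(5, 85, by = 5))
  fit <- fit_ols(d)
  expect_equal(fit$beta0_hat, 1.199, tolerance = 1e-10)
  expect_equal(fit$beta1_hat, -0.0083, tolerance = 1e-10)
  expect_equal(max(abs(fit$residuals)), 0, tolerance = 1e-12)
  expect_true(all(fit$robust_weights == 1))
})

test_that("OLS matches the lm() normal-equations solution on noisy data", {
  withr::local_seed(23)
  d <- line_districts(cpr = runif(60, 5, 85))
  d$tfr <- d$tfr * exp(rnorm(60, 0, 0.15))
  fit <- fit_ols(d)
  ref <- stats::lm(log(tfr) ~ cpr, data = d)
  expect_equal(fit$beta0_hat, unname(coef(ref)[1]), tolerance = 1e-10)
  expect_equal(fit$beta1_hat, unname(coef(ref)[2]), tolerance = 1e-10)
  # residual identity e_i = log tfr_i - (b0 + b1 cpr_i)
  expect_equal(fit$residuals,
               log(d$tfr) - fit$beta0_hat - fit$beta1_hat * d$cpr,
               tolerance = 1e-10)
})

test_that("degenerate designs are refused", {
  expect_error(fit_ols(line_districts(cpr = c(10, 20))),
               class = "avertr_estimation_error")
  expect_error(fit_ols(line_districts(cpr = rep(40, 5))),
               class = "avertr_estimation_error")
  d <- line_districts(cpr = c(10, 20, 30))
  d$tfr[1] <- -1
  expect_error(fit_ols(d), class = "avertr_estimation_error")
})

test_that("robust fit equals OLS on clean data, with unit weights", {
  withr::local_seed(29)
  d <- line_districts(cpr = runif(80, 5, 85))
  d$tfr <- d$tfr * exp(rnorm(80, 0, 0.05))
  ols <- fit_ols(d)
  rob <- fit_robust(d)
  expect_true(rob$converged)
  expect_equal(rob$beta0_hat, ols$beta0_hat, tolerance = 1e-2)
  expect_equal(rob$beta1_hat, ols$beta1_hat, tolerance = 1e-2)
  expect_true(all(rob$robust_weights > 0.5))
})

test_that("a gross outlier is down-weighted and barely moves the slope", {
  withr::local_seed(31)
  cpr <- seq(5, 85, length.out = 100)
  d <- line_districts(cpr = cpr)
  d$tfr <- d$tfr * exp(rnorm(100, 0, 0.01))
  clean_slope <- fit_ols(d)$beta1_hat

  out <- d
  out$tfr[100] <- out$tfr[100] * exp(1) # gross outlier at high CPR
  ols_out <- fit_ols(out)
  rob_out <- fit_robust(out)

  expect_gt(abs(ols_out$beta1_hat - clean_slope) / abs(clean_slope), 0.05)
  expect_lt(abs(rob_out$beta1_hat - clean_slope) / abs(clean_slope), 0.01)
  expect_lt(rob_out$robust_weights[100], 0.05)

  # robust weights are nonincreasing in |residual|
  ord <- order(abs(rob_out$residuals))
  expect_true(all(diff(rob_out$robust_weights[ord]) <= 1e-12))
})

test_that("robust fit agrees with MASS::rlm bisquare as a cross-check", {
  skip_if_not_installed("MASS")
  withr::local_seed(37)
  d <- line_districts(cpr = runif(120, 5, 85))
  d$tfr <- d$tfr * exp(rnorm(120, 0, 0.1))
  d$tfr[c(7, 80)] <- d$tfr[c(7, 80)] * exp(c(1.2, -1.5))
  mine <- fit_robust(d)
  ref <- MASS::rlm(log(tfr) ~ cpr, data = d, psi = MASS::psi.bisquare,
                   maxit = 100)
  expect_equal(mine$beta1_hat, unname(coef(ref)[2]), tolerance = 0.02)
  expect_equal(mine$beta0_hat, unname(coef(ref)[1]), tolerance = 0.02)
})

test_that("district classification covers the four strata with its tie rule", {
  expect_equal(classify_group(2.0, 40), 1L)
  expect_equal(classify_group(3.0, 40), 2L)
  expect_equal(classify_group(2.0, 60), 3L)
  expect_equal(classify_group(3.0, 60), 4L)
  expect_equal(classify_group(2.2, 50), 3L) # ties: low TFR, high CPR

  # every point maps to exactly one group
  withr::local_seed(41)
  g <- classify_group(runif(500, 0.5, 6), runif(500, 0, 100))
  expect_true(all(g %in% 1:4))
  expect_equal(length(g), 500)
})

test_that("potential TFR preserves the district residual", {
  withr::local_seed(43)
  d <- line_districts(cpr = runif(50, 5, 85))
  d$tfr <- d$tfr * exp(rnorm(50, 0, 0.1))
  fit <- fit_robust(d)
  tfrp <- potential_tfr(d$tfr, d$cpr, fit)
  # algebraic identity: exp(log tfr - b1 cpr) == exp(b0 + resid)
  expect_equal(tfrp, exp(fit$beta0_hat + fit$residuals), tolerance = 1e-12)
  # a district with no contraceptive use is unchanged
  expect_equal(potential_tfr(2.5, 0, fit), 2.5)
  # negative slope + positive CPR => potential TFR above observed
  expect_true(all(tfrp >= d$tfr))
})

test_that("BA and PIB follow their defining ratios", {
  expect_equal(births_averted(2, 2, 500), 0)
  expect_equal(pib(2, 2), 0)
  # linear in total births
  expect_equal(births_averted(2, 2.5, 1000),
               10 * births_averted(2, 2.5, 100))
  expect_error(pib(0, 1), class = "avertr_estimation_error")

  # closed form under the log-linear fit: pib = 100 (exp(c cpr) - 1)
  withr::local_seed(47)
  d <- line_districts(cpr = runif(40, 5, 85))
  d$tfr <- d$tfr * exp(rnorm(40, 0, 0.1))
  fit <- fit_robust(d)
  tfrp <- potential_tfr(d$tfr, d$cpr, fit)
  expect_equal(pib(d$tfr, tfrp),
               100 * (exp(-fit$beta1_hat * d$cpr) - 1), tolerance = 1e-10)
})

test_that("pooled and stratified methods agree in degenerate cases", {
  withr::local_seed(53)
  d <- line_districts(cpr = runif(60, 5, 85))
  d$tfr <- d$tfr * exp(rnorm(60, 0, 0.08))

  # thresholds pushed outside the data range: Method 1 == Method 2
  m1 <- run_method1(d, tfr_threshold = 100, cpr_threshold = 200)
  m2 <- run_method2(d)
  expect_equal(m1$tfrp, m2$tfrp, tolerance = 1e-12)
  expect_equal(m1$pib, m2$pib, tolerance = 1e-12)

  # a flat generating relation yields zero averted births everywhere
  flat <- tibble::tibble(district_id = 1:10, state_id = 1L,
                         tfr = rep(2.5, 10), cpr = seq(10, 80, length.out = 10),
                         total_births_window = 100)
  mf <- run_method2(flat)
  expect_equal(mf$ba, rep(0, 10), tolerance = 1e-10)
  expect_equal(mf$pib, rep(0, 10), tolerance = 1e-10)
})

test_that("stratified fits recover group-specific slopes", {
  withr::local_seed(59)
  # four strata with their own generating lines around the 2.2/50 corners
  mk <- function(n, cpr_lo, cpr_hi, b0, b1) {
    cpr <- runif(n, cpr_lo, cpr_hi)
    tibble::tibble(district_id = 0L, state_id = 1L,
                   tfr = exp(b0 + b1 * cpr), cpr = cpr,
                   total_births_window = 100)
  }
  d <- dplyr::bind_rows(
    mk(40, 5, 45, 0.60, -0.0006),   # low TFR, low CPR
    mk(40, 5, 45, 1.30, -0.0068),   # high TFR, low CPR
    mk(40, 55, 85, 0.90, -0.0034),  # low TFR, high CPR
    mk(40, 55, 85, 1.55, -0.0059)   # high TFR, high CPR
  )
  d$district_id <- seq_len(nrow(d))
  keep <- classify_group(d$tfr, d$cpr) == rep(1:4, each = 40)
  d <- d[keep, ] # noiseless lines stray across the TFR boundary; keep cores
  m1 <- run_method1(d)
  fits <- attr(m1, "fits")
  slopes <- c(-0.0006, -0.0068, -0.0034, -0.0059)
  for (g in 1:4)
    expect_equal(fits[[as.character(g)]]$beta1_hat, slopes[g],
                 tolerance = 1e-6)
})

test_that("the pooled method overestimates in the low-TFR low-CPR stratum", {
  # districts drawn from one declining log-linear law; stratifying on the
  # observed TFR/CPR quadrants truncates the low-low group so its own fit
  # is much flatter than the pooled one, which therefore overstates its PIB
  cfg <- sim_config(beta0 = 1.2, beta1 = -0.0083, sigma_eps = 0.1,
                    seed = 61)
  tr <- simulate_district_truths(cfg)
  d <- tibble::tibble(district_id = tr$district_id, state_id = tr$state_id,
                      tfr = tr$tfr_true, cpr = tr$cpr_true,
                      total_births_window = 100)
  m1 <- run_method1(d)
  m2 <- run_method2(d)
  g1 <- m1$district_id[m1$group == "1"]
  expect_gt(mean(m2$pib[m2$district_id %in% g1]),
            mean(m1$pib[m1$group == "1"]))
})

test_that("undersized strata raise an informative error", {
  d <- line_districts(cpr = c(10, 20, 30, 60, 65, 70))
  d$tfr <- c(1.5, 1.6, 1.7, 3.0, 3.1, 3.2) # group 4 has 3, group 1 has 3
  d2 <- d[-1, ] # now group 1 has only 2
  expect_error(run_method1(d2), class = "avertr_estimation_error")
})

test_that("tidy, glance and autoplot work on fits", {
  d <- line_districts(cpr = seq(10, 80, 10))
  fit <- fit_robust(d)
  td <- tidy(fit)
  expect_equal(td$term, c("(Intercept)", "cpr"))
  expect_equal(td$estimate[2], fit$beta1_hat)
  gl <- glance(fit)
  expect_equal(gl$n_obs, 8)
  expect_s3_class(autoplot(fit), "ggplot")
  expect_output(print(fit), "IRLS|OLS")
  expect_equal(predict(fit, tibble::tibble(cpr = 0)), exp(fit$beta0_hat))
})
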