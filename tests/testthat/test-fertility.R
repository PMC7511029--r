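test_that("exposure splitting matches hand-computed single-group cases", {
  t <- 1393L
  # in her early thirties for the whole window: 3 woman-years in 30-34
  w <- make_women(1, dob_cmc = t - 400L, interview_cmc = t)
  e <- compute_exposure(w, empty_births())
  expect_equal(sum(e$exposure), 3)
  expect_equal(e$exposure[e$age_group == "30-34"], 3)

  # turning 20 exactly 18 months before interview: 1.5 + 1.5 split
  w2 <- make_women(1, dob_cmc = t - 18L - 240L, interview_cmc = t)
  e2 <- compute_exposure(w2, empty_births())
  expect_equal(e2$exposure[e2$age_group == "15-19"], 1.5)
  expect_equal(e2$exposure[e2$age_group == "20-24"], 1.5)

  # linearity in the sampling weight
  w3 <- make_women(1, dob_cmc = t - 400L, interview_cmc = t, weight = 2.5)
  e3 <- compute_exposure(w3, empty_births())
  expect_equal(sum(e3$exposure), 7.5)
})

test_that("exposure equals the month-by-month brute-force oracle exactly", {
  withr::local_seed(101)
  n <- 1000
  t <- 1393L
  women <- make_women(
    n,
    district_id = sample(1:5, n, replace = TRUE),
    dob_cmc = t - sample(180:599, n, replace = TRUE),
    interview_cmc = t,
    weight = round(runif(n, 0.2, 3), 3)
  )
  # random births scattered around (and beyond) the window
  births <- tibble::tibble(
    woman_id = sample(women$woman_id, 800, replace = TRUE),
    birth_cmc = t - sample(1:60, 800, replace = TRUE)
  )
  births <- dplyr::semi_join(
    births,
    dplyr::mutate(women, ok = TRUE), by = "woman_id")
  got <- compute_exposure(women, births)
  want <- brute_exposure(women, births)
  merged <- dplyr::left_join(got, want, by = c("district_id", "age_group"),
                             suffix = c("", "_oracle"))
  merged$exposure_oracle[is.na(merged$exposure_oracle)] <- 0
  merged$births_oracle[is.na(merged$births_oracle)] <- 0
  expect_equal(merged$exposure, merged$exposure_oracle)
  expect_equal(merged$births, merged$births_oracle)
})

test_that("per-woman exposure never exceeds the window length", {
  withr::local_seed(7)
  t <- 1393L
  for (age_m in c(181, 200, 420, 595, 599)) {
    w <- make_women(1, dob_cmc = t - age_m, interview_cmc = t)
    e <- compute_exposure(w, empty_births())
    expect_lte(sum(e$exposure), 3)
  }
  # equality iff aged 15-49 throughout the window
  w <- make_women(1, dob_cmc = t - 420L, interview_cmc = t)
  expect_equal(sum(compute_exposure(w, empty_births())$exposure), 3)
})

test_that("TFR closed forms and error cases", {
  labs <- levels(age_group(20))
  # one birth per 10 woman-years in each of the 7 groups: TFR = 3.5
  e <- tibble::tibble(district_id = 1, age_group = factor(labs, labs),
                      exposure = 10, births = 1)
  expect_equal(compute_tfr(e)$tfr, 3.5)

  # childless district: TFR 0
  e0 <- dplyr::mutate(e, births = 0)
  expect_equal(compute_tfr(e0)$tfr, 0)

  # births without exposure cannot form a rate
  ebad <- dplyr::mutate(e, exposure = c(0, rep(10, 6)))
  expect_error(compute_tfr(ebad), class = "avertr_estimation_error")
})

test_that("TFR is invariant to uniform weight rescaling", {
  cfg <- sim_config(n_states = 1, districts_per_state = 2,
                    women_per_district = 150, seed = 31)
  s <- simulate_survey(cfg)
  base <- estimate_districts(s$women, s$births)
  scaled <- estimate_districts(
    dplyr::mutate(s$women, weight = weight * 7.3), s$births)
  expect_equal(scaled$tfr, base$tfr)
  expect_equal(scaled$cpr, base$cpr)
})

test_that("TFR interval matches the closed-form Poisson delta method", {
  labs <- levels(age_group(20))
  e <- tibble::tibble(
    district_id = 1, age_group = factor(labs, labs),
    exposure = c(0, 1000, 0, 0, 0, 0, 0),
    births = c(0, 100, 0, 0, 0, 0, 0)
  )
  ci <- compute_tfr_ci(e)
  z <- qnorm(0.975)
  expect_equal(ci$tfr, 0.5)
  expect_equal(ci$tfr_ci_low, 0.5 * exp(-z * 0.1))
  expect_equal(ci$tfr_ci_high, 0.5 * exp(z * 0.1))

  # interval shrinks as counts grow at fixed rates
  e_big <- dplyr::mutate(e, exposure = exposure * 100, births = births * 100)
  ci_big <- compute_tfr_ci(e_big)
  expect_lt(ci_big$tfr_ci_high - ci_big$tfr_ci_low,
            ci$tfr_ci_high - ci$tfr_ci_low)

  # all groups empty: degenerate interval with a warning
  e_none <- dplyr::mutate(e, births = 0)
  expect_warning(ci0 <- compute_tfr_ci(e_none), "undefined")
  expect_equal(c(ci0$tfr_ci_low, ci0$tfr_ci_high), c(0, 0))
})

test_that("CI bounds bracket the point estimate across simulated districts", {
  cfg <- sim_config(n_states = 2, districts_per_state = 5,
                    women_per_district = 120, seed = 13)
  s <- simulate_survey(cfg)
  est <- estimate_districts(s$women, s$births)
  expect_true(all(est$tfr_ci_low <= est$tfr & est$tfr <= est$tfr_ci_high))
})
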