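#' Default age pattern of fertility
#'
#' A fixed normalized seven-element age-specific fertility shape (one weight
#' per 5-year group, 15-19 through 45-49, summing to 1) resembling a typical
#' high-fertility schedule that peaks at ages 20-29. The simulator rescales
#' it so that `5 * sum(ASFR)` equals each district's target TFR; only the
#' scaled total matters downstream, the shape fixes how births spread over
#' maternal ages.
#'
#' @format Named numeric vector of length 7.
#' @export
asfr_shape_default <- c(
  "15-19" = 0.10, "20-24" = 0.26, "25-29" = 0.25, "30-34" = 0.18,
  "35-39" = 0.12, "40-44" = 0.06, "45-49" = 0.03
)

#' Simulation configuration
#'
#' Bundles and validates every knob of the synthetic-survey generator. The
#' defaults describe the study conditions the package is tested under: 640
#' districts (32 states x 20), a district-level log-linear TFR-CPR law
#' `log TFR = beta0 + beta1 * CPR + eps` with `eps ~ N(0, sigma_eps)`,
#' district CPR drawn uniformly on the observed all-India district range
#' 2.7-84.8 percent, and interviews in January 2016.
#'
#' @param n_states Number of states.
#' @param districts_per_state Districts in each state.
#' @param women_per_district Women aged 15-49 sampled per district.
#' @param beta0 True intercept of log TFR on CPR (dimensionless).
#' @param beta1 True slope per percentage point of CPR; must be `<= 0`.
#' @param sigma_eps Standard deviation of the district-level residual.
#' @param cpr_range Length-2 numeric, low < high, both in `[0, 100]`:
#'   district CPRs are drawn uniformly on this interval.
#' @param interview_cmc Interview month as a century month code.
#' @param married_fraction Fraction of women currently married (in union).
#' @param asfr_shape Normalized 7-element age pattern; see
#'   [asfr_shape_default].
#' @param seed Integer seed for the global stream; per-district substreams
#'   are derived by stable hashing so adding districts never perturbs
#'   existing ones.
#' @return A validated list of class `sim_config`.
#' @examples
#' cfg <- sim_config(n_states = 2, districts_per_state = 3,
#'                   women_per_district = 50)
#' @export
sim_config <- function(n_states = 32L,
                       districts_per_state = 20L,
                       women_per_district = 250L,
                       beta0 = 1.2,
                       beta1 = -0.0083,
                       sigma_eps = 0.1,
                       cpr_range = c(2.7, 84.8),
                       interview_cmc = cmc(2016, 1),
                       married_fraction = 0.75,
                       asfr_shape = asfr_shape_default,
                       seed = 1L) {
  if (n_states < 1 || districts_per_state < 1 || women_per_district < 1)
    abort("counts `n_states`, `districts_per_state`, `women_per_district` must be >= 1",
          class = "avertr_config_error")
  if (sigma_eps < 0)
    abort("`sigma_eps` must be >= 0", class = "avertr_config_error")
  if (length(cpr_range) != 2 || cpr_range[1] >= cpr_range[2] ||
      cpr_range[1] < 0 || cpr_range[2] > 100)
    abort("`cpr_range` must be (low, high) with 0 <= low < high <= 100",
          class = "avertr_config_error")
  if (beta1 > 0)
    abort("`beta1` must be <= 0 (contraception cannot raise fertility here)",
          class = "avertr_config_error")
  if (married_fraction <= 0 || married_fraction > 1)
    abort("`married_fraction` must be in (0, 1]", class = "avertr_config_error")
  if (length(asfr_shape) != 7 || any(asfr_shape < 0) || sum(asfr_shape) <= 0)
    abort("`asfr_shape` must be 7 nonnegative values with positive sum",
          class = "avertr_config_error")
  structure(
    list(
      n_states = as.integer(n_states),
      districts_per_state = as.integer(districts_per_state),
      women_per_district = as.integer(women_per_district),
      beta0 = beta0, beta1 = beta1, sigma_eps = sigma_eps,
      cpr_range = as.numeric(cpr_range),
      interview_cmc = as.integer(interview_cmc),
      married_fraction = married_fraction,
      asfr_shape = asfr_shape / sum(asfr_shape),
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

# Stable substream seed: mixes the global seed, a district key and a stage
# tag into [0, 2^31 - 2]. Pure double arithmetic, exact below 2^53.
substream_seed <- function(seed, key, stage) {
  m <- 2147483647
  ((seed %% m) * 48271 + key * 30269 + stage * 7919 + 12345) %% m
}

#' Generate the latent district truths
#'
#' Draws, per district, a true CPR uniform on `cpr_range` and a residual
#' `eps ~ N(0, sigma_eps)`, and sets the true TFR by the log-linear law
#' `tfr_true = exp(beta0 + beta1 * cpr_true + eps_true)`. These latent pairs
#' are what the downstream regression should recover; keep the returned
#' table as the oracle for recovery tests.
#'
#' @param config A [sim_config()].
#' @return Tibble with `district_id`, `state_id`, `cpr_true`, `eps_true`,
#'   `tfr_true`, one row per district, deterministic given `config$seed`.
#' @export
simulate_district_truths <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  grid <- tidyr::expand_grid(
    state_id = seq_len(config$n_states),
    dno = seq_len(config$districts_per_state)
  )
  grid$district_id <- grid$state_id * 1000L + grid$dno
  draws <- purrr::map(grid$district_id, function(d) {
    withr::with_seed(substream_seed(config$seed, d, 1L), {
      cpr <- runif(1, config$cpr_range[1], config$cpr_range[2])
      eps <- if (config$sigma_eps > 0) rnorm(1, 0, config$sigma_eps) else 0
      c(cpr = cpr, eps = eps)
    })
  })
  cpr_true <- purrr::map_dbl(draws, "cpr")
  eps_true <- purrr::map_dbl(draws, "eps")
  tibble::tibble(
    district_id = grid$district_id,
    state_id = grid$state_id,
    cpr_true = cpr_true,
    eps_true = eps_true,
    tfr_true = exp(config$beta0 + config$beta1 * cpr_true + eps_true)
  )
}

# Months each woman spends in each 5-year age group inside the reference
# window [interview - window, interview - 1]. Row per woman x group.
window_group_months <- function(dob_cmc, interview_cmc, window_months = 36L) {
  n <- length(dob_cmc)
  out <- tidyr::expand_grid(
    i = seq_len(n),
    g = seq_along(age_group_starts)
  )
  dob <- dob_cmc[out$i]
  lo_g <- dob + 12L * (age_group_starts[out$g])           # first month in group
  hi_g <- dob + 12L * (age_group_starts[out$g] + 5L) - 1L # last month in group
  win_lo <- interview_cmc - window_months
  win_hi <- interview_cmc - 1L
  out$months <- pmax(0L, pmin(hi_g, win_hi) - pmax(lo_g, win_lo) + 1L)
  out
}

#' Generate woman-level microdata from district truths
#'
#' Builds, per district, `women_per_district` women aged 15-49 at interview
#' with ages uniform over the 420 eligible months (hence uniform across the
#' seven 5-year groups), a currently-married flag with probability
#' `married_fraction`, and a contraceptive-use flag for married women with
#' probability `cpr_true / 100`. Births over the reference window are a
#' Poisson process whose age-group rates follow `asfr_shape` rescaled so
#' `5 * sum(ASFR)` equals the district's `tfr_true`. Only married women bear
#' births, at rate `ASFR / married_fraction`, so all-women age-specific
#' rates match the schedule that the fertility estimator measures.
#'
#' @param truths Tibble from [simulate_district_truths()].
#' @param config The same [sim_config()].
#' @param window_months Length of the birth window generated before the
#'   interview, in months.
#' @return List with tibbles `women` (woman_id, state_id, district_id,
#'   dob_cmc, interview_cmc, currently_married, using_any_method, weight)
#'   and `births` (woman_id, birth_cmc).
#' @export
simulate_microdata <- function(truths, config, window_months = 36L) {
  stopifnot(inherits(config, "sim_config"), nrow(truths) >= 1)
  per_district <- purrr::map(seq_len(nrow(truths)), function(r) {
    d <- truths$district_id[r]
    withr::with_seed(substream_seed(config$seed, d, 2L), {
      n <- config$women_per_district
      age_months <- sample(180:599, n, replace = TRUE)
      dob <- config$interview_cmc - age_months
      married <- rbinom(n, 1, config$married_fraction) == 1
      using <- married & rbinom(n, 1, truths$cpr_true[r] / 100) == 1
      women <- tibble::tibble(
        woman_id = d * 100000 + seq_len(n),
        state_id = truths$state_id[r],
        district_id = d,
        dob_cmc = as.integer(dob),
        interview_cmc = config$interview_cmc,
        currently_married = married,
        using_any_method = using,
        weight = 1.0
      )
      # per-woman-month birth rate over the window
      asfr <- config$asfr_shape * truths$tfr_true[r] / 5
      gm <- window_group_months(dob, config$interview_cmc, window_months)
      gm$rate <- ifelse(married[gm$i], asfr[gm$g] / config$married_fraction / 12,
                        0) * gm$months
      lambda <- tapply(gm$rate, gm$i, sum)
      n_births <- rpois(n, lambda)
      births <- if (sum(n_births) == 0) {
        tibble::tibble(woman_id = double(), birth_cmc = integer())
      } else {
        idx <- which(n_births > 0)
        win <- (config$interview_cmc - window_months):(config$interview_cmc - 1L)
        rows <- purrr::map(idx, function(i) {
          age_y <- (win - dob[i]) %/% 12L
          p <- ifelse(age_y >= 15 & age_y <= 49,
                      asfr[(age_y - 15L) %/% 5L + 1L], 0)
          if (sum(p) == 0) return(NULL) # woman in range at interview only
          tibble::tibble(
            woman_id = women$woman_id[i],
            birth_cmc = as.integer(sample(win, n_births[i], replace = TRUE,
                                          prob = p))
          )
        })
        dplyr::bind_rows(rows)
      }
      list(women = women, births = births)
    })
  })
  list(
    women = dplyr::bind_rows(purrr::map(per_district, "women")),
    births = dplyr::bind_rows(purrr::map(per_district, "births"))
  )
}

#' Simulate a complete synthetic survey
#'
#' Convenience wrapper: draws district truths and the woman-level microdata
#' in one call, optionally writing the standard CSV files plus a
#' `truths.csv` sidecar for recovery tests.
#'
#' @inheritParams simulate_microdata
#' @param config A [sim_config()].
#' @param out_dir Optional directory; when given, writes `women.csv`,
#'   `births.csv` and `truths.csv` there.
#' @return List with `women`, `births`, `truths` tibbles (invisibly when
#'   `out_dir` is given).
#' @export
simulate_survey <- function(config, window_months = 36L, out_dir = NULL) {
  truths <- simulate_district_truths(config)
  micro <- simulate_microdata(truths, config, window_months)
  res <- list(women = micro$women, births = micro$births, truths = truths)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    readr::write_csv(res$women, file.path(out_dir, "women.csv"))
    readr::write_csv(res$births, file.path(out_dir, "births.csv"))
    readr::write_csv(res$truths, file.path(out_dir, "truths.csv"))
    return(invisible(res))
  }
  res
}
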