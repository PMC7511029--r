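# Builders for tiny hand-made microdata and independent brute-force oracles.

make_women <- function(n = 1, district_id = 1L, state_id = 1L,
                       dob_cmc = 1000L, interview_cmc = 1393L,
                       currently_married = TRUE, using_any_method = FALSE,
                       weight = 1) {
  tibble::tibble(
    woman_id = seq_len(n),
    state_id = state_id,
    district_id = district_id,
    dob_cmc = as.integer(dob_cmc),
    interview_cmc = as.integer(interview_cmc),
    currently_married = currently_married,
    using_any_method = using_any_method,
    weight = weight
  )
}

empty_births <- function() {
  tibble::tibble(woman_id = double(), birth_cmc = integer())
}

# Month-by-month brute-force exposure/birth accumulation: the oracle that
# compute_exposure must match exactly (integer-month arithmetic).
brute_exposure <- function(women, births, window_months = 36L) {
  labs <- paste(seq(15, 45, 5), seq(19, 49, 5), sep = "-")
  acc <- list()
  add <- function(d, g, exposure, b) {
    key <- paste(d, g)
    cur <- acc[[key]] %||% c(exposure = 0, births = 0)
    acc[[key]] <<- cur + c(exposure = exposure, births = b)
  }
  for (i in seq_len(nrow(women))) {
    t <- women$interview_cmc[i]
    for (m in (t - window_months):(t - 1L)) {
      age <- (m - women$dob_cmc[i]) %/% 12L
      if (age >= 15 && age <= 49)
        add(women$district_id[i], labs[(age - 15) %/% 5 + 1],
            women$weight[i] / 12, 0)
    }
  }
  for (j in seq_len(nrow(births))) {
    i <- match(births$woman_id[j], women$woman_id)
    t <- women$interview_cmc[i]
    bm <- births$birth_cmc[j]
    if (bm >= t - window_months && bm <= t - 1L) {
      age <- (bm - women$dob_cmc[i]) %/% 12L
      if (age >= 15 && age <= 49)
        add(women$district_id[i], labs[(age - 15) %/% 5 + 1],
            0, women$weight[i])
    }
  }
  keys <- strsplit(names(acc), " ")
  tibble::tibble(
    district_id = as.numeric(vapply(keys, `[`, "", 1)),
    age_group = factor(vapply(keys, `[`, "", 2), levels = labs),
    exposure = unname(vapply(acc, `[[`, 0, "exposure")),
    births = unname(vapply(acc, `[[`, 0, "births"))
  )
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# Exact district-level data on a given log-linear line (no noise), shaped
# like the estimates table the counterfactual stage consumes.
line_districts <- function(cpr, beta0 = 1.199, beta1 = -0.0083,
                           births = 100) {
  tibble::tibble(
    district_id = seq_along(cpr),
    state_id = 1L,
    tfr = exp(beta0 + beta1 * cpr),
    cpr = cpr,
    total_births_window = births
  )
}
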