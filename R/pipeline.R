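#' Run the full births-averted pipeline
#'
#' Orchestrates simulate -> estimate -> avert -> aggregate -> report from
#' one configuration, writing every stage's CSV plus a JSON run manifest
#' (configuration echo and hash, seed, package version, per-fit
#' coefficients and iteration counts) so a run is reproducible and
#' auditable. Re-running with an identical configuration produces
#' identical outputs.
#'
#' Configuration keys (all optional, defaults in parentheses): `sim` — a
#' list of [sim_config()] arguments; `window_months` (36); `ci_level`
#' (0.95); `method` ("both"); `tfr_threshold` (2.2); `cpr_threshold` (50);
#' `tfr_replacement` (2.1); `cpr_cut` (50); `split_tfr` (2.1).
#'
#' @param config A list, or path to a YAML file, of configuration values.
#' @param out_dir Output directory (created if needed).
#' @param seed Optional integer; overrides `config$sim$seed`
#'   (CLI-over-config precedence).
#' @return Invisibly, a list with all stage tables and the fit objects.
#' @export
run_pipeline <- function(config = list(), out_dir, seed = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  sim_args <- config$sim %||% list()
  if (!is.null(seed)) sim_args$seed <- as.integer(seed)
  cfg <- do.call(sim_config, sim_args)
  window_months <- config$window_months %||% 36L
  ci_level <- config$ci_level %||% 0.95
  method <- as.character(config$method %||% "both")
  tfr_threshold <- config$tfr_threshold %||% 2.2
  cpr_threshold <- config$cpr_threshold %||% 50

  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  survey <- simulate_survey(cfg, window_months = window_months,
                            out_dir = out_dir)
  validate_microdata(survey$women, survey$births)

  estimates <- estimate_districts(survey$women, survey$births,
                                  window_months = window_months,
                                  ci_level = ci_level)
  write_estimates(estimates, file.path(out_dir, "district_estimates.csv"))

  usable <- dplyr::filter(estimates, !is.na(.data$cpr), .data$tfr > 0)
  if (nrow(usable) < nrow(estimates))
    warn(sprintf("%d district(s) with undefined CPR or zero TFR excluded",
                 nrow(estimates) - nrow(usable)))

  averted <- estimate_births_averted(usable, method = method,
                                     tfr_threshold = tfr_threshold,
                                     cpr_threshold = cpr_threshold)
  write_estimates(averted, file.path(out_dir, "averted.csv"))

  state_agg <- aggregate_averted(averted, usable, "state",
                                 config$tfr_replacement %||% 2.1,
                                 config$cpr_cut %||% 50)
  national <- aggregate_averted(averted, usable, "national",
                                config$tfr_replacement %||% 2.1,
                                config$cpr_cut %||% 50)
  write_estimates(state_agg, file.path(out_dir, "state_aggregates.csv"))
  write_estimates(national, file.path(out_dir, "national_aggregate.csv"))

  sens <- pib_distribution(averted, usable,
                           split_tfr = config$split_tfr %||% 2.1)
  write_estimates(sens, file.path(out_dir, "sensitivity.csv"))

  fits <- attr(averted, "fits")
  manifest <- list(
    package_version = as.character(utils::packageVersion("avertr")),
    seed = cfg$seed,
    config = config[setdiff(names(config), "sim")],
    sim_config = cfg[setdiff(names(cfg), "asfr_shape")],
    asfr_shape = as.numeric(cfg$asfr_shape),
    config_hash = rlang::hash(list(config, sim_args)),
    fits = purrr::map(fits, function(f)
      list(kind = f$kind, beta0_hat = f$beta0_hat, beta1_hat = f$beta1_hat,
           n_obs = f$n_obs, n_iter = f$n_iter, converged = f$converged))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(survey = survey, estimates = estimates, averted = averted,
                 state_aggregates = state_agg, national = national,
                 sensitivity = sens, fits = fits, manifest = manifest))
}

`%||%` <- function(x, y) if (is.null(x)) y else x
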