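#' Configuration for a full synthetic experiment
#'
#' Bundles every setting of the simulate / fit / validate / optimize /
#' report chain into one serializable object. Rerunning [run_experiment()]
#' with an identical config and seed reproduces all outputs bit-for-bit
#' (modulo floating-point formatting of the writing locale, which is fixed
#' to C inside the run).
#'
#' @param n_counties,n_years,crops,start_year generator dimensions.
#' @param mode generator mode, `"faithful"` or `"misspecified"`.
#' @param mismatch_fraction share of counties with a non-optimal observed
#'   crop before calibration.
#' @param scenario_shifts,het_sd passed to [simulate_study()].
#' @param variance_mode,chains,warmup,draws sampler settings.
#' @param split_frac temporal-split point as a fraction of the year range.
#' @param cv_mean reference-mean convention for CV R-squared.
#' @param n_mc_draws posterior draws propagated through the optimizer.
#' @param switching_costs sweep grid (USD/acre); the first entry is used
#'   for the headline Monte Carlo run.
#' @param calibration_epsilon,calibration_mode hidden-cost calibration
#'   settings.
#' @param seed root seed; per-stage seeds are derived deterministically.
#' @return list of class `experiment_config`.
#' @export
experiment_config <- function(n_counties = 40, n_years = 25,
                              crops = c("corn", "soybeans", "wheat"),
                              start_year = 1985,
                              mode = "faithful", mismatch_fraction = 0.4,
                              scenario_shifts = NULL, het_sd = 0.15,
                              variance_mode = "uniform", chains = 2,
                              warmup = 300, draws = 500,
                              split_frac = 0.75, cv_mean = "test",
                              n_mc_draws = 20,
                              switching_costs = c(0, 50, 100, 200, 500, 5000),
                              calibration_epsilon = 1,
                              calibration_mode = "raise_competitors",
                              seed = 1) {
  cfg <- as.list(environment())
  stopifnot(n_counties >= 2, n_years >= 2, length(crops) >= 1,
            split_frac > 0, split_frac < 1, n_mc_draws >= 1)
  if (!variance_mode %in% c("uniform", "county")) {
    cs_abort("variance_mode must be 'uniform' or 'county'")
  }
  structure(cfg, class = "experiment_config")
}

#' Run the full synthetic experiment
#'
#' Executes the whole chain: synthetic-data generation, per-crop
#' hierarchical fits, the OLS/Bayes comparison grid under a temporal split,
#' hidden-cost calibration, posterior-draw Monte Carlo reallocation with a
#' switching-cost sweep, and a machine-readable manifest. Every output is
#' a plain delimited table under `dir`; the manifest records the config,
#' the derived per-stage seeds, and an MD5 hash of every file, so a rerun
#' with the same config is verifiably identical.
#'
#' With `resume = TRUE`, computation (which is deterministic given the
#' config) is re-run but only missing output files are rewritten, so a
#' deleted intermediate is reproduced identically.
#'
#' @param config an [experiment_config()].
#' @param dir output directory (created if needed).
#' @param resume rewrite only missing outputs (see Details).
#' @param quiet suppress progress messages.
#' @return invisibly, a list with the in-memory objects (`study`, `fits`,
#'   `comparison`, `econ_cal`, `mc`, `sweep`, `manifest`).
#' @export
run_experiment <- function(config = experiment_config(), dir,
                           resume = FALSE, quiet = FALSE) {
  stopifnot(inherits(config, "experiment_config"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(sprintf(...))
  emit <- function(obj, file) {
    path <- file.path(dir, file)
    if (!resume || !file.exists(path)) write_tsv_plain(obj, path)
    path
  }
  old_locale <- Sys.getlocale("LC_NUMERIC")
  on.exit(suppressWarnings(Sys.setlocale("LC_NUMERIC", old_locale)))
  suppressWarnings(Sys.setlocale("LC_NUMERIC", "C"))

  say("stage 1/5: simulate (%d counties x %d years, %d crop(s), %s mode)",
      config$n_counties, config$n_years, length(config$crops), config$mode)
  study <- withCallingHandlers(
    simulate_study(
      n_counties = config$n_counties, n_years = config$n_years,
      crops = config$crops, start_year = config$start_year,
      config = sim_config(mode = config$mode,
                          mismatch_fraction = config$mismatch_fraction),
      scenario_shifts = config$scenario_shifts, het_sd = config$het_sd,
      seed = derive_seed(config$seed, "simulate")),
    error = function(e) cs_abort(paste0("stage simulate failed: ",
                                        conditionMessage(e))))
  emit(study$covariates, "covariates.tsv")
  emit(study$panel, "panel.tsv")
  emit(study$economics, "economics.tsv")
  emit(study$scenarios, "scenarios.tsv")

  panel_std <- standardize_panel(study$panel, base_year = config$start_year)

  say("stage 2/5: fit hierarchical model per crop (%d chains x %d draws)",
      config$chains, config$draws)
  fits <- lapply(setNames(config$crops, config$crops), function(cr) {
    fit <- fit_hier(panel_std[panel_std$crop == cr, ],
                    covariates_for_crop(study$covariates, cr),
                    hier_spec(variance_mode = config$variance_mode),
                    chains = config$chains, warmup = config$warmup,
                    draws = config$draws,
                    seed = derive_seed(config$seed, paste0("fit_", cr)))
    if (!resume || !file.exists(file.path(dir, paste0("posterior_", cr, ".tsv")))) {
      write_posterior(fit, file.path(dir, paste0("posterior_", cr, ".tsv")))
    }
    fit
  })

  split_year <- config$start_year +
    floor(config$split_frac * (config$n_years - 1))
  say("stage 3/5: model comparison grid (split at %d)", split_year)
  comparison <- run_comparison(
    panel_std, study$covariates,
    split_year = split_year, cv_mean = config$cv_mean,
    chains = config$chains, warmup = config$warmup, draws = config$draws,
    seed = derive_seed(config$seed, "compare"))
  emit(comparison, "comparison.tsv")

  say("stage 4/5: calibrate hidden costs and optimize (%d draws)",
      config$n_mc_draws)
  # calibration against point-predicted baseline yields from the fits
  base_scen <- study$scenarios[study$scenarios$period ==
                                 study$scenarios$period[1], ] |>
    dplyr::mutate(period = "baseline")
  clim <- attr(study$panel, "climatology")
  base_scen <- clim |>
    dplyr::mutate(period = "baseline",
                  t = max(study$panel$year) - config$start_year,
                  .before = 1)
  yields_hat <- dplyr::bind_rows(lapply(config$crops, function(cr) {
    rows <- base_scen[base_scen$crop == cr, ]
    tibble::tibble(
      county_id = rows$county_id, crop = cr,
      expected_yield = exp(point_predict(
        fits[[cr]], rows,
        new_covariates = covariates_for_crop(study$covariates, cr))))
  }))
  econ_cal <- calibrate_hidden_costs(study$economics, yields = yields_hat,
                                     epsilon = config$calibration_epsilon,
                                     mode = config$calibration_mode)
  emit(econ_cal, "economics_calibrated.tsv")

  scen_all <- dplyr::bind_rows(base_scen, study$scenarios)
  mc <- monte_carlo_optimize(fits, econ_cal, scen_all, study$covariates,
                             n_draws = config$n_mc_draws,
                             switching_cost = config$switching_costs[1],
                             seed = derive_seed(config$seed, "mc"))
  emit(mc$per_draw, "mc_per_draw.tsv")
  emit(mc$summary, "mc_summary.tsv")
  emit(mc$flows, "mc_flows.tsv")
  emit(mc$allocations, "allocations.tsv")

  # switching-cost sweep on the posterior-mean baseline surface
  surf0 <- yields_hat |>
    dplyr::inner_join(dplyr::select(econ_cal, "county_id", "crop", "price",
                                    "cost"),
                      by = c("county_id", "crop")) |>
    dplyr::mutate(profit = .data$price * .data$expected_yield - .data$cost)
  sweep <- switching_cost_sweep(surf0, econ_cal,
                                costs = config$switching_costs)
  emit(sweep, "switching_cost_sweep.tsv")

  say("stage 5/5: manifest")
  files <- sort(list.files(dir, pattern = "\\.tsv$"))
  manifest <- list(
    package = "cropshift",
    version = as.character(utils::packageVersion("cropshift")),
    config = unclass(config),
    stage_seeds = list(
      simulate = derive_seed(config$seed, "simulate"),
      fit = sapply(config$crops, function(cr)
        derive_seed(config$seed, paste0("fit_", cr))),
      compare = derive_seed(config$seed, "compare"),
      mc = derive_seed(config$seed, "mc")),
    files = as.list(tools::md5sum(file.path(dir, files)))
  )
  names(manifest$files) <- files
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(study = study, fits = fits, comparison = comparison,
                 econ_cal = econ_cal, mc = mc, sweep = sweep,
                 manifest = manifest, dir = dir))
}

#' Hyperparameter interval plot for a hierarchical fit
#'
#' @param object a [fit_hier()] result.
#' @param ... unused.
#' @return ggplot of posterior means and 95% intervals for the
#'   hyper-coefficients (covariate loadings per model component).
#' @export
autoplot.hier_fit <- function(object, ...) {
  td <- tidy(object) |>
    dplyr::filter(startsWith(.data$term, "gamma_")) |>
    tidyr::separate_wider_regex(
      "term", c("gamma_", component = "[a-z]+", "_", covariate = ".*"))
  ggplot2::ggplot(td, ggplot2::aes(x = .data$estimate,
                                   y = .data$covariate)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, color = "grey60") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$conf.low,
                                          xmax = .data$conf.high)) +
    ggplot2::facet_wrap(~component, scales = "free_x") +
    ggplot2::labs(x = "posterior mean and 95% interval", y = NULL) +
    ggplot2::theme_minimal()
}
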