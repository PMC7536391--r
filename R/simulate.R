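#' Generator configuration for synthetic county panels
#'
#' All constants of the synthetic-data generator live in this one
#' configuration object: covariate distributions, the true hierarchical
#' parameters, weather-predictor distributions, the missingness mechanism,
#' and the economics tables. Defaults are chosen to resemble a US-style
#' county panel (mean temperatures spanning roughly 5-25 C, warmer counties
#' wetter, yields around 100 units/acre with ~15% interannual noise) and are
#' documented in the methods vignette.
#'
#' Two modes are supported. In `"faithful"` mode the joint distribution of
#' the generated data matches the hierarchical model's likelihood exactly.
#' In `"misspecified"` mode additional county-idiosyncratic, heavy-tailed
#' noise is added to the county coefficients -- variation that the county
#' covariates cannot explain -- which is the regime where partial pooling
#' has real work to do and where unpenalized fixed-effects regressions
#' over-fit.
#'
#' @param mode `"faithful"` or `"misspecified"` (see Details).
#' @param mismatch_fraction fraction of counties whose designated observed
#'   crop is deliberately not the profit argmax, so hidden-cost calibration
#'   has work to do (default 0.4).
#' @param hyper optional named list overriding entries of the true
#'   hyperparameters (`a0`, `a`, `b0`, `B`, `sigma_alpha`, `sigma_beta`,
#'   `sigma`).
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(mode = c("faithful", "misspecified"),
                       mismatch_fraction = 0.4,
                       hyper = NULL) {
  mode <- match.arg(mode)
  covar_names <- c("mean_temp", "isothermality", "temp_seasonality",
                   "annual_precip", "precip_seasonality",
                   "irrigation_fraction")
  B <- rbind(
    t   = c(0.002,  0.000, -0.001,  0.001,  0.000,  0.002),
    cdi = c(-0.020, 0.000,  0.000,  0.030, -0.010,  0.040),
    gdd = c(-0.030, 0.010,  0.000,  0.020,  0.000,  0.010),
    edd = c(0.060, -0.010, -0.020,  0.020,  0.000,  0.040)
  )
  colnames(B) <- covar_names
  truth <- list(
    a0 = 4.6,
    a = c(t = 0.010, cdi = -0.12, gdd = 0.15, edd = -0.20),
    b0 = setNames(c(-0.06, 0.01, -0.02, 0.08, -0.02, 0.05), covar_names),
    B = B,
    sigma_alpha = 0.15,
    sigma_beta = c(t = 0.004, cdi = 0.03, gdd = 0.03, edd = 0.05),
    sigma = 0.15
  )
  if (!is.null(hyper)) {
    for (nm in names(hyper)) truth[[nm]] <- hyper[[nm]]
  }
  structure(list(
    mode = mode,
    covar_names = covar_names,
    covariates = list(
      mean_temp = c(mean = 15, sd = 4.5, min = 5, max = 25),
      annual_precip = c(intercept = 800, slope = 35, sd = 180,
                        min = 150, max = 2200),
      isothermality = c(mean = 0.45, sd = 0.07, min = 0.2, max = 0.8),
      temp_seasonality = c(mean = 8, sd = 1.5, min = 2),
      precip_seasonality = c(mean = 30, sd = 8, min = 5),
      irrigation = c(shape1 = 0.8, shape2 = 3)
    ),
    truth = truth,
    misspec = list(alpha = 0.10,
                   beta = c(t = 0.008, cdi = 0.05, gdd = 0.05, edd = 0.08),
                   df = 4),
    predictors = list(
      gdd = c(mu0 = 1800, per_degC = 80, sd = 120),
      edd = c(mu0 = 40, per_degC = 7, sd = 25),
      cdi = c(q0 = -1.0, per_degC = 0.06, per_mm = -0.0012, sd = 0.5)
    ),
    missingness = list(profit_quantile = 0.15, dropout = 0.02),
    economics = list(
      price0 = c(barley = 2.5, corn = 4, cotton = 5.5, rice = 6.5,
                 soybeans = 4.5, wheat = 3),
      cost0 = c(barley = 123, corn = 300, cotton = 400, rice = 499,
                soybeans = 250, wheat = 150),
      price_sdlog = 0.05, cost_sd = 25, profit_floor = 10,
      land_meanlog = log(5e4), land_sdlog = 0.4,
      share_obs = 6, share_other = 2
    ),
    mismatch_fraction = mismatch_fraction
  ), class = "sim_config")
}

#' Simulate per-county constant covariates
#'
#' Draws the six pooling covariates for `n_counties` synthetic counties:
#' annual mean temperature, isothermality, temperature seasonality, annual
#' precipitation (positively correlated with mean temperature by
#' construction), precipitation seasonality, and per-crop irrigation
#' fractions (columns `irr_<crop>`).
#'
#' @param n_counties number of counties (>= 2).
#' @param crops character vector of crop names.
#' @param config a [sim_config()].
#' @param seed integer seed; the draw is deterministic given `seed`.
#' @return covariate tibble, one row per county.
#' @export
simulate_counties <- function(n_counties, crops = "corn",
                              config = sim_config(), seed = 1) {
  if (n_counties < 2) cs_abort("n_counties must be >= 2")
  cc <- config$covariates
  with_seed(seed, {
    mt <- pmin(pmax(rnorm(n_counties, cc$mean_temp["mean"],
                          cc$mean_temp["sd"]),
                    cc$mean_temp["min"]), cc$mean_temp["max"])
    ap <- pmin(pmax(cc$annual_precip["intercept"] +
                      cc$annual_precip["slope"] * (mt - 15) +
                      rnorm(n_counties, 0, cc$annual_precip["sd"]),
                    cc$annual_precip["min"]), cc$annual_precip["max"])
    iso <- pmin(pmax(rnorm(n_counties, cc$isothermality["mean"],
                           cc$isothermality["sd"]),
                     cc$isothermality["min"]), cc$isothermality["max"])
    ts <- pmax(rnorm(n_counties, cc$temp_seasonality["mean"],
                     cc$temp_seasonality["sd"]), cc$temp_seasonality["min"])
    ps <- pmax(rnorm(n_counties, cc$precip_seasonality["mean"],
                     cc$precip_seasonality["sd"]),
               cc$precip_seasonality["min"])
    out <- tibble::tibble(
      county_id = sprintf("c%04d", seq_len(n_counties)),
      mean_temp = mt, isothermality = iso, temp_seasonality = ts,
      annual_precip = ap, precip_seasonality = ps
    )
    for (crop in crops) {
      out[[paste0("irr_", crop)]] <-
        rbeta(n_counties, cc$irrigation["shape1"], cc$irrigation["shape2"])
    }
    out
  })
}

#' Extract the six-covariate table for one crop
#'
#' The hierarchical model for a crop uses the five climate covariates plus
#' that crop's irrigation fraction.
#'
#' @param covariates output of [simulate_counties()] (or a table of the same
#'   shape).
#' @param crop crop name.
#' @return tibble `county_id` + the six covariates, with the crop's
#'   irrigation column renamed `irrigation_fraction`.
#' @export
covariates_for_crop <- function(covariates, crop) {
  col <- paste0("irr_", crop)
  if (!col %in% names(covariates)) {
    cs_abort(sprintf("covariates lack irrigation column '%s'", col),
             class = "cropshift_unknown_crop")
  }
  covariates |>
    dplyr::select("county_id", "mean_temp", "isothermality",
                  "temp_seasonality", "annual_precip", "precip_seasonality",
                  irrigation_fraction = dplyr::all_of(col))
}

# z-score the covariate columns of a per-crop covariate table; returns
# list(Z matrix with intercept column, centers, scales)
standardize_covariates <- function(covar_crop, centers = NULL, scales = NULL) {
  cols <- c("mean_temp", "isothermality", "temp_seasonality",
            "annual_precip", "precip_seasonality", "irrigation_fraction")
  check_columns(covar_crop, c("county_id", cols), "covariate table")
  M <- as.matrix(covar_crop[cols])
  if (anyNA(M)) cs_abort("covariates contain missing values")
  centers <- centers %||% colMeans(M)
  scales <- scales %||% apply(M, 2, sd)
  if (any(scales <= 0 | !is.finite(scales))) {
    cs_abort(sprintf("constant covariate(s): %s",
                     paste(cols[scales <= 0], collapse = ", ")))
  }
  Z <- sweep(sweep(M, 2, centers), 2, scales, "/")
  W <- cbind(intercept = 1, Z)
  rownames(W) <- covar_crop$county_id
  list(W = W, centers = centers, scales = scales)
}

#' Simulate true hierarchical parameters
#'
#' Draws county intercepts and slopes from their covariate-conditional
#' normal distributions given the hyper-level truth in `config`, storing
#' everything needed for parameter-recovery tests. In `"misspecified"` mode
#' additional heavy-tailed county noise (scaled Student-t with the
#' configured degrees of freedom, variance-matched to the configured SDs) is
#' added to the coefficient deviations.
#'
#' @inheritParams simulate_counties
#' @param covariates output of [simulate_counties()].
#' @return object of class `true_params`: per crop, the hyper-coefficient
#'   matrix `gamma` (components alpha, t, cdi, gdd, edd by covariates), the
#'   SDs, the county coefficient table, and the covariate scaling used.
#' @export
simulate_true_params <- function(covariates, crops = "corn",
                                 config = sim_config(), seed = 1) {
  tr <- config$truth
  if (length(tr$b0) != 6 || ncol(tr$B) != 6) {
    cs_abort("covariate loadings must have 6 entries per component")
  }
  per_crop <- with_seed(seed, {
    lapply(setNames(crops, crops), function(crop) {
      cv <- covariates_for_crop(covariates, crop)
      std <- standardize_covariates(cv)
      I <- nrow(cv)
      # hyper coefficient matrix: rows = components, cols = 1 + 6 covariates
      gamma <- rbind(
        alpha = c(tr$a0, tr$b0),
        t     = c(tr$a["t"], tr$B["t", ]),
        cdi   = c(tr$a["cdi"], tr$B["cdi", ]),
        gdd   = c(tr$a["gdd"], tr$B["gdd", ]),
        edd   = c(tr$a["edd"], tr$B["edd", ])
      )
      colnames(gamma) <- colnames(std$W)
      mu <- std$W %*% t(gamma)            # I x 5 covariate-implied means
      sds <- c(alpha = unname(tr$sigma_alpha), tr$sigma_beta)
      dev <- sapply(seq_along(sds), function(k) rnorm(I, 0, sds[k]))
      if (config$mode == "misspecified") {
        ex <- c(alpha = unname(config$misspec$alpha), config$misspec$beta)
        df <- config$misspec$df
        tscale <- sqrt((df - 2) / df)     # unit-variance t draws
        dev <- dev + sapply(seq_along(ex), function(k) {
          stats::rt(I, df) * tscale * ex[k]
        })
      }
      theta <- mu + dev
      colnames(theta) <- c("alpha", "t", "cdi", "gdd", "edd")
      list(crop = crop, gamma = gamma,
           sigma_alpha = unname(tr$sigma_alpha),
           sigma_beta = tr$sigma_beta, sigma = unname(tr$sigma),
           covar_centers = std$centers, covar_scales = std$scales,
           county = tibble::as_tibble(cbind(
             tibble::tibble(county_id = cv$county_id),
             tibble::as_tibble(theta)
           )),
           implied_mean = mu)
    })
  })
  structure(list(crops = crops, mode = config$mode, per_crop = per_crop,
                 config = config),
            class = "true_params")
}

#' Simulate a county-year yield panel
#'
#' Draws weather predictors per county-year (growing degree days increasing
#' in county mean temperature, deficit index increasing in temperature and
#' decreasing in precipitation) and log-yields from the hierarchical linear
#' model at the true county coefficients. Missingness mimics real panels:
#' each crop is absent from counties in the bottom quantile of its
#' covariate-implied mean log-yield (crops are not observed where they are
#' unattractive), plus a small random county-year dropout; every county
#' keeps at least its best crop.
#'
#' Predictors in the returned panel are in natural units; the log-yield
#' model is applied on the per-crop standardized scale (z-scores over the
#' retained county-years, trend centered at `start_year`), so that
#' [standardize_panel()] with `base_year = start_year` reproduces exactly
#' the scale on which the true coefficients are defined. The full
#' pre-missingness county-by-crop climatology of standardized predictors is
#' attached as attribute `"climatology"` (used to build future scenarios and
#' baseline economics for crops a county does not currently grow).
#'
#' @inheritParams simulate_counties
#' @param params output of [simulate_true_params()].
#' @param n_years number of years (>= 2).
#' @param start_year first calendar year of the panel.
#' @return yield-panel tibble `county_id, year, crop, t, cdi, gdd, edd,
#'   log_yield` (predictors in natural units).
#' @export
simulate_yield_panel <- function(params, covariates, n_years = 40,
                                 start_year = 1970, config = sim_config(),
                                 seed = 1) {
  if (n_years < 2) cs_abort("n_years must be >= 2")
  stopifnot(inherits(params, "true_params"))
  pc <- config$predictors
  years <- start_year + seq_len(n_years) - 1L
  with_seed(seed, {
    pieces <- lapply(params$crops, function(crop) {
      p <- params$per_crop[[crop]]
      cv <- covariates_for_crop(covariates, crop)
      I <- nrow(cv)
      grid <- tidyr::expand_grid(county_id = cv$county_id, year = years) |>
        dplyr::left_join(cv, by = "county_id")
      n <- nrow(grid)
      gdd <- rnorm(n, pc$gdd["mu0"] + pc$gdd["per_degC"] * (grid$mean_temp - 15),
                   pc$gdd["sd"])
      edd <- pmax(0, rnorm(n, pc$edd["mu0"] +
                             pc$edd["per_degC"] * (grid$mean_temp - 15),
                           pc$edd["sd"]))
      q <- pc$cdi["q0"] + pc$cdi["per_degC"] * (grid$mean_temp - 15) +
        pc$cdi["per_mm"] * (grid$annual_precip - 800)
      cdi <- stats::plogis(rnorm(n, q, pc$cdi["sd"]))
      panel <- tibble::tibble(county_id = grid$county_id, year = grid$year,
                              crop = crop, t = as.numeric(grid$year),
                              cdi = cdi, gdd = gdd, edd = edd)

      # missingness: drop counties unattractive for this crop, then dropout
      implied_alpha <- p$implied_mean[, "alpha"]
      keep_county <- implied_alpha >
        quantile(implied_alpha, config$missingness$profit_quantile)
      keep <- panel$county_id %in% cv$county_id[keep_county]
      keep <- keep & (runif(nrow(panel)) > config$missingness$dropout)
      list(panel = panel, keep = keep, params = p, cv = cv)
    })
    names(pieces) <- params$crops

    # guarantee every county retains at least one crop (its best)
    kept_any <- Reduce(`|`, lapply(pieces, function(z) {
      tapply(z$keep, z$panel$county_id, any)[sort(unique(z$panel$county_id))]
    }))
    lost <- names(kept_any)[!kept_any]
    if (length(lost) > 0) {
      best <- sapply(lost, function(cid) {
        means <- sapply(pieces, function(z) {
          z$params$implied_mean[match(cid, z$cv$county_id), "alpha"]
        })
        names(which.max(means))
      })
      for (cid in lost) {
        z <- pieces[[best[cid]]]
        pieces[[best[cid]]]$keep[z$panel$county_id == cid] <- TRUE
      }
    }

    out <- lapply(pieces, function(z) {
      panel <- z$panel[z$keep, ]
      # standardize on retained rows; define yields on that scale
      ctr <- c(cdi = mean(panel$cdi), gdd = mean(panel$gdd),
               edd = mean(panel$edd))
      scl <- c(cdi = sd(panel$cdi), gdd = sd(panel$gdd), edd = sd(panel$edd))
      th <- z$params$county
      idx <- match(panel$county_id, th$county_id)
      lin <- th$alpha[idx] +
        th$t[idx] * (panel$year - start_year) +
        th$cdi[idx] * (panel$cdi - ctr["cdi"]) / scl["cdi"] +
        th$gdd[idx] * (panel$gdd - ctr["gdd"]) / scl["gdd"] +
        th$edd[idx] * (panel$edd - ctr["edd"]) / scl["edd"]
      panel$log_yield <- lin + rnorm(nrow(panel), 0, z$params$sigma)
      # full-grid climatology on the standardized scale
      clim <- z$panel |>
        dplyr::mutate(cdi = (.data$cdi - ctr["cdi"]) / scl["cdi"],
                      gdd = (.data$gdd - ctr["gdd"]) / scl["gdd"],
                      edd = (.data$edd - ctr["edd"]) / scl["edd"]) |>
        dplyr::group_by(.data$county_id, .data$crop) |>
        dplyr::summarise(cdi = mean(.data$cdi), gdd = mean(.data$gdd),
                         edd = mean(.data$edd), .groups = "drop")
      list(panel = panel, clim = clim)
    })
    panel <- dplyr::bind_rows(lapply(out, `[[`, "panel"))
    attr(panel, "climatology") <- dplyr::bind_rows(lapply(out, `[[`, "clim"))
    attr(panel, "start_year") <- start_year
    panel
  })
}

#' Simulate a county-by-crop economics table
#'
#' Draws prices and cultivation costs around per-crop national levels,
#' splits each county's land among its grown crops, and designates an
#' observed (most-planted) crop. A configurable fraction of counties gets a
#' deliberately non-optimal observed crop, so the table is returned
#' *uncalibrated*: hidden-cost calibration
#' ([calibrate_hidden_costs()]) is expected downstream.
#'
#' @inheritParams simulate_yield_panel
#' @param panel output of [simulate_yield_panel()] (carries the climatology
#'   attribute).
#' @return tibble `county_id, crop, price, cost, baseline_area,
#'   expected_yield, observed_crop` covering every county-crop pair (area 0
#'   where the crop is not grown).
#' @export
simulate_economics <- function(panel, params, config = sim_config(),
                               seed = 1) {
  stopifnot(inherits(params, "true_params"))
  clim <- attr(panel, "climatology")
  start_year <- attr(panel, "start_year")
  if (is.null(clim) || is.null(start_year)) {
    cs_abort("panel lacks generator attributes; pass simulate_yield_panel() output")
  }
  ec <- config$economics
  t_ref <- max(panel$year) - start_year
  with_seed(seed, {
    # expected yield at baseline climatology for every county-crop pair
    ey <- dplyr::bind_rows(lapply(params$crops, function(crop) {
      p <- params$per_crop[[crop]]
      rows <- clim[clim$crop == crop, ]
      idx <- match(rows$county_id, p$county$county_id)
      th <- p$county
      lin <- th$alpha[idx] + th$t[idx] * t_ref + th$cdi[idx] * rows$cdi +
        th$gdd[idx] * rows$gdd + th$edd[idx] * rows$edd
      tibble::tibble(county_id = rows$county_id, crop = crop,
                     expected_yield = exp(lin))
    }))
    price0 <- ec$price0[params$crops]
    cost0 <- ec$cost0[params$crops]
    if (anyNA(price0)) {  # crops outside the six defaults
      price0[is.na(price0)] <- 4
      cost0[is.na(cost0)] <- 250
    }
    econ <- ey |>
      dplyr::mutate(
        price = rlnorm(dplyr::n(), log(price0[.data$crop]), ec$price_sdlog),
        cost = pmax(20, rnorm(dplyr::n(), cost0[.data$crop], ec$cost_sd)),
        profit = .data$price * .data$expected_yield - .data$cost
      )
    grown <- panel |> dplyr::distinct(.data$county_id, .data$crop) |>
      dplyr::mutate(grown = TRUE)
    econ <- econ |>
      dplyr::left_join(grown, by = c("county_id", "crop")) |>
      dplyr::mutate(grown = !is.na(.data$grown)) |>
      # cultivation persists only where it pays: grown crops get a small
      # positive profit floor via a cost reduction
      dplyr::mutate(
        cost = ifelse(.data$grown,
                      pmin(.data$cost, .data$price * .data$expected_yield -
                             ec$profit_floor),
                      .data$cost),
        profit = .data$price * .data$expected_yield - .data$cost
      )

    counties <- sort(unique(econ$county_id))
    land <- setNames(rlnorm(length(counties), ec$land_meanlog, ec$land_sdlog),
                     counties)
    mismatch <- runif(length(counties)) < config$mismatch_fraction
    names(mismatch) <- counties

    econ <- econ |>
      dplyr::group_by(.data$county_id) |>
      dplyr::group_modify(function(df, key) {
        cid <- key$county_id
        g <- which(df$grown)
        best_overall <- which.max(df$profit)
        # observed crop: profit argmax among grown crops, unless this county
        # is designated mismatched (then a random other grown crop)
        best_grown <- g[which.max(df$profit[g])]
        obs <- best_grown
        if (mismatch[cid] && length(g) > 1) {
          obs <- sample(setdiff(g, best_grown), 1)
        }
        shares <- numeric(nrow(df))
        shares[g] <- stats::rgamma(length(g), ec$share_other)
        shares[obs] <- stats::rgamma(1, ec$share_obs)
        if (max(shares) > shares[obs]) {  # enforce observed = most planted
          top <- which.max(shares)
          shares[c(top, obs)] <- shares[c(obs, top)]
        }
        df$baseline_area <- land[cid] * shares / sum(shares)
        df$observed_crop <- df$crop[obs]
        df
      }) |>
      dplyr::ungroup() |>
      dplyr::select("county_id", "crop", "price", "cost", "baseline_area",
                    "expected_yield", "observed_crop")
    econ
  })
}

#' Simulate a future climate scenario
#'
#' Shifts the baseline climatological predictors (standardized scale) by a
#' stated per-crop amount, with optional county-level heterogeneity, to
#' stand in for projected future predictor changes.
#'
#' @inheritParams simulate_economics
#' @param shifts named list: per crop, a named numeric vector of shifts in
#'   standard-deviation units for any of `cdi`, `gdd`, `edd` (unlisted
#'   predictors shift by 0). A single unnamed vector is recycled to all
#'   crops.
#' @param label period label (e.g. `"2050"`).
#' @param t_value trend value (years since the panel's base year) at which
#'   the scenario is evaluated; defaults to the baseline panel's last year.
#' @param het_sd SD of county-specific heterogeneity added to each shifted
#'   predictor (default 0).
#' @return tibble `period, county_id, crop, t, cdi, gdd, edd` on the
#'   standardized scale, covering every county-crop pair.
#' @export
simulate_scenario <- function(panel, shifts = list(), label = "future",
                              t_value = NULL, het_sd = 0, seed = 1) {
  clim <- attr(panel, "climatology")
  start_year <- attr(panel, "start_year")
  if (is.null(clim)) {
    cs_abort("panel lacks a climatology attribute; pass simulate_yield_panel() output")
  }
  crops <- sort(unique(clim$crop))
  if (length(shifts) > 0 && !is.null(names(shifts)) &&
      any(names(shifts) != "") && is.list(shifts)) {
    unknown <- setdiff(names(shifts), crops)
    if (length(unknown) > 0) {
      cs_abort(sprintf("shift specified for unknown crop(s): %s",
                       paste(unknown, collapse = ", ")),
               class = "cropshift_unknown_crop")
    }
  }
  shift_for <- function(crop) {
    s <- if (is.list(shifts)) (shifts[[crop]] %||% numeric(0)) else shifts
    out <- c(cdi = 0, gdd = 0, edd = 0)
    out[names(s)] <- s
    out
  }
  t_value <- t_value %||% (max(panel$year) - start_year)
  with_seed(seed, {
    dplyr::bind_rows(lapply(crops, function(crop) {
      rows <- clim[clim$crop == crop, ]
      s <- shift_for(crop)
      n <- nrow(rows)
      tibble::tibble(
        period = label, county_id = rows$county_id, crop = crop,
        t = t_value,
        cdi = rows$cdi + s["cdi"] + rnorm(n, 0, het_sd),
        gdd = rows$gdd + s["gdd"] + rnorm(n, 0, het_sd),
        edd = rows$edd + s["edd"] + rnorm(n, 0, het_sd)
      )
    }))
  })
}

#' Simulate a complete study fixture
#'
#' One call generating everything the downstream pipeline consumes:
#' covariates, true parameters, yield panel, economics, and a set of warming
#' scenarios. Per-stage seeds are derived deterministically from the root
#' seed, so stages are individually reproducible.
#'
#' @inheritParams simulate_counties
#' @param n_years panel length in years.
#' @param start_year first panel year.
#' @param scenario_shifts named list of per-period shift specifications
#'   passed to [simulate_scenario()]; default adds +0.5 / +1 SD of extreme
#'   heat (and smaller GDD/CDI shifts) for two future periods.
#' @param het_sd county heterogeneity SD for scenario shifts.
#' @return list with elements `covariates`, `params`, `panel`,
#'   `economics`, `scenarios` (one tibble, all periods), `config`, `seed`.
#' @export
simulate_study <- function(n_counties = 60, n_years = 30, crops = "corn",
                           start_year = 1980, config = sim_config(),
                           scenario_shifts = NULL, het_sd = 0.15, seed = 1) {
  covariates <- simulate_counties(n_counties, crops, config,
                                  seed = derive_seed(seed, "counties"))
  params <- simulate_true_params(covariates, crops, config,
                                 seed = derive_seed(seed, "params"))
  panel <- simulate_yield_panel(params, covariates, n_years, start_year,
                                config, seed = derive_seed(seed, "panel"))
  economics <- simulate_economics(panel, params, config,
                                  seed = derive_seed(seed, "economics"))
  if (is.null(scenario_shifts)) {
    scenario_shifts <- list(
      "2050" = c(gdd = 0.4, edd = 0.8, cdi = 0.2),
      "2070" = c(gdd = 0.6, edd = 1.4, cdi = 0.35)
    )
  }
  scenarios <- dplyr::bind_rows(purrr::imap(scenario_shifts, function(s, lab) {
    simulate_scenario(panel, shifts = s, label = lab, het_sd = het_sd,
                      seed = derive_seed(seed, paste0("scenario_", lab)))
  }))
  list(covariates = covariates, params = params, panel = panel,
       economics = economics, scenarios = scenarios, config = config,
       seed = seed)
}
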