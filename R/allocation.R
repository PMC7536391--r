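#' Calibrate hidden cultivation costs
#'
#' When the profit surface implied by predicted yields, prices and reported
#' costs does not rank a county's observed (most planted) crop first, the
#' discrepancy is treated as unmodelled local costs. Costs are adjusted by
#' the minimal amount that makes the observed crop's per-acre profit
#' strictly exceed every alternative by `epsilon`: either by raising the
#' competing crops' costs (default) or by lowering the observed crop's
#' cost. Counties already consistent are untouched.
#'
#' @param econ economics table: `county_id, crop, price, cost,
#'   baseline_area, observed_crop` and `expected_yield` (or supply
#'   `yields`).
#' @param yields optional tibble `county_id, crop, expected_yield`
#'   overriding/providing baseline expected yields.
#' @param epsilon required profit margin of the observed crop over the best
#'   alternative (USD/acre).
#' @param mode `"raise_competitors"` or `"lower_observed"`.
#' @return the economics table with adjusted `cost` and a `hidden_cost`
#'   column recording the signed adjustment. Post-condition (asserted): the
#'   observed crop is the per-acre-profit argmax in every county.
#' @export
calibrate_hidden_costs <- function(econ, yields = NULL, epsilon = 1,
                                   mode = c("raise_competitors",
                                            "lower_observed")) {
  mode <- match.arg(mode)
  check_columns(econ, c("county_id", "crop", "price", "cost",
                        "observed_crop"), "economics table")
  if (!is.null(yields)) {
    econ <- econ |>
      dplyr::select(-dplyr::any_of("expected_yield")) |>
      dplyr::left_join(yields, by = c("county_id", "crop"))
  }
  check_columns(econ, "expected_yield", "economics table")
  obs_missing <- econ |>
    dplyr::filter(.data$crop == .data$observed_crop,
                  is.na(.data$expected_yield))
  if (nrow(obs_missing) > 0) {
    cs_abort(paste0("missing expected yield for observed crop in: ",
                    paste(head(obs_missing$county_id, 5), collapse = ", ")))
  }
  out <- econ |>
    dplyr::mutate(profit = .data$price * .data$expected_yield - .data$cost) |>
    dplyr::group_by(.data$county_id) |>
    dplyr::group_modify(function(df, key) {
      io <- which(df$crop == df$observed_crop[1])
      if (length(io) != 1) {
        cs_abort(sprintf("county %s: observed crop not in table",
                         key$county_id))
      }
      adj <- numeric(nrow(df))
      if (mode == "raise_competitors") {
        excess <- df$profit - (df$profit[io] - epsilon)
        excess[io] <- 0
        adj <- pmax(excess, 0)
      } else {
        deficit <- max(df$profit[-io]) - df$profit[io]
        if (deficit > -epsilon) adj[io] <- -(deficit + epsilon)
      }
      df$cost <- df$cost + adj
      df$hidden_cost <- adj
      df$profit <- df$price * df$expected_yield - df$cost
      df
    }) |>
    dplyr::ungroup()
  # post-condition audit
  bad <- out |>
    dplyr::group_by(.data$county_id) |>
    dplyr::summarise(ok = .data$crop[which.max(.data$profit)] ==
                       .data$observed_crop[1], .groups = "drop") |>
    dplyr::filter(!.data$ok)
  if (nrow(bad) > 0) {
    cs_abort(paste0("calibration failed for counties: ",
                    paste(head(bad$county_id, 5), collapse = ", ")))
  }
  dplyr::select(out, -"profit")
}

#' Profit-maximizing land reallocation
#'
#' Solves the land-allocation linear program
#' `max sum_ic profit_ic * A_ic` subject to the two appropriation
#' constraints: county land totals cannot grow
#' (`sum_c A_ic <= sum_c baseline_ic` per county) and national crop totals
#' cannot grow (`sum_i A_ic <= sum_i baseline_ic` per crop, overridable via
#' `crop_caps`). Land may be left fallow where no crop is profitable. A
#' positive `switching_cost` subtracts `s * max(0, A_ic - baseline_ic)`
#' from the objective, linearized with one slack variable per county-crop
#' cell, so expanding a crop beyond its baseline footprint in a county is
#' charged but abandoning land is not.
#'
#' @param surface profit surface: tibble `county_id, crop, profit`
#'   (USD/acre) covering every county-crop cell.
#' @param baseline tibble `county_id, crop, baseline_area` (acres).
#' @param switching_cost USD per reallocated acre (default 0).
#' @param crop_caps optional named vector of per-crop area caps replacing
#'   the baseline national totals (use `Inf` entries for slack caps).
#' @return object of class `allocation`: tibble `allocation`
#'   (`county_id, crop, acres`), `objective` (USD, net of switching
#'   charges), `dual` components, and an `audit` list with the relative
#'   duality gap and maximum constraint violation.
#' @export
optimize_allocation <- function(surface, baseline, switching_cost = 0,
                                crop_caps = NULL) {
  check_columns(surface, c("county_id", "crop", "profit"), "profit surface")
  check_columns(baseline, c("county_id", "crop", "baseline_area"), "baseline")
  if (switching_cost < 0) cs_abort("switching_cost must be >= 0")
  counties <- sort(unique(surface$county_id))
  crops <- sort(unique(surface$crop))
  I <- length(counties)
  C <- length(crops)
  pi_mat <- matrix(NA_real_, I, C, dimnames = list(counties, crops))
  pi_mat[cbind(match(surface$county_id, counties),
               match(surface$crop, crops))] <- surface$profit
  if (anyNA(pi_mat)) {
    cs_abort("profit surface does not cover every county-crop cell")
  }
  base_mat <- matrix(0, I, C, dimnames = list(counties, crops))
  bi <- baseline$county_id %in% counties & baseline$crop %in% crops
  base_mat[cbind(match(baseline$county_id[bi], counties),
                 match(baseline$crop[bi], crops))] <- baseline$baseline_area[bi]
  land <- rowSums(base_mat)
  caps <- if (is.null(crop_caps)) colSums(base_mat) else {
    out <- colSums(base_mat)
    out[names(crop_caps)] <- crop_caps
    out
  }
  # finite-ize slack caps: no crop can exceed total land anyway
  caps <- pmin(caps, sum(land))

  nv <- I * C
  A_county <- do.call(cbind, replicate(C, diag(I), simplify = FALSE))
  A_crop <- kronecker(diag(C), matrix(1, 1, I))
  if (switching_cost > 0) {
    A <- rbind(cbind(A_county, matrix(0, I, nv)),
               cbind(A_crop, matrix(0, C, nv)),
               cbind(diag(nv), -diag(nv)))
    b <- c(land, caps, as.vector(base_mat))
    cv <- c(as.vector(pi_mat), rep(-switching_cost, nv))
  } else {
    A <- rbind(A_county, A_crop)
    b <- c(land, caps)
    cv <- as.vector(pi_mat)
  }
  sol <- lp_solve_simplex(cv, A, b)
  acres <- matrix(sol$x[seq_len(nv)], I, C, dimnames = list(counties, crops))

  viol <- max(c(A %*% sol$x - b, -sol$x), 0)
  alloc <- tibble::tibble(
    county_id = rep(counties, C),
    crop = rep(crops, each = I),
    acres = as.vector(acres)
  )
  structure(list(
    allocation = alloc, acres = acres, baseline = base_mat,
    objective = sol$objective,
    gross_profit = sum(pi_mat * acres),
    reallocated_acres = sum(pmax(acres - base_mat, 0)),
    switching_cost = switching_cost,
    dual = list(county = sol$dual[seq_len(I)],
                crop = sol$dual[I + seq_len(C)]),
    audit = list(duality_gap = sol$gap, max_violation = viol,
                 iterations = sol$iterations),
    land = land, caps = caps
  ), class = "allocation")
}

#' @export
print.allocation <- function(x, ...) {
  cat(sprintf("<allocation> %d counties x %d crops; objective $%.0f\n",
              nrow(x$acres), ncol(x$acres), x$objective))
  cat(sprintf("  reallocated %.0f acres; duality gap %.2e\n",
              x$reallocated_acres, x$audit$duality_gap))
  invisible(x)
}

#' Status-quo profit of the baseline allocation
#'
#' The no-adaptation counterfactual: the profit surface evaluated on
#' baseline planted areas.
#'
#' @inheritParams optimize_allocation
#' @return scalar USD.
#' @export
status_quo_profit <- function(surface, baseline) {
  joined <- dplyr::inner_join(surface, baseline,
                              by = c("county_id", "crop"))
  sum(joined$profit * joined$baseline_area)
}

#' Adjust predicted log-yields for destination irrigation capacity
#'
#' When a crop moves into a county, its predicted yield should reflect the
#' destination county's irrigation capacity. Because the coefficient model
#' is linear in the (standardized) irrigation-fraction covariate, moving a
#' prediction from irrigation fraction `from` to `to` shifts each posterior
#' draw's log-yield by exactly the irrigation loading path:
#' `sum_k gamma[k, irr] * dz * x_k`, with `dz` the standardized fraction
#' change and `x = (1, t, cdi, gdd, edd)`.
#'
#' @param log_yield_draws matrix `[draws, rows]` from
#'   [posterior_predict_log_yield()] evaluated at `from_fraction`.
#' @param fit the [fit_hier()] object that produced the draws.
#' @param newdata the predictor rows the draws were evaluated at.
#' @param from_fraction,to_fraction irrigation fractions per row (vectors
#'   in `[0, 1]`, recycled).
#' @return adjusted log-yield draw matrix of the same shape.
#' @export
apply_irrigation_adjustment <- function(log_yield_draws, fit, newdata,
                                        from_fraction, to_fraction) {
  n <- nrow(newdata)
  from_fraction <- rep_len(from_fraction, n)
  to_fraction <- rep_len(to_fraction, n)
  if (anyNA(from_fraction) || anyNA(to_fraction)) {
    cs_abort("missing irrigation fraction")
  }
  if (any(from_fraction < 0 | from_fraction > 1 |
          to_fraction < 0 | to_fraction > 1)) {
    cs_abort("irrigation fractions must lie in [0, 1]")
  }
  dz <- (to_fraction - from_fraction) /
    fit$model$covar_scales["irrigation_fraction"]
  X <- cbind(1, as.matrix(newdata[predictor_cols]))      # n x 5
  g_irr <- fit$gamma[, , "irrigation_fraction"]          # S x 5
  shift <- (g_irr %*% t(X)) * rep(dz, each = nrow(g_irr))
  log_yield_draws + shift
}

#' Posterior-draw Monte Carlo land-use optimization
#'
#' For each sampled posterior draw and each scenario period, predicts
#' expected yields for every county-crop cell (mean function, evaluated at
#' each destination county's own crop-specific irrigation covariate),
#' builds the profit surface from calibrated prices and costs, solves the
#' reallocation linear program, and pairs it with the same draw's
#' status-quo profit. Summaries aggregate across draws with equal-tailed
#' 95% credible intervals.
#'
#' @param fits a [fit_hier()] object (single crop) or a named list of fits,
#'   one per crop.
#' @param econ calibrated economics table (see
#'   [calibrate_hidden_costs()]).
#' @param scenarios tibble `period, county_id, crop, t, cdi, gdd, edd` on
#'   the standardized scale (see [simulate_scenario()]).
#' @param covariates covariate table with `irr_<crop>` columns.
#' @param n_draws number of posterior draws to propagate.
#' @param switching_cost USD per reallocated acre.
#' @param crop_caps optional named per-crop caps (see
#'   [optimize_allocation()]).
#' @param conf_level credible-interval mass.
#' @param seed seed for the draw subsample and any dispersion draws.
#' @return object of class `mc_allocation`: per-draw summaries, aggregated
#'   `summary` tibble, mean crop-flow matrices, allocations, and LP audits.
#' @export
monte_carlo_optimize <- function(fits, econ, scenarios, covariates,
                                 n_draws = 30, switching_cost = 0,
                                 crop_caps = NULL, conf_level = 0.95,
                                 seed = 1) {
  if (inherits(fits, "hier_fit")) {
    fits <- setNames(list(fits), fits$crop)
  }
  crops <- sort(unique(scenarios$crop))
  missing_fit <- setdiff(crops, names(fits))
  if (length(missing_fit) > 0) {
    cs_abort(paste0("no fit supplied for crop(s): ",
                    paste(missing_fit, collapse = ", ")))
  }
  S <- length(fits[[1]]$chain)
  n_draws <- min(n_draws, S)
  draw_idx <- with_seed(derive_seed(seed, "drawsel"),
                        sort(sample.int(S, n_draws)))
  periods <- unique(scenarios$period)

  # per crop & period: matrix [n_draws, counties] of expected log yield
  ylist <- lapply(setNames(crops, crops), function(cr) {
    cov_crop <- covariates_for_crop(covariates, cr)
    lapply(setNames(periods, periods), function(pd) {
      rows <- scenarios[scenarios$crop == cr & scenarios$period == pd, ]
      mat <- posterior_predict_log_yield(
        fits[[cr]], rows, new_covariates = cov_crop, type = "mean",
        seed = derive_seed(seed, paste0("yield_", cr, "_", pd)))
      list(county_id = rows$county_id, ly = mat[draw_idx, , drop = FALSE])
    })
  })

  baseline <- econ |>
    dplyr::select("county_id", "crop", "baseline_area")
  results <- list()
  allocs <- list()
  flows <- list()
  for (pd in periods) {
    for (d in seq_len(n_draws)) {
      surf <- dplyr::bind_rows(lapply(crops, function(cr) {
        yl <- ylist[[cr]][[pd]]
        tibble::tibble(county_id = yl$county_id, crop = cr,
                       expected_yield = exp(yl$ly[d, ]))
      })) |>
        dplyr::inner_join(dplyr::select(econ, "county_id", "crop", "price",
                                        "cost", "observed_crop"),
                          by = c("county_id", "crop")) |>
        dplyr::mutate(profit = .data$price * .data$expected_yield - .data$cost)
      opt <- optimize_allocation(surf, baseline,
                                 switching_cost = switching_cost,
                                 crop_caps = crop_caps)
      sq <- status_quo_profit(surf, baseline)
      if (opt$objective < sq - 1e-6 * max(1, abs(sq))) {
        cs_abort(sprintf(
          "draw %d period %s: optimized profit below status quo", d, pd))
      }
      sw <- summarize_switching(opt, econ, yields = surf)
      results[[length(results) + 1]] <- tibble::tibble(
        period = pd, draw = draw_idx[d],
        profit_optimized = opt$objective,
        profit_status_quo = sq,
        pct_switched = sw$pct_switched,
        pct_switched_excl_cornsoy = sw$pct_switched_excl_cornsoy,
        fallow_fraction = sw$fallow_fraction,
        reallocated_acres = opt$reallocated_acres,
        duality_gap = opt$audit$duality_gap,
        max_violation = opt$audit$max_violation
      )
      allocs[[length(allocs) + 1]] <- opt$allocation |>
        dplyr::mutate(period = pd, draw = draw_idx[d], .before = 1)
      flows[[length(flows) + 1]] <- sw$flows |>
        dplyr::mutate(period = pd, draw = draw_idx[d], .before = 1)
    }
  }
  per_draw <- dplyr::bind_rows(results)
  a <- (1 - conf_level) / 2
  summary_tbl <- per_draw |>
    tidyr::pivot_longer(c("profit_optimized", "profit_status_quo",
                          "pct_switched", "pct_switched_excl_cornsoy",
                          "fallow_fraction", "reallocated_acres"),
                        names_to = "metric") |>
    dplyr::group_by(.data$period, .data$metric) |>
    dplyr::summarise(mean = mean(.data$value),
                     conf.low = quantile(.data$value, a, names = FALSE),
                     conf.high = quantile(.data$value, 1 - a, names = FALSE),
                     .groups = "drop")
  flow_mean <- dplyr::bind_rows(flows) |>
    dplyr::group_by(.data$period, .data$from, .data$to) |>
    dplyr::summarise(area = sum(.data$area) / n_draws, .groups = "drop")
  structure(list(per_draw = per_draw, summary = summary_tbl,
                 flows = flow_mean,
                 allocations = dplyr::bind_rows(allocs),
                 draw_idx = draw_idx, switching_cost = switching_cost,
                 conf_level = conf_level),
            class = "mc_allocation")
}

#' Switching and flow summary of one allocation
#'
#' A county "switches" when its largest-area crop under the optimized
#' allocation differs from the baseline dominant (observed) crop; ties go
#' to the baseline crop, and a fully fallowed county counts as switched.
#' The corn-soy exclusion treats a pairwise corn-to-soybeans or
#' soybeans-to-corn change of dominant crop as a non-switch (the two are
#' commonly rotated). Also returns the baseline-to-optimized crop area flow
#' matrix (per county, shrinking crops feed growing crops and fallow land
#' proportionally) and the fallow-land fraction.
#'
#' @param alloc an [optimize_allocation()] result, or a tibble
#'   `county_id, crop, acres`.
#' @param econ economics table carrying `baseline_area` and
#'   `observed_crop`.
#' @param yields optional tibble `county_id, crop, expected_yield` enabling
#'   per-crop production change.
#' @return list: `pct_switched`, `pct_switched_excl_cornsoy` (both in
#'   percent of counties), `fallow_fraction`, `dominant` tibble, `flows`
#'   tibble (`from`, `to`, `area`), and `production_change` (percent, per
#'   crop; `NULL` without yields).
#' @export
summarize_switching <- function(alloc, econ, yields = NULL) {
  alloc_tbl <- if (inherits(alloc, "allocation")) alloc$allocation else alloc
  check_columns(alloc_tbl, c("county_id", "crop", "acres"), "allocation")
  base <- econ |>
    dplyr::distinct(.data$county_id, .data$crop, .data$baseline_area,
                    .data$observed_crop)
  grid <- dplyr::full_join(alloc_tbl, base, by = c("county_id", "crop")) |>
    dplyr::mutate(acres = dplyr::coalesce(.data$acres, 0),
                  baseline_area = dplyr::coalesce(.data$baseline_area, 0)) |>
    dplyr::group_by(.data$county_id) |>
    dplyr::mutate(observed_crop = .data$observed_crop[!is.na(.data$observed_crop)][1]) |>
    dplyr::ungroup()

  dominant <- grid |>
    dplyr::group_by(.data$county_id) |>
    dplyr::summarise(
      baseline_dominant = .data$observed_crop[1],
      new_dominant = {
        mx <- max(.data$acres)
        if (mx <= 0) "fallow"
        else {
          top <- .data$crop[.data$acres >= mx - 1e-9]
          if (.data$observed_crop[1] %in% top) .data$observed_crop[1]
          else top[1]
        }
      },
      .groups = "drop"
    ) |>
    dplyr::mutate(
      switched = .data$new_dominant != .data$baseline_dominant,
      cornsoy_swap = (.data$baseline_dominant == "corn" &
                        .data$new_dominant == "soybeans") |
        (.data$baseline_dominant == "soybeans" & .data$new_dominant == "corn")
    )

  flows <- grid |>
    dplyr::group_by(.data$county_id) |>
    dplyr::group_modify(function(df, key) county_flows(df)) |>
    dplyr::ungroup() |>
    dplyr::group_by(.data$from, .data$to) |>
    dplyr::summarise(area = sum(.data$area), .groups = "drop")

  total_base <- sum(grid$baseline_area)
  fallow_fraction <- (total_base - sum(grid$acres)) / total_base

  production_change <- NULL
  if (!is.null(yields)) {
    production_change <- grid |>
      dplyr::left_join(dplyr::select(yields, "county_id", "crop",
                                     "expected_yield"),
                       by = c("county_id", "crop")) |>
      dplyr::group_by(.data$crop) |>
      dplyr::summarise(
        change_pct = 100 *
          (sum(.data$expected_yield * .data$acres, na.rm = TRUE) -
             sum(.data$expected_yield * .data$baseline_area, na.rm = TRUE)) /
          max(sum(.data$expected_yield * .data$baseline_area, na.rm = TRUE),
              1e-9),
        .groups = "drop")
  }

  list(
    pct_switched = 100 * mean(dominant$switched),
    pct_switched_excl_cornsoy =
      100 * mean(dominant$switched & !dominant$cornsoy_swap),
    fallow_fraction = fallow_fraction,
    dominant = dominant, flows = flows,
    production_change = production_change
  )
}

# proportional baseline->new flow decomposition within one county
county_flows <- function(df) {
  dec <- pmax(df$baseline_area - df$acres, 0)
  inc <- pmax(df$acres - df$baseline_area, 0)
  stay <- pmin(df$baseline_area, df$acres)
  fallow_in <- sum(dec) - sum(inc)        # county land is non-increasing
  rows <- tibble::tibble(from = df$crop, to = df$crop, area = stay)
  if (sum(dec) > 0) {
    recv <- c(inc, max(fallow_in, 0))
    recv_names <- c(df$crop, "fallow")
    share <- recv / sum(recv)
    for (j in which(dec > 0)) {
      rows <- dplyr::bind_rows(rows, tibble::tibble(
        from = df$crop[j], to = recv_names, area = dec[j] * share))
    }
  }
  rows[rows$area > 0, ]
}

#' Switching-cost sweep
#'
#' Re-solves the reallocation program on one profit surface over a grid of
#' per-acre switching costs, reporting the net objective, the reallocated
#' acreage, and whether every county's dominant crop matches the baseline
#' dominant crop. Both the objective and the reallocated acreage are
#' non-increasing in the switching cost.
#'
#' @inheritParams optimize_allocation
#' @param econ economics table (for dominant-crop comparison).
#' @param costs vector of switching costs (USD/acre).
#' @return tibble: `switching_cost`, `objective`, `gross_profit`,
#'   `reallocated_acres`, `pct_switched`.
#' @export
switching_cost_sweep <- function(surface, econ,
                                 costs = c(0, 50, 100, 200, 500, 5000),
                                 crop_caps = NULL) {
  baseline <- dplyr::select(econ, "county_id", "crop", "baseline_area")
  purrr::map_dfr(costs, function(s) {
    opt <- optimize_allocation(surface, baseline, switching_cost = s,
                               crop_caps = crop_caps)
    sw <- summarize_switching(opt, econ)
    tibble::tibble(switching_cost = s, objective = opt$objective,
                   gross_profit = opt$gross_profit,
                   reallocated_acres = opt$reallocated_acres,
                   pct_switched = sw$pct_switched)
  })
}

#' @export
print.mc_allocation <- function(x, ...) {
  cat(sprintf("<mc_allocation> %d draws x %d period(s), switching cost $%g/acre\n",
              length(x$draw_idx), length(unique(x$per_draw$period)),
              x$switching_cost))
  print(x$summary, n = 30)
  invisible(x)
}

#' Profit bars with credible intervals for a Monte Carlo optimization
#'
#' @param object an [monte_carlo_optimize()] result.
#' @param ... unused.
#' @return ggplot of mean status-quo and optimized profits per period with
#'   equal-tailed credible-interval error bars.
#' @export
autoplot.mc_allocation <- function(object, ...) {
  dat <- object$summary |>
    dplyr::filter(.data$metric %in% c("profit_status_quo",
                                      "profit_optimized")) |>
    dplyr::mutate(metric = dplyr::recode(.data$metric,
                                         profit_status_quo = "without reallocation",
                                         profit_optimized = "with reallocation"))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$period, y = .data$mean,
                                    fill = .data$metric)) +
    ggplot2::geom_col(position = ggplot2::position_dodge(width = 0.8),
                      width = 0.7) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$conf.low,
                                        ymax = .data$conf.high),
                           position = ggplot2::position_dodge(width = 0.8),
                           width = 0.2) +
    ggplot2::labs(x = NULL, y = "total profit (USD)", fill = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Crop-flow tile plot
#'
#' @param x an [monte_carlo_optimize()] result or a flow tibble
#'   (`from`, `to`, `area`, optionally `period`).
#' @return ggplot tile plot of mean baseline-to-optimized area flows.
#' @export
plot_flows <- function(x) {
  flows <- if (inherits(x, "mc_allocation")) x$flows else x
  p <- ggplot2::ggplot(flows, ggplot2::aes(x = .data$to, y = .data$from,
                                           fill = .data$area)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = "acres") +
    ggplot2::labs(x = "optimized allocation", y = "baseline allocation") +
    ggplot2::theme_minimal()
  if ("period" %in% names(flows)) p <- p + ggplot2::facet_wrap(~period)
  p
}
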