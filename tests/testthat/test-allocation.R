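two_crop_econ <- function() {
  # county with corn profit 100 and soy profit 120, observed corn
  tibble::tibble(
    county_id = "c1", crop = c("corn", "soybeans"),
    price = c(1, 1), cost = c(100, 120),
    baseline_area = c(60, 40),
    expected_yield = c(200, 240),
    observed_crop = "corn"
  )
}

test_that("hidden-cost calibration makes observed crops optimal minimally", {
  econ <- two_crop_econ()
  cal <- calibrate_hidden_costs(econ, epsilon = 1)
  # soy profit must drop from 120 to 99: cost rises by 21
  expect_equal(cal$cost[cal$crop == "soybeans"], 141)
  expect_equal(cal$hidden_cost[cal$crop == "soybeans"], 21)
  expect_equal(cal$hidden_cost[cal$crop == "corn"], 0)

  # alternative mode: lower the observed crop's cost instead
  low <- calibrate_hidden_costs(econ, epsilon = 1, mode = "lower_observed")
  expect_equal(low$cost[low$crop == "corn"], 79)   # profit 121 = 120 + 1
  expect_equal(low$cost[low$crop == "soybeans"], 120)

  # an already-consistent county is untouched
  ok <- dplyr::mutate(econ, observed_crop = "soybeans")
  cal2 <- calibrate_hidden_costs(ok, epsilon = 1)
  expect_equal(cal2$hidden_cost, c(0, 0))
  expect_equal(cal2$cost, econ$cost)

  # missing observed-crop yield is an error
  bad <- dplyr::mutate(econ, expected_yield = c(NA, 240))
  expect_error(calibrate_hidden_costs(bad), "missing expected yield")
})

test_that("calibration audit holds on a realistic mismatched table", {
  setup <- alloc_setup()
  cal <- setup$econ_cal
  argmax <- cal |>
    dplyr::mutate(profit = price * expected_yield - cost) |>
    dplyr::group_by(county_id) |>
    dplyr::summarise(ok = crop[which.max(profit)] == observed_crop[1])
  expect_true(all(argmax$ok))
})

test_that("single-county allocations behave analytically", {
  surface <- tibble::tibble(county_id = "c1", crop = c("a", "b"),
                            profit = c(10, 5))
  baseline <- tibble::tibble(county_id = "c1", crop = c("a", "b"),
                             baseline_area = c(50, 50))
  opt <- optimize_allocation(surface, baseline,
                             crop_caps = c(a = 100, b = 100))
  expect_equal(opt$objective, 1000)
  expect_equal(opt$allocation$acres[opt$allocation$crop == "a"], 100)
  expect_equal(opt$allocation$acres[opt$allocation$crop == "b"], 0)

  # nothing profitable: everything goes fallow at zero objective
  fal <- optimize_allocation(dplyr::mutate(surface, profit = c(-3, -1)),
                             baseline)
  expect_equal(fal$objective, 0)
  expect_equal(sum(fal$allocation$acres), 0)
})

test_that("the allocation LP matches brute force on a 3x2 instance", {
  set.seed(504)
  counties <- c("c1", "c2", "c3")
  crops <- c("a", "b")
  pi_mat <- matrix(c(4, -2, 7, 3, 1, 5), 3, 2)
  base <- matrix(c(2, 1, 0, 1, 2, 3), 3, 2)
  surface <- tibble::tibble(county_id = rep(counties, 2),
                            crop = rep(crops, each = 3),
                            profit = as.vector(pi_mat))
  baseline <- tibble::tibble(county_id = rep(counties, 2),
                             crop = rep(crops, each = 3),
                             baseline_area = as.vector(base))
  opt <- optimize_allocation(surface, baseline)
  bf <- brute_force_allocation(pi_mat, rowSums(base), colSums(base))
  expect_equal(opt$objective, max(bf, 0), tolerance = 1e-9)
  expect_lte(opt$audit$duality_gap, 1e-9)
  expect_lte(opt$audit$max_violation, 1e-9)
})

test_that("the objective is scale-equivariant in prices and costs", {
  setup <- alloc_setup()
  surf <- setup$surf0
  baseline <- dplyr::select(setup$econ_cal, county_id, crop, baseline_area)
  o1 <- optimize_allocation(surf, baseline)
  o2 <- optimize_allocation(dplyr::mutate(surf, profit = 3.7 * profit),
                            baseline)
  expect_equal(o2$objective, 3.7 * o1$objective, tolerance = 1e-9)
  expect_equal(o2$allocation$acres, o1$allocation$acres, tolerance = 1e-6)
})

test_that("irrigation adjustment follows the covariate pathway exactly", {
  setup <- alloc_setup()
  fit <- setup$fits$corn
  cc <- covariates_for_crop(setup$st$covariates, "corn")
  newd <- tibble::tibble(county_id = fit$county_ids[1:4],
                         t = 2, cdi = 0.2, gdd = -0.1, edd = 0.5)
  ly <- posterior_predict_log_yield(fit, newd, type = "mean")
  frac <- cc$irrigation_fraction[match(newd$county_id, cc$county_id)]

  # destination equals source: no change
  same <- apply_irrigation_adjustment(ly, fit, newd, frac, frac)
  expect_equal(same, ly)

  # zero irrigation loadings: adjustment is the identity
  fit0 <- fit
  fit0$gamma[, , "irrigation_fraction"] <- 0
  none <- apply_irrigation_adjustment(ly, fit0, newd, frac,
                                      pmin(frac + 0.3, 1))
  expect_equal(none, ly)

  # manual propagation: shift = sum_k gamma_irr_k * dz * x_k per draw
  to <- pmin(frac + 0.25, 1)
  adj <- apply_irrigation_adjustment(ly, fit, newd, frac, to)
  dz <- (to - frac) / fit$model$covar_scales["irrigation_fraction"]
  r <- 2
  x_r <- c(1, 2, 0.2, -0.1, 0.5)
  manual <- ly[, r] + as.vector(fit$gamma[, , "irrigation_fraction"] %*%
                                  x_r) * dz[r]
  expect_equal(adj[, r], manual, tolerance = 1e-12)

  expect_error(apply_irrigation_adjustment(ly, fit, newd, frac, rep(NA, 4)),
               "missing irrigation")
  expect_error(apply_irrigation_adjustment(ly, fit, newd, frac, rep(1.2, 4)),
               "irrigation fractions")
})

test_that("switching summaries count dominant-crop changes correctly", {
  econ <- tibble::tibble(
    county_id = rep(c("c1", "c2", "c3", "c4"), each = 2),
    crop = rep(c("corn", "soybeans"), 4),
    baseline_area = c(80, 20, 70, 30, 60, 40, 90, 10),
    observed_crop = rep("corn", 8)
  )
  # identical allocation: nothing switches, flows are diagonal
  id_alloc <- dplyr::select(econ, county_id, crop) |>
    dplyr::mutate(acres = econ$baseline_area)
  sw <- summarize_switching(id_alloc, econ)
  expect_equal(sw$pct_switched, 0)
  expect_equal(sw$fallow_fraction, 0)
  expect_true(all(sw$flows$from == sw$flows$to))

  # one county flips corn -> soybeans: 25% switched, 0% excluding the swap
  flip <- id_alloc
  flip$acres[flip$county_id == "c1"] <- c(10, 90)
  sw2 <- summarize_switching(flip, econ)
  expect_equal(sw2$pct_switched, 25)
  expect_equal(sw2$pct_switched_excl_cornsoy, 0)

  # hand-tallied flow matrix: c1 moves 70 corn-acres into soybeans
  corn_to_soy <- sw2$flows$area[sw2$flows$from == "corn" &
                                  sw2$flows$to == "soybeans"]
  expect_equal(corn_to_soy, 70)
  corn_stay <- sw2$flows$area[sw2$flows$from == "corn" &
                                sw2$flows$to == "corn"]
  expect_equal(corn_stay, 10 + 70 + 60 + 90)

  # fallowing shows up as a flow into fallow and as switched counties
  fallow <- id_alloc
  fallow$acres[fallow$county_id == "c2"] <- 0
  sw3 <- summarize_switching(fallow, econ)
  expect_equal(sw3$pct_switched, 25)
  expect_equal(sw3$fallow_fraction, 100 / sum(econ$baseline_area))
  expect_equal(sw3$flows$area[sw3$flows$to == "fallow"], c(70, 30))
})

test_that("monte carlo optimization dominates the status quo draw by draw", {
  setup <- alloc_setup()
  scen <- dplyr::bind_rows(
    setup$base_scen,
    simulate_scenario(setup$st$panel, shifts = c(edd = 1), label = "warm",
                      het_sd = 0.1, seed = 12))
  mc <- monte_carlo_optimize(setup$fits, setup$econ_cal, scen,
                             setup$st$covariates, n_draws = 6, seed = 13)
  expect_true(all(mc$per_draw$profit_optimized >=
                    mc$per_draw$profit_status_quo - 1e-6))
  expect_true(all(mc$per_draw$duality_gap <= 1e-6))
  expect_true(all(mc$per_draw$max_violation <= 1e-6))
  # interval endpoints are the empirical 2.5% / 97.5% quantiles
  prof <- mc$per_draw$profit_optimized[mc$per_draw$period == "warm"]
  s <- mc$summary[mc$summary$period == "warm" &
                    mc$summary$metric == "profit_optimized", ]
  expect_equal(s$conf.low, unname(quantile(prof, 0.025)))
  expect_equal(s$conf.high, unname(quantile(prof, 0.975)))
  expect_equal(s$mean, mean(prof))

  # degenerate single-draw run: zero-width intervals equal to the outcome
  mc1 <- monte_carlo_optimize(setup$fits, setup$econ_cal, setup$base_scen,
                              setup$st$covariates, n_draws = 1, seed = 14)
  s1 <- mc1$summary
  expect_equal(s1$conf.low, s1$mean)
  expect_equal(s1$conf.high, s1$mean)
})

test_that("switching costs monotonically suppress reallocation", {
  setup <- alloc_setup()
  sweep <- switching_cost_sweep(setup$surf0, setup$econ_cal,
                                costs = c(0, 100, 500, 5000))
  expect_true(all(diff(sweep$objective) <= 1e-7 * sweep$objective[1]))
  expect_true(all(diff(sweep$reallocated_acres) <= 1e-6))
  # at a prohibitive cost the baseline-dominant pattern is restored
  expect_equal(sweep$pct_switched[sweep$switching_cost == 5000], 0)
  # and the net objective approaches the status-quo profit from above
  sq <- status_quo_profit(setup$surf0,
                          dplyr::select(setup$econ_cal, county_id, crop,
                                        baseline_area))
  expect_gte(sweep$objective[4], sq - 1e-6)
  expect_lt((sweep$objective[4] - sq) / abs(sq), 0.02)
})
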