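test_that("county generation is seed-deterministic with documented moments", {
  cfg <- sim_config()
  a <- simulate_counties(50, "corn", cfg, seed = 1)
  b <- simulate_counties(50, "corn", cfg, seed = 1)
  expect_identical(a, b)
  c2 <- simulate_counties(50, "corn", cfg, seed = 2)
  expect_false(identical(a, c2))
  expect_error(simulate_counties(1, "corn", cfg), "n_counties")

  # law-of-large-numbers check against the generator's documented values
  big <- simulate_counties(10000, "corn", cfg, seed = 3)
  expect_lt(abs(mean(big$mean_temp) - 15), 3 * 4.5 / sqrt(10000) + 0.05)
  expect_lt(abs(mean(big$isothermality) - 0.45), 3 * 0.07 / sqrt(10000) + 0.01)
  # declared positive temperature-precipitation association
  expect_gt(cor(big$mean_temp, big$annual_precip), 0.3)
  expect_true(all(big$irr_corn >= 0 & big$irr_corn <= 1))
})

test_that("true-parameter draws follow the covariate-conditional model", {
  cov <- simulate_counties(10000, "corn", sim_config(), seed = 4)
  # degenerate spread: coefficients equal their covariate-implied means
  cfg0 <- sim_config(hyper = list(sigma_alpha = 0,
                                  sigma_beta = c(t = 0, cdi = 0, gdd = 0,
                                                 edd = 0)))
  tp0 <- simulate_true_params(cov[1:100, ], "corn", cfg0, seed = 5)
  p <- tp0$per_crop$corn
  expect_equal(unname(as.matrix(p$county[, -1])), unname(p$implied_mean),
               tolerance = 1e-12)

  # zero loadings, unit spread: sample SD near 1
  B0 <- matrix(0, 4, 6, dimnames = list(c("t", "cdi", "gdd", "edd"), NULL))
  cfg1 <- sim_config(hyper = list(
    b0 = setNames(rep(0, 6), names(sim_config()$truth$b0)), B = B0,
    sigma_beta = c(t = 1, cdi = 1, gdd = 1, edd = 1)))
  tp1 <- simulate_true_params(cov, "corn", cfg1, seed = 6)
  sds <- apply(as.matrix(tp1$per_crop$corn$county[, c("t", "cdi", "gdd",
                                                      "edd")]), 2, sd)
  expect_true(all(abs(sds - 1) < 3 / sqrt(2 * 10000) + 0.02))

  # determinism
  expect_identical(simulate_true_params(cov[1:50, ], "corn", sim_config(),
                                        seed = 7),
                   simulate_true_params(cov[1:50, ], "corn", sim_config(),
                                        seed = 7))
})

test_that("noise-free panels reproduce the linear predictor exactly", {
  cfg <- sim_config(hyper = list(sigma = 0))
  cov <- simulate_counties(10, "corn", cfg, seed = 8)
  tp <- simulate_true_params(cov, "corn", cfg, seed = 9)
  pan <- simulate_yield_panel(tp, cov, n_years = 12, start_year = 2000,
                              cfg, seed = 10)
  std <- standardize_panel(pan, base_year = 2000)
  th <- tp$per_crop$corn$county
  one <- std[std$county_id == th$county_id[1], ]
  i <- 1
  pred <- th$alpha[i] + th$t[i] * one$t + th$cdi[i] * one$cdi +
    th$gdd[i] * one$gdd + th$edd[i] * one$edd
  expect_equal(one$log_yield, pred, tolerance = 1e-12)
})

test_that("per-county regression recovers that county's coefficients", {
  cfg <- sim_config()
  cov <- simulate_counties(5, "corn", cfg, seed = 11)
  tp <- simulate_true_params(cov, "corn", cfg, seed = 12)
  pan <- simulate_yield_panel(tp, cov, n_years = 400, start_year = 1800,
                              cfg, seed = 13)
  std <- standardize_panel(pan, base_year = 1800)
  th <- tp$per_crop$corn$county
  cid <- th$county_id[2]
  sub <- std[std$county_id == cid, ]
  fit <- lm(log_yield ~ t + cdi + gdd + edd, data = sub)
  est <- coef(fit)
  se <- sqrt(diag(vcov(fit)))
  truth <- unlist(th[th$county_id == cid, c("alpha", "t", "cdi", "gdd",
                                            "edd")])
  expect_true(all(abs(est - truth) < 4 * se))
})

test_that("panel bookkeeping matches grid minus recorded missingness", {
  cfg <- sim_config()
  cov <- simulate_counties(30, c("corn", "wheat"), cfg, seed = 14)
  tp <- simulate_true_params(cov, c("corn", "wheat"), cfg, seed = 15)
  pan <- simulate_yield_panel(tp, cov, n_years = 10, start_year = 2000,
                              cfg, seed = 16)
  expect_lte(nrow(pan), 30 * 10 * 2)
  expect_gte(nrow(pan), 30 * 10 * 2 * (1 - 0.15 - 0.02) * 0.9)
  # every county grows at least one crop
  expect_setequal(unique(pan$county_id), cov$county_id)
  # climatology covers the full grid
  clim <- attr(pan, "climatology")
  expect_equal(nrow(clim), 30 * 2)
})

test_that("economics designates observed crops with a controlled mismatch", {
  cfg0 <- sim_config(mismatch_fraction = 0)
  cov <- simulate_counties(40, c("corn", "soybeans", "wheat"), cfg0, seed = 17)
  tp <- simulate_true_params(cov, c("corn", "soybeans", "wheat"), cfg0,
                             seed = 18)
  pan <- simulate_yield_panel(tp, cov, n_years = 8, start_year = 2002, cfg0,
                              seed = 19)
  econ <- simulate_economics(pan, tp, cfg0, seed = 20)
  # with zero mismatch the observed crop is the grown-crop profit argmax
  chk <- econ |>
    dplyr::mutate(profit = price * expected_yield - cost) |>
    dplyr::filter(baseline_area > 0) |>
    dplyr::group_by(county_id) |>
    dplyr::summarise(ok = crop[which.max(profit)] == observed_crop[1],
                     biggest = crop[which.max(baseline_area)] ==
                       observed_crop[1])
  expect_true(all(chk$ok))
  expect_true(all(chk$biggest))   # observed crop is the most planted

  # mismatch rate close to its configured value among multi-crop counties
  cfg4 <- sim_config(mismatch_fraction = 0.4)
  cov2 <- simulate_counties(600, c("corn", "soybeans", "wheat"), cfg4,
                            seed = 21)
  tp2 <- simulate_true_params(cov2, c("corn", "soybeans", "wheat"), cfg4,
                              seed = 22)
  pan2 <- simulate_yield_panel(tp2, cov2, n_years = 6, start_year = 2004,
                               cfg4, seed = 23)
  econ2 <- simulate_economics(pan2, tp2, cfg4, seed = 24)
  mm <- econ2 |>
    dplyr::mutate(profit = price * expected_yield - cost) |>
    dplyr::filter(baseline_area > 0) |>
    dplyr::group_by(county_id) |>
    dplyr::filter(dplyr::n() > 1) |>
    dplyr::summarise(mis = crop[which.max(profit)] != observed_crop[1])
  n <- nrow(mm)
  expect_lt(abs(mean(mm$mis) - 0.4), 3 * sqrt(0.4 * 0.6 / n))
  expect_identical(simulate_economics(pan2, tp2, cfg4, seed = 24), econ2)
})

test_that("scenario shifts move the climatology by the stated amounts", {
  st <- small_study()
  zero <- simulate_scenario(st$panel, shifts = list(), label = "base",
                            het_sd = 0, seed = 1)
  clim <- attr(st$panel, "climatology")
  expect_equal(zero$edd, clim$edd)
  expect_equal(zero$cdi, clim$cdi)

  plus1 <- simulate_scenario(st$panel, shifts = list(corn = c(edd = 1)),
                             label = "warm", het_sd = 0, seed = 1)
  expect_equal(plus1$edd, clim$edd + 1)
  expect_equal(plus1$gdd, clim$gdd)

  het <- simulate_scenario(st$panel, shifts = list(corn = c(edd = 1)),
                           label = "warm", het_sd = 0.3, seed = 2)
  shift <- het$edd - clim$edd
  expect_lt(abs(mean(shift) - 1), 3 * 0.3 / sqrt(nrow(clim)))

  expect_error(simulate_scenario(st$panel, shifts = list(maize = c(edd = 1))),
               class = "cropshift_unknown_crop")
})

test_that("a full study fixture is reproducible end to end", {
  a <- simulate_study(n_counties = 10, n_years = 6, crops = "corn",
                      seed = 50)
  b <- simulate_study(n_counties = 10, n_years = 6, crops = "corn",
                      seed = 50)
  expect_identical(a$panel, b$panel)
  expect_identical(a$economics, b$economics)
  expect_identical(a$scenarios, b$scenarios)
})
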