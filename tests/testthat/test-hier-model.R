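tiny_model <- function() {
  # 3 counties x 2 years, fixed numbers
  pan <- tibble::tibble(
    county_id = rep(c("a", "b", "c"), each = 2),
    crop = "corn",
    t = rep(0:1, 3),
    cdi = c(0.1, -0.2, 0.3, 0.0, -0.1, 0.2),
    gdd = c(1.0, -0.5, 0.2, 0.8, -0.3, 0.1),
    edd = c(0.0, 1.2, -0.4, 0.3, 0.9, -0.2),
    log_yield = c(4.5, 4.7, 4.4, 4.6, 4.8, 4.3)
  )
  cov <- tibble::tibble(
    county_id = c("a", "b", "c"), mean_temp = c(10, 15, 20),
    isothermality = c(0.4, 0.45, 0.5), temp_seasonality = c(7, 8, 9),
    annual_precip = c(600, 800, 1000), precip_seasonality = c(25, 30, 35),
    irrigation_fraction = c(0.1, 0.2, 0.3)
  )
  build_hier_model(pan, cov, hier_spec())
}

test_that("log posterior equals an independently hand-coded density sum", {
  m <- tiny_model()
  set.seed(31)
  par <- list(
    gamma = matrix(rnorm(35, 0, 0.3), 5, 7),
    theta = matrix(rnorm(15, c(4.6, 0, 0, 0, 0), 0.2), 3, 5, byrow = TRUE),
    sd_group = c(0.2, 0.05, 0.1, 0.1, 0.15),
    sigma = 0.2
  )
  # oracle: direct summation of normal log densities, written from scratch
  Z <- cbind(1, scale(as.matrix(
    data.frame(mt = c(10, 15, 20), iso = c(0.4, 0.45, 0.5),
               ts = c(7, 8, 9), ap = c(600, 800, 1000),
               ps = c(25, 30, 35), irr = c(0.1, 0.2, 0.3)))))
  pan <- tibble::tibble(
    county = rep(1:3, each = 2), t = rep(0:1, 3),
    cdi = c(0.1, -0.2, 0.3, 0.0, -0.1, 0.2),
    gdd = c(1.0, -0.5, 0.2, 0.8, -0.3, 0.1),
    edd = c(0.0, 1.2, -0.4, 0.3, 0.9, -0.2),
    y = c(4.5, 4.7, 4.4, 4.6, 4.8, 4.3)
  )
  lp <- 0
  for (i in 1:3) {
    mu_i <- as.vector(Z[i, ] %*% t(par$gamma))
    lp <- lp + sum(dnorm(par$theta[i, ], mu_i, par$sd_group, log = TRUE))
  }
  for (n in seq_len(6)) {
    i <- pan$county[n]
    mu <- par$theta[i, 1] + par$theta[i, 2] * pan$t[n] +
      par$theta[i, 3] * pan$cdi[n] + par$theta[i, 4] * pan$gdd[n] +
      par$theta[i, 5] * pan$edd[n]
    lp <- lp + dnorm(pan$y[n], mu, par$sigma, log = TRUE)
  }
  lp <- lp + sum(dnorm(par$gamma, 0, 5, log = TRUE)) +
    sum(dnorm(par$sd_group, 0, 2.5, log = TRUE)) +
    dnorm(par$sigma, 0, 2.5, log = TRUE)
  expect_equal(log_posterior(m, par), lp, tolerance = 1e-10)
})

test_that("model building validates inputs", {
  m <- tiny_model()
  expect_s3_class(m, "hier_model")
  pan <- tibble::tibble(county_id = "zz", crop = "corn", t = 0, cdi = 0,
                        gdd = 0, edd = 0, log_yield = 4)
  cov <- tibble::tibble(county_id = "a", mean_temp = 1, isothermality = 1,
                        temp_seasonality = 1, annual_precip = 1,
                        precip_seasonality = 1, irrigation_fraction = 0.5)
  err <- expect_error(build_hier_model(pan, cov, hier_spec()),
                      class = "cropshift_missing_covariates")
  expect_match(conditionMessage(err), "zz")
  # non-positive raw yields rejected when log must be taken
  pan2 <- tibble::tibble(county_id = "a", crop = "corn", t = 0, cdi = 0,
                         gdd = 0, edd = 0, yield = -1)
  expect_error(build_hier_model(pan2, cov, hier_spec()),
               class = "cropshift_invalid_panel")
})

test_that("sampling is deterministic given the seed", {
  st <- small_study()
  f1 <- suppressWarnings(fit_hier(st$panel_std, st$cov_corn, hier_spec(),
                                  chains = 2, warmup = 50, draws = 60,
                                  seed = 42))
  f2 <- suppressWarnings(fit_hier(st$panel_std, st$cov_corn, hier_spec(),
                                  chains = 2, warmup = 50, draws = 60,
                                  seed = 42))
  expect_identical(f1$gamma, f2$gamma)
  expect_identical(f1$sigma, f2$sigma)
  f3 <- suppressWarnings(fit_hier(st$panel_std, st$cov_corn, hier_spec(),
                                  chains = 2, warmup = 50, draws = 60,
                                  seed = 43))
  expect_false(identical(f1$gamma, f3$gamma))
})

test_that("adding a constant to log-yields shifts only the intercept level", {
  st <- small_study()
  base <- small_fit()
  shifted_panel <- dplyr::mutate(st$panel_std, log_yield = log_yield + 1)
  shifted <- suppressWarnings(fit_hier(shifted_panel, st$cov_corn,
                                       hier_spec(), chains = 2,
                                       warmup = 200, draws = 300, seed = 7))
  a0_base <- mean(base$gamma[, "alpha", "intercept"])
  a0_shift <- mean(shifted$gamma[, "alpha", "intercept"])
  expect_lt(abs(a0_shift - a0_base - 1), 0.05)
  for (k in c("t", "cdi", "gdd", "edd")) {
    expect_lt(abs(mean(shifted$gamma[, k, "intercept"]) -
                    mean(base$gamma[, k, "intercept"])), 0.02)
  }
})

test_that("county-variance and uniform-variance fits agree on predictions", {
  st <- small_study()
  f2 <- small_fit()
  f1 <- suppressWarnings(fit_hier(st$panel_std, st$cov_corn,
                                  hier_spec(variance_mode = "county"),
                                  chains = 2, warmup = 200, draws = 300,
                                  seed = 7))
  p1 <- point_predict(f1, st$panel_std)
  p2 <- point_predict(f2, st$panel_std)
  expect_gt(cor(p1, p2), 0.995)
  # per-county residual SDs scatter around the uniform estimate
  expect_equal(median(colMeans(f1$sigma)), mean(f2$sigma), tolerance = 0.05)
})

test_that("posterior means match an independent JAGS fit of the same model", {
  skip_if_not_installed("rjags")
  cfg <- sim_config()
  cov <- simulate_counties(25, "corn", cfg, seed = 61)
  tp <- simulate_true_params(cov, "corn", cfg, seed = 62)
  pan <- simulate_yield_panel(tp, cov, n_years = 10, start_year = 2000,
                              cfg, seed = 63)
  std <- standardize_panel(pan, base_year = 2000)
  cc <- covariates_for_crop(cov, "corn")
  mine <- suppressWarnings(fit_hier(std, cc, hier_spec(), chains = 2,
                                    warmup = 400, draws = 1200, seed = 64))

  m <- build_hier_model(std, cc, hier_spec())
  jags_code <- "
    model {
      for (n in 1:N) {
        mu[n] <- inprod(D[n, ], theta[county[n], ])
        y[n] ~ dnorm(mu[n], prec_y)
      }
      for (i in 1:I) {
        for (k in 1:5) {
          mth[i, k] <- inprod(W[i, ], gamma[k, ])
          theta[i, k] ~ dnorm(mth[i, k], prec_g[k])
        }
      }
      for (k in 1:5) {
        for (j in 1:P) { gamma[k, j] ~ dnorm(0, 1 / 25) }
        sd_g[k] ~ dnorm(0, 1 / 6.25) T(0, )
        prec_g[k] <- 1 / (sd_g[k] * sd_g[k])
      }
      sigma ~ dnorm(0, 1 / 6.25) T(0, )
      prec_y <- 1 / (sigma * sigma)
    }"
  jm <- rjags::jags.model(
    textConnection(jags_code),
    data = list(N = m$N, I = m$I, P = ncol(m$W), y = m$y, D = m$D,
                county = m$idx, W = m$W),
    inits = list(.RNG.name = "base::Mersenne-Twister", .RNG.seed = 7),
    n.chains = 1, n.adapt = 500, quiet = TRUE)
  samp <- rjags::coda.samples(jm, c("gamma", "sd_g", "sigma"), n.iter = 3000)
  jmeans <- colMeans(as.matrix(samp))

  expect_lt(abs(mean(mine$gamma[, "alpha", "intercept"]) -
                  jmeans["gamma[1,1]"]), 0.02)
  expect_lt(abs(mean(mine$gamma[, "edd", "intercept"]) -
                  jmeans["gamma[5,1]"]), 0.02)
  expect_lt(abs(mean(mine$gamma[, "edd", "mean_temp"]) -
                  jmeans["gamma[5,2]"]), 0.02)
  expect_lt(abs(mean(mine$sigma) - jmeans["sigma"]), 0.01)
  expect_lt(abs(mean(mine$sd[, "sd_alpha"]) - jmeans["sd_g[1]"]), 0.03)
})

test_that("pinning group SDs reproduces the interacted regression limit", {
  st <- small_study()
  pin <- fit_hier(st$panel_std, st$cov_corn, hier_spec(pin_group_sd = 1e-4),
                  chains = 2, warmup = 200, draws = 500, seed = 9)
  ols3 <- fit_ols(build_ols_design(st$panel_std, st$cov_corn,
                                   ols_spec("ols3")))
  # reconstruct implied county coefficients from the OLS3 fit
  std <- cropshift:::standardize_covariates(st$cov_corn)
  covs <- cropshift:::covariate_cols
  co <- ols3$coefficients
  gmat <- rbind(co[1:7],
                co[c("t", paste0("t:", covs))],
                co[c("cdi", paste0("cdi:", covs))],
                co[c("gdd", paste0("gdd:", covs))],
                co[c("edd", paste0("edd:", covs))])
  th_ols <- std$W %*% t(gmat)
  th_bar <- apply(pin$theta, c(2, 3), mean)
  expect_lt(max(abs(th_bar - th_ols)), 0.01)
})

test_that("misspecified data yield clearly positive pooling SDs", {
  cfg <- sim_config(mode = "misspecified")
  cov <- simulate_counties(60, "corn", cfg, seed = 71)
  tp <- simulate_true_params(cov, "corn", cfg, seed = 72)
  pan <- simulate_yield_panel(tp, cov, n_years = 20, start_year = 1990,
                              cfg, seed = 73)
  std <- standardize_panel(pan, base_year = 1990)
  fit <- suppressWarnings(fit_hier(std, covariates_for_crop(cov, "corn"),
                                   hier_spec(), chains = 2, warmup = 200,
                                   draws = 400, seed = 74))
  # little pooling: the between-county EDD spread is bounded away from zero
  expect_gt(quantile(fit$sd[, "sd_edd"], 0.025), 0.03)
  expect_gt(quantile(fit$sd[, "sd_alpha"], 0.025), 0.05)
})
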