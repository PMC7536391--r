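#' Specify the hierarchical yield model
#'
#' The model is a three-level normal hierarchy fitted per crop. Level 1:
#' county-year log-yields are normal around a county-specific linear
#' function of trend, water-deficit index, and growing/extreme degree days.
#' Level 2: each county's intercept and four slopes are normal around a
#' linear function of six county covariates (partial pooling). Level 3:
#' weakly informative priors on all hyperparameters.
#'
#' `variance_mode = "county"` gives every county its own residual SD with a
#' shared lognormal hierarchical prior (few-year counties would otherwise
#' have unidentified variances); `"uniform"` constrains all counties to one
#' residual SD.
#'
#' @param variance_mode `"uniform"` (one residual SD) or `"county"`
#'   (per-county residual SDs with a hierarchical prior on their logs).
#' @param hyper_sd prior SD of the normal(0, `hyper_sd`) priors on
#'   hyper-intercepts and covariate loadings (covariates are standardized
#'   internally, so this is a weak prior on per-SD effects).
#' @param sd_scale scale of the half-normal priors on the between-county
#'   SDs and the residual SD.
#' @param lsig_mu_sd,lsig_tau_scale (county variance mode) prior SD of the
#'   mean of log residual SDs, and half-normal scale of their spread.
#' @param pin_group_sd optional: pin all between-county SDs to this value.
#'   Values below `1e-3` are treated as the exact degenerate limit: county
#'   effects are set identically to their covariate-implied means, which
#'   reduces the model to a Bayesian regression with covariate-interacted
#'   coefficients (the fixed-effects-free pooling limit).
#' @return object of class `hier_spec`.
#' @export
hier_spec <- function(variance_mode = c("uniform", "county"),
                      hyper_sd = 5, sd_scale = 2.5,
                      lsig_mu_sd = 1, lsig_tau_scale = 1,
                      pin_group_sd = NULL) {
  variance_mode <- match.arg(variance_mode)
  structure(list(variance_mode = variance_mode, hyper_sd = hyper_sd,
                 sd_scale = sd_scale, lsig_mu_sd = lsig_mu_sd,
                 lsig_tau_scale = lsig_tau_scale,
                 pin_group_sd = pin_group_sd),
            class = "hier_spec")
}

predictor_cols <- c("t", "cdi", "gdd", "edd")
component_names <- c("alpha", "t", "cdi", "gdd", "edd")

#' Build the hierarchical model object
#'
#' Assembles per-county sufficient statistics (cross-products of the
#' county design matrices) and the standardized covariate matrix, and
#' returns an object whose unnormalized log posterior can be evaluated at
#' any parameter point. The panel must contain one crop and be on the
#' standardized predictor scale (see [standardize_panel()]).
#'
#' @param panel standardized single-crop yield panel with columns
#'   `county_id, t, cdi, gdd, edd` and `log_yield` (or positive `yield`).
#' @param covariates per-crop covariate table (see [covariates_for_crop()]).
#' @param spec a [hier_spec()].
#' @return object of class `hier_model`.
#' @export
build_hier_model <- function(panel, covariates, spec = hier_spec()) {
  stopifnot(inherits(spec, "hier_spec"))
  check_columns(panel, c("county_id", predictor_cols), "panel")
  if (!"log_yield" %in% names(panel)) {
    check_columns(panel, "yield", "panel")
    if (any(panel$yield <= 0)) {
      cs_abort("yields must be positive (log-yield undefined)",
               class = "cropshift_invalid_panel")
    }
    panel$log_yield <- log(panel$yield)
  }
  if (length(unique(panel$crop %||% "one")) > 1) {
    cs_abort("build_hier_model fits one crop at a time")
  }
  if (anyNA(panel[c("log_yield", predictor_cols)])) {
    cs_abort("panel contains missing values", class = "cropshift_invalid_panel")
  }
  missing_cov <- setdiff(unique(panel$county_id), covariates$county_id)
  if (length(missing_cov) > 0) {
    cs_abort(paste0("counties in panel but not in covariates: ",
                    paste(head(missing_cov, 10), collapse = ", ")),
             class = "cropshift_missing_covariates")
  }
  covariates <- covariates[covariates$county_id %in% panel$county_id, ]
  std <- standardize_covariates(covariates)
  county_ids <- covariates$county_id
  I <- length(county_ids)
  idx <- match(panel$county_id, county_ids)

  D <- cbind(1, as.matrix(panel[predictor_cols]))
  colnames(D) <- component_names
  y <- panel$log_yield
  n_i <- tabulate(idx, I)
  DtD <- array(0, c(5, 5, I))
  Dty <- matrix(0, 5, I)
  yty <- numeric(I)
  for (i in seq_len(I)) {
    rows <- idx == i
    Di <- D[rows, , drop = FALSE]
    DtD[, , i] <- crossprod(Di)
    Dty[, i] <- crossprod(Di, y[rows])
    yty[i] <- sum(y[rows]^2)
  }
  # flattened DtD for vectorized quadratic forms
  DtDflat <- matrix(aperm(DtD, c(3, 1, 2)), nrow = I)

  structure(list(
    spec = spec, county_ids = county_ids, I = I, N = length(y),
    W = std$W, WtW = crossprod(std$W),
    covar_centers = std$centers, covar_scales = std$scales,
    DtD = DtD, DtDflat = DtDflat, Dty = Dty, yty = yty, n_i = n_i,
    D = D, y = y, idx = idx,
    crop = panel$crop[1] %||% NA_character_
  ), class = "hier_model")
}

#' Unnormalized log posterior of a hierarchical model
#'
#' Evaluates the log joint density (likelihood plus all priors, dropping
#' constants that do not involve parameters) at a full parameter point.
#' Used mainly for verification.
#'
#' @param model a [build_hier_model()] object.
#' @param par list with elements `gamma` (5 x 7 matrix, components alpha,
#'   t, cdi, gdd, edd by intercept + 6 covariates), `theta` (I x 5 county
#'   effects), `sd_group` (length-5 between-county SDs), and `sigma`
#'   (scalar, uniform mode) or `sigma_i`, `lsig_mu`, `lsig_tau` (county
#'   mode).
#' @return scalar log density.
#' @export
log_posterior <- function(model, par) {
  sp <- model$spec
  mu_theta <- model$W %*% t(par$gamma)        # I x 5
  lp <- sum(dnorm(par$theta, mu_theta,
                  rep(par$sd_group, each = model$I), log = TRUE))
  lp <- lp + sum(dnorm(par$gamma, 0, sp$hyper_sd, log = TRUE))
  lp <- lp + sum(dnorm(par$sd_group, 0, sp$sd_scale, log = TRUE))
  fitted <- model$D %*% t(par$theta)
  mu_y <- fitted[cbind(seq_len(model$N), model$idx)]
  if (sp$variance_mode == "uniform") {
    lp <- lp + sum(dnorm(model$y, mu_y, par$sigma, log = TRUE))
    lp <- lp + dnorm(par$sigma, 0, sp$sd_scale, log = TRUE)
  } else {
    lp <- lp + sum(dnorm(model$y, mu_y, par$sigma_i[model$idx], log = TRUE))
    lp <- lp + sum(dnorm(log(par$sigma_i), par$lsig_mu, par$lsig_tau,
                         log = TRUE))
    lp <- lp + dnorm(par$lsig_mu, 0, sp$lsig_mu_sd, log = TRUE)
    lp <- lp + dnorm(par$lsig_tau, 0, sp$lsig_tau_scale, log = TRUE)
  }
  lp
}

# univariate slice sampler (stepping out + shrinkage), Neal (2003)
slice_sample1 <- function(x0, logf, w = 1, m = 50L) {
  f0 <- logf(x0)
  if (!is.finite(f0)) cs_abort("slice sampler started at zero-density point")
  logy <- f0 - stats::rexp(1)
  u <- runif(1) * w
  L <- x0 - u
  R <- x0 + (w - u)
  j <- floor(runif(1) * m)
  k <- m - 1 - j
  while (j > 0 && logf(L) > logy) { L <- L - w; j <- j - 1 }
  while (k > 0 && logf(R) > logy) { R <- R + w; k <- k - 1 }
  repeat {
    x1 <- runif(1, L, R)
    if (logf(x1) >= logy) return(x1)
    if (x1 < x0) L <- x1 else R <- x1
  }
}

# sample from N(P^{-1} b, P^{-1}) given precision P and linear term b
rmvnorm_prec <- function(b, P) {
  ch <- chol(P)
  mu <- backsolve(ch, backsolve(ch, b, transpose = TRUE))
  mu + backsolve(ch, rnorm(length(b)))
}

# one Gibbs chain; returns draw matrices (post-warmup)
run_gibbs_chain <- function(model, warmup, draws, init) {
  sp <- model$spec
  I <- model$I
  W <- model$W
  p <- ncol(W)
  total <- warmup + draws
  pinned <- !is.null(sp$pin_group_sd)

  gamma <- init$gamma
  theta <- init$theta
  sd_group <- init$sd_group
  sigma <- init$sigma
  sigma_i <- init$sigma_i
  lsig_mu <- init$lsig_mu
  lsig_tau <- init$lsig_tau

  out_gamma <- array(NA_real_, c(draws, 5, p))
  out_sd <- matrix(NA_real_, draws, 5)
  out_theta <- array(NA_real_, c(draws, I, 5))
  out_sigma <- if (sp$variance_mode == "uniform") {
    numeric(draws)
  } else matrix(NA_real_, draws, I)
  out_lsig <- matrix(NA_real_, draws, 2)

  pairs_a <- rep(1:5, times = 5)
  pairs_b <- rep(1:5, each = 5)
  county_rss <- function(th) {
    quad <- rowSums(model$DtDflat * (th[, pairs_a] * th[, pairs_b]))
    cross <- rowSums(th * t(model$Dty))
    model$yty - 2 * cross + quad
  }

  if (pinned && sp$pin_group_sd < 1e-3) {
    # degenerate pooling limit: theta == W gamma'; Gibbs over (gamma, sigma)
    # on the induced covariate-interacted design
    V <- model$W[model$idx, rep(seq_len(p), times = 5)] *
      model$D[, rep(1:5, each = p)]
    VtV <- crossprod(V)
    Vty <- crossprod(V, model$y)
    yty_tot <- sum(model$y^2)
    gvec <- as.vector(t(gamma))          # length 5*p, component-major
    for (s in seq_len(total)) {
      P <- VtV / sigma^2 + diag(1 / sp$hyper_sd^2, 5 * p)
      gvec <- rmvnorm_prec(Vty / sigma^2, P)
      rss <- max(yty_tot - 2 * sum(gvec * Vty) +
                   sum(gvec * (VtV %*% gvec)), 1e-12)
      lsig <- slice_sample1(log(sigma), function(l) {
        -model$N * l - rss / (2 * exp(2 * l)) -
          exp(2 * l) / (2 * sp$sd_scale^2) + l
      }, w = 0.3)
      sigma <- exp(lsig)
      if (s > warmup) {
        k <- s - warmup
        gmat <- matrix(gvec, nrow = 5, byrow = TRUE)
        out_gamma[k, , ] <- gmat
        out_sd[k, ] <- sp$pin_group_sd
        out_theta[k, , ] <- W %*% t(gmat)
        out_sigma[k] <- sigma
      }
    }
    dimnames(out_gamma) <- list(NULL, component_names, colnames(W))
    colnames(out_sd) <- paste0("sd_", component_names)
    return(list(gamma = out_gamma, sd = out_sd, theta = out_theta,
                sigma = out_sigma, lsig = out_lsig))
  }

  for (s in seq_len(total)) {
    mu_theta <- W %*% t(gamma)                       # I x 5
    Tprec <- 1 / sd_group^2
    sig2_i <- if (sp$variance_mode == "uniform") {
      rep(sigma^2, I)
    } else sigma_i^2

    # county effects: joint 5-dim conjugate update per county
    for (i in seq_len(I)) {
      P <- model$DtD[, , i] / sig2_i[i] + diag(Tprec)
      b <- model$Dty[, i] / sig2_i[i] + Tprec * mu_theta[i, ]
      theta[i, ] <- rmvnorm_prec(b, P)
    }

    # hyper-coefficients: conjugate p-dim update per component
    for (k in 1:5) {
      P <- model$WtW / sd_group[k]^2 + diag(1 / sp$hyper_sd^2, p)
      b <- crossprod(W, theta[, k]) / sd_group[k]^2
      gamma[k, ] <- rmvnorm_prec(b, P)
    }

    # between-county SDs: slice sample each log-SD
    mu_theta <- W %*% t(gamma)
    if (!pinned) {
      dev2 <- colSums((theta - mu_theta)^2)
      for (k in 1:5) {
        lk <- slice_sample1(log(sd_group[k]), function(l) {
          -I * l - dev2[k] / (2 * exp(2 * l)) -
            exp(2 * l) / (2 * sp$sd_scale^2) + l
        }, w = 0.5)
        sd_group[k] <- exp(lk)
      }
    }

    # interweaving (ancillarity-sufficiency): re-draw (gamma_k, sd_k)
    # jointly in the non-centered parameterization, where the group SD
    # enters the likelihood as a regression coefficient on the scaled
    # deviations; cures the slow mixing of small group SDs under the
    # centered updates. Sign ambiguity of (sd, eta) resolved by folding.
    if (!pinned) {
      sig2_n <- if (sp$variance_mode == "uniform") {
        rep(sigma^2, model$N)
      } else sigma_i[model$idx]^2
      eta <- (theta - mu_theta) / rep(sd_group, each = I)
      fitted_n <- rowSums(model$D * theta[model$idx, ])
      Wn <- W[model$idx, , drop = FALSE]
      for (k in 1:5) {
        contrib <- theta[model$idx, k] * model$D[, k]
        yres <- model$y - fitted_n + contrib
        Xk <- cbind(Wn * model$D[, k], eta[model$idx, k] * model$D[, k])
        Xw <- Xk / sig2_n
        P <- crossprod(Xk, Xw)
        diag(P) <- diag(P) + c(rep(1 / sp$hyper_sd^2, p), 1 / sp$sd_scale^2)
        coefs <- rmvnorm_prec(crossprod(Xw, yres), P)
        gamma[k, ] <- coefs[seq_len(p)]
        if (coefs[p + 1] < 0) eta[, k] <- -eta[, k]
        sd_group[k] <- abs(coefs[p + 1])
        theta[, k] <- W %*% gamma[k, ] + sd_group[k] * eta[, k]
        fitted_n <- fitted_n - contrib + theta[model$idx, k] * model$D[, k]
      }
    }

    # residual SD(s)
    rss_i <- pmax(county_rss(theta), 0)
    if (sp$variance_mode == "uniform") {
      rss <- sum(rss_i)
      lsig <- slice_sample1(log(sigma), function(l) {
        -model$N * l - rss / (2 * exp(2 * l)) -
          exp(2 * l) / (2 * sp$sd_scale^2) + l
      }, w = 0.3)
      sigma <- exp(lsig)
    } else {
      lsig_i <- log(sigma_i)
      for (i in seq_len(I)) {
        lsig_i[i] <- slice_sample1(lsig_i[i], function(l) {
          -model$n_i[i] * l - rss_i[i] / (2 * exp(2 * l)) -
            (l - lsig_mu)^2 / (2 * lsig_tau^2)
        }, w = 0.5)
      }
      sigma_i <- exp(lsig_i)
      prec <- I / lsig_tau^2 + 1 / sp$lsig_mu_sd^2
      lsig_mu <- rnorm(1, (sum(lsig_i) / lsig_tau^2) / prec, sqrt(1 / prec))
      ss <- sum((lsig_i - lsig_mu)^2)
      ltau <- slice_sample1(log(lsig_tau), function(l) {
        -I * l - ss / (2 * exp(2 * l)) -
          exp(2 * l) / (2 * sp$lsig_tau_scale^2) + l
      }, w = 0.5)
      lsig_tau <- exp(ltau)
    }

    if (s > warmup) {
      k <- s - warmup
      out_gamma[k, , ] <- gamma
      out_sd[k, ] <- sd_group
      out_theta[k, , ] <- theta
      if (sp$variance_mode == "uniform") {
        out_sigma[k] <- sigma
      } else {
        out_sigma[k, ] <- sigma_i
        out_lsig[k, ] <- c(lsig_mu, lsig_tau)
      }
    }
  }
  dimnames(out_gamma) <- list(NULL, component_names, colnames(W))
  colnames(out_sd) <- paste0("sd_", component_names)
  list(gamma = out_gamma, sd = out_sd, theta = out_theta,
       sigma = out_sigma, lsig = out_lsig)
}

# data-driven starting point with per-chain jitter
gibbs_init <- function(model, chain) {
  I <- model$I
  theta0 <- matrix(0, I, 5)
  for (i in seq_len(I)) {
    theta0[i, ] <- solve(model$DtD[, , i] + diag(1e-4, 5), model$Dty[, i])
  }
  gamma0 <- t(solve(model$WtW + diag(1e-6, ncol(model$W)),
                    crossprod(model$W, theta0)))
  resid <- theta0 - model$W %*% t(gamma0)
  sd0 <- pmax(apply(resid, 2, sd), 0.02)
  rss <- pmax(sum(model$yty) - sum(theta0 * t(model$Dty)), 1e-6)
  sigma0 <- sqrt(rss / model$N)
  jit <- function(x, rel = 0.1) {
    if (chain == 1) x else x * exp(rnorm(length(x), 0, rel))
  }
  sp <- model$spec
  pin <- sp$pin_group_sd
  list(
    gamma = gamma0 + if (chain == 1) 0 else rnorm(length(gamma0), 0, 0.05),
    theta = theta0,
    sd_group = if (!is.null(pin)) rep(pin, 5) else jit(sd0),
    sigma = jit(sigma0),
    sigma_i = rep(jit(sigma0), I),
    lsig_mu = log(sigma0),
    lsig_tau = 0.3
  )
}

#' Fit the hierarchical model by blocked Gibbs sampling
#'
#' Runs a blocked Gibbs sampler: joint conjugate normal updates for each
#' county's five effects, conjugate updates for the hyper-coefficients, and
#' univariate slice sampling for every SD parameter. Chains start from a
#' jittered data-based point and are deterministic given `seed`.
#'
#' Convergence is assessed with split-R-hat and effective sample size on
#' all hyperparameters; a fit with `max(rhat) > rhat_max` is flagged with a
#' warning (never silently returned). Gibbs transitions have no divergence
#' pathology analogous to Hamiltonian samplers; the `divergences` field is
#' always 0 and is kept for interface compatibility.
#'
#' @param model a [build_hier_model()] object (or a standardized panel, in
#'   which case `covariates` and `spec` must be supplied).
#' @param covariates,spec used only when `model` is a panel.
#' @param chains,warmup,draws sampler settings (post-warmup draws per
#'   chain).
#' @param seed integer seed.
#' @param rhat_max convergence gate for flagging (default 1.01).
#' @return object of class `hier_fit`.
#' @export
fit_hier <- function(model, covariates = NULL, spec = hier_spec(),
                     chains = 4, warmup = 500, draws = 1000, seed = 1,
                     rhat_max = 1.01) {
  if (!inherits(model, "hier_model")) {
    model <- build_hier_model(model, covariates, spec)
  }
  stopifnot(chains >= 1, warmup >= 0, draws >= 1)
  t0 <- Sys.time()
  chain_out <- lapply(seq_len(chains), function(ch) {
    with_seed(derive_seed(seed, paste0("chain", ch)), {
      init <- gibbs_init(model, ch)
      run_gibbs_chain(model, warmup, draws, init)
    })
  })
  S <- chains * draws
  p <- ncol(model$W)
  bind1 <- function(name) {
    x <- lapply(chain_out, `[[`, name)
    if (is.matrix(x[[1]])) do.call(rbind, x)
    else if (is.array(x[[1]])) {
      out <- array(NA_real_, c(S, dim(x[[1]])[-1]), dimnames = c(list(NULL),
                   dimnames(x[[1]])[-1]))
      for (ch in seq_len(chains)) {
        out[(ch - 1) * draws + seq_len(draws), , ] <- x[[ch]]
      }
      out
    } else do.call(c, x)
  }
  fit <- structure(list(
    model = model, spec = model$spec, crop = model$crop,
    county_ids = model$county_ids,
    chains = chains, warmup = warmup, draws_per_chain = draws, seed = seed,
    chain = rep(seq_len(chains), each = draws),
    gamma = bind1("gamma"), sd = bind1("sd"),
    theta = structure(bind1("theta"),
                      dimnames = list(NULL, model$county_ids,
                                      component_names)),
    sigma = bind1("sigma"), lsig = bind1("lsig"),
    divergences = 0L,
    elapsed = as.numeric(difftime(Sys.time(), t0, units = "secs"))
  ), class = "hier_fit")
  fit$diagnostics <- hier_diagnostics(fit)
  fit$flagged <- any(fit$diagnostics$rhat > rhat_max, na.rm = TRUE)
  if (fit$flagged) {
    warn(sprintf("fit flagged: max split-R-hat %.3f exceeds %.3f",
                 max(fit$diagnostics$rhat, na.rm = TRUE), rhat_max))
  }
  fit
}

# split-R-hat from an iterations x chains matrix
split_rhat <- function(x) {
  n <- nrow(x)
  half <- floor(n / 2)
  if (half < 2) return(NA_real_)
  sub <- cbind(x[seq_len(half), , drop = FALSE],
               x[(n - half + 1):n, , drop = FALSE])
  m <- ncol(sub)
  means <- colMeans(sub)
  vars <- apply(sub, 2, var)
  W <- mean(vars)
  B <- half * var(means)
  if (W < 1e-12) return(1)
  sqrt(((half - 1) / half * W + B / half) / W)
}

# effective sample size via Geyer initial-monotone pairwise sums
ess_geyer <- function(x) {
  n <- nrow(x)
  m <- ncol(x)
  if (n < 8) return(NA_real_)
  rho <- sapply(seq_len(m), function(j) {
    a <- acf(x[, j], lag.max = min(n - 2, 200), plot = FALSE,
             demean = TRUE)$acf[, 1, 1]
    a
  })
  rho_mean <- rowMeans(rho)
  # pairwise sums Gamma_k = rho_{2k} + rho_{2k+1}, truncate at first
  # negative, enforce monotone decrease
  maxk <- floor((length(rho_mean) - 1) / 2)
  gam <- sapply(seq_len(maxk), function(k) {
    rho_mean[2 * k] + rho_mean[2 * k + 1]
  })
  pos <- which(gam <= 0)
  stop_at <- if (length(pos)) pos[1] - 1 else length(gam)
  if (stop_at > 1) gam <- cummin(gam[seq_len(stop_at)]) else gam <- gam[0]
  tau <- 1 + 2 * sum(gam)
  max(n * m / max(tau, 1e-6), 1)
}

hier_diagnostics <- function(fit) {
  draws <- fit$draws_per_chain
  chains <- fit$chains
  as_mat <- function(v) matrix(v, nrow = draws, ncol = chains)
  params <- list()
  p <- dim(fit$gamma)[3]
  for (k in 1:5) {
    for (j in 1:p) {
      nm <- paste0("gamma_", component_names[k], "_",
                   dimnames(fit$gamma)[[3]][j])
      params[[nm]] <- fit$gamma[, k, j]
    }
  }
  for (k in 1:5) params[[colnames(fit$sd)[k]]] <- fit$sd[, k]
  if (fit$spec$variance_mode == "uniform") {
    params[["sigma"]] <- fit$sigma
  } else {
    params[["lsig_mu"]] <- fit$lsig[, 1]
    params[["lsig_tau"]] <- fit$lsig[, 2]
  }
  pinned <- !is.null(fit$spec$pin_group_sd)
  purrr::imap_dfr(params, function(v, nm) {
    m <- as_mat(v)
    skip <- pinned && grepl("^sd_", nm)   # constants under pinning
    tibble::tibble(
      parameter = nm,
      mean = mean(v), sd = sd(v),
      rhat = if (skip) NA_real_ else split_rhat(m),
      ess = if (skip) NA_real_ else ess_geyer(m)
    )
  })
}

#' @export
print.hier_fit <- function(x, ...) {
  cat(sprintf("<hier_fit> crop=%s  %d counties, %d obs\n",
              x$crop, length(x$county_ids), x$model$N))
  cat(sprintf("  variance mode: %s;  %d chains x %d draws (warmup %d)\n",
              x$spec$variance_mode, x$chains, x$draws_per_chain, x$warmup))
  cat(sprintf("  max split-R-hat %.3f, min ESS %.0f, divergences %d%s\n",
              max(x$diagnostics$rhat, na.rm = TRUE),
              min(x$diagnostics$ess, na.rm = TRUE), x$divergences,
              if (isTRUE(x$flagged)) "  [FLAGGED]" else ""))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy hyperparameter summary of a hierarchical fit
#'
#' @param x a `hier_fit`.
#' @param conf_level credible-interval mass (default 0.95, equal-tailed).
#' @param ... unused.
#' @return tibble with one row per hyperparameter: posterior mean, SD,
#'   credible bounds, split-R-hat, and effective sample size.
#' @export
tidy.hier_fit <- function(x, conf_level = 0.95, ...) {
  a <- (1 - conf_level) / 2
  qs <- function(v) quantile(v, c(a, 1 - a), names = FALSE)
  base <- x$diagnostics
  lohi <- t(sapply(base$parameter, function(nm) {
    v <- hyper_param_vector(x, nm)
    qs(v)
  }))
  tibble::tibble(term = base$parameter, estimate = base$mean,
                 std.error = base$sd,
                 conf.low = lohi[, 1], conf.high = lohi[, 2],
                 rhat = base$rhat, ess = base$ess)
}

hyper_param_vector <- function(fit, nm) {
  if (grepl("^gamma_", nm)) {
    parts <- sub("^gamma_", "", nm)
    for (k in 1:5) {
      comp <- component_names[k]
      if (startsWith(parts, paste0(comp, "_"))) {
        j <- sub(paste0("^", comp, "_"), "", parts)
        return(fit$gamma[, k, j])
      }
    }
  }
  if (nm %in% colnames(fit$sd)) return(fit$sd[, nm])
  if (nm == "sigma") return(fit$sigma)
  if (nm == "lsig_mu") return(fit$lsig[, 1])
  if (nm == "lsig_tau") return(fit$lsig[, 2])
  cs_abort(sprintf("unknown parameter '%s'", nm))
}

#' One-row summary of a hierarchical fit
#' @param x a `hier_fit`.
#' @param ... unused.
#' @export
glance.hier_fit <- function(x, ...) {
  tibble::tibble(
    crop = x$crop, n_counties = length(x$county_ids), n_obs = x$model$N,
    chains = x$chains, draws = x$chains * x$draws_per_chain,
    max_rhat = max(x$diagnostics$rhat, na.rm = TRUE),
    min_ess = min(x$diagnostics$ess, na.rm = TRUE),
    divergences = x$divergences, flagged = isTRUE(x$flagged),
    elapsed_s = x$elapsed
  )
}

#' Serialize posterior draws to a long table
#'
#' Writes hyperparameter draws as a columnar table (`draw`, `chain`,
#' `parameter`, `value`) plus a diagnostics table, with the model spec
#' echoed in a comment header for provenance.
#'
#' @param fit a `hier_fit`.
#' @param path output TSV path; diagnostics go to
#'   `<path>_diagnostics.tsv`.
#' @export
write_posterior <- function(fit, path) {
  hdr <- sprintf("# crop=%s variance_mode=%s chains=%d draws=%d warmup=%d seed=%d",
                 fit$crop, fit$spec$variance_mode, fit$chains,
                 fit$draws_per_chain, fit$warmup, fit$seed)
  long <- purrr::map_dfr(fit$diagnostics$parameter, function(nm) {
    tibble::tibble(draw = seq_along(fit$chain), chain = fit$chain,
                   parameter = nm, value = hyper_param_vector(fit, nm))
  })
  con <- file(path, "w")
  writeLines(hdr, con)
  close(con)
  suppressWarnings(write.table(long, path, sep = "\t", quote = FALSE,
                               row.names = FALSE, append = TRUE))
  write_tsv_plain(fit$diagnostics,
                  sub("\\.tsv$", "_diagnostics.tsv", path))
  invisible(path)
}
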