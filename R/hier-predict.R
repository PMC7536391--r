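#' Posterior coefficient draws for observed or new counties
#'
#' For a county the model was fitted to, returns its fitted posterior
#' draws. For a county never observed growing the crop, each posterior draw
#' yields coefficients drawn from the covariate model: the covariate-implied
#' mean plus between-county dispersion, so predictive uncertainty for
#' unobserved counties is strictly larger than the covariate-mean
#' uncertainty alone.
#'
#' @param fit a [fit_hier()] object.
#' @param new_covariates per-crop covariate table (`county_id` + six
#'   covariates); defaults to the fitted counties.
#' @param seed seed for the between-county dispersion draws of unobserved
#'   counties.
#' @return array `[draws, counties, 5]` with component dimnames
#'   (alpha, t, cdi, gdd, edd) and an `observed` logical attribute.
#' @export
coefficient_draws <- function(fit, new_covariates = NULL, seed = 1) {
  if (is.null(new_covariates)) {
    out <- fit$theta
    dimnames(out) <- list(NULL, fit$county_ids, component_names)
    attr(out, "observed") <- rep(TRUE, length(fit$county_ids))
    return(out)
  }
  check_columns(new_covariates, "county_id", "new_covariates")
  ids <- new_covariates$county_id
  S <- length(fit$chain)
  out <- array(NA_real_, c(S, length(ids), 5),
               dimnames = list(NULL, ids, component_names))
  obs <- ids %in% fit$county_ids
  if (any(obs)) {
    out[, obs, ] <- fit$theta[, match(ids[obs], fit$county_ids), , drop = FALSE]
  }
  if (any(!obs)) {
    std <- standardize_covariates(new_covariates[!obs, , drop = FALSE],
                                  centers = fit$model$covar_centers,
                                  scales = fit$model$covar_scales)
    mu <- array(NA_real_, c(S, sum(!obs), 5))
    for (k in 1:5) {
      mu[, , k] <- fit$gamma[, k, ] %*% t(std$W)
    }
    noise <- with_seed(seed, {
      array(rnorm(S * sum(!obs) * 5), c(S, sum(!obs), 5))
    })
    for (k in 1:5) {
      noise[, , k] <- noise[, , k] * fit$sd[, k]   # recycles by draw
    }
    out[, !obs, ] <- mu + noise
  }
  attr(out, "observed") <- obs
  out
}

#' Summarize predicted county coefficients
#'
#' Posterior summaries of county-level coefficients for any set of
#' counties, observed or not, including the sign-agreement fraction (the
#' share of posterior draws on the majority sign, the statistic used to
#' outline high-confidence counties on coefficient maps).
#'
#' @inheritParams coefficient_draws
#' @param conf_level credible-interval mass.
#' @return tibble: `county_id`, `term`, `estimate`, `std.error`,
#'   `conf.low`, `conf.high`, `sign_agreement`, `observed`.
#' @export
predict_coefficients <- function(fit, new_covariates = NULL, seed = 1,
                                 conf_level = 0.95) {
  dr <- coefficient_draws(fit, new_covariates, seed)
  obs <- attr(dr, "observed")
  a <- (1 - conf_level) / 2
  ids <- dimnames(dr)[[2]]
  purrr::map_dfr(seq_along(ids), function(i) {
    purrr::map_dfr(1:5, function(k) {
      v <- dr[, i, k]
      tibble::tibble(
        county_id = ids[i], term = component_names[k],
        estimate = mean(v), std.error = sd(v),
        conf.low = quantile(v, a, names = FALSE),
        conf.high = quantile(v, 1 - a, names = FALSE),
        sign_agreement = sign_agreement(v),
        observed = obs[i]
      )
    })
  })
}

# fraction of draws sharing the majority sign (zeros split the vote)
sign_agreement <- function(x) {
  max(mean(x > 0), mean(x < 0))
}

#' Posterior predictive draws of log-yield
#'
#' Evaluates the model's mean function per posterior draw at given
#' predictor values, optionally adding observation noise.
#'
#' @param fit a [fit_hier()] object.
#' @param newdata rows with `county_id` and standardized predictors
#'   `t, cdi, gdd, edd`.
#' @param new_covariates covariate rows for counties absent from the fit.
#' @param type `"mean"` (mean function only) or `"predictive"` (adds
#'   residual noise; for unobserved counties in county-variance mode, the
#'   residual SD is drawn from the fitted lognormal population).
#' @param seed seed for dispersion/noise draws.
#' @return matrix `[draws, rows]` of log-yield values.
#' @export
posterior_predict_log_yield <- function(fit, newdata, new_covariates = NULL,
                                        type = c("mean", "predictive"),
                                        seed = 1) {
  type <- match.arg(type)
  check_columns(newdata, c("county_id", predictor_cols), "newdata")
  ids <- unique(newdata$county_id)
  cov_tbl <- new_covariates
  if (is.null(cov_tbl)) {
    missing <- setdiff(ids, fit$county_ids)
    if (length(missing) > 0) {
      cs_abort(paste0("counties not in fit and no covariates supplied: ",
                      paste(head(missing, 5), collapse = ", ")))
    }
    cov_tbl <- tibble::tibble(county_id = ids)
    dr <- fit$theta[, match(ids, fit$county_ids), , drop = FALSE]
    dimnames(dr) <- list(NULL, ids, component_names)
    obs <- rep(TRUE, length(ids))
  } else {
    cov_tbl <- cov_tbl[match(ids, cov_tbl$county_id), , drop = FALSE]
    dr <- coefficient_draws(fit, cov_tbl, seed = derive_seed(seed, "coef"))
    obs <- attr(dr, "observed")
  }
  S <- length(fit$chain)
  X <- cbind(1, as.matrix(newdata[predictor_cols]))
  ci <- match(newdata$county_id, ids)
  out <- matrix(0, S, nrow(newdata))
  for (k in 1:5) {
    out <- out + dr[, ci, k, drop = TRUE] * rep(X[, k], each = S)
  }
  if (type == "predictive") {
    sig <- residual_sd_draws(fit, ids, obs, seed = derive_seed(seed, "sig"))
    out <- out + with_seed(derive_seed(seed, "noise"), {
      matrix(rnorm(length(out)), S, ncol(out))
    }) * sig[, ci, drop = FALSE]
  }
  out
}

# per-draw residual SD for each county id (matrix draws x counties)
residual_sd_draws <- function(fit, ids, obs, seed = 1) {
  S <- length(fit$chain)
  if (fit$spec$variance_mode == "uniform") {
    return(matrix(fit$sigma, S, length(ids)))
  }
  out <- matrix(NA_real_, S, length(ids))
  inb <- ids %in% fit$county_ids
  if (any(inb)) out[, inb] <- fit$sigma[, match(ids[inb], fit$county_ids)]
  if (any(!inb)) {
    out[, !inb] <- with_seed(seed, {
      exp(rnorm(S * sum(!inb), fit$lsig[, 1], fit$lsig[, 2]))
    })
  }
  out
}

#' Point predictions at the posterior-mean parameters
#'
#' Follows the convention of evaluating the mean function at the average
#' of the parameter draws (parameters are averaged first, then the linear
#' predictor is evaluated). Because the mean function is linear in the
#' parameters, this equals the average of per-draw mean predictions.
#'
#' @inheritParams posterior_predict_log_yield
#' @return numeric vector of predicted log-yields, one per row of
#'   `newdata`.
#' @export
point_predict <- function(fit, newdata, new_covariates = NULL) {
  check_columns(newdata, c("county_id", predictor_cols), "newdata")
  ids <- unique(newdata$county_id)
  theta_bar <- matrix(NA_real_, length(ids), 5)
  obs <- ids %in% fit$county_ids
  if (any(obs)) {
    theta_bar[obs, ] <- apply(fit$theta[, match(ids[obs], fit$county_ids), ,
                                        drop = FALSE], c(2, 3), mean)
  }
  if (any(!obs)) {
    if (is.null(new_covariates)) {
      cs_abort(paste0("counties not in fit and no covariates supplied: ",
                      paste(head(ids[!obs], 5), collapse = ", ")))
    }
    std <- standardize_covariates(
      new_covariates[match(ids[!obs], new_covariates$county_id), , drop = FALSE],
      centers = fit$model$covar_centers, scales = fit$model$covar_scales)
    gamma_bar <- apply(fit$gamma, c(2, 3), mean)
    theta_bar[!obs, ] <- std$W %*% t(gamma_bar)
  }
  X <- cbind(1, as.matrix(newdata[predictor_cols]))
  rowSums(X * theta_bar[match(newdata$county_id, ids), , drop = FALSE])
}
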