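#' Coefficient of determination for log-yield predictions
#'
#' `R^2 = 1 - sum((y - yhat)^2) / sum((y - ybar)^2)`, with `ybar` the mean
#' of the observations being evaluated by default. Unbounded below: a model
#' can be (much) worse than predicting the mean, and negative values are
#' reported as-is, never clamped. Under a temporal holdout the reference
#' mean is ambiguous; pass `ybar` explicitly (e.g. the training-set mean)
#' for the alternative convention.
#'
#' @param y observed values.
#' @param yhat predictions, same length.
#' @param ybar reference mean (default `mean(y)`).
#' @return scalar R-squared.
#' @examples
#' r_squared(c(1, 2, 3), c(1, 2, 5))  # 1 - 4/2 = -1
#' @export
r_squared <- function(y, yhat, ybar = mean(y)) {
  if (length(y) != length(yhat)) cs_abort("y and yhat must match in length")
  if (length(y) < 2) cs_abort("need at least 2 observations")
  denom <- sum((y - ybar)^2)
  if (denom <= 0) {
    cs_abort("constant observations: R-squared undefined (zero denominator)",
             class = "cropshift_constant_response")
  }
  1 - sum((y - yhat)^2) / denom
}

#' Split a panel into training and evaluation years
#'
#' Exact, exhaustive partition by year: training rows have
#' `year <= split_year`, evaluation rows have `year > split_year`.
#'
#' @param panel a yield panel with a `year` column.
#' @param split_year last training year (default 1994).
#' @return list with tibbles `train` and `test`.
#' @export
temporal_split <- function(panel, split_year = 1994) {
  check_columns(panel, "year", "panel")
  train <- panel[panel$year <= split_year, , drop = FALSE]
  test <- panel[panel$year > split_year, , drop = FALSE]
  if (nrow(train) == 0 || nrow(test) == 0) {
    cs_abort(sprintf("split at %d leaves an empty side (years %d-%d)",
                     split_year, min(panel$year), max(panel$year)),
             class = "cropshift_bad_split")
  }
  list(train = train, test = test)
}

#' Run the model-comparison grid
#'
#' Fits the requested models per crop on all years (in-sample scope) and on
#' the training side of a temporal split (cross-validation scope, evaluated
#' on the held-out years), and reports the R-squared of point predictions:
#' the posterior-mean-parameter prediction for the Bayesian models and the
#' least-squares point estimate for the OLS baselines.
#'
#' @param panel standardized multi- or single-crop panel with `log_yield`.
#' @param covariates covariate table ([simulate_counties()] layout, i.e.
#'   with `irr_<crop>` columns) or a single-crop six-covariate table.
#' @param models subset of `c("ols1","ols2","ols3","ols4","bayes1","bayes2")`.
#' @param split_year temporal split for the CV scope; `NULL` skips CV.
#' @param cv_mean `"test"` (default) or `"train"`: which observations
#'   define the reference mean in the CV R-squared denominator.
#' @param chains,warmup,draws,seed sampler settings for the Bayesian models.
#' @return tibble: `crop`, `model`, `scope` (`"all-years"` / `"cv"`),
#'   `r_squared`, `n_obs`.
#' @export
run_comparison <- function(panel, covariates,
                           models = c("ols1", "ols2", "ols3", "ols4",
                                      "bayes1", "bayes2"),
                           split_year = NULL, cv_mean = c("test", "train"),
                           chains = 2, warmup = 300, draws = 500, seed = 1) {
  cv_mean <- match.arg(cv_mean)
  crops <- unique(panel$crop %||% "crop")
  purrr::map_dfr(crops, function(cr) {
    pan <- panel[is.null(panel$crop) | panel$crop == cr, , drop = FALSE]
    cov_crop <- if ("irrigation_fraction" %in% names(covariates)) {
      covariates
    } else {
      covariates_for_crop(covariates, cr)
    }
    scopes <- list(`all-years` = list(train = pan, test = pan))
    if (!is.null(split_year)) {
      scopes$cv <- temporal_split(pan, split_year)
    }
    purrr::imap_dfr(scopes, function(sc, scope_name) {
      ybar <- if (scope_name == "cv" && cv_mean == "train") {
        mean(sc$train$log_yield)
      } else {
        mean(sc$test$log_yield)
      }
      purrr::map_dfr(models, function(m) {
        yhat <- if (startsWith(m, "ols")) {
          fit <- fit_ols(build_ols_design(sc$train, cov_crop, ols_spec(m)))
          predict_ols(fit, sc$test, cov_crop)
        } else {
          vm <- if (m == "bayes1") "county" else "uniform"
          fit <- fit_hier(sc$train, cov_crop, hier_spec(variance_mode = vm),
                          chains = chains, warmup = warmup, draws = draws,
                          seed = derive_seed(seed, paste(cr, m, scope_name)))
          point_predict(fit, sc$test, new_covariates = cov_crop)
        }
        tibble::tibble(crop = cr, model = m, scope = scope_name,
                       r_squared = r_squared(sc$test$log_yield, yhat, ybar),
                       n_obs = nrow(sc$test))
      })
    })
  })
}

#' Plot a model-comparison grid
#'
#' @param comparison output of [run_comparison()].
#' @return a ggplot: R-squared by model, faceted by crop, colored by scope.
#' @export
plot_comparison <- function(comparison) {
  ggplot2::ggplot(comparison,
                  ggplot2::aes(x = .data$model, y = .data$r_squared,
                               fill = .data$scope)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_wrap(~crop) +
    ggplot2::labs(x = NULL, y = expression(R^2), fill = NULL) +
    ggplot2::theme_minimal()
}
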