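#' The four least-squares baseline specifications
#'
#' The comparison grid spans four OLS specifications distinguished by their
#' intercepts and slopes: `ols1` (uniform intercept, uniform slopes),
#' `ols2` (county intercepts, uniform slopes), `ols3`
#' (covariate-interacted intercept and slopes), and `ols4` (county
#' intercepts, covariate-interacted slopes). `ols4` omits covariate main
#' effects on the intercept, which would be collinear with the county
#' indicators.
#'
#' @param name one of `"ols1"`, `"ols2"`, `"ols3"`, `"ols4"`.
#' @return object of class `ols_spec`.
#' @export
ols_spec <- function(name = c("ols1", "ols2", "ols3", "ols4")) {
  name <- match.arg(name)
  layout <- switch(name,
    ols1 = list(intercepts = "uniform", coefficients = "uniform"),
    ols2 = list(intercepts = "county", coefficients = "uniform"),
    ols3 = list(intercepts = "interacted", coefficients = "interacted"),
    ols4 = list(intercepts = "county", coefficients = "interacted"))
  structure(c(list(name = name), layout), class = "ols_spec")
}

covariate_cols <- c("mean_temp", "isothermality", "temp_seasonality",
                    "annual_precip", "precip_seasonality",
                    "irrigation_fraction")

#' Build the design matrix for an OLS specification
#'
#' @param panel standardized single-crop panel with `county_id`,
#'   predictors, and `log_yield`.
#' @param covariates per-crop covariate table (standardized internally;
#'   pass `scaling` to reuse a training-set scaling at prediction time).
#' @param spec an [ols_spec()] or its name.
#' @param scaling optional list(centers, scales) from a previous design.
#' @param county_levels county set defining the indicator columns (defaults
#'   to counties present in `panel`).
#' @return list: `X` (design matrix), `y` (response, `NULL` when the panel
#'   has no `log_yield`), `spec`, `county_levels`, `scaling`.
#' @export
build_ols_design <- function(panel, covariates, spec = ols_spec("ols1"),
                             scaling = NULL, county_levels = NULL) {
  if (is.character(spec)) spec <- ols_spec(spec)
  check_columns(panel, c("county_id", predictor_cols), "panel")
  county_levels <- county_levels %||% sort(unique(panel$county_id))

  needs_cov <- spec$intercepts == "interacted" ||
    spec$coefficients == "interacted"
  Z <- NULL
  if (needs_cov) {
    cv <- covariates[match(panel$county_id, covariates$county_id), ,
                     drop = FALSE]
    if (anyNA(cv$county_id)) {
      cs_abort("counties in panel missing from covariates",
               class = "cropshift_missing_covariates")
    }
    std <- standardize_covariates(cv, centers = scaling$centers,
                                  scales = scaling$scales)
    Z <- std$W[, -1, drop = FALSE]        # standardized covariates, no 1s
    scaling <- list(centers = std$centers, scales = std$scales)
  }

  X_int <- switch(spec$intercepts,
    uniform = matrix(1, nrow(panel), 1, dimnames = list(NULL, "(Intercept)")),
    county = {
      f <- factor(panel$county_id, levels = county_levels)
      if (anyNA(f)) {
        bad <- unique(panel$county_id[is.na(f)])
        cs_abort(paste0("unseen county under county-intercept spec: ",
                        paste(head(bad, 5), collapse = ", ")),
                 class = "cropshift_unseen_county")
      }
      M <- stats::model.matrix(~ 0 + f)
      colnames(M) <- paste0("county:", county_levels)
      M
    },
    interacted = {
      M <- cbind(1, Z)
      colnames(M) <- c("(Intercept)", paste0("covar:", covariate_cols))
      M
    })

  Xp <- as.matrix(panel[predictor_cols])
  X_slope <- if (spec$coefficients == "uniform") {
    Xp
  } else {
    blocks <- lapply(predictor_cols, function(v) {
      B <- cbind(panel[[v]], Z * panel[[v]])
      colnames(B) <- c(v, paste0(v, ":", covariate_cols))
      B
    })
    do.call(cbind, blocks)
  }
  X <- cbind(X_int, X_slope)
  list(X = X, y = panel$log_yield, spec = spec,
       county_levels = county_levels, scaling = scaling)
}

#' Fit an OLS baseline by QR decomposition
#'
#' @param design a [build_ols_design()] result, or a panel (then
#'   `covariates` and `spec` build the design first).
#' @param covariates,spec used when `design` is a panel.
#' @return object of class `ols_fit` with named coefficients, the residual
#'   variance, and the design metadata needed for prediction. A
#'   rank-deficient design is an error naming the aliased columns, never a
#'   silent pseudo-inverse.
#' @export
fit_ols <- function(design, covariates = NULL, spec = NULL) {
  if (!is.list(design) || is.data.frame(design)) {
    design <- build_ols_design(design, covariates, spec)
  }
  X <- design$X
  y <- design$y
  if (is.null(y)) cs_abort("design has no response (panel lacked log_yield)")
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    aliased <- colnames(X)[qr_x$pivot[(qr_x$rank + 1):ncol(X)]]
    cs_abort(paste0("rank-deficient design; aliased columns: ",
                    paste(head(aliased, 10), collapse = ", ")),
             class = "cropshift_rank_deficient")
  }
  beta <- qr.coef(qr_x, y)
  resid <- y - X %*% beta
  structure(list(
    coefficients = setNames(as.vector(beta), colnames(X)),
    sigma2 = sum(resid^2) / max(length(y) - ncol(X), 1),
    n = length(y), rank = qr_x$rank, spec = design$spec,
    county_levels = design$county_levels, scaling = design$scaling
  ), class = "ols_fit")
}

#' Predict from an OLS baseline
#'
#' Under county-intercept specifications, counties absent from the training
#' data have no intercept; by default that is an error. With
#' `unseen = "mean_intercept"` the average fitted county intercept is used
#' instead and the affected rows are flagged in the `"unseen_counties"`
#' attribute.
#'
#' @param fit an [fit_ols()] object.
#' @param panel rows to predict (standardized predictors).
#' @param covariates per-crop covariate table (interacted specs).
#' @param unseen `"error"` or `"mean_intercept"`.
#' @return numeric vector of predicted log-yields.
#' @export
predict_ols <- function(fit, panel, covariates = NULL,
                        unseen = c("error", "mean_intercept")) {
  unseen <- match.arg(unseen)
  spec <- fit$spec
  unseen_ids <- character(0)
  if (spec$intercepts == "county") {
    unseen_ids <- setdiff(unique(panel$county_id), fit$county_levels)
    if (length(unseen_ids) > 0 && unseen == "error") {
      cs_abort(paste0("prediction in counties unseen at fit time: ",
                      paste(head(unseen_ids, 5), collapse = ", "),
                      " (county-intercept specification)"),
               class = "cropshift_unseen_county")
    }
    panel_known <- panel[!panel$county_id %in% unseen_ids, , drop = FALSE]
  } else {
    panel_known <- panel
  }
  out <- rep(NA_real_, nrow(panel))
  if (nrow(panel_known) > 0) {
    d <- build_ols_design(panel_known, covariates, spec,
                          scaling = fit$scaling,
                          county_levels = fit$county_levels)
    out[!panel$county_id %in% unseen_ids] <-
      as.vector(d$X %*% fit$coefficients)
  }
  if (length(unseen_ids) > 0) {
    # mean county intercept + the slope part of the design
    ci <- fit$coefficients[startsWith(names(fit$coefficients), "county:")]
    rows <- panel$county_id %in% unseen_ids
    pu <- panel[rows, , drop = FALSE]
    d <- build_ols_design(dplyr::mutate(pu, county_id = fit$county_levels[1]),
                          covariates, spec, scaling = fit$scaling,
                          county_levels = fit$county_levels)
    slope_cols <- !startsWith(colnames(d$X), "county:")
    out[rows] <- mean(ci) +
      as.vector(d$X[, slope_cols, drop = FALSE] %*%
                  fit$coefficients[slope_cols])
    attr(out, "unseen_counties") <- unseen_ids
  }
  out
}

#' @export
print.ols_fit <- function(x, ...) {
  cat(sprintf("<ols_fit> %s: %d terms, n=%d, residual SD %.4f\n",
              x$spec$name, length(x$coefficients), x$n, sqrt(x$sigma2)))
  invisible(x)
}

#' @export
tidy.ols_fit <- function(x, ...) {
  tibble::tibble(term = names(x$coefficients),
                 estimate = unname(x$coefficients))
}

#' @export
glance.ols_fit <- function(x, ...) {
  tibble::tibble(spec = x$spec$name, n = x$n, rank = x$rank,
                 sigma = sqrt(x$sigma2))
}
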