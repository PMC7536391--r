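# shared fixtures, built once per test run and cached
.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixtures)) {
    assign(name, builder(), envir = .fixtures)
  }
  get(name, envir = .fixtures)
}

# small single-crop faithful study + standardized panel
small_study <- function() {
  fixture("small_study", function() {
    st <- simulate_study(n_counties = 40, n_years = 20, crops = "corn",
                         start_year = 1990, seed = 101)
    st$panel_std <- standardize_panel(st$panel, base_year = 1990)
    st$cov_corn <- covariates_for_crop(st$covariates, "corn")
    st
  })
}

# a reusable short hierarchical fit on the small study
small_fit <- function() {
  fixture("small_fit", function() {
    st <- small_study()
    suppressWarnings(fit_hier(st$panel_std, st$cov_corn, hier_spec(),
                              chains = 2, warmup = 200, draws = 300,
                              seed = 7))
  })
}

# multi-crop study for the economics / allocation stack
alloc_study <- function() {
  fixture("alloc_study", function() {
    st <- simulate_study(n_counties = 25, n_years = 12,
                         crops = c("corn", "soybeans", "wheat"),
                         start_year = 1998, seed = 33)
    st$panel_std <- standardize_panel(st$panel, base_year = 1998)
    st
  })
}

# fits + calibrated economics + baseline scenario for the alloc study
alloc_setup <- function() {
  fixture("alloc_setup", function() {
    st <- alloc_study()
    fits <- lapply(setNames(st$params$crops, st$params$crops), function(cr) {
      suppressWarnings(fit_hier(
        st$panel_std[st$panel_std$crop == cr, ],
        covariates_for_crop(st$covariates, cr), hier_spec(),
        chains = 2, warmup = 120, draws = 200, seed = 5))
    })
    clim <- attr(st$panel, "climatology")
    base_scen <- dplyr::mutate(clim, period = "baseline",
                               t = max(st$panel$year) - 1998, .before = 1)
    yhat <- dplyr::bind_rows(lapply(names(fits), function(cr) {
      rows <- base_scen[base_scen$crop == cr, ]
      tibble::tibble(
        county_id = rows$county_id, crop = cr,
        expected_yield = exp(point_predict(
          fits[[cr]], rows,
          new_covariates = covariates_for_crop(st$covariates, cr))))
    }))
    econ_cal <- calibrate_hidden_costs(st$economics, yields = yhat)
    surf0 <- yhat |>
      dplyr::inner_join(dplyr::select(econ_cal, county_id, crop, price, cost),
                        by = c("county_id", "crop")) |>
      dplyr::mutate(profit = price * expected_yield - cost)
    list(st = st, fits = fits, base_scen = base_scen, yhat = yhat,
         econ_cal = econ_cal, surf0 = surf0)
  })
}

# brute-force optimum of a tiny integer transportation instance
brute_force_allocation <- function(pi_mat, land, caps) {
  I <- nrow(pi_mat)
  C <- ncol(pi_mat)
  opts <- lapply(seq_len(I), function(i) {
    g <- as.matrix(expand.grid(rep(list(0:land[i]), C)))
    g[rowSums(g) <= land[i], , drop = FALSE]
  })
  best <- -Inf
  recurse <- function(i, acc) {
    if (i > I) {
      A <- do.call(rbind, acc)
      if (all(colSums(A) <= caps + 1e-9)) {
        best <<- max(best, sum(pi_mat * A))
      }
      return(invisible())
    }
    for (r in seq_len(nrow(opts[[i]]))) {
      recurse(i + 1, c(acc, list(opts[[i]][r, ])))
    }
  }
  recurse(1, list())
  best
}

# fine-quadrature oracle for single-sine degree days (dt seconds)
quadrature_degree_days <- function(tmin, tmax, base, ceiling = Inf,
                                   dt = 1) {
  h <- seq(0, 86400 - dt, by = dt) / 86400
  temp <- (tmax + tmin) / 2 + (tmax - tmin) / 2 * sin(2 * pi * h)
  mean(pmin(pmax(temp - base, 0), ceiling - base))
}
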