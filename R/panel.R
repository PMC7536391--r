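#' Standardize a yield panel's weather predictors
#'
#' Puts the predictors on the per-crop standardized scale used throughout
#' the modelling: `cdi`, `gdd` and `edd` are z-scored within crop (centered
#' at the per-crop mean over all county-years and divided by the per-crop
#' standard deviation), and the trend `t` is centered at `base_year` but not
#' rescaled, so trend coefficients stay in per-year units. Weather
#' coefficients are then interpretable as the fractional yield effect of a
#' one-standard-deviation change in the predictor. The applied centers and
#' scales are recorded so the transform is invertible.
#'
#' @param panel yield panel with columns `county_id`, `year`, `crop`, `t`,
#'   `cdi`, `gdd`, `edd` (and usually `log_yield`).
#' @param base_year year at which the trend is centered; defaults to the
#'   earliest year in the panel.
#' @return the standardized panel (tibble) with a `scaling` attribute: a
#'   tibble of per-crop centers and scales, retrievable with
#'   [panel_scaling()].
#' @examples
#' pan <- tibble::tibble(county_id = "c1", year = 2000:2004,
#'                       crop = "corn", t = 2000:2004,
#'                       cdi = c(.1, .2, .3, .2, .1),
#'                       gdd = c(1500, 1600, 1550, 1700, 1650),
#'                       edd = c(10, 40, 20, 80, 30))
#' std <- standardize_panel(pan)
#' panel_scaling(std)
#' @export
standardize_panel <- function(panel, base_year = NULL) {
  check_columns(panel, c("county_id", "year", "crop", "t", "cdi", "gdd", "edd"),
                "yield panel")
  panel <- tibble::as_tibble(panel)
  if (nrow(panel) == 0) cs_abort("panel is empty")
  base_year <- base_year %||% min(panel$year)

  scaling <- panel |>
    dplyr::group_by(.data$crop) |>
    dplyr::summarise(dplyr::across(c("cdi", "gdd", "edd"),
                                   list(center = mean, sd = sd)),
                     .groups = "drop") |>
    dplyr::mutate(base_year = base_year)

  bad <- scaling |>
    tidyr::pivot_longer(dplyr::ends_with("_sd"),
                        names_to = "predictor", values_to = "sd_value") |>
    dplyr::filter(is.na(.data$sd_value) | .data$sd_value <= 0)
  if (nrow(bad) > 0) {
    cs_abort(sprintf("zero-variance predictor(s): %s",
                     paste(sub("_sd$", "", bad$predictor), "for crop",
                           bad$crop, collapse = "; ")),
             class = "cropshift_zero_variance")
  }

  out <- panel |>
    dplyr::left_join(scaling, by = "crop") |>
    dplyr::mutate(
      t = .data$t - base_year,
      cdi = (.data$cdi - .data$cdi_center) / .data$cdi_sd,
      gdd = (.data$gdd - .data$gdd_center) / .data$gdd_sd,
      edd = (.data$edd - .data$edd_center) / .data$edd_sd
    ) |>
    dplyr::select(-dplyr::ends_with("_center"), -dplyr::ends_with("_sd"),
                  -"base_year")
  attr(out, "scaling") <- scaling
  out
}

#' Retrieve the scaling recorded by [standardize_panel()]
#' @param panel a panel returned by [standardize_panel()].
#' @return per-crop tibble of predictor centers and standard deviations.
#' @export
panel_scaling <- function(panel) {
  sc <- attr(panel, "scaling")
  if (is.null(sc)) cs_abort("panel carries no scaling attribute")
  sc
}

#' Invert [standardize_panel()]
#' @param panel standardized panel.
#' @param scaling scaling tibble; defaults to the one attached to `panel`.
#' @return panel on the original predictor scale.
#' @export
unstandardize_panel <- function(panel, scaling = NULL) {
  scaling <- scaling %||% attr(panel, "scaling")
  if (is.null(scaling)) cs_abort("no scaling supplied or attached")
  out <- panel |>
    dplyr::left_join(scaling, by = "crop") |>
    dplyr::mutate(
      t = .data$t + .data$base_year,
      cdi = .data$cdi * .data$cdi_sd + .data$cdi_center,
      gdd = .data$gdd * .data$gdd_sd + .data$gdd_center,
      edd = .data$edd * .data$edd_sd + .data$edd_center
    ) |>
    dplyr::select(-dplyr::ends_with("_center"), -dplyr::ends_with("_sd"),
                  -"base_year")
  attr(out, "scaling") <- NULL
  out
}

# ---- delimited-table IO ------------------------------------------------
# All pipeline tables are plain TSV with a header row; readers return
# tibbles. Kept deliberately thin.

#' Read / write the package's delimited tables
#'
#' Plain tab-separated tables with a header row. `read_daily_weather()`
#' expects columns `county_id, date, tmin, tmax, precip, pet` (ISO-8601
#' dates); `read_yield_panel()` expects
#' `county_id, year, crop, t, cdi, gdd, edd` plus optionally `log_yield`.
#' `read_crop_calendar()` reads a YAML file keyed by crop name with fields
#' `season_start`, `season_end`, `gdd_base`, `gdd_ceiling`, `edd_threshold`.
#'
#' @param path file path.
#' @name table_io
#' @return a tibble (readers) or `path`, invisibly (writers).
NULL

#' @rdname table_io
#' @export
read_daily_weather <- function(path) {
  w <- tibble::as_tibble(read.delim(path, sep = "\t", stringsAsFactors = FALSE))
  check_columns(w, c("county_id", "date", "tmin", "tmax", "precip", "pet"),
                path)
  w$date <- as.Date(w$date)
  w
}

#' @rdname table_io
#' @param x table to write.
#' @export
write_daily_weather <- function(x, path) {
  write_tsv_plain(x, path)
}

#' @rdname table_io
#' @export
read_yield_panel <- function(path) {
  p <- tibble::as_tibble(read.delim(path, sep = "\t", stringsAsFactors = FALSE))
  check_columns(p, c("county_id", "year", "crop", "t", "cdi", "gdd", "edd"),
                path)
  p
}

#' @rdname table_io
#' @export
write_yield_panel <- function(x, path) {
  write_tsv_plain(x, path)
}

#' @rdname table_io
#' @export
read_crop_calendar <- function(path) {
  raw <- yaml::read_yaml(path)
  purrr::imap_dfr(raw, function(entry, crop) {
    tibble::tibble(crop = crop,
                   season_start = as.integer(entry$season_start),
                   season_end = as.integer(entry$season_end),
                   gdd_base = as.numeric(entry$gdd_base),
                   gdd_ceiling = as.numeric(entry$gdd_ceiling),
                   edd_threshold = as.numeric(entry$edd_threshold))
  })
}

write_tsv_plain <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv_plain <- function(path) {
  tibble::as_tibble(read.delim(path, sep = "\t", stringsAsFactors = FALSE))
}
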