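#' Single-sine degree days for one day
#'
#' Computes degree days accumulated over a single day, interpolating the
#' diurnal temperature cycle as a sine wave between `tmin` and `tmax`
#' (the classic single-sine / single-triangle family of methods; here the
#' sine variant). Temperature contributions are truncated below at `base`
#' and capped at `ceiling`, i.e. the integrand is
#' `clamp(T(h) - base, 0, ceiling - base)`.
#'
#' The capped integral is evaluated as the difference of two uncapped
#' exceedance integrals, `dd_above(base) - dd_above(ceiling)`, each of which
#' has a closed form. A constant-temperature day (`tmin == tmax`) is the
#' analytic limit of the sine formula and needs no special branch.
#'
#' @param tmin,tmax daily minimum and maximum temperature (degrees C).
#'   Vectors are recycled to a common length.
#' @param base lower development threshold (degrees C).
#' @param ceiling upper cap (degrees C); use `Inf` for uncapped exceedance
#'   (the extreme-degree-day convention).
#' @return numeric vector of degree days (degree C days), in
#'   `[0, ceiling - base]` per day.
#' @examples
#' degree_days(25, 25, base = 8, ceiling = 32)  # constant 25 C -> 17
#' degree_days(10, 30, base = 29, ceiling = Inf)  # extreme degree days
#' @export
degree_days <- function(tmin, tmax, base, ceiling = Inf) {
  n <- max(length(tmin), length(tmax))
  tmin <- rep_len(tmin, n)
  tmax <- rep_len(tmax, n)
  if (any(tmax < tmin)) {
    cs_abort("tmax must be >= tmin for every day",
             class = "cropshift_invalid_weather")
  }
  if (any(base >= ceiling)) {
    cs_abort("base must be < ceiling", class = "cropshift_invalid_calendar")
  }
  dd_above(tmin, tmax, base) - dd_above(tmin, tmax, ceiling)
}

# exceedance integral: int over one day of max(T(h) - thresh, 0), with
# T(h) a sine wave between tmin and tmax
dd_above <- function(tmin, tmax, thresh) {
  if (is.infinite(thresh)) {
    return(rep(0, length(tmin)))
  }
  tavg <- (tmax + tmin) / 2
  amp <- (tmax - tmin) / 2
  out <- numeric(length(tmin))
  below <- thresh <= tmin             # whole day above threshold
  above <- thresh >= tmax             # whole day below threshold
  mid <- !below & !above
  out[below] <- tavg[below] - thresh
  if (any(mid)) {
    phi <- asin((thresh - tavg[mid]) / amp[mid])
    out[mid] <- ((tavg[mid] - thresh) * (pi / 2 - phi) +
                   amp[mid] * cos(phi)) / pi
  }
  out
}

#' Seasonal growing and extreme degree days
#'
#' Sums daily single-sine degree days over each crop's growing-season window
#' for every county-year present in a daily weather table. Growing degree
#' days (GDD) use the crop's base and ceiling; extreme degree days (EDD)
#' accumulate above the damage threshold with no upper cap.
#'
#' @param weather daily weather data frame with columns `county_id`, `date`
#'   (Date or ISO-8601 string), `tmin`, `tmax`.
#' @param calendar one-row crop calendar (see [crop_calendar()]) or a crop
#'   name matching a default calendar entry.
#' @return a tibble with one row per county-year: `county_id`, `year`,
#'   `crop`, `gdd`, `edd`.
#' @seealso [degree_days()], [water_deficit_index()]
#' @export
seasonal_degree_days <- function(weather, calendar) {
  calendar <- resolve_calendar(calendar)
  w <- prepare_season(weather, calendar, c("tmin", "tmax"))
  w |>
    dplyr::group_by(.data$county_id, .data$year) |>
    dplyr::summarise(
      gdd = sum(degree_days(.data$tmin, .data$tmax,
                            base = calendar$gdd_base,
                            ceiling = calendar$gdd_ceiling)),
      edd = sum(degree_days(.data$tmin, .data$tmax,
                            base = calendar$edd_threshold,
                            ceiling = Inf)),
      .groups = "drop"
    ) |>
    dplyr::mutate(crop = calendar$crop, .after = "year")
}

#' Seasonal crop water deficit index
#'
#' A normalized seasonal water deficit: the summed daily shortfall of
#' precipitation relative to potential evapotranspiration, divided by total
#' seasonal potential evapotranspiration,
#' `CDI = sum(max(0, pet - precip)) / sum(pet)`. The index lies in `[0, 1]`;
#' 0 means precipitation met atmospheric demand every day, 1 means no rain
#' fell all season. A season with zero total PET yields `CDI = 0` with a
#' warning. This is a deliberately simple supply-demand deficit; it does not
#' carry soil moisture between days (see the methods vignette).
#'
#' @inheritParams seasonal_degree_days
#' @param weather daily weather with columns `county_id`, `date`, `precip`,
#'   `pet` (both mm/day, non-negative).
#' @return tibble with columns `county_id`, `year`, `crop`, `cdi`.
#' @export
water_deficit_index <- function(weather, calendar) {
  calendar <- resolve_calendar(calendar)
  w <- prepare_season(weather, calendar, c("precip", "pet"))
  if (any(w$precip < 0) || any(w$pet < 0)) {
    cs_abort("precip and pet must be non-negative",
             class = "cropshift_invalid_weather")
  }
  out <- w |>
    dplyr::group_by(.data$county_id, .data$year) |>
    dplyr::summarise(
      cdi = if (sum(.data$pet) > 0) {
        sum(pmax(0, .data$pet - .data$precip)) / sum(.data$pet)
      } else NA_real_,
      .groups = "drop"
    ) |>
    dplyr::mutate(crop = calendar$crop, .after = "year")
  if (anyNA(out$cdi)) {
    warn("season(s) with zero total PET: CDI set to 0")
    out$cdi[is.na(out$cdi)] <- 0
  }
  out
}

#' Weather predictors for the yield panel
#'
#' Convenience wrapper computing all weather predictors (GDD, EDD, CDI) for
#' one crop from a daily weather table, together with the calendar-year
#' trend column `t`.
#'
#' @inheritParams seasonal_degree_days
#' @return tibble `county_id`, `year`, `crop`, `t`, `cdi`, `gdd`, `edd`
#'   (with `t = year`, uncentered; see [standardize_panel()]).
#' @export
weather_predictors <- function(weather, calendar) {
  calendar <- resolve_calendar(calendar)
  dd <- seasonal_degree_days(weather, calendar)
  cdi <- water_deficit_index(weather, calendar)
  dd |>
    dplyr::left_join(cdi, by = c("county_id", "year", "crop")) |>
    dplyr::mutate(t = as.numeric(.data$year), .after = "crop") |>
    dplyr::select("county_id", "year", "crop", "t", "cdi", "gdd", "edd")
}

#' Default crop calendars
#'
#' Growing-season windows and degree-day thresholds for the six crops the
#' package models. These are conventional values of the style used in the
#' degree-day literature (e.g. corn: base 8 C, ceiling 32 C, extreme-heat
#' threshold 29 C), shipped as editable configuration -- they are not
#' measurements, and a user with crop-specific agronomy should replace them
#' via [read_crop_calendar()] or by editing the returned tibble.
#'
#' @param crop optional crop name; if given, returns that single row.
#' @return tibble with columns `crop`, `season_start`, `season_end`
#'   (day-of-year), `gdd_base`, `gdd_ceiling`, `edd_threshold` (degrees C).
#' @export
crop_calendar <- function(crop = NULL) {
  cal <- tibble::tribble(
    ~crop,       ~season_start, ~season_end, ~gdd_base, ~gdd_ceiling, ~edd_threshold,
    "barley",    91L,  243L, 0,  25, 25,
    "corn",      91L,  273L, 8,  32, 29,
    "cotton",    91L,  304L, 10, 33, 32,
    "rice",      91L,  273L, 8,  33, 32,
    "soybeans",  121L, 288L, 8,  30, 30,
    "wheat",     60L,  196L, 0,  26, 26
  )
  if (!is.null(crop)) {
    row <- cal[cal$crop == crop, ]
    if (nrow(row) == 0) {
      cs_abort(sprintf("no default calendar for crop '%s'", crop),
               class = "cropshift_unknown_crop")
    }
    return(row)
  }
  cal
}

resolve_calendar <- function(calendar) {
  if (is.character(calendar)) {
    calendar <- crop_calendar(calendar)
  }
  check_columns(calendar, c("crop", "season_start", "season_end",
                            "gdd_base", "gdd_ceiling", "edd_threshold"),
                "crop calendar")
  if (nrow(calendar) != 1) {
    cs_abort("calendar must be a single crop (one row)")
  }
  if (calendar$season_start >= calendar$season_end) {
    cs_abort("season_start must be < season_end (normalize wrap-around windows first)",
             class = "cropshift_invalid_calendar")
  }
  if (!(calendar$gdd_base < calendar$gdd_ceiling &&
        calendar$edd_threshold > calendar$gdd_base)) {
    cs_abort("calendar must satisfy gdd_base < gdd_ceiling and edd_threshold > gdd_base",
             class = "cropshift_invalid_calendar")
  }
  calendar
}

# subset daily weather to the season window and fail loudly on gaps
prepare_season <- function(weather, calendar, value_cols) {
  check_columns(weather, c("county_id", "date", value_cols), "daily weather")
  w <- tibble::as_tibble(weather)
  w$date <- as.Date(w$date)
  w$year <- as.integer(format(w$date, "%Y"))
  w$doy <- as.integer(format(w$date, "%j"))
  w <- w[w$doy >= calendar$season_start & w$doy <= calendar$season_end, ]
  if (nrow(w) == 0) {
    cs_abort("no weather rows fall inside the season window")
  }
  expected <- calendar$season_end - calendar$season_start + 1L
  gaps <- w |>
    dplyr::group_by(.data$county_id, .data$year) |>
    dplyr::summarise(n_days = dplyr::n(), .groups = "drop") |>
    dplyr::filter(.data$n_days < expected)
  if (nrow(gaps) > 0) {
    eg <- utils::head(sprintf("%s/%d (%d of %d days)", gaps$county_id,
                              gaps$year, gaps$n_days, expected), 5)
    cs_abort(paste0("missing days inside the season window for: ",
                    paste(eg, collapse = "; ")),
             class = "cropshift_missing_days")
  }
  w
}
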