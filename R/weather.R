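#' Savanna weather archetypes
#'
#' Parameter sets describing the two Nigerian savanna rainfall regimes the
#' package emulates: a dry savanna with a short (~3.5 month) unimodal rainy
#' season totalling ~825 mm, most of it falling in July-August, and a wet
#' savanna with a longer (~5 month) season totalling ~1125 mm.  The rainfall
#' model is a first-order two-state (wet/dry day) occurrence chain whose
#' stationary wet-day probability follows a Gaussian-shaped seasonal profile,
#' with exponentially distributed wet-day amounts calibrated so the expected
#' annual total equals `annual_rain_mm`.
#'
#' @param name `"dry"` or `"wet"`.
#' @param ... Optional overrides of individual archetype fields (for example
#'   `wet_prob_peak = 0` to switch rainfall off entirely).
#' @return A list of class `savanna_archetype` with fields `name`,
#'   `annual_rain_mm`, `season_start_doy`, `season_length_days`,
#'   `peak_months`, `rain_peak_doy`, `rain_sd_days`, `wet_prob_peak`,
#'   `rain_autocorr`, `tmax_mean`, `tmin_mean`, `temp_amplitude`,
#'   `temp_peak_doy`, `srad_mean`, `srad_amplitude`, `latitude`.
#' @examples
#' savanna_archetype("dry")$annual_rain_mm   # 825
#' @export
savanna_archetype <- function(name = c("dry", "wet"), ...) {
  name <- match.arg(name)
  base <- switch(name,
    dry = list(
      name = "dry", annual_rain_mm = 825, season_start_doy = 152,
      season_length_days = 105, peak_months = c(7L, 8L),
      rain_peak_doy = 208, rain_sd_days = 27, wet_prob_peak = 0.75,
      rain_autocorr = 0.5,
      tmax_mean = 34, tmin_mean = 21, temp_amplitude = 4, temp_peak_doy = 105,
      srad_mean = 20, srad_amplitude = 2.5, latitude = 12.0
    ),
    wet = list(
      name = "wet", annual_rain_mm = 1125, season_start_doy = 121,
      season_length_days = 152, peak_months = c(6L, 7L, 8L, 9L),
      rain_peak_doy = 196, rain_sd_days = 35, wet_prob_peak = 0.80,
      rain_autocorr = 0.5,
      tmax_mean = 31, tmin_mean = 20, temp_amplitude = 3.5, temp_peak_doy = 110,
      srad_mean = 19, srad_amplitude = 2.0, latitude = 11.1
    )
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(base))
  if (length(unknown)) {
    abort(paste0("Unknown archetype field(s): ", paste(unknown, collapse = ", ")))
  }
  base[names(dots)] <- dots
  if (base$annual_rain_mm <= 0) abort("`annual_rain_mm` must be positive.")
  if (base$season_length_days < 60 || base$season_length_days > 240) {
    abort("`season_length_days` must lie in [60, 240].")
  }
  if (base$tmax_mean <= base$tmin_mean) abort("`tmax_mean` must exceed `tmin_mean`.")
  structure(base, class = "savanna_archetype")
}

# Stationary wet-day probability profile over the year (Gaussian bump).
wet_prob_profile <- function(archetype, doy) {
  archetype$wet_prob_peak *
    exp(-((doy - archetype$rain_peak_doy) / archetype$rain_sd_days)^2)
}

#' Generate synthetic daily savanna weather
#'
#' Simulates contiguous daily weather (srad, tmax, tmin, rain) for one or
#' more 365-day years under a [savanna_archetype()].  Rain occurrence follows
#' a first-order two-state chain with transition probabilities
#' `p01 = (1 - rho) * pi(doy)` and `p11 = pi(doy) + rho * (1 - pi(doy))`
#' (Wilks parameterisation), so the stationary wet-day probability tracks the
#' seasonal profile `pi(doy)`; wet-day amounts are exponential with a mean
#' calibrated so the expected annual total equals the archetype target.
#' Temperatures and solar radiation are day-of-year sinusoids plus bounded
#' uniform noise; the noise bound is smaller than the seasonal tmax-tmin gap,
#' so `tmax > tmin` holds on every day.  Wet days are slightly cooler and
#' less irradiated (cloud cover).
#'
#' @param archetype A [savanna_archetype()].
#' @param n_years Number of 365-day years, `>= 1`.
#' @param seed Integer seed; all randomness flows from it.
#' @return A tibble with columns `date`, `year`, `doy`, `srad`
#'   (MJ m-2 d-1), `tmax`, `tmin` (deg C), `rain` (mm), `latitude`.
#' @examples
#' wx <- generate_weather(savanna_archetype("dry"), n_years = 2, seed = 7)
#' sum(wx$rain) / 2   # near 825 mm per year
#' @export
generate_weather <- function(archetype, n_years, seed = 20160316L) {
  if (!inherits(archetype, "savanna_archetype")) {
    abort("`archetype` must be created by `savanna_archetype()`.")
  }
  if (length(n_years) != 1 || is.na(n_years) || n_years < 1) {
    abort("`n_years` must be a positive integer.")
  }
  n_years <- as.integer(n_years)
  if (!is.null(seed)) withr::local_seed(as.integer(seed))

  doy <- rep(1:365, times = n_years)
  year <- rep(seq_len(n_years) + 2000L, each = 365L)
  n <- length(doy)
  pi_doy <- wet_prob_profile(archetype, doy)

  # mean wet-day amount calibrated against the discrete stationary profile
  exp_wet_days <- sum(wet_prob_profile(archetype, 1:365))
  mu_rain <- if (exp_wet_days > 0) archetype$annual_rain_mm / exp_wet_days else 0

  rho <- archetype$rain_autocorr
  wet <- logical(n)
  u <- runif(n)
  wet[1] <- u[1] < pi_doy[1]
  for (i in 2:n) {
    p <- if (wet[i - 1]) {
      pi_doy[i] + rho * (1 - pi_doy[i])
    } else {
      (1 - rho) * pi_doy[i]
    }
    # a day with zero stationary probability is always dry
    if (pi_doy[i] <= 0) p <- 0
    wet[i] <- u[i] < p
  }
  rain <- numeric(n)
  nw <- sum(wet)
  if (nw > 0 && mu_rain > 0) rain[wet] <- rexp(nw, rate = 1 / mu_rain)

  seas <- cos(2 * pi * (doy - archetype$temp_peak_doy) / 365)
  tmax <- archetype$tmax_mean + archetype$temp_amplitude * seas +
    runif(n, -2, 2) - 2 * wet
  tmin <- archetype$tmin_mean + archetype$temp_amplitude * seas +
    runif(n, -2, 2) + 0.5 * wet
  srad <- archetype$srad_mean +
    archetype$srad_amplitude * cos(2 * pi * (doy - 100) / 365) +
    runif(n, -1.5, 1.5) - 4.5 * wet
  srad <- pmax(3, srad)

  stopifnot(all(tmax > tmin), all(rain >= 0), all(srad >= 0))
  tibble::tibble(
    date = as.Date(doy - 1, origin = paste0(year, "-01-01")),
    year = year, doy = doy,
    srad = srad, tmax = tmax, tmin = tmin, rain = rain,
    latitude = archetype$latitude
  )
}

#' Read and write daily weather CSV
#'
#' The plain CSV dialect has header `DATE,SRAD,TMAX,TMIN,RAIN` with ISO-8601
#' dates, solar radiation in MJ m-2 d-1, temperatures in deg C and rain in
#' mm.  `read_wth()` reads a DSSAT-WTH-like whitespace-separated table whose
#' DATE column is `yyddd`.
#'
#' @param path File path.
#' @param latitude Site latitude attached as a column (decimal degrees).
#' @param wx A weather tibble as produced by [generate_weather()].
#' @return `read_weather_csv()` and `read_wth()` return a weather tibble;
#'   `write_weather_csv()` returns `path` invisibly.
#' @export
read_weather_csv <- function(path, latitude = 12) {
  raw <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("DATE", "SRAD", "TMAX", "TMIN", "RAIN")
  if (!all(need %in% names(raw))) {
    abort(paste0("Weather CSV must have columns ", paste(need, collapse = ",")))
  }
  date <- as.Date(raw$DATE)
  if (any(is.na(date))) abort("DATE column must be ISO-8601 dates.")
  tibble::tibble(
    date = date,
    year = as.integer(format(date, "%Y")),
    doy = as.integer(format(date, "%j")),
    srad = raw$SRAD, tmax = raw$TMAX, tmin = raw$TMIN, rain = raw$RAIN,
    latitude = latitude
  )
}

#' @rdname read_weather_csv
#' @export
write_weather_csv <- function(wx, path) {
  out <- tibble::tibble(
    DATE = format(wx$date, "%Y-%m-%d"),
    SRAD = round(wx$srad, 2), TMAX = round(wx$tmax, 2),
    TMIN = round(wx$tmin, 2), RAIN = round(wx$rain, 2)
  )
  readr::write_csv(out, path)
  invisible(path)
}

#' @rdname read_weather_csv
#' @export
read_wth <- function(path, latitude = 12) {
  raw <- utils::read.table(path, header = TRUE, comment.char = "!",
                           check.names = FALSE)
  names(raw) <- sub("^@", "", names(raw))
  need <- c("DATE", "SRAD", "TMAX", "TMIN", "RAIN")
  if (!all(need %in% names(raw))) {
    abort(paste0("WTH file must have columns ", paste(need, collapse = ",")))
  }
  code <- sprintf("%05d", as.integer(raw$DATE))
  yy <- as.integer(substr(code, 1, 2))
  ddd <- as.integer(substr(code, 3, 5))
  year <- ifelse(yy <= 30, 2000L + yy, 1900L + yy)
  tibble::tibble(
    date = as.Date(ddd - 1, origin = paste0(year, "-01-01")),
    year = year, doy = ddd,
    srad = raw$SRAD, tmax = raw$TMAX, tmin = raw$TMIN, rain = raw$RAIN,
    latitude = latitude
  )
}
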