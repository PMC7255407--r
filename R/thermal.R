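#' Daily thermal time (growing degree days)
#'
#' Accumulated heat driving maize development, computed from the daily
#' temperature extremes as `max(0, (tmax + tmin)/2 - tbase)`.  The default
#' base temperature for tropical maize is 8 degrees C.  An optional
#' DSSAT-style cap limits the effective mean temperature response between an
#' optimum (`topt`) and a ceiling (`tceil`): between the two the daily value
#' declines linearly from its value at `topt` to zero, and above the ceiling
#' it is zero.  The cap never increases the uncapped value.
#'
#' @param tmax,tmin Daily maximum and minimum air temperature (degrees C).
#'   Vectorised; `tmax >= tmin` is required elementwise.
#' @param tbase Base temperature (degrees C), default 8.
#' @param cap Either `NULL` (default, the literal clamped-mean rule) or a
#'   numeric vector `c(topt, tceil)` such as `c(34, 44)`.
#' @return Numeric vector of daily thermal time (degree C days), `>= 0`.
#' @examples
#' thermal_time_daily(30, 20)        # 17
#' thermal_time_daily(10, 4)         # 0: mean 7 below the 8 C base
#' @export
thermal_time_daily <- function(tmax, tmin, tbase = 8, cap = NULL) {
  if (any(tmax < tmin)) {
    abort("`tmax` must be >= `tmin` for every day.")
  }
  tmean <- (tmax + tmin) / 2
  gdd <- pmax(0, tmean - tbase)
  if (!is.null(cap)) {
    if (length(cap) != 2 || cap[1] >= cap[2]) {
      abort("`cap` must be c(topt, tceil) with topt < tceil.")
    }
    topt <- cap[1]
    tceil <- cap[2]
    at_opt <- pmax(0, topt - tbase)
    frac <- pmax(0, 1 - (tmean - topt) / (tceil - topt))
    capped <- ifelse(tmean > topt, at_opt * frac, gdd)
    gdd <- pmin(gdd, capped)
  }
  gdd
}

#' Astronomical day length
#'
#' Standard day-length formula from solar declination, used to drive the
#' photoperiod sensitivity of tassel initiation.  Valid away from polar
#' latitudes.
#'
#' @param latitude Site latitude in decimal degrees, `abs(latitude) < 66`.
#' @param doy Day of year (1-based), vectorised.
#' @return Day length in hours.
#' @examples
#' day_length(0, 80)       # ~12 h at the equator
#' day_length(11.5, 172)   # longest days near the June solstice
#' @export
day_length <- function(latitude, doy) {
  if (abs(latitude) >= 66) {
    abort("`latitude` must satisfy abs(latitude) < 66 (no polar day/night).")
  }
  decl <- -23.44 * cos(2 * pi * (doy + 10) / 365) * pi / 180
  lat <- latitude * pi / 180
  x <- pmin(1, pmax(-1, -tan(lat) * tan(decl)))
  24 * acos(x) / pi
}

#' Photoperiod-induced development delay
#'
#' Delay in days of development for each hour that day length exceeds the
#' photoperiod threshold (12.5 h for maize); the cultivar coefficient `P2`
#' is the delay per hour.
#'
#' @param daylength Day length in hours.
#' @param P2 Cultivar photoperiod sensitivity (days of delay per hour above
#'   threshold), `>= 0`.
#' @param threshold Photoperiod threshold in hours, default 12.5.
#' @return Delay in days, `>= 0`.
#' @export
photoperiod_delay <- function(daylength, P2, threshold = 12.5) {
  if (any(P2 < 0)) abort("`P2` must be >= 0.")
  P2 * pmax(0, daylength - threshold)
}

# Piecewise-linear response factor on [0, 1]; constant beyond the endpoints.
piecewise_factor <- function(temp, breakpoints, factors) {
  stats::approx(breakpoints, factors, xout = temp, rule = 2)$y
}
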