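#' Priestley-Taylor potential evapotranspiration
#'
#' Equilibrium evaporation from net radiation scaled by the Priestley-Taylor
#' coefficient 1.26, using the slope of the saturation vapour pressure curve
#' at the daily mean temperature.  Net radiation is approximated as
#' `0.77 * srad - 2.0` MJ m-2 d-1 (albedo plus longwave loss), floored at 0.
#'
#' @param srad Solar radiation, MJ m-2 d-1.
#' @param tmax,tmin Daily temperature extremes, deg C.
#' @return Potential ET in mm d-1.
#' @export
pt_eo <- function(srad, tmax, tmin) {
  tmean <- (tmax + tmin) / 2
  es <- 0.6108 * exp(17.27 * tmean / (tmean + 237.3))
  delta <- 4098 * es / (tmean + 237.3)^2
  gamma <- 0.066
  rn <- pmax(0, 0.77 * srad - 2.0)
  pmax(0, 1.26 * delta / (delta + gamma) * rn / 2.45)
}

#' One day of the soil water bucket
#'
#' Advances the layered soil water store by one day: SCS curve-number
#' runoff, infiltration cascading through the layers (saturation excess
#' passes down; water above the drained upper limit drains at a fixed 0.4
#' fraction per day), two-stage soil evaporation from the top layer
#' (energy-limited while the top layer is moist, supply-limited below half
#' of its plant-available range), and transpiration extracted from the
#' layers in proportion to available water, capped at 10 percent of each
#' layer's plant-available store per day.  The crop water-stress factor is
#' `min(1, paw_fraction / threshold)` over the root zone.
#'
#' All fluxes are returned so the water balance closes exactly:
#' `rain = runoff + delta_storage + es + ep + drainage`.
#'
#' @param state Numeric vector of layer water contents, mm.
#' @param soil A [generate_soil()] profile.
#' @param rain Water reaching the surface today (rain + irrigation), mm.
#' @param eo Potential ET demand, mm (see [pt_eo()]).
#' @param cover Fractional canopy cover in [0, 1], splitting `eo` into
#'   transpiration demand (`eo * cover`) and soil evaporation demand.
#' @param stress_threshold Plant-available fraction below which the stress
#'   factor falls linearly to 0.
#' @param root_weights Per-layer root activity weights (normalised
#'   internally).
#' @return A list: `state` (updated mm per layer), `stress` in [0, 1],
#'   `runoff`, `infiltration`, `drainage`, `es`, `ep` (all mm),
#'   `paw_fraction`.
#' @export
water_balance_step <- function(state, soil, rain, eo, cover = 0,
                               stress_threshold = 0.5,
                               root_weights = c(0.5, 0.3, 0.2)) {
  if (rain < 0) abort("`rain` must be >= 0.")
  nl <- nrow(soil)
  ll <- layer_mm(soil, soil$ll)
  dul <- layer_mm(soil, soil$dul)
  sat <- layer_mm(soil, soil$sat)
  sw <- pmin(pmax(state, 0.5 * ll), sat)
  w <- rep_len(root_weights, nl)
  w <- w / sum(w)

  # SCS curve-number runoff
  cn <- soil$curve_number[1]
  smax <- 25400 / cn - 254
  runoff <- if (rain > 0.2 * smax && rain > 0) {
    (rain - 0.2 * smax)^2 / (rain + 0.8 * smax)
  } else 0
  infil <- rain - runoff

  # infiltration cascade: fill to saturation, pass the excess down
  drain_out <- 0
  inflow <- infil
  for (i in seq_len(nl)) {
    sw[i] <- sw[i] + inflow
    inflow <- max(0, sw[i] - sat[i])
    sw[i] <- min(sw[i], sat[i])
  }
  drain_out <- drain_out + inflow

  # drainage of water held above the drained upper limit
  for (i in seq_len(nl)) {
    drn <- 0.4 * max(0, sw[i] - dul[i])
    sw[i] <- sw[i] - drn
    if (i < nl) sw[i + 1] <- sw[i + 1] + drn else drain_out <- drain_out + drn
  }
  # the cascade may have pushed a lower layer above saturation
  for (i in rev(seq_len(nl))) {
    excess <- max(0, sw[i] - sat[i])
    sw[i] <- sw[i] - excess
    if (i > 1) sw[i - 1] <- sw[i - 1] + excess else drain_out <- drain_out + excess
  }

  cover <- min(1, max(0, cover))
  # two-stage soil evaporation from the top layer
  es_demand <- eo * (1 - cover)
  f1 <- (sw[1] - ll[1]) / (dul[1] - ll[1])
  f1 <- min(1, max(0, f1))
  es_rate <- if (f1 >= 0.5) es_demand else es_demand * f1 / 0.5
  es <- min(es_rate, max(0, sw[1] - 0.5 * ll[1]))
  sw[1] <- sw[1] - es

  # transpiration, supply-limited at 10% of plant-available water per layer
  ep_demand <- eo * cover
  avail <- pmax(0, sw - ll)
  uptake_cap <- 0.10 * avail
  ep <- min(ep_demand, sum(uptake_cap))
  if (ep > 0) {
    take <- ep * uptake_cap / sum(uptake_cap)
    sw <- sw - take
  }

  paw_frac <- sum(w * pmin(1, pmax(0, (sw - ll) / (dul - ll))))
  stress <- min(1, paw_frac / stress_threshold)

  list(state = sw, stress = stress, runoff = runoff, infiltration = infil,
       drainage = drain_out, es = es, ep = ep, paw_fraction = paw_frac)
}

#' Moisture-triggered planting date
#'
#' Scans a sowing window for the first day whose top-layer plant-available
#' water fraction (after that day's rain) reaches the planting threshold,
#' simulating a bare-soil water balance from the start of the weather
#' series.  The profile starts dry (top layer at the lower limit) as at the
#' end of a savanna dry season.
#'
#' @param wx A single-year weather tibble.
#' @param soil A [generate_soil()] profile.
#' @param window Day-of-year range `c(first, last)` searched.
#' @param threshold Plant-available fraction of the top layer required
#'   (0 plants on the first window day).
#' @return The sowing day-of-year (integer).
#' @export
auto_plant <- function(wx, soil, window = c(152, 243), threshold = 0.5) {
  if (length(window) != 2 || window[1] > window[2]) {
    abort("`window` must be c(first_doy, last_doy).")
  }
  days <- which(wx$doy >= window[1] & wx$doy <= window[2])
  if (!length(days)) abort("The sowing window is outside the weather series.")
  ll <- layer_mm(soil, soil$ll)
  dul <- layer_mm(soil, soil$dul)
  state <- ll + 0.1 * (dul - ll)  # dry-season start
  state[1] <- ll[1]
  for (i in seq_len(max(days))) {
    eo <- pt_eo(wx$srad[i], wx$tmax[i], wx$tmin[i])
    st <- water_balance_step(state, soil, wx$rain[i], eo, cover = 0)
    state <- st$state
    if (i %in% days) {
      f1 <- (state[1] - ll[1]) / (dul[1] - ll[1])
      if (f1 >= threshold) return(wx$doy[i])
    }
  }
  abort("No day in the sowing window reached the planting moisture threshold.",
        class = "gxemaize_no_planting")
}
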