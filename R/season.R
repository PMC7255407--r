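#' Simulate one maize season
#'
#' Desk-scale daily simulation of a single cultivar-season in the
#' CERES-Maize tradition.  Phenology runs on thermal time (base 8 deg C):
#' sowing, emergence after a fixed 45 deg C d, end of the juvenile phase at
#' `P1`, photoperiod-delayed tassel initiation (`P2` days per hour of day
#' length above 12.5 h), anthesis once all leaves have appeared at `PHINT`
#' deg C d per leaf tip (total leaf number is `tlno_base + P1/leaf_init_tt`),
#' and physiological maturity `P5` deg C d after silking.  Daily biomass is
#' `rue * PAR * (1 - exp(-kcan * LAI)) * min(temperature factor, water
#' factor)`; kernel number is `G2 * density` scaled by the mean stress
#' around anthesis (+/- 7 days); linear grain fill proceeds at `G3` mg per
#' kernel per day scaled by the RGFIL temperature factor and the water
#' stress factor, capped by the harvest-index ceiling on accumulated
#' biomass.  A three-layer bucket handles the water balance
#' ([water_balance_step()]); the season's balance closes exactly.
#'
#' @param cultivar One cultivar: a one-row data frame or named list with
#'   `P1`, `P2`, `P5`, `G2`, `G3`, `PHINT` (see [maize_cultivars()]).
#' @param wx Weather tibble covering sowing through maturity (one site-year
#'   or longer).
#' @param soil A [generate_soil()] profile.
#' @param mgmt A [management()] object.
#' @param species A [species_params()] object.
#' @param ecotype An [ecotype_params()] object.
#' @param detail If `TRUE`, attach the daily state log as attribute
#'   `"daily"`.
#' @return A one-row tibble (`season_result`): `cultivar`, `sowing_doy`,
#'   `dta`, `dtm` (days from sowing to anthesis / maturity),
#'   `biomass_anthesis`, `biomass_maturity`, `grain_yield` (Mg ha-1),
#'   `kernel_number` (m-2), `stress_water`, `stress_temp` (mean factors in
#'   [0, 1]), `water_balance_error` (mm).
#' @examples
#' wx <- generate_weather(savanna_archetype("wet"), 1, seed = 1)
#' cv <- maize_cultivars()[1, ]
#' simulate_season(cv, wx, generate_soil("loamy"),
#'                 management(sowing_date = 160, irrigation = "auto"))
#' @export
simulate_season <- function(cultivar, wx, soil,
                            mgmt = management(),
                            species = species_params(),
                            ecotype = ecotype_params(),
                            detail = FALSE) {
  cv <- as_cultivar(cultivar)
  validate_cultivar(tibble::as_tibble(cv[c("P1", "P2", "P5", "G2", "G3",
                                           "PHINT")]))
  if (!all(c("doy", "srad", "tmax", "tmin", "rain") %in% names(wx))) {
    abort("`wx` must be a weather tibble (doy, srad, tmax, tmin, rain).")
  }

  sow_doy <- if (identical(mgmt$sowing_date, "auto")) {
    auto_plant(wx, soil, mgmt$sowing_window, mgmt$plant_threshold)
  } else {
    as.integer(mgmt$sowing_date)
  }
  i_sow <- which(wx$doy == sow_doy)[1]
  if (is.na(i_sow)) abort("Sowing date not found in the weather series.")

  lat <- if ("latitude" %in% names(wx)) wx$latitude[1] else 12
  density_m2 <- mgmt$plant_density / 1e4
  tlno <- species$tlno_base + cv$P1 / species$leaf_init_tt
  anth_tt_target <- tlno * cv$PHINT  # devTT from emergence to anthesis

  ll <- layer_mm(soil, soil$ll)
  dul <- layer_mm(soil, soil$dul)
  sw <- ll + 0.75 * (dul - ll)  # moist seedbed at sowing
  stored0 <- sum(sw)
  in_sum <- 0; out_sum <- 0

  cum_sow <- 0      # TT since sowing (for emergence)
  dev_tt <- 0       # TT since emergence (paused by photoperiod delay)
  tt_silk <- 0      # TT since silking
  emerged <- FALSE; juvenile_done <- FALSE; anthesis_day <- NA_integer_
  maturity_day <- NA_integer_; dta_frac <- NA_real_; dtm_frac <- NA_real_
  pause_days <- 0
  biomass <- 0; grain <- 0; lai <- 0; lai_anth <- NA_real_
  kernels <- NA_real_
  n <- nrow(wx)
  min_fac <- numeric(n - i_sow + 1)
  biomass_anth <- NA_real_
  wfac_log <- numeric(0); tfac_log <- numeric(0)
  par_int_sum <- 0
  daily <- if (detail) vector("list", 0) else NULL

  day <- 0
  for (i in i_sow:n) {
    day <- day + 1
    tt <- thermal_time_daily(wx$tmax[i], wx$tmin[i], species$tbase,
                             cap = species$cap)
    tmean <- (wx$tmax[i] + wx$tmin[i]) / 2

    # --- water balance first (drives today's stress) ---
    cover <- 1 - exp(-ecotype$kcan * lai)
    eo <- pt_eo(wx$srad[i], wx$tmax[i], wx$tmin[i])
    irr <- 0
    if (mgmt$irrigation == "auto" && emerged) {
      paw_now <- sum(pmax(0, sw - ll)) / sum(dul - ll)
      if (paw_now < mgmt$stress_threshold) irr <- sum(pmax(0, dul - sw))
    }
    st <- water_balance_step(sw, soil, wx$rain[i] + irr, eo, cover,
                             mgmt$stress_threshold)
    sw <- st$state
    in_sum <- in_sum + wx$rain[i] + irr
    out_sum <- out_sum + st$runoff + st$drainage + st$es + st$ep
    wfac <- st$stress

    # --- phenology ---
    if (!emerged) {
      cum_sow <- cum_sow + tt
      if (cum_sow >= species$emergence_tt) emerged <- TRUE
    } else if (is.na(anthesis_day)) {
      # photoperiod hold slows development by the fractional day owed
      if (pause_days > 0) {
        held <- min(1, pause_days)
        pause_days <- pause_days - held
        dev_tt <- dev_tt + tt * (1 - held)
      } else {
        dev_tt <- dev_tt + tt
      }
      if (!juvenile_done && dev_tt >= cv$P1) {
        juvenile_done <- TRUE
        dl <- day_length(lat, wx$doy[i])
        pause_days <- photoperiod_delay(dl, cv$P2,
                                        species$photoperiod_threshold)
      }
      if (juvenile_done && dev_tt >= anth_tt_target) {
        anthesis_day <- day
        # fractional crossing time within the day keeps cultivar ordering
        # free of whole-day rounding ties
        dta_frac <- day - if (tt > 0) (dev_tt - anth_tt_target) / tt else 0
        biomass_anth <- biomass
        lai_anth <- lai
      }
    } else {
      tt_silk <- tt_silk + tt
    }

    # --- canopy ---
    leaves <- min(tlno, dev_tt / cv$PHINT)
    if (is.na(anthesis_day)) {
      frac <- min(1, leaves / tlno)
      lai <- density_m2 * ecotype$leaf_area_max * frac^1.5
    } else {
      sen <- max(0.15, 1 - 0.85 * tt_silk / cv$P5)
      lai <- lai_anth * sen
    }

    # --- growth ---
    tfac <- piecewise_factor(tmean, species$prftc$temp, species$prftc$factor)
    if (emerged) {
      par <- 0.5 * wx$srad[i]
      li <- 1 - exp(-ecotype$kcan * lai)
      par_int_sum <- par_int_sum + par * li
      biomass <- biomass + ecotype$rue * par * li * min(tfac, wfac)
      wfac_log <- c(wfac_log, wfac)
      tfac_log <- c(tfac_log, tfac)
    }

    # --- kernel set over anthesis +/- 7 days ---
    min_fac[day] <- min(wfac, tfac)
    if (!is.na(anthesis_day) && is.na(kernels) && day >= anthesis_day + 7) {
      win <- max(1, anthesis_day - 7):day
      kernels <- cv$G2 * density_m2 * mean(min_fac[win])
    }

    # --- grain fill ---
    if (!is.na(anthesis_day) && !is.na(kernels)) {
      gfac <- piecewise_factor(tmean, species$rgfil$temp,
                               species$rgfil$factor)
      dgrain <- kernels * cv$G3 * 1e-3 * gfac * wfac
      grain <- min(grain + dgrain, ecotype$hi_max * biomass)
    }

    if (detail) {
      daily[[length(daily) + 1]] <- tibble::tibble(
        day = day, doy = wx$doy[i], tt = tt, dev_tt = dev_tt, lai = lai,
        biomass = biomass, grain = grain, wfac = wfac, tfac = tfac,
        paw_fraction = st$paw_fraction, rain = wx$rain[i], irrigation = irr
      )
    }

    if (!is.na(anthesis_day) && tt_silk >= cv$P5) {
      maturity_day <- day
      dtm_frac <- day - if (tt > 0) (tt_silk - cv$P5) / tt else 0
      break
    }
  }

  if (is.na(maturity_day)) {
    abort(paste0("Weather series ends before cultivar '", cv$name,
                 "' reaches maturity."),
          class = "gxemaize_incomplete_season")
  }
  if (is.na(kernels)) {
    win <- max(1, anthesis_day - 7):maturity_day
    kernels <- cv$G2 * density_m2 * mean(min_fac[win])
  }
  balance_err <- in_sum - out_sum - (sum(sw) - stored0)

  out <- tibble::tibble(
    cultivar = cv$name,
    sowing_doy = sow_doy,
    dta = dta_frac,
    dtm = dtm_frac,
    biomass_anthesis = biomass_anth / 100,  # g m-2 -> Mg ha-1
    biomass_maturity = biomass / 100,
    grain_yield = grain / 100,
    kernel_number = kernels,
    stress_water = if (length(wfac_log)) mean(wfac_log) else NA_real_,
    stress_temp = if (length(tfac_log)) mean(tfac_log) else NA_real_,
    par_intercepted = par_int_sum,
    water_balance_error = balance_err
  )
  class(out) <- c("season_result", class(out))
  if (detail) attr(out, "daily") <- dplyr::bind_rows(daily)
  out
}
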