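#' Species, ecotype and management parameter sets
#'
#' `species_params()` loads the species-level temperature and development
#' responses: base temperature (8 deg C), the photoperiod threshold
#' (12.5 h), emergence thermal time, the piecewise-linear temperature
#' response of photosynthesis (PRFTC) and of relative grain fill (RGFIL),
#' and the leaf-number constants.  They ship as an editable YAML file so the
#' responses can be adjusted without touching code.
#'
#' `ecotype_params()` holds the ecotype-level canopy/radiation parameters:
#' radiation use efficiency `rue` (g biomass per MJ intercepted PAR), canopy
#' light extinction coefficient `kcan`, maximum per-plant leaf area
#' (m2 plant-1), and the harvest-index ceiling that caps grain growth by
#' available assimilate.
#'
#' `management()` describes sowing and water management: sowing date
#' (`"auto"` for moisture-triggered planting inside `sowing_window`, or a
#' day-of-year), plant density (default 53,333 plants ha-1), and the
#' irrigation rule (`"none"` or `"auto"` = refill the root zone to the
#' drained upper limit whenever plant-available water drops below the
#' stress threshold).
#'
#' @param file Optional path to a species YAML file; defaults to the
#'   packaged one.
#' @param cap Optional `c(topt, tceil)` cap passed to
#'   [thermal_time_daily()]; `NULL` keeps the literal clamped-mean rule.
#' @return A list of class `species_params`.
#' @export
species_params <- function(file = NULL, cap = NULL) {
  file <- file %||% system.file("extdata", "species_maize.yaml",
                                package = "gxemaize", mustWork = TRUE)
  sp <- yaml::read_yaml(file)
  need <- c("tbase", "photoperiod_threshold", "emergence_tt", "prftc",
            "rgfil", "tlno_base", "leaf_init_tt")
  if (!all(need %in% names(sp))) {
    abort(paste0("Species file must define ", paste(need, collapse = ", ")))
  }
  for (resp in c("prftc", "rgfil")) {
    b <- sp[[resp]]
    if (is.unsorted(b$temp, strictly = TRUE)) {
      abort(paste0(resp, " breakpoints must be strictly increasing."))
    }
    if (any(b$factor < 0 | b$factor > 1)) {
      abort(paste0(resp, " factors must lie in [0, 1]."))
    }
  }
  sp$cap <- cap
  structure(sp, class = "species_params")
}

#' @rdname species_params
#' @param rue Radiation use efficiency, g biomass per MJ intercepted PAR.
#' @param kcan Canopy light extinction coefficient, in (0, 1.5].
#' @param leaf_area_max Maximum per-plant leaf area, m2.
#' @param hi_max Harvest-index ceiling in (0, 1].
#' @export
ecotype_params <- function(rue = 4.2, kcan = 0.85, leaf_area_max = 0.55,
                           hi_max = 0.6) {
  if (rue <= 0) abort("`rue` must be > 0.")
  if (kcan <= 0 || kcan > 1.5) abort("`kcan` must lie in (0, 1.5].")
  if (hi_max <= 0 || hi_max > 1) abort("`hi_max` must lie in (0, 1].")
  structure(list(rue = rue, kcan = kcan, leaf_area_max = leaf_area_max,
                 hi_max = hi_max), class = "ecotype_params")
}

#' @rdname species_params
#' @param sowing_date `"auto"` or a day-of-year (integer).
#' @param sowing_window Day-of-year range searched by auto planting.
#' @param plant_density Plants per hectare.
#' @param irrigation `"none"` or `"auto"`.
#' @param plant_threshold Top-layer plant-available water fraction that
#'   triggers auto planting.
#' @param stress_threshold Root-zone plant-available fraction below which
#'   the water stress factor falls off linearly (and below which auto
#'   irrigation refills the profile).
#' @export
management <- function(sowing_date = "auto", sowing_window = c(152, 243),
                       plant_density = 53333, irrigation = c("none", "auto"),
                       plant_threshold = 0.5, stress_threshold = 0.5) {
  irrigation <- match.arg(irrigation)
  if (plant_density <= 0) abort("`plant_density` must be > 0.")
  structure(list(
    sowing_date = sowing_date, sowing_window = sowing_window,
    plant_density = plant_density, irrigation = irrigation,
    plant_threshold = plant_threshold, stress_threshold = stress_threshold
  ), class = "management")
}
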