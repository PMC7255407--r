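#' Synthetic layered soil profiles
#'
#' Builds a three-layer bucket-model soil profile of a named texture kind.
#' Each layer carries a lower limit (`ll`), drained upper limit (`dul`) and
#' saturation (`sat`) volumetric water content with `ll < dul < sat`, a
#' thickness in cm, and the profile carries an SCS runoff curve number.
#' Plant-available water capacity (PAW) is `sum((dul - ll) * thickness_cm * 10)`
#' mm; sandy profiles hold less than loamy ones, clayey ones most.
#'
#' @param kind `"sandy"`, `"loamy"` or `"clay"`.
#' @param curve_number Optional SCS curve number override (0-100].
#' @return A tibble of class `soil_profile`, one row per layer, with columns
#'   `layer`, `thickness_cm`, `ll`, `dul`, `sat`, plus constant columns
#'   `curve_number` and `kind`.
#' @examples
#' soil_paw_mm(generate_soil("sandy")) < soil_paw_mm(generate_soil("loamy"))
#' @export
generate_soil <- function(kind = c("loamy", "sandy", "clay"),
                          curve_number = NULL) {
  kind <- match.arg(kind)
  p <- switch(kind,
    sandy = list(ll = c(0.05, 0.06, 0.07), dul = c(0.13, 0.15, 0.16),
                 sat = c(0.35, 0.36, 0.37), cn = 68),
    loamy = list(ll = c(0.11, 0.12, 0.13), dul = c(0.25, 0.27, 0.28),
                 sat = c(0.44, 0.45, 0.46), cn = 76),
    clay  = list(ll = c(0.17, 0.18, 0.19), dul = c(0.32, 0.33, 0.34),
                 sat = c(0.47, 0.48, 0.49), cn = 82)
  )
  cn <- curve_number %||% p$cn
  if (cn <= 0 || cn > 100) abort("`curve_number` must lie in (0, 100].")
  out <- tibble::tibble(
    layer = 1:3,
    thickness_cm = c(20, 30, 50),
    ll = p$ll, dul = p$dul, sat = p$sat,
    curve_number = cn, kind = kind
  )
  stopifnot(all(out$ll < out$dul), all(out$dul < out$sat))
  class(out) <- c("soil_profile", class(out))
  out
}

#' @rdname generate_soil
#' @param soil A soil profile tibble.
#' @export
soil_paw_mm <- function(soil) {
  sum((soil$dul - soil$ll) * soil$thickness_cm * 10)
}

# water held at a given volumetric fraction, in mm per layer
layer_mm <- function(soil, theta) theta * soil$thickness_cm * 10
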