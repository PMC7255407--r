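#' Multi-year seasonal analysis
#'
#' Runs [simulate_season()] for each cultivar in each year of a multi-year
#' weather series (rainy-season, rainfed by default, with moisture-triggered
#' planting), and summarises per-cultivar yield distributions: max, min,
#' mean, standard deviation, and the empirical cumulative distribution of
#' yields across years.  Years in which the planting trigger is never
#' reached are skipped with a warning.
#'
#' @param cultivars Cultivar tibble (one row per cultivar), e.g.
#'   [maize_cultivars()].
#' @param wx Multi-year weather tibble from [generate_weather()] (needs a
#'   `year` column and at least 2 years for dispersion summaries).
#' @param soil A [generate_soil()] profile.
#' @param mgmt A [management()] object; defaults to auto planting, rainfed.
#' @param species,ecotype Parameter sets as in [simulate_season()].
#' @return A list of class `gxe_seasonal`: `results` (one row per
#'   cultivar-year), `summary` (per-cultivar max/min/mean/sd/n_years),
#'   `cdf` (per-cultivar empirical CDF points), `skipped_years`.
#' @export
seasonal_analysis <- function(cultivars, wx, soil, mgmt = management(),
                              species = species_params(),
                              ecotype = ecotype_params()) {
  if (!"year" %in% names(wx)) abort("`wx` must carry a `year` column.")
  years <- unique(wx$year)
  if (length(years) < 2) abort("Seasonal analysis needs >= 2 years of weather.")
  if (nrow(cultivars) < 1) abort("Empty cultivar list.")

  skipped <- integer(0)
  res <- list()
  for (yr in years) {
    wy <- dplyr::filter(wx, .data$year == yr)
    sow <- tryCatch(
      if (identical(mgmt$sowing_date, "auto")) {
        auto_plant(wy, soil, mgmt$sowing_window, mgmt$plant_threshold)
      } else {
        as.integer(mgmt$sowing_date)
      },
      gxemaize_no_planting = function(e) NA_integer_
    )
    if (is.na(sow)) {
      skipped <- c(skipped, yr)
      next
    }
    m <- mgmt
    m$sowing_date <- sow
    for (k in seq_len(nrow(cultivars))) {
      one <- simulate_season(cultivars[k, ], wy, soil, m, species, ecotype)
      one$year <- yr
      res[[length(res) + 1]] <- one
    }
  }
  if (length(skipped)) {
    warn(paste0("No planting opportunity in year(s): ",
                paste(skipped, collapse = ", ")))
  }
  if (!length(res)) {
    abort("Planting failed in every year.", class = "gxemaize_no_planting")
  }
  results <- dplyr::bind_rows(res)

  summary <- results |>
    dplyr::group_by(.data$cultivar) |>
    dplyr::summarise(
      n_years = dplyr::n(),
      max = max(.data$grain_yield),
      min = min(.data$grain_yield),
      mean = mean(.data$grain_yield),
      sd = if (dplyr::n() > 1) sd(.data$grain_yield) else 0,
      .groups = "drop"
    )

  cdf <- results |>
    dplyr::group_by(.data$cultivar) |>
    dplyr::arrange(.data$grain_yield, .by_group = TRUE) |>
    dplyr::mutate(prob = dplyr::row_number() / dplyr::n()) |>
    dplyr::ungroup() |>
    dplyr::select("cultivar", "year", "grain_yield", "prob")

  structure(list(results = results, summary = summary, cdf = cdf,
                 skipped_years = skipped), class = "gxe_seasonal")
}

#' @export
print.gxe_seasonal <- function(x, ...) {
  cat("Seasonal analysis:", length(unique(x$results$year)), "years x",
      length(unique(x$results$cultivar)), "cultivars\n")
  print(x$summary, n = Inf)
  invisible(x)
}

#' Plot seasonal-analysis yield distributions
#'
#' Cumulative distribution curves of grain yield across years, one line per
#' cultivar.
#'
#' @param object A `gxe_seasonal` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.gxe_seasonal <- function(object, ...) {
  ggplot2::ggplot(object$cdf,
                  ggplot2::aes(.data$grain_yield, .data$prob,
                               colour = .data$cultivar)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "Grain yield (Mg/ha)",
                  y = "Cumulative probability across years",
                  colour = "Cultivar")
}
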