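#' Pipeline configuration
#'
#' Declarative configuration for [run_gxe_pipeline()].  The default layout
#' mirrors a savanna multi-environment trial: four sites (two dry-savanna,
#' two wet-savanna archetypes), each grown in two seasons — a dry season
#' (fixed mid-March sowing, irrigated to field capacity on demand) and a
#' rainy season (moisture-triggered sowing, rainfed) — giving eight
#' environments; at every site two soil profiles stand in for the two
#' replicate profile pits.  The "observed" arm is a synthetic surrogate
#' trial with the variance structure typical of such trials (E 67 %, G 19 %,
#' GEI 13 % of SS); its labels match the simulated arm so the two can be
#' compared rank-for-rank.
#'
#' @param cultivar_file CSV of cultivar coefficients; default the packaged
#'   16-variety set.
#' @param seed Master seed; every stage derives its own stream from it.
#' @param site_archetypes Character vector of `"dry"`/`"wet"` site
#'   archetypes.
#' @param soil_kinds Two soil kinds acting as the replicate profile pits.
#' @param observed_spec A [trial_spec()] for the observed-surrogate arm
#'   (dimensions are forced to match the simulated arm).
#' @param seasonal_years Years of weather for the long-term seasonal
#'   analysis (0 skips it).
#' @param out_dir Directory for artefacts (`NULL` = keep in memory only).
#' @return A list of class `gxe_config`.
#' @export
gxe_config <- function(cultivar_file = NULL, seed = 20160316L,
                       site_archetypes = c("dry", "dry", "wet", "wet"),
                       soil_kinds = c("loamy", "sandy"),
                       observed_spec = NULL, seasonal_years = 26,
                       out_dir = NULL) {
  if (length(soil_kinds) != 2) {
    abort("Exactly 2 soil kinds are required (the two replicate profile pits).")
  }
  structure(list(
    cultivar_file = cultivar_file, seed = as.integer(seed),
    site_archetypes = site_archetypes, soil_kinds = soil_kinds,
    observed_spec = observed_spec, seasonal_years = seasonal_years,
    out_dir = out_dir
  ), class = "gxe_config")
}

#' @rdname gxe_config
#' @param path Path to a YAML file whose keys are `gxe_config()` arguments.
#' @export
read_gxe_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(gxe_config, raw)
}

#' Run the full GEI / stability workflow
#'
#' Simulates every cultivar in every environment (site x season, two soil
#' profiles as replicates), builds the simulated yield trial and an
#' observed-surrogate trial, and runs the complete analysis: fit statistics
#' between the two arms, ANOVA variance partitioning, stability reports with
#' AICc model comparison for both arms, rank concordance between them, and
#' (optionally) the multi-year seasonal analysis for both savanna
#' archetypes.  Deterministic for a fixed config seed.  If `out_dir` is set,
#' every stage's tables are written as CSV/JSON together with a manifest of
#' file hashes.
#'
#' @param config A [gxe_config()] (or path to a YAML config).
#' @return A list of class `gxe_bundle`: `trial_sim`, `trial_obs`,
#'   `evaluation`, `anova_sim`, `anova_obs`, `report_sim`, `report_obs`,
#'   `concordance`, `seasonal` (list of `gxe_seasonal` by archetype or
#'   `NULL`), `config`, `manifest`.
#' @export
run_gxe_pipeline <- function(config = gxe_config()) {
  if (is.character(config)) config <- read_gxe_config(config)
  stopifnot(inherits(config, "gxe_config"))
  cv <- if (is.null(config$cultivar_file)) maize_cultivars() else {
    read_cultivars(config$cultivar_file)
  }
  if (nrow(cv) < 3) abort("Need at least 3 cultivars.")
  species <- species_params()
  ecotype <- ecotype_params()
  seed <- config$seed

  # --- simulated arm: site x season environments, soil pits as reps ---
  sims <- list()
  for (s in seq_along(config$site_archetypes)) {
    arch <- savanna_archetype(config$site_archetypes[s])
    wx <- generate_weather(arch, n_years = 1, seed = seed + s)
    for (season in c("dry", "rainy")) {
      env_label <- sprintf("%sS%d", ifelse(season == "dry", "DS", "RS"), s)
      mgmt <- if (season == "dry") {
        management(sowing_date = 75, irrigation = "auto")
      } else {
        management(sowing_date = "auto",
                   sowing_window = c(arch$season_start_doy,
                                     arch$season_start_doy + 91),
                   irrigation = "none")
      }
      for (rp in seq_along(config$soil_kinds)) {
        soil <- generate_soil(config$soil_kinds[rp])
        for (k in seq_len(nrow(cv))) {
          one <- simulate_season(cv[k, ], wx, soil, mgmt, species, ecotype)
          sims[[length(sims) + 1]] <- tibble::tibble(
            genotype = cv$name[k], environment = env_label, rep = rp,
            yield_mg_ha = one$grain_yield, site = s, season = season,
            soil = config$soil_kinds[rp]
          )
        }
      }
    }
  }
  trial_sim <- dplyr::bind_rows(sims)
  q <- length(unique(trial_sim$environment))

  # --- observed-surrogate arm with matching labels ---
  spec <- config$observed_spec %||% trial_spec()
  spec$n_genotypes <- nrow(cv)
  spec$n_environments <- q
  spec$n_reps <- length(config$soil_kinds)
  spec$seed <- seed + 101L
  trial_obs <- generate_trial(spec)
  glab <- sort(unique(trial_sim$genotype))
  elab <- sort(unique(trial_sim$environment))
  trial_obs$genotype <- glab[match(trial_obs$genotype,
                                   sort(unique(trial_obs$genotype)))]
  trial_obs$environment <- elab[match(trial_obs$environment,
                                      sort(unique(trial_obs$environment)))]

  # --- analysis stages ---
  cm_obs <- cell_means(trial_obs)
  cm_sim <- cell_means(trial_sim)[rownames(cm_obs), colnames(cm_obs)]
  evaluation <- evaluate_fit(
    tibble::tibble(obs = as.vector(cm_obs), sim = as.vector(cm_sim)),
    .data$obs, .data$sim
  )
  anova_obs <- two_way_anova(trial_obs)
  anova_sim <- two_way_anova(trial_sim)
  report_obs <- stability_report(trial_obs, "observed")
  report_sim <- stability_report(trial_sim, "simulated")
  concordance <- rank_concordance(report_obs, report_sim)

  seasonal <- NULL
  if (config$seasonal_years >= 2) {
    seasonal <- list()
    for (arch_name in c("dry", "wet")) {
      arch <- savanna_archetype(arch_name)
      wx <- generate_weather(arch, config$seasonal_years, seed = seed + 500 +
                               match(arch_name, c("dry", "wet")))
      seasonal[[arch_name]] <- seasonal_analysis(
        cv, wx, generate_soil(config$soil_kinds[1]),
        management(sowing_window = c(arch$season_start_doy,
                                     arch$season_start_doy + 91)),
        species, ecotype
      )
    }
  }

  bundle <- structure(list(
    trial_sim = trial_sim, trial_obs = trial_obs, evaluation = evaluation,
    anova_sim = anova_sim, anova_obs = anova_obs,
    report_sim = report_sim, report_obs = report_obs,
    concordance = concordance, seasonal = seasonal,
    config = config, manifest = NULL
  ), class = "gxe_bundle")

  if (!is.null(config$out_dir)) {
    bundle$manifest <- write_bundle(bundle, config$out_dir)
  }
  bundle
}

# write all bundle artefacts and return the manifest tibble
write_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  path <- function(f) file.path(out_dir, f)
  readr::write_csv(bundle$trial_sim, path("trial_simulated.csv"))
  readr::write_csv(bundle$trial_obs, path("trial_observed.csv"))
  readr::write_csv(bundle$evaluation, path("evaluation.csv"))
  readr::write_csv(bundle$anova_sim, path("anova_simulated.csv"))
  readr::write_csv(bundle$anova_obs, path("anova_observed.csv"))
  readr::write_csv(tidy(bundle$report_sim), path("stability_simulated.csv"))
  readr::write_csv(tidy(bundle$report_obs), path("stability_observed.csv"))
  jsonlite::write_json(
    list(observed = bundle$report_obs$aicc, simulated = bundle$report_sim$aicc),
    path("aicc.json"), dataframe = "rows", digits = NA
  )
  readr::write_csv(bundle$concordance, path("concordance.csv"))
  if (!is.null(bundle$seasonal)) {
    for (nm in names(bundle$seasonal)) {
      readr::write_csv(bundle$seasonal[[nm]]$summary,
                       path(paste0("seasonal_summary_", nm, ".csv")))
      readr::write_csv(bundle$seasonal[[nm]]$cdf,
                       path(paste0("seasonal_cdf_", nm, ".csv")))
    }
  }
  files <- setdiff(list.files(out_dir), "manifest.json")
  manifest <- tibble::tibble(
    file = files,
    md5 = unname(tools::md5sum(file.path(out_dir, files)))
  )
  jsonlite::write_json(
    list(seed = bundle$config$seed,
         site_archetypes = bundle$config$site_archetypes,
         soil_kinds = bundle$config$soil_kinds,
         files = manifest),
    path("manifest.json"), dataframe = "rows", auto_unbox = TRUE, digits = NA
  )
  manifest
}

#' Human-readable pipeline report
#'
#' Renders the bundle's main tables (ANOVA shares, stability statistics,
#' AICc comparison, concordance, seasonal summaries) as a markdown
#' character vector.
#'
#' @param bundle A `gxe_bundle` from [run_gxe_pipeline()].
#' @return Character vector of markdown lines, invisibly printable via
#'   `cat(..., sep = "\n")`.
#' @export
gxe_report <- function(bundle) {
  if (!inherits(bundle, "gxe_bundle")) abort("`bundle` must be a gxe_bundle.")
  if (is.null(bundle$report_sim) || !nrow(bundle$report_sim$genotypes)) {
    abort("Bundle is incomplete: no genotypes in the stability report.")
  }
  md_table <- function(df) {
    df <- dplyr::mutate(df, dplyr::across(dplyr::where(is.numeric),
                                          ~ round(.x, 3)))
    header <- paste0("| ", paste(names(df), collapse = " | "), " |")
    sep <- paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|")
    rows <- apply(df, 1, function(r) paste0("| ", paste(r, collapse = " | "),
                                            " |"))
    c(header, sep, rows)
  }
  out <- c(
    "# GEI and stability analysis",
    "", "## ANOVA (% of total SS)", "",
    md_table(dplyr::select(bundle$anova_obs, "source", "df", "ss", "ms",
                           "pct_ss")),
    "", "(observed arm above; simulated arm below)", "",
    md_table(dplyr::select(bundle$anova_sim, "source", "df", "ss", "ms",
                           "pct_ss")),
    "", "## Stability statistics (simulated arm)", "",
    md_table(dplyr::select(bundle$report_sim$genotypes, "genotype",
                           "mean_yield", "bi", "s2d", "ecovalence", "sigma2",
                           "asv", "ysi", "stable")),
    "", "## AICc model comparison", "",
    md_table(bundle$report_obs$aicc),
    "", "## Observed vs simulated rank concordance", "",
    md_table(bundle$concordance)
  )
  if (!is.null(bundle$seasonal)) {
    for (nm in names(bundle$seasonal)) {
      out <- c(out, "", paste0("## Seasonal analysis (", nm, " savanna)"), "",
               md_table(bundle$seasonal[[nm]]$summary))
    }
  }
  out
}
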