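#' Balanced two-way ANOVA for a multi-environment trial
#'
#' Partitions the total variation of a complete, balanced genotype x
#' environment x replicate yield table into Genotype, Environment, GEI,
#' Rep (crossed block) and Error components, with the percent-of-total-SS
#' "% variance estimate" used to report how much of the variation each
#' source explains.  Degrees of freedom are `p-1`, `q-1`, `(p-1)(q-1)`,
#' `r-1` and `(pq-1)(r-1)`.  Fitting is done by [stats::aov()]; with
#' balanced data the sequential sums of squares are the orthogonal
#' decomposition.
#'
#' @param trial A long trial tibble (`genotype`, `environment`, `rep`,
#'   `yield_mg_ha`).
#' @return A tibble of class `gxe_anova` with columns `source`, `df`, `ss`,
#'   `ms`, `f_value`, `p_value`, `pct_ss`; sources are Genotype,
#'   Environment, GEI, Rep, Error and Total.
#' @examples
#' tr <- generate_trial(trial_spec(n_genotypes = 4, n_environments = 4))
#' two_way_anova(tr)
#' @export
two_way_anova <- function(trial) {
  trial <- check_trial(trial)
  tab <- table(trial$genotype, trial$environment)
  if (length(unique(as.vector(tab))) != 1L) {
    abort("Trial must be complete and balanced (equal reps in every cell).",
          class = "gxemaize_unbalanced")
  }
  if (sum((trial$yield_mg_ha - mean(trial$yield_mg_ha))^2) < 1e-12) {
    abort("All yields are equal: %SS is undefined.",
          class = "gxemaize_zero_variance")
  }
  d <- dplyr::mutate(trial,
    genotype = factor(.data$genotype),
    environment = factor(.data$environment),
    rep = factor(.data$rep)
  )
  fit <- aov(yield_mg_ha ~ genotype + environment + rep +
               genotype:environment, data = d)
  sm <- summary(fit)[[1]]
  rows <- trimws(rownames(sm))
  pick <- function(nm) which(rows == nm)
  src <- c("Genotype", "Environment", "GEI", "Rep", "Error")
  idx <- c(pick("genotype"), pick("environment"),
           pick("genotype:environment"), pick("rep"), pick("Residuals"))
  df <- sm$Df[idx]
  ss <- sm$`Sum Sq`[idx]
  anova_from_ss(setNames(ss, src), setNames(df, src))
}

#' Build an ANOVA share table from printed sums of squares
#'
#' Computes mean squares, F ratios against the error term, and the percent
#' of total SS for each source, from sums of squares and degrees of freedom
#' given directly (for example the printed values of a published ANOVA
#' table).
#'
#' @param ss Named numeric of sums of squares; must include `"Error"`.
#' @param df Named numeric of degrees of freedom, same names.
#' @return A `gxe_anova` tibble (see [two_way_anova()]).
#' @export
anova_from_ss <- function(ss, df) {
  if (!identical(sort(names(ss)), sort(names(df)))) {
    abort("`ss` and `df` must carry the same source names.")
  }
  if (!"Error" %in% names(ss)) abort("An `Error` source is required.")
  src <- names(ss)
  ms <- ss / df
  ms_err <- ms[["Error"]]
  df_err <- df[["Error"]]
  fv <- ifelse(src == "Error", NA_real_, ms / ms_err)
  pv <- ifelse(is.na(fv), NA_real_, pf(fv, df, df_err, lower.tail = FALSE))
  total_ss <- sum(ss)
  ss_col <- c(unname(ss), total_ss)
  out <- tibble::tibble(
    source = c(src, "Total"),
    df = c(unname(df), sum(df)),
    ss = ss_col,
    ms = c(unname(ms), NA_real_),
    f_value = c(unname(fv), NA_real_),
    p_value = c(unname(pv), NA_real_),
    pct_ss = 100 * ss_col / total_ss
  )
  class(out) <- c("gxe_anova", class(out))
  out
}

#' Environment index
#'
#' The environment effect used by joint regression: the environment mean
#' minus the grand mean, `I_j = ybar_.j - ybar_..`; the indices sum to zero
#' exactly.
#'
#' @param trial A long trial tibble.
#' @return A tibble with columns `environment`, `index`.
#' @export
environment_index <- function(trial) {
  trial <- check_trial(trial)
  gm <- mean(trial$yield_mg_ha)
  trial |>
    dplyr::group_by(.data$environment) |>
    dplyr::summarise(index = mean(.data$yield_mg_ha) - gm, .groups = "drop")
}

# validate the long trial layout
check_trial <- function(trial) {
  need <- c("genotype", "environment", "rep", "yield_mg_ha")
  if (!is.data.frame(trial) || !all(need %in% names(trial))) {
    abort(paste0("A trial needs columns ", paste(need, collapse = ", ")))
  }
  if (any(is.na(trial$yield_mg_ha))) {
    abort("Missing yields are not supported; estimators assume balance.",
          class = "gxemaize_missing_cells")
  }
  tibble::as_tibble(trial)
}

# genotype x environment cell-mean matrix (reps averaged first)
cell_means <- function(trial) {
  trial <- check_trial(trial)
  cm <- trial |>
    dplyr::group_by(.data$genotype, .data$environment) |>
    dplyr::summarise(m = mean(.data$yield_mg_ha), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "environment", values_from = "m")
  mat <- as.matrix(cm[, -1])
  rownames(mat) <- cm$genotype
  if (any(is.na(mat))) {
    abort("Trial has empty genotype x environment cells.",
          class = "gxemaize_missing_cells")
  }
  mat
}
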