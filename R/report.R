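#' Full stability report for a yield trial
#'
#' Runs the complete stability battery on one yield source: the balanced
#' two-way ANOVA, Finlay-Wilkinson regression (`bi`, `S2d`), Wricke
#' ecovalence, Shukla stability variance, AMMI + the AMMI stability value,
#' and the Kang yield-stability rank sum, together with per-statistic ranks
#' (1 = most stable; for mean yield 1 = highest) and the AICc model
#' comparison.
#'
#' @inheritParams finlay_wilkinson
#' @param source_label Label for the yield source (e.g. `"observed"` or
#'   `"simulated"`); carried through reports and concordance.
#' @return An object of class `gxe_stability`: a list with elements
#'   `genotypes` (tibble of per-genotype statistics and ranks), `anova`
#'   (`gxe_anova` tibble), `aicc` (model-comparison tibble), `ammi`
#'   (`gxe_ammi`), and `meta` (p, q, r, source label).
#' @examples
#' tr <- generate_trial(trial_spec(n_genotypes = 6, n_environments = 5))
#' rep <- stability_report(tr)
#' tidy(rep)
#' glance(rep)
#' @export
stability_report <- function(trial, source_label = "observed") {
  trial <- check_trial(trial)
  mat <- cell_means(trial)
  p <- nrow(mat); q <- ncol(mat)
  if (p < 3 || q < 3) {
    abort("Stability estimators need at least 3 genotypes and 3 environments.")
  }
  r <- nrow(trial) / (p * q)
  an <- two_way_anova(trial)
  fw <- finlay_wilkinson(trial)
  wi <- wricke_ecovalence(trial)
  s2 <- shukla_sigma2(wi$ecovalence, p, q)
  am <- ammi(trial)
  asv_i <- asv_from_ammi(am)
  kang <- kang_ysi(trial, sigma2 = s2)

  g <- fw |>
    dplyr::left_join(wi, by = "genotype") |>
    dplyr::mutate(
      sigma2 = s2[match(.data$genotype, wi$genotype)],
      asv = unname(asv_i)[match(.data$genotype, rownames(mat))],
      ysi = kang$ysi[match(.data$genotype, kang$genotype)],
      stable = kang$stable[match(.data$genotype, kang$genotype)],
      rank_yield = stability_rank(.data$mean_yield, .data$genotype, desc = TRUE),
      rank_bi = stability_rank(abs(.data$bi - 1), .data$genotype),
      rank_s2d = stability_rank(.data$s2d, .data$genotype),
      rank_ecovalence = stability_rank(.data$ecovalence, .data$genotype),
      rank_sigma2 = stability_rank(.data$sigma2, .data$genotype),
      rank_asv = stability_rank(.data$asv, .data$genotype),
      rank_ysi = stability_rank(.data$ysi, .data$genotype, desc = TRUE)
    )

  structure(list(
    genotypes = g, anova = an,
    aicc = aicc_compare(trial, models = aicc_feasible_models(p, q)),
    ammi = am,
    meta = list(p = p, q = q, r = r, source = source_label)
  ), class = "gxe_stability")
}

#' @export
print.gxe_stability <- function(x, ...) {
  cat("Stability report (", x$meta$source, "): ", x$meta$p, " genotypes x ",
      x$meta$q, " environments x ", x$meta$r, " reps\n", sep = "")
  gei <- x$anova$pct_ss[x$anova$source == "GEI"]
  cat("GEI share of total SS:", sprintf("%.1f%%", gei),
      "| best model by AICc:", x$aicc$model[1], "\n")
  print(x$genotypes, n = Inf)
  invisible(x)
}

#' Tidy a stability report
#'
#' One row per genotype per statistic with its value and stability rank.
#'
#' @param x A `gxe_stability` object.
#' @param ... Unused.
#' @return A tibble with columns `source`, `genotype`, `statistic`, `value`,
#'   `rank`.
#' @export
tidy.gxe_stability <- function(x, ...) {
  g <- x$genotypes
  stats_map <- c(mean_yield = "rank_yield", bi = "rank_bi", s2d = "rank_s2d",
                 ecovalence = "rank_ecovalence", sigma2 = "rank_sigma2",
                 asv = "rank_asv", ysi = "rank_ysi")
  purrr::imap_dfr(stats_map, function(rk, st) {
    tibble::tibble(
      source = x$meta$source, genotype = g$genotype, statistic = st,
      value = g[[st]], rank = g[[rk]]
    )
  })
}

#' Glance at a stability report
#'
#' @param x A `gxe_stability` object.
#' @param ... Unused.
#' @return A one-row tibble: dimensions, GEI %SS, best AICc model, number of
#'   Kang-stable genotypes, most and least stable genotype by Shukla
#'   variance.
#' @export
glance.gxe_stability <- function(x, ...) {
  g <- x$genotypes
  tibble::tibble(
    source = x$meta$source, n_genotypes = x$meta$p,
    n_environments = x$meta$q, n_reps = x$meta$r,
    pct_ss_gei = x$anova$pct_ss[x$anova$source == "GEI"],
    pct_ss_env = x$anova$pct_ss[x$anova$source == "Environment"],
    pct_ss_gen = x$anova$pct_ss[x$anova$source == "Genotype"],
    best_model = x$aicc$model[1],
    n_stable_kang = sum(g$stable),
    most_stable = g$genotype[which.min(g$sigma2)],
    least_stable = g$genotype[which.max(g$sigma2)]
  )
}

#' Rank concordance between two stability reports
#'
#' Compares the genotype rankings that two yield sources (typically observed
#' and simulated) induce for each stability statistic: Spearman rank
#' correlation (ties mid-ranked) and the fraction of agreement among the
#' top-k most stable genotypes.
#'
#' @param report_a,report_b `gxe_stability` objects over the same genotypes.
#' @param top_k Size of the head-of-ranking agreement set (default 3).
#' @return A tibble with columns `statistic`, `spearman_rho`,
#'   `top_k_agreement`.
#' @export
rank_concordance <- function(report_a, report_b, top_k = 3) {
  stopifnot(inherits(report_a, "gxe_stability"),
            inherits(report_b, "gxe_stability"))
  ta <- tidy(report_a)
  tb <- tidy(report_b)
  if (!setequal(report_a$genotypes$genotype, report_b$genotypes$genotype)) {
    abort("The two reports cover different genotype sets.",
          class = "gxemaize_label_mismatch")
  }
  j <- dplyr::inner_join(ta, tb, by = c("genotype", "statistic"),
                         suffix = c("_a", "_b"))
  j |>
    dplyr::group_by(.data$statistic) |>
    dplyr::summarise(
      spearman_rho = stats::cor(.data$rank_a, .data$rank_b,
                                method = "spearman"),
      top_k_agreement = {
        ka <- .data$genotype[order(.data$rank_a)][seq_len(top_k)]
        kb <- .data$genotype[order(.data$rank_b)][seq_len(top_k)]
        length(intersect(ka, kb)) / top_k
      },
      .groups = "drop"
    )
}

#' Plot a stability report
#'
#' Mean yield against the chosen stability statistic; the ideal genotype
#' sits high (yield) and left (stability).
#'
#' @param object A `gxe_stability` object.
#' @param statistic Which stability statistic to plot on the x axis.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.gxe_stability <- function(object,
                                   statistic = c("sigma2", "asv",
                                                 "ecovalence", "bi"),
                                   ...) {
  statistic <- match.arg(statistic)
  g <- object$genotypes
  ggplot2::ggplot(g, ggplot2::aes(.data[[statistic]], .data$mean_yield)) +
    ggplot2::geom_point() +
    ggplot2::geom_text(ggplot2::aes(label = .data$genotype),
                       vjust = -0.6, size = 3) +
    ggplot2::geom_hline(yintercept = mean(g$mean_yield), linetype = 2) +
    ggplot2::labs(
      x = statistic, y = "Mean yield (Mg/ha)",
      title = paste0("Yield vs stability (", object$meta$source, ")")
    )
}
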