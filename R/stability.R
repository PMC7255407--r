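#' Finlay-Wilkinson joint regression
#'
#' Regresses each genotype's environment means on the environment index
#' `I_j = ybar_.j - ybar_..`.  The slope `bi` measures sensitivity to
#' environmental quality (1 = average response; above 1 = adapted to
#' high-yielding environments; below 1 = buffered), and `S2d` is the mean
#' square of deviations from the regression with `q - 2` degrees of freedom.
#' On balanced data the genotype slopes average exactly 1.
#'
#' @param trial A long trial tibble (`genotype`, `environment`, `rep`,
#'   `yield_mg_ha`).
#' @return A tibble with columns `genotype`, `mean_yield`, `bi`, `s2d`.
#' @examples
#' tr <- generate_trial(trial_spec(n_genotypes = 4, n_environments = 5,
#'                                 gei_structure = "slope",
#'                                 beta = c(0.5, 1, 1, 1.5)))
#' finlay_wilkinson(tr)
#' @export
finlay_wilkinson <- function(trial) {
  mat <- cell_means(trial)
  q <- ncol(mat)
  if (q < 3) abort("Finlay-Wilkinson needs at least 3 environments.")
  idx <- colMeans(mat) - mean(mat)
  sxx <- sum(idx^2)
  if (sxx <= 0) {
    abort("No environmental gradient: all environment means are equal.",
          class = "gxemaize_degenerate_series")
  }
  gm <- rowMeans(mat)
  dev <- mat - gm
  bi <- as.vector(dev %*% idx) / sxx
  resid <- dev - outer(bi, idx)
  s2d <- rowSums(resid^2) / (q - 2)
  tibble::tibble(genotype = rownames(mat), mean_yield = unname(gm), bi = bi,
                 s2d = unname(s2d))
}

#' Wricke ecovalence
#'
#' Each genotype's contribution to the interaction sum of squares of the
#' genotype x environment cell-mean table:
#' `W_i = sum_j (ybar_ij - ybar_i. - ybar_.j + ybar_..)^2`.  Summed over
#' genotypes the ecovalences equal the GEI SS of the cell means exactly.
#'
#' @inheritParams finlay_wilkinson
#' @return A tibble with columns `genotype`, `ecovalence`.
#' @export
wricke_ecovalence <- function(trial) {
  mat <- cell_means(trial)
  ctr <- sweep(sweep(mat, 1, rowMeans(mat)), 2, colMeans(mat)) + mean(mat)
  tibble::tibble(genotype = rownames(mat),
                 ecovalence = unname(rowSums(ctr^2)))
}

#' Shukla stability variance
#'
#' The standard unbiased per-genotype interaction variance, an affine and
#' strictly increasing function of the ecovalence:
#' `sigma2_i = p * W_i / ((p-2)(q-1)) - sum(W) / ((p-1)(p-2)(q-1))`
#' for `p` genotypes and `q` environments.  The estimator is unbiased and
#' can be negative; negative values are reported as-is, never clamped.
#'
#' @param ecovalence Numeric vector of per-genotype ecovalences (or a tibble
#'   from [wricke_ecovalence()]).
#' @param n_genotypes,n_environments `p >= 3` and `q >= 2`; `p` defaults to
#'   `length(ecovalence)`.
#' @return Numeric vector of stability variances (a tibble in, a tibble out
#'   with an added `sigma2` column).
#' @examples
#' shukla_sigma2(c(10, 2, 6), n_environments = 4)
#' @export
shukla_sigma2 <- function(ecovalence, n_genotypes = NULL, n_environments) {
  if (is.data.frame(ecovalence)) {
    w <- ecovalence$ecovalence
    p <- n_genotypes %||% length(w)
    out <- dplyr::mutate(ecovalence,
      sigma2 = shukla_sigma2(w, p, n_environments))
    return(out)
  }
  w <- ecovalence
  p <- n_genotypes %||% length(w)
  q <- n_environments
  if (p < 3) abort("Shukla stability variance needs p >= 3 genotypes.")
  if (q < 2) abort("Shukla stability variance needs q >= 2 environments.")
  p * w / ((p - 2) * (q - 1)) - sum(w) / ((p - 1) * (p - 2) * (q - 1))
}

#' AMMI decomposition of a yield trial
#'
#' Additive main effects and multiplicative interaction: the genotype x
#' environment cell means are fitted additively (grand mean + genotype +
#' environment effects) and the interaction residual is decomposed by
#' singular value decomposition.  The squared singular values sum to the
#' GEI sum of squares of the cell-mean table; axis `k` carries `lambda_k^2`.
#' Genotype and environment IPCA scores are the singular vectors scaled by
#' `sqrt(lambda_k)`.
#'
#' @inheritParams finlay_wilkinson
#' @return A list of class `gxe_ammi`: `grand_mean`, `genotype_effects`,
#'   `environment_effects`, `singular_values`, `ss_axis`, `gei_ss`,
#'   `genotype_scores` (p x K), `environment_scores` (q x K),
#'   `pct_gei` (percent of GEI SS per axis).
#' @export
ammi <- function(trial) {
  mat <- cell_means(trial)
  p <- nrow(mat); q <- ncol(mat)
  if (p < 3 || q < 3) abort("AMMI needs at least 3 genotypes and 3 environments.")
  resid <- sweep(sweep(mat, 1, rowMeans(mat)), 2, colMeans(mat)) + mean(mat)
  kmax <- min(p - 1, q - 1)
  sv <- svd(resid, nu = kmax, nv = kmax)
  lambda <- sv$d[seq_len(kmax)]
  # degenerate (additive) tables: all axes zero
  lambda[lambda < 1e-10] <- 0
  gs <- sv$u %*% diag(sqrt(lambda), kmax, kmax)
  es <- sv$v %*% diag(sqrt(lambda), kmax, kmax)
  rownames(gs) <- rownames(mat)
  rownames(es) <- colnames(mat)
  colnames(gs) <- colnames(es) <- paste0("IPCA", seq_len(kmax))
  gei_ss <- sum(resid^2)
  structure(list(
    grand_mean = mean(mat),
    genotype_effects = rowMeans(mat) - mean(mat),
    environment_effects = colMeans(mat) - mean(mat),
    singular_values = lambda,
    ss_axis = lambda^2,
    gei_ss = gei_ss,
    genotype_scores = gs,
    environment_scores = es,
    pct_gei = if (gei_ss > 0) 100 * lambda^2 / gei_ss else rep(0, kmax)
  ), class = "gxe_ammi")
}

#' AMMI stability value
#'
#' Distance of each genotype from the origin of the weighted IPCA1/IPCA2
#' plane (Purchase formulation):
#' `ASV_i = sqrt((ss1/ss2 * IPCA1_i)^2 + IPCA2_i^2)`.  Lower is more stable.
#' If the second axis carries no variation the absolute IPCA1 score is
#' returned with a warning.
#'
#' @param ipca1,ipca2 Per-genotype scores on the first two interaction axes.
#' @param ss1,ss2 Sums of squares of the first two axes.
#' @return Numeric vector of ASV values, `>= 0`.
#' @examples
#' asv(3, 4, ss1 = 10, ss2 = 10)  # 5
#' @export
asv <- function(ipca1, ipca2, ss1, ss2) {
  if (ss2 <= 0) {
    warn("Second IPCA axis carries no variation; falling back to |IPCA1|.")
    return(abs(ipca1))
  }
  sqrt((ss1 / ss2 * ipca1)^2 + ipca2^2)
}

#' @rdname asv
#' @param decomposition A `gxe_ammi` object; scores and axis SS are taken
#'   from its first two axes.
#' @export
asv_from_ammi <- function(decomposition) {
  stopifnot(inherits(decomposition, "gxe_ammi"))
  gs <- decomposition$genotype_scores
  if (ncol(gs) < 2) {
    warn("Fewer than two IPCA axes; falling back to |IPCA1|.")
    return(abs(gs[, 1]))
  }
  asv(gs[, 1], gs[, 2], decomposition$ss_axis[1], decomposition$ss_axis[2])
}

#' Kang yield-stability rank-sum index
#'
#' Combines mean yield and Shukla stability variance into an integer score
#' (Kang 1993).  Yields are ranked 1 (lowest) to p (highest); a genotype
#' whose mean differs from the grand mean by more than the LSD gains (+1) or
#' loses (-1) a rank point; a stability penalty of 0 / -2 / -4 / -8 is then
#' applied according to the significance of the genotype's stability
#' variance in an F test against the pooled error (`F = sigma2 * r / MS_err`
#' on `q - 1` and error df).  Genotypes with YSi above the mean YSi are
#' flagged stable.
#'
#' @inheritParams finlay_wilkinson
#' @param sigma2 Optional per-genotype Shukla variances (computed from the
#'   trial if omitted).
#' @param alpha Significance thresholds for the stability penalty.
#' @param penalties Penalty magnitudes matched to `alpha` (after a leading
#'   0 for "not significant").
#' @return A tibble with columns `genotype`, `mean_yield`, `yield_rank`,
#'   `rank_adjustment`, `stability_penalty`, `ysi`, `stable`.
#' @export
kang_ysi <- function(trial, sigma2 = NULL, alpha = c(0.05, 0.01, 0.001),
                     penalties = c(0, 2, 4, 8)) {
  trial <- check_trial(trial)
  mat <- cell_means(trial)
  p <- nrow(mat); q <- ncol(mat)
  r <- nrow(trial) / (p * q)
  if (is.null(sigma2)) {
    sigma2 <- shukla_sigma2(wricke_ecovalence(trial)$ecovalence, p, q)
  }
  an <- two_way_anova(trial)
  ms_err <- an$ms[an$source == "Error"]
  df_err <- an$df[an$source == "Error"]
  if (!length(ms_err) || is.na(ms_err)) {
    abort("Pooled error mean square unavailable for significance tests.")
  }

  gm <- rowMeans(mat)
  grand <- mean(mat)
  # average ranks for ties, genotype label as the stable second key
  ord <- order(gm, rownames(mat))
  yr <- rank(gm, ties.method = "average")

  # LSD-style adjustment of the yield rank against the grand mean
  se_diff <- sqrt(2 * ms_err / (q * r))
  lsd <- qt(0.975, df_err) * se_diff
  adj <- ifelse(gm - grand > lsd, 1, ifelse(grand - gm > lsd, -1, 0))

  # significance of sigma2 against pooled error (on the cell-mean scale)
  fstat <- pmax(0, sigma2) * r / ms_err
  pval <- pf(fstat, q - 1, df_err, lower.tail = FALSE)
  level <- vapply(pval, function(pp) sum(pp < alpha), integer(1))
  penalty <- penalties[level + 1L]

  ysi <- yr + adj - penalty
  tibble::tibble(
    genotype = rownames(mat), mean_yield = unname(gm),
    yield_rank = unname(yr), rank_adjustment = unname(adj),
    stability_penalty = penalty, ysi = ysi,
    stable = ysi > mean(ysi)
  )
}

#' Rank genotypes by a stability statistic
#'
#' Average ranks for ties; genotype label is the stable second sort key.
#' @param x Numeric statistic (lower = more stable unless `desc = TRUE`).
#' @param labels Genotype labels.
#' @param desc Rank from highest to lowest instead.
#' @return Integer-ish rank vector (1 = most stable / best).
#' @keywords internal
stability_rank <- function(x, labels, desc = FALSE) {
  v <- if (desc) -x else x
  rank(v, ties.method = "average")
}
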