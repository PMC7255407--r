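#' AICc comparison of stability models
#'
#' Fits the candidate stability models to the genotype x environment
#' cell-mean table and compares them by the corrected Akaike information
#' criterion `AICc = n log(RSS/n) + 2k + 2k(k+1)/(n-k-1)`, where `n = p*q`
#' cells.  Parameter counts, documented here because conventions vary:
#' \describe{
#'   \item{additive}{grand mean + genotype + environment effects,
#'     `k = p + q - 1`.}
#'   \item{FW}{additive plus per-genotype regression slopes on the
#'     environment index, `k = p + q - 1 + (p - 1)`.}
#'   \item{AMMI1, AMMI2}{additive plus `m` multiplicative axes,
#'     `k = p + q - 1 + m(p + q - 1 - m)`.}
#' }
#' A model that fits exactly (RSS = 0) is flagged `perfect_fit` and given
#' `AICc = -Inf` rather than a fabricated finite value.
#'
#' @inheritParams finlay_wilkinson
#' @param models Character subset of `c("additive", "FW", "AMMI1", "AMMI2")`.
#'   `aicc_feasible_models()` returns the subset whose parameter count leaves
#'   `n - k - 1 > 0` on a `p x q` table, which is what [stability_report()]
#'   compares on small trials.
#' @return A tibble with columns `model`, `k`, `rss`, `aicc`, `delta_aicc`,
#'   `rank`, `perfect_fit`, ordered best first.
#' @examples
#' tr <- generate_trial(trial_spec(n_genotypes = 6, n_environments = 5))
#' aicc_compare(tr)
#' @export
#' @rdname aicc_compare
#' @param p,q Numbers of genotypes and environments.
#' @export
aicc_feasible_models <- function(p, q) {
  n <- p * q
  k_add <- p + q - 1
  k <- c(additive = k_add, FW = k_add + (p - 1),
         AMMI1 = k_add + 1 * (p + q - 2),
         AMMI2 = k_add + 2 * (p + q - 3))
  ammi_ok <- c(TRUE, TRUE, min(p, q) - 1 >= 1, min(p, q) - 1 >= 2)
  names(k)[n - k - 1 > 0 & ammi_ok]
}

#' @rdname aicc_compare
#' @export
aicc_compare <- function(trial, models = c("additive", "FW", "AMMI1", "AMMI2")) {
  models <- match.arg(models, several.ok = TRUE)
  mat <- cell_means(trial)
  p <- nrow(mat); q <- ncol(mat)
  n <- p * q
  grand <- mean(mat)
  geff <- rowMeans(mat) - grand
  eeff <- colMeans(mat) - grand
  additive_fit <- grand + outer(geff, rep(1, q)) + outer(rep(1, p), eeff)
  inter <- mat - additive_fit
  k_add <- p + q - 1

  fit_one <- function(model) {
    if (model == "additive") {
      rss <- sum(inter^2)
      k <- k_add
    } else if (model == "FW") {
      fw <- finlay_wilkinson(trial)
      idx <- colMeans(mat) - grand
      fitted <- additive_fit + outer(fw$bi - 1, idx)
      rss <- sum((mat - fitted)^2)
      k <- k_add + (p - 1)
    } else {
      m <- as.integer(sub("AMMI", "", model))
      kmax <- min(p - 1, q - 1)
      if (m > kmax) {
        abort(paste0(model, " needs min(p,q) - 1 >= ", m, " axes."))
      }
      sv <- svd(inter)
      lam2 <- sv$d^2
      rss <- sum(lam2[-seq_len(m)])
      k <- k_add + m * (p + q - 1 - m)
    }
    if (n - k - 1 <= 0) {
      abort(paste0("AICc undefined for ", model, ": n - k - 1 <= 0."))
    }
    perfect <- rss < 1e-12
    aicc <- if (perfect) -Inf else {
      n * log(rss / n) + 2 * k + 2 * k * (k + 1) / (n - k - 1)
    }
    tibble::tibble(model = model, k = k, rss = rss, aicc = aicc,
                   perfect_fit = perfect)
  }

  out <- purrr::map_dfr(models, fit_one) |>
    dplyr::arrange(.data$aicc, .data$k)
  best <- out$aicc[1]
  out |>
    dplyr::mutate(
      delta_aicc = dplyr::case_when(
        .data$aicc == best ~ 0,
        is.infinite(best) ~ Inf,
        TRUE ~ .data$aicc - best
      ),
      rank = dplyr::row_number()
    )
}
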