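#' Specify a synthetic multi-environment yield trial
#'
#' Describes a balanced genotype x environment x replicate yield table with a
#' known variance structure.  Yields are generated as
#' `Y_ijr = mu + G_i + E_j + GE_ij + R_r + eps_ijr` with effect vectors
#' scaled so that each source's *expected* sum of squares equals the
#' requested fraction of the total: effects are drawn, centred and rescaled
#' exactly, and the residual-noise contribution each source's SS picks up
#' (`df_source * sigma2`) is subtracted from its structural share, so
#' `E[SS_source] = fraction * total` holds for every source.
#'
#' @param n_genotypes,n_environments,n_reps Counts, all `>= 2` (stability
#'   statistics downstream need `>= 3` genotypes and environments).
#' @param grand_mean Grand mean yield, Mg ha-1.
#' @param var_fractions Named numeric `c(E=, G=, GEI=, rep=, error=)`,
#'   non-negative, summing to 1.
#' @param gei_structure `"multiplicative"` (low-rank, AMMI-type),
#'   `"slope"` (Finlay-Wilkinson type, `GE_ij = (beta_i - 1) * E_j` exactly),
#'   or `"unstructured"`.
#' @param rank Rank of the multiplicative interaction (default 2).
#' @param beta Per-genotype slopes for `gei_structure = "slope"`; recycled to
#'   `n_genotypes`.  With slope structure the GEI share is implied by `beta`
#'   and the environment share, and `var_fractions["GEI"]` is ignored.
#' @param total_variance Total variance of the table, (Mg ha-1)^2; sets the
#'   absolute scale of all sums of squares.
#' @param seed Integer seed for [generate_trial()].
#' @return A list of class `trial_spec`.
#' @export
trial_spec <- function(n_genotypes = 16, n_environments = 8, n_reps = 2,
                       grand_mean = 3.8,
                       var_fractions = c(E = 0.67, G = 0.19, GEI = 0.13,
                                         rep = 0, error = 0.01),
                       gei_structure = c("multiplicative", "slope",
                                         "unstructured"),
                       rank = 2, beta = NULL, total_variance = 1.5,
                       seed = 20160316L) {
  gei_structure <- match.arg(gei_structure)
  if (any(c(n_genotypes, n_environments, n_reps) < 2)) {
    abort("All counts must be >= 2.")
  }
  need <- c("E", "G", "GEI", "rep", "error")
  if (!all(need %in% names(var_fractions))) {
    abort(paste0("`var_fractions` must be named ", paste(need, collapse = ", ")))
  }
  var_fractions <- var_fractions[need]
  if (any(var_fractions < 0)) abort("Variance fractions must be >= 0.")
  if (abs(sum(var_fractions) - 1) > 1e-12) {
    abort("Variance fractions must sum to 1 (within 1e-12).")
  }
  if (gei_structure == "slope") {
    beta <- rep_len(beta %||% 1, n_genotypes)
  }
  structure(list(
    n_genotypes = as.integer(n_genotypes),
    n_environments = as.integer(n_environments),
    n_reps = as.integer(n_reps),
    grand_mean = grand_mean, var_fractions = var_fractions,
    gei_structure = gei_structure, rank = rank, beta = beta,
    total_variance = total_variance, seed = as.integer(seed)
  ), class = "trial_spec")
}

# draw a vector, centre it, rescale so its sum of squares is ss_target
scaled_effects <- function(n, ss_target) {
  if (ss_target <= 0) return(numeric(n))
  x <- rnorm(n)
  x <- x - mean(x)
  s <- sum(x^2)
  if (s == 0) return(numeric(n))
  x * sqrt(ss_target / s)
}

#' Generate a synthetic yield trial
#'
#' Draws a balanced long-format yield table from a [trial_spec()].  The
#' environment effects are drawn once per trial (constant across reps); the
#' replicate effect is a crossed block.  Reproducible for a fixed seed.
#'
#' @param spec A [trial_spec()].
#' @param seed Optional seed overriding `spec$seed`.
#' @return A tibble with columns `genotype`, `environment`, `rep`,
#'   `yield_mg_ha`.
#' @examples
#' tr <- generate_trial(trial_spec(n_genotypes = 4, n_environments = 4))
#' dplyr::count(tr, genotype)
#' @export
generate_trial <- function(spec, seed = NULL) {
  if (!inherits(spec, "trial_spec")) abort("`spec` must come from `trial_spec()`.")
  withr::local_seed(as.integer(seed %||% spec$seed))
  p <- spec$n_genotypes; q <- spec$n_environments; r <- spec$n_reps
  f <- spec$var_fractions
  n <- p * q * r
  total_ss <- spec$total_variance * (n - 1)

  df_err <- (p * q - 1) * (r - 1)
  sigma2 <- f[["error"]] * total_ss / df_err
  ss_g <- f[["G"]] * total_ss - (p - 1) * sigma2
  ss_e <- f[["E"]] * total_ss - (q - 1) * sigma2
  ss_ge <- f[["GEI"]] * total_ss - (p - 1) * (q - 1) * sigma2
  ss_r <- f[["rep"]] * total_ss - (r - 1) * sigma2
  gei_checked <- spec$gei_structure != "slope" && f[["GEI"]] > 0
  if (min(ss_g, ss_e) < 0 || (gei_checked && ss_ge < 0) ||
      (f[["rep"]] > 0 && ss_r < 0)) {
    abort("Error fraction too large relative to the structural fractions.")
  }

  g_eff <- scaled_effects(p, ss_g / (r * q))
  e_eff <- scaled_effects(q, ss_e / (r * p))
  r_eff <- if (ss_r > 0) scaled_effects(r, ss_r / (p * q)) else numeric(r)

  ge <- switch(spec$gei_structure,
    slope = outer(spec$beta - 1, e_eff),
    multiplicative = {
      k <- min(spec$rank, p - 1, q - 1)
      u <- matrix(rnorm(p * k), p, k)
      v <- matrix(rnorm(q * k), q, k)
      u <- sweep(u, 2, colMeans(u))
      v <- sweep(v, 2, colMeans(v))
      d <- 0.6^(seq_len(k) - 1)
      m <- u %*% diag(d, k, k) %*% t(v)
      m <- sweep(sweep(m, 1, rowMeans(m)), 2, colMeans(m)) # double-centre
      s <- sum(m^2)
      if (s > 0 && ss_ge > 0) m * sqrt(ss_ge / (r * s)) else m * 0
    },
    unstructured = {
      m <- matrix(rnorm(p * q), p, q)
      m <- sweep(sweep(m, 1, rowMeans(m)), 2, colMeans(m))
      s <- sum(m^2)
      if (s > 0 && ss_ge > 0) m * sqrt(ss_ge / (r * s)) else m * 0
    }
  )

  gl <- sprintf("G%02d", seq_len(p))
  el <- sprintf("E%02d", seq_len(q))
  grid <- tidyr::expand_grid(genotype = gl, environment = el,
                             rep = seq_len(r))
  gi <- match(grid$genotype, gl)
  ej <- match(grid$environment, el)
  yield <- spec$grand_mean + g_eff[gi] + e_eff[ej] +
    ge[cbind(gi, ej)] + r_eff[grid$rep] + rnorm(n, 0, sqrt(sigma2))
  dplyr::mutate(grid, yield_mg_ha = yield)
}

#' Read and write long-format yield trial CSV
#'
#' The dialect is `genotype,environment,rep,yield_mg_ha`.
#'
#' @param path File path.
#' @param trial A trial tibble.
#' @return `read_trial_csv()` returns the trial tibble; `write_trial_csv()`
#'   returns `path` invisibly.
#' @export
read_trial_csv <- function(path) {
  tr <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("genotype", "environment", "rep", "yield_mg_ha")
  if (!all(need %in% names(tr))) {
    abort(paste0("Trial CSV must have columns ", paste(need, collapse = ",")))
  }
  tibble::as_tibble(tr[need])
}

#' @rdname read_trial_csv
#' @export
write_trial_csv <- function(trial, path) {
  readr::write_csv(trial, path)
  invisible(path)
}
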