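# Brute-force oracles: explicit loops over the textbook definitions, kept
# deliberately independent of the package implementations they check.

# random balanced long trial with arbitrary structure
make_trial <- function(p, q, r = 2, seed = 1, sd = 1) {
  set.seed(seed)
  grid <- expand.grid(genotype = sprintf("G%02d", 1:p),
                      environment = sprintf("E%02d", 1:q),
                      rep = 1:r, stringsAsFactors = FALSE)
  grid$yield_mg_ha <- 4 + rnorm(nrow(grid), 0, sd)
  tibble::as_tibble(grid)
}

# cell-mean matrix by explicit averaging
bf_cell_means <- function(trial) {
  g <- sort(unique(trial$genotype)); e <- sort(unique(trial$environment))
  m <- matrix(NA_real_, length(g), length(e), dimnames = list(g, e))
  for (i in seq_along(g)) for (j in seq_along(e)) {
    m[i, j] <- mean(trial$yield_mg_ha[trial$genotype == g[i] &
                                        trial$environment == e[j]])
  }
  m
}

# balanced two-way ANOVA sums of squares by definition
bf_anova_ss <- function(trial) {
  y <- trial$yield_mg_ha
  gm <- mean(y)
  g <- sort(unique(trial$genotype)); e <- sort(unique(trial$environment))
  reps <- sort(unique(trial$rep))
  p <- length(g); q <- length(e); r <- length(reps)
  mg <- sapply(g, function(x) mean(y[trial$genotype == x]))
  me <- sapply(e, function(x) mean(y[trial$environment == x]))
  mr <- sapply(reps, function(x) mean(y[trial$rep == x]))
  cm <- bf_cell_means(trial)
  ss_g <- q * r * sum((mg - gm)^2)
  ss_e <- p * r * sum((me - gm)^2)
  ss_r <- p * q * sum((mr - gm)^2)
  ss_ge <- 0
  for (i in seq_len(p)) for (j in seq_len(q)) {
    ss_ge <- ss_ge + r * (cm[i, j] - mg[i] - me[j] + gm)^2
  }
  ss_tot <- sum((y - gm)^2)
  lapply(list(G = ss_g, E = ss_e, GEI = ss_ge, Rep = ss_r,
              Error = ss_tot - ss_g - ss_e - ss_ge - ss_r, Total = ss_tot),
         unname)
}

# Wricke ecovalence by explicit double-centred loop
bf_ecovalence <- function(mat) {
  gm <- mean(mat)
  out <- numeric(nrow(mat))
  for (i in seq_len(nrow(mat))) {
    for (j in seq_len(ncol(mat))) {
      out[i] <- out[i] +
        (mat[i, j] - mean(mat[i, ]) - mean(mat[, j]) + gm)^2
    }
  }
  out
}

# GEI SS of a cell-mean table by loop
bf_gei_ss <- function(mat) sum(bf_ecovalence(mat))

# Finlay-Wilkinson slopes via per-genotype lm() fits (independent route)
bf_fw <- function(mat) {
  idx <- colMeans(mat) - mean(mat)
  t(sapply(seq_len(nrow(mat)), function(i) {
    fit <- lm(mat[i, ] ~ idx)
    res <- sum(residuals(fit)^2) / (ncol(mat) - 2)
    c(bi = unname(coef(fit)[2]), s2d = res)
  }))
}
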