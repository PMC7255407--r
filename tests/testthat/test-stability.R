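# exact slope-structured table: row i = 4 + slope_i * e_j, e = (-1, 0, 1)
slope_table_trial <- function(slopes = c(2, 0.5, 0.5), base = 4) {
  e <- c(-1, 0, 1)
  g <- sprintf("G%d", seq_along(slopes))
  tidyr::expand_grid(genotype = g, environment = c("E1", "E2", "E3"),
                     rep = 1L) |>
    dplyr::mutate(yield_mg_ha = base +
                    slopes[match(genotype, g)] * e[match(environment,
                                                         c("E1", "E2", "E3"))])
}

test_that("Finlay-Wilkinson recovers exact slopes and the mean-slope identity", {
  tr <- slope_table_trial()           # mean slope 1 keeps I_j = e_j
  fw <- finlay_wilkinson(tr)
  expect_equal(fw$bi[fw$genotype == "G1"], 2)
  expect_equal(fw$s2d, rep(0, 3), tolerance = 1e-12)
  # an average genotype (cell means = environment means) has bi = 1
  expect_equal(mean(fw$bi), 1, tolerance = 1e-12)
  for (s in 1:6) {
    fw <- finlay_wilkinson(make_trial(5, 4, 2, seed = 300 + s))
    expect_equal(mean(fw$bi), 1, tolerance = 1e-9)
  }
})

test_that("Finlay-Wilkinson agrees with per-genotype regression fits", {
  for (s in 1:6) {
    tr <- make_trial(5, 5, 2, seed = 310 + s)
    fw <- finlay_wilkinson(tr)
    bf <- bf_fw(bf_cell_means(tr))
    expect_equal(fw$bi, unname(bf[, "bi"]), tolerance = 1e-9)
    expect_equal(fw$s2d, unname(bf[, "s2d"]), tolerance = 1e-9)
  }
})

test_that("Finlay-Wilkinson needs an environmental gradient", {
  tr <- slope_table_trial(slopes = c(0, 0, 0))  # all environments equal
  expect_error(finlay_wilkinson(tr), class = "gxemaize_degenerate_series")
})

test_that("ecovalence matches brute force and sums to the GEI SS", {
  # additive table has zero ecovalence everywhere
  tr_add <- slope_table_trial(slopes = c(1, 1, 1))
  expect_equal(wricke_ecovalence(tr_add)$ecovalence, rep(0, 3),
               tolerance = 1e-12)
  # one +delta/-delta interaction cell pattern
  tr <- slope_table_trial(slopes = c(1, 1, 1))
  tr$yield_mg_ha[tr$genotype == "G1" & tr$environment == "E1"] <-
    tr$yield_mg_ha[tr$genotype == "G1" & tr$environment == "E1"] + 0.9
  tr$yield_mg_ha[tr$genotype == "G1" & tr$environment == "E3"] <-
    tr$yield_mg_ha[tr$genotype == "G1" & tr$environment == "E3"] - 0.9
  w <- wricke_ecovalence(tr)
  expect_equal(w$ecovalence, bf_ecovalence(bf_cell_means(tr)),
               tolerance = 1e-12)
  for (s in 1:6) {
    tr <- make_trial(4, 4, 2, seed = 320 + s)
    w <- wricke_ecovalence(tr)
    expect_equal(w$ecovalence, bf_ecovalence(bf_cell_means(tr)),
                 tolerance = 1e-9)
    expect_equal(sum(w$ecovalence), bf_gei_ss(bf_cell_means(tr)),
                 tolerance = 1e-9)
  }
})

test_that("Shukla variance is an order-preserving affine map of ecovalence", {
  w <- c(10, 2, 6, 6, 30)
  s2 <- shukla_sigma2(w, n_environments = 6)
  expect_equal(rank(s2), rank(w))
  # equal ecovalences give equal variances
  expect_equal(diff(shukla_sigma2(rep(4, 5), n_environments = 6)),
               rep(0, 4))
  # permutation equivariance
  perm <- c(3, 1, 5, 2, 4)
  expect_equal(shukla_sigma2(w[perm], n_environments = 6), s2[perm])
  expect_error(shukla_sigma2(c(1, 2), n_environments = 4), "p >= 3")
  # tibble-in, tibble-out
  tr <- make_trial(4, 4, 2, seed = 9)
  tb <- shukla_sigma2(wricke_ecovalence(tr), n_environments = 4)
  expect_true("sigma2" %in% names(tb))
})

test_that("AMMI conserves the interaction sum of squares", {
  # purely additive table: all singular values vanish
  am0 <- ammi(slope_table_trial(slopes = c(1, 1, 1)))
  expect_equal(am0$singular_values, rep(0, 2))
  # rank-1 interaction is fully captured by IPCA1
  u <- c(1, -0.5, -0.5, 0); v <- c(0.5, 0.5, -1)
  tr <- slope_table_trial(slopes = c(1, 1, 1, 1)[1:3])
  tr4 <- tidyr::expand_grid(genotype = sprintf("G%d", 1:4),
                            environment = sprintf("E%d", 1:3), rep = 1L) |>
    dplyr::mutate(yield_mg_ha = 4 +
                    0.8 * u[match(genotype, sprintf("G%d", 1:4))] *
                    v[match(environment, sprintf("E%d", 1:3))])
  am1 <- ammi(tr4)
  expect_equal(am1$pct_gei[1], 100, tolerance = 1e-9)
  for (s in 1:6) {
    tr <- make_trial(5, 4, 2, seed = 330 + s)
    am <- ammi(tr)
    expect_equal(sum(am$ss_axis), bf_gei_ss(bf_cell_means(tr)),
                 tolerance = 1e-9)
    # genotype scores orthogonal across axes
    gs <- am$genotype_scores
    cross <- crossprod(gs)
    expect_equal(cross[upper.tri(cross)], rep(0, sum(upper.tri(cross))),
                 tolerance = 1e-9)
  }
})

test_that("the AMMI stability value follows the Purchase formulation", {
  expect_equal(asv(3, 4, 10, 10), 5)
  expect_equal(asv(1, 1, 20, 10), sqrt(5))
  expect_equal(asv(0, 0, 10, 5), 0)
  expect_warning(out <- asv(c(2, -3), c(1, 1), 10, 0), "IPCA1")
  expect_equal(out, c(2, 3))
})

test_that("Kang YSi penalises unstable genotypes and flags stable ones", {
  # identical genotypes: equal scores, none strictly above the mean
  tr <- slope_table_trial(slopes = c(1, 1, 1))
  tr <- dplyr::bind_rows(tr, dplyr::mutate(tr, rep = 2L,
                                           yield_mg_ha = yield_mg_ha + 0.01))
  k <- kang_ysi(tr)
  expect_equal(length(unique(k$ysi)), 1)
  expect_false(any(k$stable))

  # one genotype with a huge interaction variance ends below the mean score
  set.seed(4)
  tr2 <- make_trial(6, 5, 2, seed = 44, sd = 0.05)
  bump <- tr2$genotype == "G03" & tr2$environment %in% c("E01", "E02")
  tr2$yield_mg_ha[bump] <- tr2$yield_mg_ha[bump] +
    rep(c(4, -4), length.out = sum(bump))
  k2 <- kang_ysi(tr2)
  expect_lt(k2$ysi[k2$genotype == "G03"], mean(k2$ysi))
})

test_that("stability report assembles consistent per-genotype ranks", {
  tr <- generate_trial(trial_spec(n_genotypes = 8, n_environments = 6,
                                  seed = 5L))
  rep <- stability_report(tr, "observed")
  g <- rep$genotypes
  expect_equal(nrow(g), 8)
  for (col in grep("^rank_", names(g), value = TRUE)) {
    expect_equal(sum(g[[col]]), sum(1:8))  # mid-ranked ties preserve the sum
  }
  for (col in c("rank_sigma2", "rank_asv", "rank_ecovalence", "rank_yield")) {
    expect_equal(sort(g[[col]]), as.numeric(1:8))  # continuous: no ties
  }
  # ecovalence and Shukla ranks coincide (affine order preservation)
  expect_equal(g$rank_ecovalence, g$rank_sigma2)
  td <- tidy(rep)
  expect_equal(nrow(td), 8 * 7)
  gl <- glance(rep)
  expect_equal(gl$n_genotypes, 8)
  expect_equal(gl$most_stable, g$genotype[which.min(g$sigma2)])
})
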