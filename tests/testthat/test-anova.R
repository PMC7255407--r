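test_that("ANOVA matches the brute-force decomposition on random trials", {
  for (s in 1:8) {
    p <- sample(3:6, 1); q <- sample(3:5, 1); r <- sample(2:3, 1)
    tr <- make_trial(p, q, r, seed = 200 + s)
    an <- two_way_anova(tr)
    bf <- bf_anova_ss(tr)
    for (src in c("Genotype", "Environment", "GEI", "Rep", "Error")) {
      key <- c(Genotype = "G", Environment = "E", GEI = "GEI",
               Rep = "Rep", Error = "Error")[[src]]
      expect_equal(an$ss[an$source == src], bf[[key]], tolerance = 1e-9)
    }
    expect_equal(an$df[an$source == "Genotype"], p - 1)
    expect_equal(an$df[an$source == "GEI"], (p - 1) * (q - 1))
    expect_equal(an$df[an$source == "Error"], (p * q - 1) * (r - 1))
    expect_equal(sum(an$pct_ss[an$source != "Total"]), 100, tolerance = 1e-9)
  }
})

test_that("degenerate and unbalanced trials are rejected", {
  tr <- make_trial(3, 3, 2, seed = 1)
  tr$yield_mg_ha <- 5
  expect_error(two_way_anova(tr), class = "gxemaize_zero_variance")
  expect_error(two_way_anova(make_trial(3, 3, 2)[-1, ]),
               class = "gxemaize_unbalanced")
  tr2 <- make_trial(3, 3, 2)
  tr2$yield_mg_ha[1] <- NA
  expect_error(two_way_anova(tr2), class = "gxemaize_missing_cells")
})

test_that("share table from given sums of squares", {
  an <- anova_from_ss(ss = c(G = 30, E = 60, Error = 10),
                      df = c(G = 3, E = 2, Error = 12))
  expect_equal(an$pct_ss[an$source == "E"], 60)
  expect_equal(an$ms[an$source == "G"], 10)
  expect_equal(an$ss[an$source == "Total"], 100)
  expect_error(anova_from_ss(c(G = 1), c(G = 2)), "Error")
})

test_that("environment index centres environment means", {
  tr <- tibble::tibble(
    genotype = rep(c("A", "B"), each = 4),
    environment = rep(c("E1", "E2"), times = 4),
    rep = rep(c(1, 1, 2, 2), 2),
    yield_mg_ha = c(3, 5, 3, 5, 3, 5, 3, 5)
  )
  ix <- environment_index(tr)
  expect_equal(sort(ix$index), c(-1, 1))
  for (s in 1:5) {
    ix <- environment_index(make_trial(4, 5, 2, seed = s))
    expect_equal(sum(ix$index), 0, tolerance = 1e-12)
  }
})
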