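test_that("trial spec validates its inputs", {
  expect_error(trial_spec(var_fractions = c(E = 0.5, G = 0.3, GEI = 0.1,
                                            rep = 0, error = 0.2) * 1.1),
               "sum to 1")
  expect_error(trial_spec(n_genotypes = 1), ">= 2")
  expect_error(trial_spec(var_fractions = c(E = 1.2, G = -0.2, GEI = 0,
                                            rep = 0, error = 0)), ">= 0")
})

test_that("pure-environment fractions make genotypes identical within environments", {
  spec <- trial_spec(n_genotypes = 5, n_environments = 4,
                     var_fractions = c(E = 1, G = 0, GEI = 0, rep = 0,
                                       error = 0))
  tr <- generate_trial(spec)
  spread <- tapply(tr$yield_mg_ha, tr$environment, function(x) diff(range(x)))
  expect_true(all(spread < 1e-12))
})

test_that("trial generation is seed-reproducible and hits the grand mean", {
  spec <- trial_spec(seed = 99L)
  expect_identical(generate_trial(spec), generate_trial(spec))
  for (s in 1:5) {
    tr <- generate_trial(trial_spec(grand_mean = 3.8), seed = s)
    se <- sd(tr$yield_mg_ha) / sqrt(nrow(tr))
    expect_lt(abs(mean(tr$yield_mg_ha) - 3.8), 3 * se + 1e-9)
  }
})

test_that("requested variance fractions are recovered in expectation", {
  targets <- c(E = 0.67, G = 0.19, GEI = 0.13, rep = 0, error = 0.01)
  shares <- sapply(1:40, function(s) {
    tr <- generate_trial(trial_spec(var_fractions = targets), seed = 1000 + s)
    an <- two_way_anova(tr)
    c(E = an$pct_ss[an$source == "Environment"],
      G = an$pct_ss[an$source == "Genotype"],
      GEI = an$pct_ss[an$source == "GEI"])
  })
  mean_shares <- rowMeans(shares)
  expect_lt(abs(mean_shares[["E"]] - 67), 3)
  expect_lt(abs(mean_shares[["G"]] - 19), 3)
  expect_lt(abs(mean_shares[["GEI"]] - 13), 3)
})

test_that("slope-structured interaction injects recoverable FW slopes", {
  beta <- c(0.5, 1.0, 1.5, 0.8, 1.2, 1.0)
  spec <- trial_spec(n_genotypes = 6, n_environments = 8,
                     gei_structure = "slope", beta = beta,
                     var_fractions = c(E = 0.79, G = 0.1, GEI = 0.1,
                                       rep = 0, error = 0.01))
  got <- rowMeans(sapply(1:10, function(s) {
    fw <- finlay_wilkinson(generate_trial(spec, seed = 70 + s))
    fw$bi[match(sprintf("G%02d", 1:6), fw$genotype)]
  }))
  expect_lt(max(abs(got - beta)), 0.05)
  # a single noiseless draw recovers the slopes exactly
  noiseless <- trial_spec(n_genotypes = 6, n_environments = 8,
                          gei_structure = "slope", beta = beta,
                          var_fractions = c(E = 0.8, G = 0.2, GEI = 0,
                                            rep = 0, error = 0))
  fw0 <- finlay_wilkinson(generate_trial(noiseless, seed = 4))
  expect_equal(fw0$bi[match(sprintf("G%02d", 1:6), fw0$genotype)], beta,
               tolerance = 1e-9)
})

test_that("trial CSV round-trips", {
  tr <- generate_trial(trial_spec(n_genotypes = 3, n_environments = 3))
  f <- withr::local_tempfile(fileext = ".csv")
  write_trial_csv(tr, f)
  expect_equal(as.data.frame(read_trial_csv(f)), as.data.frame(tr),
               tolerance = 1e-12)
})
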