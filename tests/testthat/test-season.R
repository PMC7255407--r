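# constant benign weather: warm, bright, dry (irrigation supplies water)
benign_wx <- function(days = 365, srad = 20, tmax = 30, tmin = 22) {
  tibble::tibble(date = as.Date("2001-01-01") + 0:(days - 1), year = 2001L,
                 doy = 1:days, srad = srad, tmax = tmax, tmin = tmin,
                 rain = 0, latitude = 11.5)
}
irrigated <- function(sow = 60) management(sowing_date = sow,
                                           irrigation = "auto")

test_that("a season with no radiation produces no biomass and no grain", {
  cv <- maize_cultivars()[1, ]
  out <- simulate_season(cv, benign_wx(srad = 0), generate_soil("loamy"),
                         irrigated())
  expect_equal(out$biomass_anthesis, 0)
  expect_equal(out$biomass_maturity, 0)
  expect_equal(out$grain_yield, 0)
})

test_that("simulated seasons respect energy and water budgets", {
  eco <- ecotype_params()
  for (k in c(1, 8, 16)) {
    out <- simulate_season(maize_cultivars()[k, ], benign_wx(),
                           generate_soil("loamy"), irrigated(),
                           ecotype = eco)
    # biomass can never exceed RUE x intercepted PAR
    expect_lte(out$biomass_maturity * 100,
               eco$rue * out$par_intercepted + 1e-9)
    expect_lt(abs(out$water_balance_error), 0.1)
    expect_lte(out$grain_yield, out$biomass_maturity)
    expect_gt(out$dtm, out$dta)
    expect_gt(out$dta, 0)
  }
})

test_that("identical inputs give identical season results", {
  cv <- maize_cultivars()[5, ]
  a <- simulate_season(cv, benign_wx(), generate_soil("sandy"), irrigated())
  b <- simulate_season(cv, benign_wx(), generate_soil("sandy"), irrigated())
  expect_identical(a, b)
})

test_that("phenology responds monotonically to its coefficients", {
  base <- as.list(maize_cultivars()[3, ])
  run <- function(cv) simulate_season(cv, benign_wx(), generate_soil("loamy"),
                                      irrigated())
  ref <- run(base)
  p5x <- base; p5x$P5 <- base$P5 * 2
  out <- run(p5x)
  expect_gt(out$dtm, ref$dtm)                    # longer grain fill
  expect_equal(out$dta, ref$dta)                 # anthesis untouched
  p1x <- base; p1x$P1 <- base$P1 + 30
  expect_gt(run(p1x)$dta, ref$dta)
  phx <- base; phx$PHINT <- base$PHINT + 5
  expect_gt(run(phx)$dta, ref$dta)
})

test_that("grain yield is non-decreasing in G2 and G3", {
  base <- as.list(maize_cultivars()[6, ])
  run <- function(cv) simulate_season(cv, benign_wx(), generate_soil("loamy"),
                                      irrigated())$grain_yield
  ref <- run(base)
  g2x <- base; g2x$G2 <- base$G2 * 1.2
  expect_gte(run(g2x), ref)
  g3x <- base; g3x$G3 <- base$G3 * 1.2
  expect_gte(run(g3x), ref)
})

test_that("photoperiod-insensitive cultivars ignore day length", {
  cv <- as.list(maize_cultivars()[2, ]); cv$P2 <- 0
  wx_n <- benign_wx(); wx_n$latitude <- 14
  wx_s <- benign_wx(); wx_s$latitude <- 4
  a <- simulate_season(cv, wx_n, generate_soil("loamy"), irrigated(150))
  b <- simulate_season(cv, wx_s, generate_soil("loamy"), irrigated(150))
  expect_equal(a$dta, b$dta)
  # a sensitive cultivar sown into long days is delayed relative to P2 = 0
  cv2 <- cv; cv2$P2 <- 2
  d <- simulate_season(cv2, wx_n, generate_soil("loamy"), irrigated(150))
  expect_gte(d$dta, a$dta)
})

test_that("anthesis ordering follows the maturity groups", {
  cv <- maize_cultivars()
  res <- purrr::map_dfr(seq_len(nrow(cv)), function(k)
    simulate_season(cv[k, ], benign_wx(tmax = 33, tmin = 22),
                    generate_soil("loamy"), irrigated()))
  dta <- tapply(res$dta, cv$maturity_group, mean)
  expect_lt(dta[["extra-early"]], dta[["early"]])
  expect_lt(dta[["early"]], dta[["intermediate"]])
  expect_lt(dta[["intermediate"]], dta[["late"]])
})

test_that("a weather series ending too early raises an incomplete-season error", {
  expect_error(
    simulate_season(maize_cultivars()[16, ], benign_wx(days = 90),
                    generate_soil("loamy"), irrigated()),
    class = "gxemaize_incomplete_season"
  )
})
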