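two_identical_years <- function() {
  one <- generate_weather(savanna_archetype("wet"), n_years = 1, seed = 8)
  two <- dplyr::mutate(one, year = year + 1L, date = date + 365)
  dplyr::bind_rows(one, two)
}

test_that("identical weather years give zero interannual spread", {
  wx <- two_identical_years()
  sa <- seasonal_analysis(maize_cultivars()[c(1, 9), ], wx,
                          generate_soil("loamy"),
                          management(sowing_window = c(121, 212)))
  expect_equal(sa$summary$sd, rep(0, 2))
  expect_equal(sa$summary$max, sa$summary$min)
  expect_equal(sa$summary$max, sa$summary$mean)
  expect_equal(sa$summary$n_years, rep(2L, 2))
  # CDF covers both years per cultivar and ends at probability 1
  expect_equal(max(sa$cdf$prob), 1)
  expect_equal(nrow(sa$cdf), 4)
})

test_that("years without a planting opportunity are skipped with a warning", {
  wx <- two_identical_years()
  wx$rain[wx$year == max(wx$year)] <- 0   # second year never wets up
  expect_warning(
    sa <- seasonal_analysis(maize_cultivars()[1, ], wx,
                            generate_soil("loamy"),
                            management(sowing_window = c(121, 212))),
    "No planting"
  )
  expect_equal(unique(sa$results$year), min(wx$year))
  # an all-dry record fails outright
  dry <- dplyr::mutate(two_identical_years(), rain = 0)
  expect_error(
    suppressWarnings(seasonal_analysis(maize_cultivars()[1, ], dry,
                                       generate_soil("loamy"),
                                       management(sowing_window = c(121, 212)))),
    class = "gxemaize_no_planting"
  )
})

test_that("wet-over-dry yield advantage grows with maturity group", {
  cv <- maize_cultivars()[c(1, 2, 13, 14), ]   # 2 extra-early + 2 late
  gaps <- sapply(c("dry", "wet"), function(a) {
    arch <- savanna_archetype(a)
    wx <- generate_weather(arch, n_years = 8, seed = 31)
    sa <- seasonal_analysis(cv, wx, generate_soil("loamy"),
                            management(sowing_window =
                                         c(arch$season_start_doy,
                                           arch$season_start_doy + 91)))
    sa$summary$mean[match(cv$name, sa$summary$cultivar)]
  })
  gap <- gaps[, "wet"] - gaps[, "dry"]
  expect_gt(mean(gap[3:4]), mean(gap[1:2]))   # late gains more from wet
})
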