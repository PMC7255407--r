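test_that("generated weather respects physical invariants", {
  wx <- generate_weather(savanna_archetype("dry"), n_years = 5, seed = 11)
  expect_equal(nrow(wx), 5 * 365)
  expect_true(all(wx$tmax > wx$tmin))
  expect_true(all(wx$rain >= 0))
  expect_true(all(wx$srad >= 0))
  expect_equal(unname(table(wx$year)), rep(365L, 5), ignore_attr = TRUE)
  # deterministic under a fixed seed
  wx2 <- generate_weather(savanna_archetype("dry"), n_years = 5, seed = 11)
  expect_identical(wx, wx2)
})

test_that("dry-archetype annual rainfall is near its 825 mm target", {
  wx <- generate_weather(savanna_archetype("dry"), n_years = 26, seed = 7)
  ann <- tapply(wx$rain, wx$year, sum)
  se <- sd(ann) / sqrt(length(ann))
  expect_lt(abs(mean(ann) - 825), 3 * se + 25)
  # long-run expectation within 10 % of target
  wxl <- generate_weather(savanna_archetype("dry"), n_years = 150, seed = 3)
  expect_lt(abs(mean(tapply(wxl$rain, wxl$year, sum)) - 825) / 825, 0.1)
})

test_that("rainfall seasality separates the two savannas", {
  wxd <- generate_weather(savanna_archetype("dry"), n_years = 60, seed = 5)
  wxw <- generate_weather(savanna_archetype("wet"), n_years = 60, seed = 5)
  ja <- function(wx) {
    sum(wx$rain[wx$doy >= 182 & wx$doy <= 243]) / sum(wx$rain)
  }
  # more than half of dry-savanna rain falls in July-August ...
  expect_gte(ja(wxd), 0.5)
  # ... and the wet savanna is less concentrated there
  expect_lt(ja(wxw), ja(wxd))
  # wet savanna is wetter overall
  expect_gt(sum(wxw$rain), sum(wxd$rain))
})

test_that("zero rain intensity produces an entirely dry series", {
  wx <- generate_weather(savanna_archetype("dry", wet_prob_peak = 0),
                         n_years = 2, seed = 1)
  expect_true(all(wx$rain == 0))
})

test_that("weather generator rejects invalid inputs", {
  expect_error(generate_weather(savanna_archetype("dry"), 0), "n_years")
  expect_error(generate_weather(list(), 2), "archetype")
  expect_error(savanna_archetype("coastal"))
  expect_error(savanna_archetype("dry", annual_rain_mm = -5), "positive")
})

test_that("weather CSV and WTH readers round-trip the series", {
  wx <- generate_weather(savanna_archetype("wet"), n_years = 1, seed = 2)
  f <- withr::local_tempfile(fileext = ".csv")
  write_weather_csv(wx, f)
  back <- read_weather_csv(f, latitude = wx$latitude[1])
  expect_equal(back$rain, round(wx$rain, 2))
  expect_equal(back$tmax, round(wx$tmax, 2))
  expect_equal(back$date, wx$date)

  # minimal DSSAT-like fixed-width table
  wth <- withr::local_tempfile(fileext = ".WTH")
  writeLines(c(
    "@DATE  SRAD  TMAX  TMIN  RAIN",
    "01152  21.0  33.2  21.5   0.0",
    "01153  18.5  31.0  20.9  12.4"
  ), wth)
  w <- read_wth(wth, latitude = 12)
  expect_equal(w$doy, c(152L, 153L))
  expect_equal(w$year, c(2001L, 2001L))
  expect_equal(w$rain, c(0, 12.4))
})
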