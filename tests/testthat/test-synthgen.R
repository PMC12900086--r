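test_that("scene rendering realizes the exact pixel count", {
  sc0 <- render_canopy(scene_spec(10, 10, 0, seed = 1))
  expect_identical(sum(sc0$mask), 0L)
  expect_identical(cover_ratio(segment_canopy(sc0$image))$cover_percent, 0)

  sc5 <- render_canopy(scene_spec(10, 10, 0.5, seed = 1))
  expect_identical(sum(sc5$mask), 50L)
  expect_identical(cover_ratio(segment_canopy(sc5$image))$cover_percent, 50)

  sc37 <- render_canopy(scene_spec(100, 100, 0.37, seed = 1))
  expect_identical(cover_ratio(segment_canopy(sc37$image))$cover_percent, 37)
  expect_equal(sc37$true_fraction, 0.37)
})

test_that("segmentation recovers the construction mask exactly", {
  set.seed(77)
  for (i in 1:10) {
    f <- runif(1)
    sc <- render_canopy(scene_spec(sample(15:60, 1), sample(15:60, 1), f,
                                   seed = sample.int(1e6, 1)))
    got <- segment_canopy(sc$image)
    expect_identical(unclass(got)[, ], sc$mask)
    expect_identical(sum(sc$mask), as.integer(round(f * length(sc$mask))))
  }
})

test_that("rendering is deterministic for a fixed spec and seed", {
  spec <- scene_spec(30, 30, 0.4, seed = 99)
  a <- render_canopy(spec)
  b <- render_canopy(spec)
  expect_identical(unclass(a$image), unclass(b$image))
  expect_identical(a$mask, b$mask)
  c <- render_canopy(scene_spec(30, 30, 0.4, seed = 100))
  expect_false(identical(unclass(a$image), unclass(c$image)))
})

test_that("render_canopy leaves the caller's RNG state alone", {
  set.seed(123)
  before <- .Random.seed
  render_canopy(scene_spec(10, 10, 0.5, seed = 7))
  expect_identical(.Random.seed, before)
})

test_that("palette bounds are enforced at construction", {
  expect_error(
    scene_spec(10, 10, 0.5, vegetation_palette = list(c(100L, 110L, 0L))),
    "vegetation colour")  # index ~134.1 < 140: too close to the boundary
  expect_error(
    scene_spec(10, 10, 0.5, background_palette = list(c(100L, 120L, 0L))),
    "background colour")  # index ~139.6 > 128
  expect_error(scene_spec(10, 10, 1.5), "0, 1")
  expect_error(scene_spec(0, 10, 0.5), "positive whole")
})

test_that("calibration simulation is exact when noiseless and seeded when not", {
  m <- default_model()
  df0 <- simulate_calibration(calibration_spec(m, 10, 70, 5, 0))
  fit <- fit_model(df0$cover_percent, df0$tillers_per_m2)
  expect_equal(fit$a, m$a, tolerance = 1e-8)
  expect_equal(fit$b, m$b, tolerance = 1e-8)
  expect_equal(fit$c, m$c, tolerance = 1e-8)
  d1 <- simulate_calibration(calibration_spec(m, 10, 70, 50, 5, seed = 7))
  d2 <- simulate_calibration(calibration_spec(m, 10, 70, 50, 5, seed = 7))
  expect_identical(d1, d2)
  expect_false(identical(
    d1, simulate_calibration(calibration_spec(m, 10, 70, 50, 5, seed = 8))))
  expect_error(calibration_spec(m, 10, 70, 2, 0), "at least 3")
  expect_error(calibration_spec(m, 70, 10, 5, 0), "cover_min < cover_max")
})

test_that("noisy calibration recovers the generating coefficients", {
  m <- default_model()
  reps <- 60
  est <- matrix(NA_real_, reps, 3)
  for (i in seq_len(reps)) {
    df <- simulate_calibration(calibration_spec(m, 5, 80, 200, 5, seed = 1000 + i))
    f <- fit_model(df$cover_percent, df$tillers_per_m2)
    est[i, ] <- c(f$a, f$b, f$c)
  }
  truth <- c(m$a, m$b, m$c)
  for (j in 1:3) {
    se_mean <- sd(est[, j]) / sqrt(reps)
    expect_lt(abs(mean(est[, j]) - truth[j]), 3 * se_mean + 1e-12)
  }
})

test_that("growth series is an arithmetic progression with predictable crossing", {
  g <- simulate_growth(growth_spec(300, 20, 6))
  expect_identical(g$tillers_per_m2, c(300, 320, 340, 360, 380, 400))
  expect_identical(crossing_day(g, 360), 3L)
  expect_identical(crossing_day(g, 401), NA_integer_)
  # a constant estimator bias delays the crossing by bias/rate days
  rate <- 12.0; bias <- 34.6
  long <- simulate_growth(growth_spec(200, rate, 40))
  biased <- long
  biased$tillers_per_m2 <- long$tillers_per_m2 - bias
  target <- 320
  true_day <- (target - 200) / rate
  biased_day <- (target + bias - 200) / rate
  expect_equal(biased_day - true_day, error_in_days(bias, rate))
  expect_identical(crossing_day(long, target), as.integer(ceiling(true_day)))
  expect_identical(crossing_day(biased, target), as.integer(ceiling(biased_day)))
  expect_error(growth_spec(300, 0, 5), "positive")
  expect_error(growth_spec(300, 12, 0), "whole number")
})
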