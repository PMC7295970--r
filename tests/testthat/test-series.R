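test_that("threshold extraction finds a constructed parabolic minimum", {
  tt <- seq(0, 12.4, 0.1)
  tr <- scalar_series(tt, -93 + 2 * (tt - 6.2)^2, "MPa")
  th <- threshold_pressure(tr, window = 1)
  # the moving average lifts a parabolic minimum by curvature * window^2 / 12
  expect_equal(th$min_pressure, -93, tolerance = 5e-3)
  expect_equal(th$time_at_min, 6.2, tolerance = 0.05)
  expect_false(th$boundary)
})

test_that("the smoothed minimum survives 5% noise to within 2%", {
  tt <- seq(0, 12.4, 0.02)
  clean <- -93 + 2 * (tt - 6.2)^2
  for (s in 1:5) {
    set.seed(s)
    noisy <- scalar_series(tt, clean + rnorm(length(tt), sd = 0.05 * 93), "MPa")
    th <- threshold_pressure(noisy, window = 1)
    expect_equal(th$min_pressure, -93, tolerance = 0.02)
    expect_equal(th$time_at_min, 6.2, tolerance = 1)
  }
})

test_that("a monotone trace yields a flagged boundary minimum", {
  tr <- scalar_series(0:20, -(0:20), "MPa")
  th <- threshold_pressure(tr, window = 2)
  expect_true(th$boundary)
  expect_equal(th$time_at_min, 20)
  expect_error(threshold_pressure(tr, window = 50), "longer")
  expect_error(threshold_pressure(scalar_series(0:1, 0:1, ""), window = 1),
               "3 samples")
})

test_that("ties in the smoothed minimum resolve to the earliest time", {
  # symmetric double well: two equal minima, earliest must win
  tt <- seq(0, 10, 0.5)
  vals <- pmin((tt - 3)^2, (tt - 7)^2)
  th <- threshold_pressure(scalar_series(tt, vals, "MPa"), window = 0.5)
  expect_equal(th$time_at_min, 3)
})

test_that("X for 60 ps and 2X for 30 ps reach the same volume strain", {
  sx <- volume_strain_schedule(6.7e9, 60)
  s2x <- volume_strain_schedule(1.35e10, 30)
  fx <- attr(sx, "final_strain")
  f2x <- attr(s2x, "final_strain")
  expect_equal(fx, f2x, tolerance = 0.01)
  expect_equal(fx, 6.7e9 * 60e-12, tolerance = 1e-12)
  # linear in time
  expect_equal(sx$value, 6.7e9 * sx$time * 1e-12)

  expect_equal(attr(volume_strain_schedule(6.7e9, 0), "final_strain"), 0)
  # doubling the rate exactly halves the time to any fixed strain
  sdbl <- volume_strain_schedule(2 * 6.7e9, 60)
  t_half <- approx(sdbl$value, sdbl$time, xout = 0.2)$y
  t_full <- approx(sx$value, sx$time, xout = 0.2)$y
  expect_equal(t_half, t_full / 2, tolerance = 1e-6)
  expect_error(volume_strain_schedule(-1, 10), "positive")
})

test_that("volume decomposition conserves and errors on negative residuals", {
  d0 <- volume_decomposition(7e6, 7e6, 0)
  expect_equal(d0$v_bubble, 0)
  expect_equal(d0$bubble_radius, 0)
  # growing the system at fixed water/network volume goes entirely to the bubble
  dv <- 5.2e5
  d1 <- volume_decomposition(7e6 + dv, 6.5e6, 5e5)
  expect_equal(d1$v_bubble, dv)
  expect_equal(d1$bubble_radius, (3 * dv / (4 * pi))^(1 / 3))
  expect_error(volume_decomposition(7e6, 7.5e6, 0), "accounting")
  expect_error(volume_decomposition(-1, 0, 0), "non-negative")
})

test_that("scalar series validate their time axis", {
  expect_error(scalar_series(c(0, 0, 1), 1:3), "strictly increasing")
  expect_error(scalar_series(1:3, 1:2), "equal length")
  s <- scalar_series(1:3, 4:6, "MPa")
  expect_identical(series_unit(s), "MPa")
})
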