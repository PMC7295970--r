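test_that("a bubble at the Laplace equilibrium pressure holds its radius", {
  for (med in list(medium_water(), medium_gel())) {
    r0 <- 95.16e-10
    peq <- equilibrium_cavitation_pressure(med, r0)$pressure
    # ten times the inertial collapse scale of the same tension magnitude
    t_scale <- rayleigh_collapse_time(med$density, r0, abs(peq))
    sol <- solve_rp(med, r0, pressure_schedule(peq), horizon = 10 * t_scale)
    expect_identical(attr(sol, "termination"), "horizon_reached")
    expect_lt(max(abs(sol$radius - r0)) / r0, 1e-3)
  }
})

test_that("inviscid zero-tension collapse reproduces the Rayleigh closed form", {
  cases <- expand.grid(
    rho = c(700, 1020, 1500),
    r0 = c(95.16e-10, 1e-6),
    dp = c(2e7, 1e5)
  )[c(1, 4, 6, 8, 11, 12), ]
  for (i in seq_len(nrow(cases))) {
    rho <- cases$rho[i]; r0 <- cases$r0[i]; dp <- cases$dp[i]
    med <- fluid_medium("ideal", rho, 0, 0)
    t_exact <- rayleigh_collapse_time(rho, r0, dp)
    sol <- solve_rp(med, r0, pressure_schedule(dp), horizon = 3 * t_exact)
    expect_identical(attr(sol, "termination"), "collapsed")
    expect_equal(attr(sol, "collapse_time"), t_exact, tolerance = 5e-3)
  }
})

test_that("collapse time is non-decreasing in viscosity and longer in gel", {
  r0 <- 95.16e-10
  dp <- 5e7
  etas <- 0.321e-3 * c(0.5, 1, 2, 4)
  times <- vapply(etas, function(eta) {
    med <- fluid_medium("v", 1020, eta, 0.0557)
    sol <- solve_rp(med, r0, pressure_schedule(dp), horizon = 1e-9)
    attr(sol, "collapse_time")
  }, numeric(1))
  expect_true(all(is.finite(times)))
  expect_true(all(diff(times) > 0))

  # the presets: same driving pressure, gel outlives water
  tw <- attr(solve_rp(medium_water(), 95.16e-10, pressure_schedule(dp),
                      horizon = 1e-9), "collapse_time")
  tg <- attr(solve_rp(medium_gel(), 95.35e-10, pressure_schedule(dp),
                      horizon = 1e-9), "collapse_time")
  expect_gt(tg, tw)
})

test_that("pressure schedules validate and sampled schedules match constants", {
  expect_error(pressure_schedule(times = c(0, 0), values = c(1, 2)),
               "strictly increasing")
  expect_error(pressure_schedule(times = 1, values = 1), "length >= 2")
  med <- fluid_medium("ideal", 1000, 0, 0)
  # sampled schedule not covering the horizon is rejected
  sch_short <- pressure_schedule(times = c(0, 1e-8), values = c(1e5, 1e5))
  expect_error(solve_rp(med, 1e-6, sch_short, horizon = 1e-7), "cover")
  # a flat sampled schedule reproduces the constant-pressure solution
  sch <- pressure_schedule(times = c(0, 3e-7), values = c(1e5, 1e5))
  s1 <- solve_rp(med, 1e-6, sch, horizon = 2.5e-7)
  s2 <- solve_rp(med, 1e-6, pressure_schedule(1e5), horizon = 2.5e-7)
  expect_equal(attr(s1, "collapse_time"), attr(s2, "collapse_time"),
               tolerance = 1e-9)
})

test_that("rp_solution exposes tidy/glance and sane invariants", {
  sol <- solve_rp(medium_water(), 95.16e-10, pressure_schedule(5e7),
                  horizon = 1e-9)
  td <- tidy(sol)
  expect_true(all(diff(td$time) > 0))
  expect_true(all(td$radius > 0))
  g <- glance(sol)
  expect_identical(g$termination, "collapsed")
  expect_true(is.finite(g$collapse_time))
  # collapse_time present iff collapsed
  s2 <- solve_rp(medium_water(), 95.16e-10, pressure_schedule(-1e6),
                 horizon = 1e-12)
  expect_identical(attr(s2, "termination"), "horizon_reached")
  expect_true(is.na(attr(s2, "collapse_time")))
  expect_error(solve_rp(medium_water(), 95.16e-10, pressure_schedule(1e5),
                        horizon = -1), "positive")
})
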