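test_that("equilibrium cavitation pressure follows the Laplace balance", {
  # zero surface tension: no tension needed
  m0 <- fluid_medium("ideal", 1000, 0, 0)
  expect_equal(equilibrium_cavitation_pressure(m0, 1e-8)$pressure, 0)

  # hand arithmetic -2 sigma / R for the water and gel presets
  pw <- equilibrium_cavitation_pressure(medium_water(), 95.16e-10)$pressure
  expect_equal(pw, -2 * 0.0557 / 95.16e-10, tolerance = 1e-12)
  expect_equal(pw / 1e6, -11.707, tolerance = 1e-4)
  pg <- equilibrium_cavitation_pressure(medium_gel(), 95.35e-10)$pressure
  expect_equal(pg / 1e6, -20.472, tolerance = 1e-4)
  # the gel requires a larger-magnitude negative pressure
  expect_lt(pg, pw)

  expect_error(equilibrium_cavitation_pressure(medium_water(), 0), "positive")
  expect_error(equilibrium_cavitation_pressure(medium_water(), -1), "positive")
})

test_that("network pressure is the gel-minus-liquid decomposition", {
  expect_equal(network_pressure(-101, -93), -8)
  expect_equal(network_pressure(-42.5, -42.5), 0)
  expect_equal(network_pressure(-20.472, -11.707), -8.765, tolerance = 1e-12)
})

test_that("Rayleigh collapse time has the classical closed form and scalings", {
  expect_equal(rayleigh_collapse_time(1000, 1e-6, 1e5), 9.14681e-8,
               tolerance = 1e-6)
  t1 <- rayleigh_collapse_time(1000, 1e-6, 1e5)
  expect_equal(rayleigh_collapse_time(1000, 1e-6, 4e5), t1 / 2)
  expect_equal(rayleigh_collapse_time(1000, 2e-6, 1e5), t1 * 2)
  expect_equal(rayleigh_collapse_time(4000, 1e-6, 1e5), t1 * 2)
  expect_error(rayleigh_collapse_time(0, 1e-6, 1e5), "positive")
  expect_error(rayleigh_collapse_time(1000, 1e-6, -1), "positive")
})

test_that("nucleation-time threshold ratio matches direct log evaluation", {
  expect_equal(fisher_threshold_ratio(1e-9, 1e-9), 1)

  # independent oracle: direct evaluation of the two logarithms
  kB <- 1.380649e-23
  h <- 6.62607015e-34
  a <- 6.022e23 * kB * 300 / h
  oracle <- sqrt(log(a * 1e18) / log(a * 1e-15))
  r <- fisher_threshold_ratio(1e-15, 1e18)
  expect_equal(r, oracle, tolerance = 1e-12)
  # over 33 decades of waiting time the threshold changes only ~1.58-fold
  expect_equal(r, 1.58, tolerance = 0.01)

  # monotone in the longer waiting time
  rs <- vapply(10^(0:18), function(t2) fisher_threshold_ratio(1e-15, t2),
               numeric(1))
  expect_true(all(diff(rs) > 0))

  expect_error(fisher_threshold_ratio(1e-40, 1), "positive for both")
  expect_error(fisher_threshold_ratio(1e-15, 1e-16), ">=")
})

test_that("threshold ratio depends on N, T only through the product N*kB*T/h", {
  base <- fisher_threshold_ratio(1e-12, 1e-3)
  resc <- fisher_threshold_ratio(1e-12, 1e-3,
                                 n_molecules = 6.022e23 * 7,
                                 temperature = 300 / 7)
  expect_equal(base, resc, tolerance = 1e-12)
  # and on the waiting times through their values, not the pair scaling
  expect_false(isTRUE(all.equal(
    fisher_threshold_ratio(1e-12, 1e-3),
    fisher_threshold_ratio(1e-11, 1e-2)
  )))
})

test_that("pulsation constants follow the viscous-damping model", {
  # undamped limit
  m0 <- fluid_medium("inviscid", 1000, 0, 0.05)
  om0 <- oscillation_parameters(m0, 1e-8)
  expect_equal(om0$damping_b, 0)
  expect_equal(om0$relaxation_rate, 0)

  # hand arithmetic for the water preset at the relaxed bubble radius
  om <- oscillation_parameters(medium_water(), 95.16e-10)
  r <- 95.16e-10
  expect_equal(om$damping_b, 0.321e-3 / (pi * r^3), tolerance = 1e-12)
  expect_equal(om$inertia_m, 1020 / (4 * pi * r), tolerance = 1e-12)
  expect_equal(om$relaxation_rate, 4 * 0.321e-3 / (1020 * r^2),
               tolerance = 1e-12)
  expect_equal(om$relaxation_rate, 1.39e10, tolerance = 1e-3)

  # the gel damps roughly twice as fast, tracking the viscosity ratio
  omg <- oscillation_parameters(medium_gel(), 95.35e-10)
  ratio <- omg$relaxation_rate / om$relaxation_rate
  oracle <- (0.684e-3 / 0.321e-3) * (1020 / 1050) * (95.16 / 95.35)^2
  expect_equal(ratio, oracle, tolerance = 1e-12)
  expect_gt(ratio, 2)

  expect_error(oscillation_parameters(medium_water(), 1e-8, stiffness_k = -1),
               "non-negative")
})

test_that("with stiffness the natural frequency and damping ratios are reported", {
  med <- medium_water()
  r <- 95.16e-10
  m <- 1020 / (4 * pi * r)
  b <- 0.321e-3 / (pi * r^3)
  # pick k so the reported damping parameter b / sqrt(k/m) is 1 (underdamped)
  k <- b^2 * m
  om <- oscillation_parameters(med, r, stiffness_k = k)
  delta <- b / sqrt(k / m)
  expect_equal(delta, 1, tolerance = 1e-12)
  expect_equal(om$damping_ratio_delta, delta, tolerance = 1e-12)
  expect_equal(om$damping_ratio_std, b / (2 * sqrt(k * m)), tolerance = 1e-12)
  expect_equal(om$natural_frequency,
               sqrt(k / m) * sqrt(1 - delta^2 / 4) / (2 * pi),
               tolerance = 1e-12)
  expect_false(is.na(om$natural_frequency))
  # overdamped: delta^2 >= 4 suppresses the frequency
  k_over <- b^2 * m / 100
  expect_true(is.na(oscillation_parameters(med, r, stiffness_k = k_over)$natural_frequency))
})

test_that("volume relaxation solves m V'' + b V' = 0 with the stated constants", {
  om <- oscillation_parameters(medium_water(), 95.16e-10)
  rate <- om$relaxation_rate
  v0 <- 3.6e-24
  vdot0 <- -1e-14

  # constant solution when the initial rate vanishes
  still <- damped_volume_relaxation(om, v0, 0, seq(0, 1e-9, length.out = 7))
  expect_equal(still$volume, rep(v0, 7))

  # decaying component halves after (m/b) log 2
  tt <- c(0, log(2) / rate)
  vv <- damped_volume_relaxation(om, v0, vdot0, tt)$volume
  c2 <- v0 + vdot0 / rate
  expect_equal(vv[2] - c2, (vv[1] - c2) / 2, tolerance = 1e-12)

  # characteristic-recurrence residual: any solution of m V'' + b V' = 0
  # sampled uniformly satisfies V(t+s) - V(t) = e^(-b s / m) (V(t) - V(t-s));
  # check it to 1e-9 of the leading increment
  s <- 0.1 / rate
  tt <- (0:50) * s
  vv <- damped_volume_relaxation(om, v0, vdot0, tt)$volume
  inc <- diff(vv)
  resid <- inc[-1] - exp(-rate * s) * inc[-length(inc)]
  expect_lt(max(abs(resid)) / max(abs(inc)), 1e-9)

  # b -> 0 limit: free drift
  om0 <- oscillation_parameters(fluid_medium("inviscid", 1000, 0, 0), 1e-8)
  drift <- damped_volume_relaxation(om0, v0, vdot0, c(0, 1, 2))
  expect_equal(drift$volume, v0 + vdot0 * c(0, 1, 2))

  expect_error(damped_volume_relaxation(om, v0, vdot0, c(-1, 0)), "non-negative")
  omk <- oscillation_parameters(medium_water(), 1e-8, stiffness_k = 1)
  expect_error(damped_volume_relaxation(omk, v0, vdot0, 0), "zero-stiffness")
})
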