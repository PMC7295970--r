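test_that("generators are bit-reproducible for a fixed seed", {
  a <- make_fluid_with_cavity(box = c(50, 50, 50), cavity_radius = 12,
                              density = 1.0, seed = 42, target_pressure = -10)
  b <- make_fluid_with_cavity(box = c(50, 50, 50), cavity_radius = 12,
                              density = 1.0, seed = 42, target_pressure = -10)
  expect_identical(a, b)
  c_ <- make_fluid_with_cavity(box = c(50, 50, 50), cavity_radius = 12,
                               density = 1.0, seed = 43, target_pressure = -10)
  expect_false(identical(a$x, c_$x))

  t1 <- make_brownian_trajectory(10, 20, 0.1, 1e-9, seed = 7)
  t2 <- make_brownian_trajectory(10, 20, 0.1, 1e-9, seed = 7)
  expect_identical(tidy(t1), tidy(t2))

  s1 <- make_ou_stress_series(500, 0.01, 1, 0.1, seed = 9)
  s2 <- make_ou_stress_series(500, 0.01, 1, 0.1, seed = 9)
  expect_identical(s1$pxy, s2$pxy)
})

test_that("generators do not disturb the caller's RNG stream", {
  set.seed(123)
  r1 <- runif(1)
  set.seed(123)
  invisible(make_fluid_with_cavity(box = c(30, 30, 30), cavity_radius = 0,
                                   density = 0.5, seed = 1))
  expect_identical(runif(1), r1)
})

test_that("realised fluid density matches the request within 1%", {
  for (s in 1:3) {
    fr <- make_fluid_with_cavity(box = c(70, 70, 70), cavity_radius = 20,
                                 density = 1.05, seed = s)
    vfluid <- prod(frame_box(fr)) - 4 / 3 * pi * 20^3
    rho <- sum(fr$mass) * 1.66053906660 / vfluid
    expect_equal(rho, 1.05, tolerance = 0.01)
    # no particle inside the carved cavity
    u <- cbind(fr$x - 35, fr$y - 35, fr$z - 35)
    expect_true(all(rowSums(u^2) >= 20^2))
  }
})

test_that("ground truth is recorded and sufficient for downstream oracles", {
  fr <- make_fluid_with_cavity(box = c(50, 50, 50), cavity_radius = 10,
                               density = 1.0, seed = 2, target_pressure = -33)
  gt <- ground_truth(fr)
  expect_equal(gt$cavity_volume, 4 / 3 * pi * 10^3)
  expect_equal(gt$target_pressure, -33)
  expect_equal(global_pressure(fr)$pressure, gt$target_pressure,
               tolerance = 1e-12)

  st <- make_ou_stress_series(1000, 0.01, sd_stress = 3, tau = 0.5, seed = 1,
                              volume = 2e6, temperature = 310)
  gt2 <- ground_truth(st)
  expect_equal(gt2$gk_integral, 9 * 0.5)
  expect_equal(gt2$implied_viscosity,
               2e6 * 1e-30 * 9 * 0.5 / (1.380649e-23 * 310), tolerance = 1e-12)
  # white-noise limit: the implied viscosity depends on s^2 * tau only
  gt3 <- ground_truth(make_ou_stress_series(1000, 0.01, sd_stress = 3 * sqrt(10),
                                            tau = 0.05, seed = 1,
                                            volume = 2e6, temperature = 310))
  expect_equal(gt3$implied_viscosity, gt2$implied_viscosity, tolerance = 1e-12)
})

test_that("growth trajectories keep particle identity on the retained set", {
  sched <- data.frame(time = c(0, 1, 2), radius = c(10, 12, 15))
  traj <- make_growth_trajectory(sched, box = c(50, 50, 50), seed = 4)
  frames <- unclass(traj)
  # ids of the largest-cavity frame are a subset of every other frame
  ids <- lapply(frames, function(f) f$id)
  expect_true(all(ids[[3]] %in% ids[[1]]))
  expect_true(all(ids[[3]] %in% ids[[2]]))
  expect_error(
    make_growth_trajectory(data.frame(time = 0, radius = 30),
                           box = c(50, 50, 50)),
    "exceeds the box"
  )
})

test_that("zero-diffusivity walkers do not move", {
  traj <- make_brownian_trajectory(5, 10, 0.1, 0, seed = 1)
  long <- tidy(traj)
  expect_equal(stats::sd(long$x[long$id == 1]), 0)
})

test_that("damped series fits recover the generator decay within 5%", {
  for (s in 1:3) {
    ds <- make_damped_series(n_steps = 400, dt = 0.01, c1 = 2, decay = 1.5,
                             freq = 0, offset = 5, noise_sd = 0.01, seed = s)
    gt <- ground_truth(ds)
    fit <- stats::lm(log(value - gt$offset) ~ time,
                     data = ds[ds$value > gt$offset, ])
    expect_equal(-stats::coef(fit)[["time"]], gt$decay, tolerance = 0.05)
  }
})
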