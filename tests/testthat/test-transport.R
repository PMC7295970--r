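test_that("the FFT all-origins MSD matches the brute-force oracle", {
  traj <- make_brownian_trajectory(8, 40, 0.5, 2e-9, seed = 11)
  m <- msd(traj, max_lag = 40 * 0.5)
  # independent O(n^2) oracle over the same coordinates
  frames <- unclass(traj)
  coords <- lapply(frames, function(f) as.matrix(f[, c("x", "y", "z")]))
  oracle <- brute_msd(coords)
  expect_equal(m$value, oracle[seq_len(nrow(m))], tolerance = 1e-10)
})

test_that("stationary particles have zero MSD and zero diffusivity", {
  f <- lapply(0:9, function(t) {
    particle_frame(cbind(x = 1:5, y = 2, z = 3), box = c(50, 50, 50), time = t)
  })
  m <- msd(trajectory(f))
  expect_equal(max(abs(m$value)), 0)
  d <- diffusion_coefficient(m)
  expect_equal(d$value, 0)
})

test_that("Brownian walkers recover the generator diffusivity within 10%", {
  traj <- make_brownian_trajectory(300, 500, 0.1, 1e-9, seed = 2)
  d <- diffusion_coefficient(msd(traj))
  expect_equal(d$value, 1e-9, tolerance = 0.1)
  expect_true(d$diffusive)
  expect_gt(d$standard_error, 0)
})

test_that("ballistic motion is flagged as non-diffusive", {
  f <- lapply(0:19, function(t) {
    particle_frame(cbind(x = 1:5 + 0.8 * t, y = 2, z = 3),
                   box = c(1000, 1000, 1000), time = t)
  })
  m <- msd(trajectory(f))
  # MSD = v^2 t^2 exactly
  expect_equal(m$value, 0.8^2 * m$time^2, tolerance = 1e-10)
  d <- diffusion_coefficient(m)
  expect_false(d$diffusive)
  expect_equal(d$alpha, 2, tolerance = 0.01)
})

test_that("wrapped coordinates without image flags are refused", {
  # a particle crossing the boundary of a small box looks like a jump
  f <- lapply(0:5, function(t) {
    particle_frame(cbind(x = (2 + 3 * t) %% 10, y = 2, z = 3),
                   box = c(10, 10, 10), time = t)
  })
  expect_error(msd(trajectory(f)), "unwrap")
})

test_that("zero stress gives zero viscosity", {
  st <- tibble::tibble(time = (0:1999) * 0.01, pxy = 0, pxz = 0, pyz = 0)
  gk <- green_kubo_viscosity(st, volume = 1e6, temperature = 300, cutoff = 1)
  expect_equal(gk$value, 0)
})

test_that("Green-Kubo recovers the OU analytic viscosity within 15%", {
  for (s in 1:3) {
    st <- make_ou_stress_series(n_steps = 40000, dt = 0.01, sd_stress = 2,
                                tau = 0.2, seed = s,
                                volume = 1e6, temperature = 300)
    truth <- ground_truth(st)$implied_viscosity
    gk <- green_kubo_viscosity(st, volume = 1e6, temperature = 300)
    expect_equal(gk$value, truth, tolerance = 0.15)
    expect_gt(gk$standard_error, 0)
  }
})

test_that("the viscosity integral is converged at the default cutoff", {
  st <- make_ou_stress_series(n_steps = 60000, dt = 0.01, sd_stress = 2,
                              tau = 0.2, seed = 4)
  g1 <- green_kubo_viscosity(st, 1e6, 300, cutoff = 2)    # 10 tau
  g2 <- green_kubo_viscosity(st, 1e6, 300, cutoff = 4)    # 20 tau
  expect_equal(g2$value, g1$value, tolerance = 0.05)
})

test_that("cutoff preconditions are enforced", {
  st <- make_ou_stress_series(n_steps = 1000, dt = 0.01, sd_stress = 1,
                              tau = 0.1, seed = 5)
  expect_error(green_kubo_viscosity(st, 1e6, 300, cutoff = 20), "shorter")
  expect_error(green_kubo_viscosity(st, 1e6, 300, cutoff = 5), "10x")
})
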