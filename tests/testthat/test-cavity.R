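test_that("a carved 50 A void is recovered within 5%, improving with the grid", {
  fr <- make_fluid_with_cavity(box = c(120, 120, 120), cavity_radius = 50,
                               density = 1.02, seed = 1)
  vtrue <- 4 / 3 * pi * 50^3
  err <- vapply(c(4, 2), function(gs) {
    cav <- detect_cavity(fr, grid_spacing = gs, probe_radius = 3)
    expect_true(cav$found)
    expect_equal(cav$volume, vtrue, tolerance = 0.05)
    abs(cav$volume - vtrue) / vtrue
  }, numeric(1))
  # refinement does not degrade the recovery (within voxel noise)
  expect_lt(err[2], err[1] + 0.01)
})

test_that("the production-box geometry recovers its carved 5 nm bubble", {
  # the full simulation cell: 211 x 211 x 165 A with a 50 A central void
  fr <- make_fluid_with_cavity(box = c(211, 211, 165), cavity_radius = 50,
                               density = 1.02, seed = 1)
  cav <- detect_cavity(fr, grid_spacing = 4, probe_radius = 3)
  expect_true(cav$found)
  expect_equal(cav$volume, 4 / 3 * pi * 50^3, tolerance = 0.05)
})

test_that("a homogeneous fluid has no cavity above the size threshold", {
  fr <- make_fluid_with_cavity(box = c(60, 60, 60), cavity_radius = 0,
                               density = 1.02, seed = 2)
  cav <- detect_cavity(fr, grid_spacing = 2, probe_radius = 3)
  expect_false(cav$found)
  expect_equal(cav$volume, 0)
  expect_error(cavity_metrics(cav), "no cavity")
})

test_that("with two carved voids the larger wins and the rest are counted", {
  fr <- make_fluid_with_cavity(box = c(140, 140, 140), cavity_radius = 50,
                               density = 1.02, seed = 3)
  # carve a second, smaller void off-centre
  u <- cbind(fr$x - 30, fr$y - 30, fr$z - 110)
  keep <- rowSums(u^2) >= 15^2
  fr2 <- particle_frame(as.matrix(fr[keep, c("x", "y", "z")]),
                        box = c(140, 140, 140))
  cav <- detect_cavity(fr2, grid_spacing = 2, probe_radius = 3)
  expect_true(cav$found)
  expect_equal(cav$volume, 4 / 3 * pi * 50^3, tolerance = 0.05)
  expect_gte(cav$n_secondary, 1L)
})

test_that("cavity metrics report a consistent effective radius and sane Psi", {
  fr <- make_fluid_with_cavity(box = c(90, 90, 90), cavity_radius = 30,
                               density = 1.02, seed = 6)
  cav <- detect_cavity(fr, grid_spacing = 2, probe_radius = 3)
  cm <- cavity_metrics(cav)
  expect_equal(cm$effective_radius, (3 * cm$volume_c / (4 * pi))^(1 / 3),
               tolerance = 1e-12)
  expect_equal(cm$volume_c, 4 / 3 * pi * 30^3, tolerance = 0.05)
  expect_lte(cm$sphericity, 1.02)
  expect_gt(cm$sphericity, 0.85)
})

test_that("an ellipsoidal cavity has sphericity below 1", {
  fr <- make_fluid_with_cavity(box = c(150, 130, 130),
                               cavity_radius = c(60, 30, 30),
                               density = 1.02, seed = 4)
  cav <- detect_cavity(fr, grid_spacing = 2, probe_radius = 3)
  cm <- cavity_metrics(cav)
  expect_equal(cm$volume_c, 4 / 3 * pi * 60 * 30 * 30, tolerance = 0.05)
  expect_lt(cm$sphericity, 0.95)
  expect_gt(cm$sphericity, (pi / 6)^(1 / 3))
})

test_that("grid and probe preconditions are enforced", {
  fr <- make_fluid_with_cavity(box = c(30, 30, 30), cavity_radius = 0,
                               density = 1.0, seed = 8)
  expect_error(detect_cavity(fr, grid_spacing = 15), "grid too coarse")
  expect_error(detect_cavity(fr, grid_spacing = -1), "positive")
})

test_that("density excluding the cavity recovers the generator density", {
  fr <- make_fluid_with_cavity(box = c(120, 120, 120), cavity_radius = 50,
                               density = 1.02, seed = 1)
  cav <- detect_cavity(fr, 2, 3)
  d_excl <- density_excluding_cavity(fr, cav)
  expect_equal(d_excl, 1.02, tolerance = 0.01)
  # counting the void as liquid dilutes the apparent density
  expect_lt(density_excluding_cavity(fr, 0), d_excl)
  expect_error(density_excluding_cavity(fr, box_volume(fr)), "smaller")
})

test_that("cavity volume cross-checks the system-volume decomposition", {
  fr <- make_fluid_with_cavity(box = c(120, 120, 120), cavity_radius = 50,
                               density = 1.02, seed = 7)
  cav <- detect_cavity(fr, 2, 3)
  vbox <- box_volume(fr)
  vcav_true <- 4 / 3 * pi * 50^3
  dec <- volume_decomposition(v_system = vbox, v_water = vbox - vcav_true)
  expect_equal(dec$v_bubble, cav$volume, tolerance = 0.05)
  expect_equal(dec$bubble_radius, 50, tolerance = 0.02)
})
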