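# run code under a fixed RNG seed without clobbering the caller's RNG state
with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Synthetic fluid frame with a carved cavity
#'
#' Emulates the starting configuration of the cavitation simulations: a
#' homogeneous bead fluid (18 amu water-like beads) at a requested mass
#' density filling a periodic box, with a spherical or ellipsoidal cavity
#' carved out of the centre. Particles are placed by uniform rejection
#' sampling outside the cavity, so the realised density of the condensed
#' phase matches the request to within rounding of the particle count.
#' Optionally assigns an isotropic per-atom stress that makes
#' [global_pressure()] return `target_pressure` exactly (each atom gets an
#' equal volume share and the matching diagonal stress), and per-atom
#' volumes.
#'
#' Every generator in the package is deterministic: the same arguments and
#' seed give bit-identical output, and the generating parameters are recorded
#' in a `ground_truth` attribute.
#'
#' @param box Box edge lengths, A.
#' @param cavity_radius Sphere radius (A), or length-3 semi-axes for an
#'   ellipsoid; 0 for a homogeneous fluid.
#' @param density Target mass density of the condensed phase, g/cm^3.
#' @param seed RNG seed.
#' @param mass Bead mass, amu (default 18).
#' @param target_pressure Optional global pressure to encode in per-atom
#'   stress, MPa (tension negative).
#' @param cavity_center Cavity centre (default box centre).
#' @param time Frame time, ps.
#' @return A [particle_frame()] with attribute `ground_truth`.
#' @export
#' @examples
#' fr <- make_fluid_with_cavity(box = c(60, 60, 60), cavity_radius = 15,
#'                              density = 1.02, seed = 7,
#'                              target_pressure = -20)
#' global_pressure(fr)
make_fluid_with_cavity <- function(box, cavity_radius = 0, density = 1.02,
                                   seed = 1, mass = 18, target_pressure = NULL,
                                   cavity_center = NULL, time = 0) {
  stopifnot(length(box) == 3L, all(box > 0))
  axes <- if (length(cavity_radius) == 1L) rep(cavity_radius, 3) else cavity_radius
  stopifnot(length(axes) == 3L, all(axes >= 0))
  if (any(2 * axes >= box)) {
    stop("cavity does not fit inside the box.", call. = FALSE)
  }
  if (is.null(cavity_center)) cavity_center <- box / 2
  vbox <- prod(box)
  vcav <- 4 / 3 * pi * prod(axes)
  rho_amu <- density / 1.66053906660 # amu per A^3
  n <- round(rho_amu * (vbox - vcav) / mass)
  if (n < 1) stop("density/box infeasible: fewer than one particle.", call. = FALSE)
  coords <- with_local_seed(seed, {
    out <- matrix(NA_real_, 0, 3)
    while (nrow(out) < n) {
      m <- ceiling((n - nrow(out)) * (1 + 1.5 * vcav / vbox) + 50)
      cand <- cbind(stats::runif(m, 0, box[1]), stats::runif(m, 0, box[2]),
                    stats::runif(m, 0, box[3]))
      if (any(axes > 0)) {
        u <- sweep(cand, 2, cavity_center, "-")
        u <- minimum_image(u, box)
        inside <- (u[, 1] / axes[1])^2 + (u[, 2] / axes[2])^2 +
          (u[, 3] / axes[3])^2 < 1
        cand <- cand[!inside, , drop = FALSE]
      }
      out <- rbind(out, cand)
    }
    out[seq_len(n), , drop = FALSE]
  })
  stress <- NULL
  volume <- NULL
  if (!is.null(target_pressure)) {
    vshare <- vbox / n
    diag <- target_pressure / .atm_MPa * vshare
    stress <- cbind(sxx = rep(diag, n), syy = diag, szz = diag,
                    sxy = 0, sxz = 0, syz = 0)
    volume <- rep(vshare, n)
  }
  fr <- particle_frame(coords, box = box, time = time, mass = mass,
                       stress = stress, volume = volume)
  attr(fr, "ground_truth") <- list(
    kind = "fluid_with_cavity", box = box, cavity_axes = axes,
    cavity_center = cavity_center, cavity_volume = vcav, density = density,
    n_particles = n, mass = mass, target_pressure = target_pressure,
    seed = seed
  )
  fr
}

#' Synthetic growth/collapse trajectory with a prescribed radius history
#'
#' Builds a trajectory whose cavity follows a prescribed radius schedule
#' R(t): a single base fluid is generated once (so particle identity is
#' stable), and each frame removes the particles inside the scheduled cavity
#' radius and adds small-amplitude Gaussian surface jitter emulating thermal
#' roughness. Particles outside the largest scheduled radius are present in
#' every frame, keeping MSD computable on the retained set.
#'
#' @param schedule Data frame with `time` (ps) and `radius` (A) columns; an
#'   [solve_rp()] result can be passed after converting units.
#' @param box Box edges, A.
#' @param density Condensed-phase density, g/cm^3.
#' @param seed RNG seed.
#' @param jitter Per-frame Gaussian positional jitter, A (default 0.3).
#' @param mass Bead mass, amu.
#' @return A [trajectory()] with attribute `ground_truth`.
#' @export
#' @examples
#' sched <- data.frame(time = seq(0, 10, 2),
#'                     radius = seq(15, 20, length.out = 6))
#' traj <- make_growth_trajectory(sched, box = c(70, 70, 70), seed = 3)
make_growth_trajectory <- function(schedule, box, density = 1.02, seed = 1,
                                   jitter = 0.3, mass = 18) {
  stopifnot(is.data.frame(schedule), all(c("time", "radius") %in% names(schedule)))
  if (any(schedule$radius < 0) || any(2 * schedule$radius >= min(box))) {
    stop("schedule radius exceeds the box.", call. = FALSE)
  }
  if (nrow(schedule) > 1L && any(diff(schedule$time) <= 0)) {
    stop("schedule times must be strictly increasing.", call. = FALSE)
  }
  centre <- box / 2
  rho_amu <- density / 1.66053906660
  n <- round(rho_amu * prod(box) / mass)
  frames <- with_local_seed(seed, {
    base <- cbind(stats::runif(n, 0, box[1]), stats::runif(n, 0, box[2]),
                  stats::runif(n, 0, box[3]))
    lapply(seq_len(nrow(schedule)), function(i) {
      r <- schedule$radius[i]
      pos <- base + matrix(stats::rnorm(3 * n, sd = jitter), n, 3)
      pos <- wrap_coords(pos, box)
      u <- minimum_image(sweep(pos, 2, centre, "-"), box)
      keep <- rowSums(u^2) >= r^2
      particle_frame(pos[keep, , drop = FALSE], box = box,
                     time = schedule$time[i], mass = mass,
                     id = which(keep))
    })
  })
  traj <- trajectory(frames)
  attr(traj, "ground_truth") <- list(
    kind = "growth_trajectory", box = box, schedule = schedule,
    density = density, jitter = jitter, seed = seed, n_base = n
  )
  traj
}

#' Synthetic Brownian (random-walk) trajectory with known diffusivity
#'
#' Independent 3D Gaussian random walks: per step and axis the displacement
#' variance is `2 D dt`, so the walkers diffuse with exactly the requested
#' diffusion coefficient and `MSD = 6 D tau`. Coordinates are unwrapped (the
#' nominal box is made large enough never to matter).
#'
#' @param n_particles,n_steps Walkers and steps.
#' @param dt Time step, ps.
#' @param D Diffusion coefficient, m^2/s.
#' @param seed RNG seed.
#' @return A [trajectory()] of `n_steps + 1` frames with attribute
#'   `ground_truth` (including `D` and the per-step displacement sd).
#' @export
make_brownian_trajectory <- function(n_particles, n_steps, dt, D, seed = 1) {
  stopifnot(n_particles >= 1, n_steps >= 1, dt > 0, D >= 0)
  d_a2ps <- D / .A2ps_to_m2s
  sd_step <- sqrt(2 * d_a2ps * dt)
  span <- max(100, 20 * sd_step * sqrt(n_steps))
  box <- rep(span, 3)
  frames <- with_local_seed(seed, {
    start <- matrix(stats::runif(3 * n_particles, span * 0.4, span * 0.6),
                    n_particles, 3)
    steps <- array(stats::rnorm(3 * n_particles * n_steps, sd = sd_step),
                   dim = c(n_particles, 3, n_steps))
    pos <- start
    out <- vector("list", n_steps + 1)
    out[[1]] <- particle_frame(pos, box = box, time = 0)
    for (s in seq_len(n_steps)) {
      pos <- pos + steps[, , s]
      out[[s + 1]] <- particle_frame(pos, box = box, time = s * dt)
    }
    out
  })
  traj <- trajectory(frames)
  attr(traj, "ground_truth") <- list(
    kind = "brownian", D = D, dt = dt, sd_step = sd_step,
    n_particles = n_particles, n_steps = n_steps, seed = seed
  )
  traj
}

#' Synthetic Ornstein-Uhlenbeck stress series with known viscosity
#'
#' Stationary, exponentially correlated stress fluctuations generated by the
#' exact OU discretisation `x' = x e^(-dt/tau) + s sqrt(1 - e^(-2 dt/tau)) z`.
#' The autocorrelation is `s^2 exp(-t/tau)`, whose Green-Kubo integral is
#' `s^2 tau`, so the implied shear viscosity for a system of volume V at
#' temperature T is `eta = V s^2 tau / (kB T)` -- recorded in `ground_truth`
#' when `volume` and `temperature` are given.
#'
#' @param n_steps Series length.
#' @param dt Sampling interval, ps.
#' @param sd_stress Stationary standard deviation s, MPa.
#' @param tau Correlation time, ps.
#' @param n_components Number of independent components (default 3:
#'   `pxy, pxz, pyz`).
#' @param seed RNG seed.
#' @param volume,temperature Optional V (A^3) and T (K) used to record the
#'   implied viscosity in `ground_truth`.
#' @return A tibble (`time` + component columns, MPa) with attribute
#'   `ground_truth`.
#' @export
make_ou_stress_series <- function(n_steps, dt, sd_stress, tau,
                                  n_components = 3, seed = 1,
                                  volume = NULL, temperature = NULL) {
  stopifnot(n_steps >= 2, dt > 0, sd_stress >= 0, tau > 0)
  a <- exp(-dt / tau)
  b <- sd_stress * sqrt(1 - a^2)
  comps <- with_local_seed(seed, {
    lapply(seq_len(n_components), function(j) {
      z <- stats::rnorm(n_steps)
      x <- numeric(n_steps)
      x[1] <- sd_stress * z[1]
      for (i in 2:n_steps) x[i] <- a * x[i - 1] + b * z[i]
      x
    })
  })
  names(comps) <- c("pxy", "pxz", "pyz", paste0("p", seq_len(max(0, n_components - 3)) + 3))[
    seq_len(n_components)
  ]
  out <- tibble::as_tibble(c(list(time = (seq_len(n_steps) - 1) * dt), comps))
  gt <- list(
    kind = "ou_stress", sd_stress = sd_stress, tau = tau, dt = dt,
    n_steps = n_steps, n_components = n_components, seed = seed,
    gk_integral = sd_stress^2 * tau # MPa^2 ps
  )
  if (!is.null(volume) && !is.null(temperature)) {
    gt$implied_viscosity <- volume * 1e-30 * sd_stress^2 * tau /
      (.kB * temperature)
  }
  attr(out, "ground_truth") <- gt
  out
}

#' Synthetic exponentially damped oscillation series
#'
#' `v(t) = c1 exp(-decay t) cos(2 pi freq t) + offset + noise`, the shape of
#' a damped bubble pulsation trace; used as a fit-recovery oracle for the
#' volume-relaxation model.
#'
#' @param n_steps,dt Length and spacing (ps).
#' @param c1 Initial amplitude.
#' @param decay Decay rate, 1/ps.
#' @param freq Oscillation frequency, 1/ps (0 for pure decay).
#' @param offset Constant offset.
#' @param noise_sd Gaussian noise sd.
#' @param seed RNG seed.
#' @return A [scalar_series()] with attribute `ground_truth`.
#' @export
make_damped_series <- function(n_steps, dt, c1 = 1, decay = 0.1, freq = 0,
                               offset = 0, noise_sd = 0, seed = 1) {
  stopifnot(n_steps >= 2, dt > 0, decay >= 0)
  tt <- (seq_len(n_steps) - 1) * dt
  vals <- with_local_seed(seed, {
    c1 * exp(-decay * tt) * cos(2 * pi * freq * tt) + offset +
      stats::rnorm(n_steps, sd = noise_sd)
  })
  out <- scalar_series(tt, vals, unit = "arb")
  attr(out, "ground_truth") <- list(
    kind = "damped_series", c1 = c1, decay = decay, freq = freq,
    offset = offset, noise_sd = noise_sd, dt = dt, n_steps = n_steps,
    seed = seed
  )
  out
}

#' @rdname make_fluid_with_cavity
#' @param x An object produced by a generator.
#' @return `ground_truth()` returns the recorded generating parameters.
#' @export
ground_truth <- function(x) attr(x, "ground_truth")
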