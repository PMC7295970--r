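#' Lumped-parameter model of small-amplitude bubble volume pulsation
#'
#' A small, non-condensable pulsating bubble obeys a damped oscillator
#' equation in its volume perturbation, `m V'' + b V' + k V = 0`, with an
#' inertia constant `m`, a dissipation constant `b` and a stiffness `k`
#' proportional to the internal gas pressure. For a near-empty nanobubble at
#' constant temperature the thermal, radiation and phase-change parts of `b`
#' are negligible, leaving the viscous part `b = eta / (pi R^3)`; the inertia
#' is the volume-pulsation inertia `m = rho / (4 pi R)`. With negligible
#' internal gas pressure the stiffness defaults to zero, in which regime the
#' volume relaxes exponentially at rate `b/m = 4 eta / (rho R^2)` (see
#' [damped_volume_relaxation()]); gel, being about twice as viscous as water,
#' damps the pulsation about twice as fast.
#'
#' When a positive stiffness is supplied, the model also reports the natural
#' frequency `f_n = (1/(2 pi)) sqrt(k/m) sqrt(1 - delta^2/4)` with the
#' damping parameter `delta = b / sqrt(k/m)` (as conventionally written for
#' this model), alongside the textbook dimensionless damping ratio
#' `zeta = b / (2 sqrt(k m))`. `f_n` is reported as `NA` when `delta^2 >= 4`
#' (overdamped).
#'
#' @param medium A [fluid_medium()].
#' @param radius Equilibrium bubble radius in metres (> 0).
#' @param stiffness_k Optional stiffness constant, kg m^-4 s^-2 (>= 0);
#'   default 0 (negligible internal gas pressure).
#'
#' @return A one-row tibble of class `oscillation_model` with columns
#'   `medium`, `radius`, `inertia_m`, `damping_b`, `stiffness_k`,
#'   `relaxation_rate` (`b/m`, 1/s), `natural_frequency` (Hz or `NA`),
#'   `damping_ratio_delta` (`b/sqrt(k/m)`), `damping_ratio_std`
#'   (`b/(2 sqrt(km))`).
#' @export
#' @examples
#' oscillation_parameters(medium_water(), 95.16e-10)$relaxation_rate # ~1.39e10 1/s
oscillation_parameters <- function(medium, radius, stiffness_k = 0) {
  medium <- as_medium(medium)
  if (!is.numeric(radius) || length(radius) != 1L || !is.finite(radius) || radius <= 0) {
    stop("`radius` must be a single positive number (m).", call. = FALSE)
  }
  if (!is.numeric(stiffness_k) || length(stiffness_k) != 1L || !is.finite(stiffness_k) ||
      stiffness_k < 0) {
    stop("`stiffness_k` must be a single non-negative number.", call. = FALSE)
  }
  m <- medium$density / (4 * pi * radius)
  b <- medium$viscosity / (pi * radius^3)
  if (stiffness_k > 0) {
    delta <- b / sqrt(stiffness_k / m)
    zeta <- b / (2 * sqrt(stiffness_k * m))
    fn <- if (delta^2 < 4) (1 / (2 * pi)) * sqrt(stiffness_k / m) * sqrt(1 - delta^2 / 4) else NA_real_
  } else {
    delta <- NA_real_
    zeta <- NA_real_
    fn <- NA_real_
  }
  out <- tibble::tibble(
    medium = medium$name, radius = radius,
    inertia_m = m, damping_b = b, stiffness_k = stiffness_k,
    relaxation_rate = b / m,
    natural_frequency = fn,
    damping_ratio_delta = delta,
    damping_ratio_std = zeta
  )
  class(out) <- c("oscillation_model", class(out))
  out
}

#' Exponential relaxation of a pulsating bubble volume (zero stiffness)
#'
#' Solves `m V'' + b V' = 0` (the zero-stiffness pulsation regime, internal
#' gas pressure negligible): `V(t) = C1 exp(-b t / m) + C2` with
#' `C1 = -Vdot0 * m / b` and `C2 = V0 + Vdot0 * m / b` fixed by the initial
#' volume and volume rate. In the `b -> 0` limit the solution degenerates to
#' the free drift `V(t) = V0 + Vdot0 * t`. An equivalent radius
#' `R = (3 V / (4 pi))^(1/3)` is reported alongside the volume.
#'
#' @param model An [oscillation_parameters()] result with `stiffness_k == 0`.
#' @param v0 Initial volume (m^3, > 0).
#' @param vdot0 Initial volume rate (m^3/s).
#' @param times Evaluation times in seconds (>= 0).
#'
#' @return A tibble with columns `time` (s), `volume` (m^3) and `radius` (m;
#'   `NA` where the extrapolated volume is non-positive).
#' @export
#' @examples
#' om <- oscillation_parameters(medium_water(), 95.16e-10)
#' damped_volume_relaxation(om, v0 = 3.6e-24, vdot0 = -1e-14,
#'                          times = seq(0, 5e-10, length.out = 11))
damped_volume_relaxation <- function(model, v0, vdot0, times) {
  stopifnot(inherits(model, "oscillation_model"))
  if (model$stiffness_k != 0) {
    stop("exponential relaxation applies only in the zero-stiffness regime; ",
         "refit with `stiffness_k = 0`.", call. = FALSE)
  }
  if (any(!is.finite(times)) || any(times < 0)) {
    stop("`times` must be finite and non-negative.", call. = FALSE)
  }
  if (v0 <= 0) stop("`v0` must be positive.", call. = FALSE)
  rate <- model$relaxation_rate # b/m
  if (rate > 0) {
    c1 <- -vdot0 / rate
    c2 <- v0 + vdot0 / rate
    vol <- c1 * exp(-rate * times) + c2
  } else {
    vol <- v0 + vdot0 * times
  }
  tibble::tibble(
    time = times, volume = vol,
    radius = ifelse(vol > 0, (3 * vol / (4 * pi))^(1 / 3), NA_real_)
  )
}

#' @export
glance.oscillation_model <- function(x, ...) {
  tibble::as_tibble(unclass(x))
}
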