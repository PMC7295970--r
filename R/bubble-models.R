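#' Equilibrium (threshold) cavitation pressure for a stable bubble
#'
#' For a pre-existing spherical bubble of radius R with negligible internal
#' vapor pressure, mechanical equilibrium requires the far-field pressure to
#' balance the Laplace pressure of the curved interface:
#' `2*sigma/R + P_cav = 0`, i.e. `P_cav = -2*sigma/R`. The required pressure
#' is a tension (negative by this package's sign convention) and scales with
#' the medium's surface tension, so a gel with higher surface tension needs a
#' larger-magnitude negative pressure for the same bubble to be stable.
#'
#' @param medium A [fluid_medium()] (one-row data frame).
#' @param radius Bubble radius in metres (> 0); vectorised.
#'
#' @return Far-field equilibrium pressure(s) in Pa (negative = tension),
#'   as a tibble with columns `radius` and `pressure`.
#' @export
#' @examples
#' equilibrium_cavitation_pressure(medium_water(), 95.16e-10) # ~ -11.7 MPa
#' equilibrium_cavitation_pressure(medium_gel(), 95.35e-10)   # ~ -20.5 MPa
equilibrium_cavitation_pressure <- function(medium, radius) {
  medium <- as_medium(medium)
  if (!is.numeric(radius) || any(!is.finite(radius)) || any(radius <= 0)) {
    stop("`radius` must be positive and finite (m).", call. = FALSE)
  }
  tibble::tibble(radius = radius, pressure = -2 * medium$surface_tension / radius)
}

#' Network contribution to the cavitation threshold
#'
#' Decomposes the gel threshold into the pure-liquid part plus the pressure
#' equivalent of the strain energy stored in the polymer network:
#' `P_cav|network = P_cav|gel - P_cav|liq`.
#'
#' @param p_cav_gel Threshold pressure in the gel (any consistent unit).
#' @param p_cav_liq Threshold pressure in the pure liquid (same unit).
#'
#' @return Network pressure contribution, same unit as the inputs.
#' @export
#' @examples
#' network_pressure(-101, -93) # -8 MPa attributable to the network
network_pressure <- function(p_cav_gel, p_cav_liq) {
  p_cav_gel - p_cav_liq
}

#' Closed-form Rayleigh collapse time of an empty cavity
#'
#' For an empty spherical cavity in an inviscid liquid with zero surface
#' tension, held at a constant positive pressure excess `delta_p`, the
#' collapse time has the classical closed form
#' `t_c = 0.914681 * R0 * sqrt(rho / delta_p)`. This is the analytic limit
#' against which [solve_rp()] is validated.
#'
#' @param density Liquid density, kg/m^3 (> 0).
#' @param radius0 Initial cavity radius, m (> 0).
#' @param delta_p Constant driving pressure `P_ext - P_b`, Pa (> 0).
#'
#' @return Collapse time in seconds (vectorised over its arguments).
#' @export
#' @examples
#' rayleigh_collapse_time(1000, 1e-6, 1e5) # 9.15e-8 s
rayleigh_collapse_time <- function(density, radius0, delta_p) {
  if (any(density <= 0) || any(radius0 <= 0) || any(delta_p <= 0)) {
    stop("`density`, `radius0` and `delta_p` must all be positive.", call. = FALSE)
  }
  0.914681 * radius0 * sqrt(density / delta_p)
}

#' Nucleation-time scaling of the homogeneous cavitation threshold
#'
#' Classical (Fisher) homogeneous-nucleation kinetics give a critical tension
#' `P ~ [ln(N*kB*T*t/h)]^(-1/2)` for `N` molecules observed for a waiting time
#' `t` at temperature `T`. The ratio of thresholds at two waiting times is
#' therefore `P(t1)/P(t2) = sqrt(ln(N*kB*T*t2/h) / ln(N*kB*T*t1/h))` for
#' `t1 < t2`; surface tension cancels. Evaluated between the atomistic
#' vibration time (1e-15 s) and the age of the universe (1e18 s), a span of
#' 33 decades in waiting time, the threshold changes only by a factor of
#' about 1.58 -- the basis for treating strain-rate effects on homogeneous
#' nucleation as weak.
#'
#' @param t1,t2 Waiting times in seconds, `t1 <= t2`.
#' @param n_molecules Number of molecules N (default one mole).
#' @param temperature Temperature in K (default 300).
#'
#' @return Dimensionless critical-pressure ratio `P(t1)/P(t2)` (>= 1).
#' @export
#' @examples
#' fisher_threshold_ratio(1e-15, 1e18) # ~ 1.59
fisher_threshold_ratio <- function(t1, t2, n_molecules = 6.022e23, temperature = 300) {
  if (any(t1 <= 0) || any(t2 <= 0)) stop("waiting times must be positive.", call. = FALSE)
  if (any(n_molecules <= 0) || any(temperature <= 0)) {
    stop("`n_molecules` and `temperature` must be positive.", call. = FALSE)
  }
  if (any(t2 < t1)) stop("`t2` must be >= `t1`.", call. = FALSE)
  a <- n_molecules * .kB * temperature / .planck
  l1 <- log(a * t1)
  l2 <- log(a * t2)
  if (any(l1 <= 0) || any(l2 <= 0)) {
    stop("ln(N*kB*T*t/h) must be positive for both waiting times.", call. = FALSE)
  }
  sqrt(l2 / l1)
}
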