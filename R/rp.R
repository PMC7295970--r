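#' Far-field pressure schedule for bubble-dynamics integration
#'
#' Either a constant far-field pressure or a sampled trace `P_ext(t)` that is
#' linearly interpolated during integration. A sampled schedule must cover the
#' whole integration window.
#'
#' @param value Constant pressure in Pa (constant mode).
#' @param times,values Sampled schedule: strictly increasing times (s) and
#'   pressures (Pa).
#' @return An object of class `pressure_schedule`.
#' @export
#' @examples
#' pressure_schedule(1e5)
#' pressure_schedule(times = c(0, 1e-9), values = c(0, -9e7))
pressure_schedule <- function(value = NULL, times = NULL, values = NULL) {
  if (!is.null(value)) {
    stopifnot(is.numeric(value), length(value) == 1L, is.finite(value))
    out <- list(mode = "constant", value = value)
  } else {
    if (is.null(times) || is.null(values)) {
      stop("supply either `value`, or both `times` and `values`.", call. = FALSE)
    }
    if (length(times) != length(values) || length(times) < 2L) {
      stop("`times` and `values` must have equal length >= 2.", call. = FALSE)
    }
    if (any(diff(times) <= 0)) stop("schedule `times` must be strictly increasing.", call. = FALSE)
    out <- list(mode = "sampled", times = as.numeric(times), values = as.numeric(values))
  }
  structure(out, class = "pressure_schedule")
}

schedule_fun <- function(schedule, horizon) {
  if (!inherits(schedule, "pressure_schedule")) {
    if (is.numeric(schedule) && length(schedule) == 1L) {
      schedule <- pressure_schedule(schedule)
    } else {
      stop("`schedule` must be a pressure_schedule or a single number (Pa).", call. = FALSE)
    }
  }
  if (schedule$mode == "constant") {
    v <- schedule$value
    function(t) v
  } else {
    if (min(schedule$times) > 0 || max(schedule$times) < horizon) {
      stop("sampled pressure schedule does not cover [0, horizon].", call. = FALSE)
    }
    stats::approxfun(schedule$times, schedule$values, rule = 2)
  }
}

#' Integrate the Rayleigh-Plesset equation for a spherical bubble
#'
#' Integrates the incompressible, constant-property Rayleigh-Plesset equation
#' \deqn{R \ddot R + \tfrac{3}{2}\dot R^2 + \frac{4\eta}{\rho R}\dot R +
#'   \frac{2\sigma}{\rho R} = -\frac{P_{ext} - P_b}{\rho}}
#' with adaptive, stiff-capable stepping (`deSolve::lsodar`) and root-based
#' event detection on the collapse threshold. Integration stops, and the
#' collapse time is recorded, when the radius falls below
#' `collapse_frac * radius0` (default 1%): the radial velocity diverges as
#' `R -> 0`, so full collapse cannot be integrated through, but by that point
#' the remaining fall time is a negligible fraction of the total. The internal
#' pressure `P_b` is taken constant and defaults to zero: a nanoscale cavity
#' holds too few vapor molecules to resist collapse.
#'
#' The balance of terms reproduces the standard limits: with
#' `P_ext = P_b - 2 sigma / R0` and zero initial velocity the bubble is
#' stationary; with `eta = sigma = 0` and constant positive `P_ext - P_b` the
#' collapse time approaches the Rayleigh closed form
#' ([rayleigh_collapse_time()]); raising viscosity retards collapse, which is
#' why a bubble in gel outlives an identical bubble in water.
#'
#' @param medium A [fluid_medium()].
#' @param radius0 Initial radius, m (> 0).
#' @param schedule Far-field pressure: a [pressure_schedule()] or a single
#'   number (Pa).
#' @param horizon Integration horizon, s (> 0).
#' @param radial_velocity0 Initial radial velocity, m/s (default 0).
#' @param internal_pressure Constant internal pressure `P_b`, Pa (default 0).
#' @param collapse_frac Collapse threshold as a fraction of `radius0`
#'   (default 0.01).
#' @param n_out Number of output grid points (default 1000).
#' @param rtol,atol Solver tolerances (defaults 1e-8 and 1e-12 m).
#'
#' @return An `rp_solution`: a tibble with columns `time` (s), `radius` (m),
#'   `velocity` (m/s), carrying attributes `collapse_time` (s or `NA`),
#'   `termination` (`"collapsed"`, `"horizon_reached"` or `"solver_failure"`)
#'   and the inputs. Use [glance()] for a one-row summary.
#' @export
#' @examples
#' sol <- solve_rp(medium_water(), radius0 = 95.16e-10,
#'                 schedule = pressure_schedule(1e6), horizon = 2e-9)
#' glance(sol)
solve_rp <- function(medium, radius0, schedule, horizon,
                     radial_velocity0 = 0, internal_pressure = 0,
                     collapse_frac = 0.01, n_out = 1000,
                     rtol = 1e-8, atol = 1e-12) {
  medium <- as_medium(medium)
  if (!is.numeric(radius0) || length(radius0) != 1L || radius0 <= 0) {
    stop("`radius0` must be a single positive number (m).", call. = FALSE)
  }
  if (!is.numeric(horizon) || length(horizon) != 1L || horizon <= 0) {
    stop("`horizon` must be a single positive number (s).", call. = FALSE)
  }
  if (collapse_frac <= 0 || collapse_frac >= 1) {
    stop("`collapse_frac` must lie in (0, 1).", call. = FALSE)
  }
  pext <- schedule_fun(schedule, horizon)
  rho <- medium$density
  eta <- medium$viscosity
  sigma <- medium$surface_tension
  pb <- internal_pressure
  r_stop <- collapse_frac * radius0

  rhs <- function(t, y, parms) {
    r <- y[1]
    rdot <- y[2]
    rdd <- (-(pext(t) - pb) / rho - 1.5 * rdot^2 -
              (4 * eta / (rho * r)) * rdot - 2 * sigma / (rho * r)) / r
    list(c(rdot, rdd))
  }
  rootfun <- function(t, y, parms) y[1] - r_stop

  times <- seq(0, horizon, length.out = n_out)
  res <- try(suppressWarnings(
    deSolve::lsodar(
      y = c(radius0, radial_velocity0), times = times, func = rhs,
      rootfunc = rootfun, rtol = rtol, atol = c(atol, atol * 1e6)
    )
  ), silent = TRUE)

  if (inherits(res, "try-error")) {
    out <- tibble::tibble(time = 0, radius = radius0, velocity = radial_velocity0)
    termination <- "solver_failure"
    collapse_time <- NA_real_
  } else {
    m <- as.matrix(res)
    keep <- is.finite(m[, 2]) & m[, 2] > 0
    out <- tibble::tibble(time = m[keep, 1], radius = m[keep, 2], velocity = m[keep, 3])
    istate <- attr(res, "istate")
    if (!is.null(attr(res, "troot")) && length(attr(res, "troot")) > 0) {
      collapse_time <- attr(res, "troot")[1]
      termination <- "collapsed"
    } else if (!is.null(istate) && istate[1] < 0) {
      collapse_time <- NA_real_
      termination <- "solver_failure"
    } else {
      collapse_time <- NA_real_
      termination <- "horizon_reached"
    }
  }
  structure(out,
    class = c("rp_solution", class(out)),
    medium = medium$name, radius0 = radius0, collapse_frac = collapse_frac,
    internal_pressure = pb, horizon = horizon,
    collapse_time = collapse_time, termination = termination
  )
}

#' @export
tidy.rp_solution <- function(x, ...) {
  tibble::tibble(time = x$time, radius = x$radius, velocity = x$velocity)
}

#' @export
glance.rp_solution <- function(x, ...) {
  tibble::tibble(
    medium = attr(x, "medium"),
    radius0 = attr(x, "radius0"),
    collapse_time = attr(x, "collapse_time"),
    termination = attr(x, "termination"),
    min_radius = min(x$radius),
    horizon = attr(x, "horizon"),
    n_points = nrow(x)
  )
}

#' @export
autoplot.rp_solution <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(x = .data$time * 1e9, y = .data$radius * 1e9)) +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = "time (ns)", y = "bubble radius (nm)",
      title = paste0("Rayleigh-Plesset radius history (", attr(object, "medium"), ")"),
      subtitle = if (attr(object, "termination") == "collapsed") {
        sprintf("collapse at %.3g ns", attr(object, "collapse_time") * 1e9)
      } else {
        attr(object, "termination")
      }
    )
}
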