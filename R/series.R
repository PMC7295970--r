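#' Scalar time series with a unit label
#'
#' The common container for per-frame traces (pressure, radius, sphericity,
#' density, MSD, strain). A tibble with `time` and `value` columns and a
#' `unit` attribute; written to and read from CSV with a `# unit:` header by
#' [write_series_csv()] / [read_series_csv()].
#'
#' @param times Strictly increasing times (ps unless noted).
#' @param values Values, same length.
#' @param unit Unit label for the values.
#' @return A tibble of class `scalar_series`.
#' @export
scalar_series <- function(times, values, unit = "") {
  if (length(times) != length(values)) {
    stop("`times` and `values` must have equal length.", call. = FALSE)
  }
  if (length(times) > 1L && any(diff(times) <= 0)) {
    stop("`times` must be strictly increasing.", call. = FALSE)
  }
  out <- tibble::tibble(time = as.numeric(times), value = as.numeric(values))
  structure(out, class = c("scalar_series", class(out)), unit = unit)
}

#' @rdname scalar_series
#' @param x A `scalar_series`.
#' @export
series_unit <- function(x) attr(x, "unit")

#' Threshold (minimum) pressure of a smoothed trace
#'
#' The cavitation threshold is read off a pressure trace as the global
#' minimum after light smoothing: raw MD pressure fluctuates by tens of MPa
#' frame to frame, so the minimum of the raw trace would be dominated by
#' noise. A centred moving average of the stated window (default 1 ps) is
#' applied with shrinking windows at the edges; ties are broken by the
#' earliest time, and a minimum at either end of the trace is flagged as a
#' boundary minimum (the trace never turned around).
#'
#' @param series A [scalar_series()] (pressure in MPa) or a data frame with
#'   `time` and `value` columns.
#' @param window Smoothing window in the series' time unit (default 1 ps).
#' @return A one-row tibble: `min_pressure`, `time_at_min`, `boundary`
#'   (logical), `window`.
#' @export
#' @examples
#' tr <- scalar_series(seq(0, 12, 0.1), -93 + 2 * (seq(0, 12, 0.1) - 6.2)^2, "MPa")
#' threshold_pressure(tr)
threshold_pressure <- function(series, window = 1) {
  if (!is.data.frame(series) || !all(c("time", "value") %in% names(series))) {
    stop("`series` must have `time` and `value` columns.", call. = FALSE)
  }
  n <- nrow(series)
  if (n < 3L) stop("need at least 3 samples.", call. = FALSE)
  tt <- series$time
  vv <- series$value
  span <- tt[n] - tt[1]
  if (window > span) {
    stop("smoothing `window` is longer than the series.", call. = FALSE)
  }
  dt <- stats::median(diff(tt))
  half <- max(0L, floor(window / dt / 2))
  # centred moving average, window shrinking symmetrically at the edges
  cs <- cumsum(c(0, vv))
  sm <- vapply(seq_len(n), function(i) {
    h <- min(half, i - 1L, n - i)
    (cs[i + h + 1] - cs[i - h]) / (2 * h + 1)
  }, numeric(1))
  imin <- which.min(sm) # which.min takes the earliest tie
  tibble::tibble(
    min_pressure = sm[imin],
    time_at_min = tt[imin],
    boundary = imin == 1L || imin == n,
    window = window
  )
}

#' Linear volumetric strain schedule
#'
#' Hydrostatic tension is imposed by expanding the system volume at a
#' constant volumetric strain rate, so the strain is linear in time:
#' `eps_v(t) = rate * t`. Two schedules reach the same final strain when
#' `rate * duration` matches -- e.g. the standard X rate (6.7e9 1/s) held for
#' 60 ps and the 2X rate (1.35e10 1/s) held for 30 ps expand the system by
#' the same fraction to within 1%.
#'
#' @param rate Volumetric strain rate in 1/s (> 0).
#' @param duration Schedule duration in ps (> 0).
#' @param n Number of samples (default 121).
#' @return A [scalar_series()] of dimensionless volumetric strain vs time
#'   (ps), with attribute `final_strain`.
#' @export
#' @examples
#' attr(volume_strain_schedule(6.7e9, 60), "final_strain")
volume_strain_schedule <- function(rate, duration, n = 121) {
  if (rate <= 0) stop("`rate` must be positive (1/s).", call. = FALSE)
  if (duration < 0) stop("`duration` must be non-negative (ps).", call. = FALSE)
  if (duration == 0) {
    out <- scalar_series(0, 0, unit = "volumetric strain")
    attr(out, "final_strain") <- 0
    return(out)
  }
  tt <- seq(0, duration, length.out = n)
  out <- scalar_series(tt, rate * tt * 1e-12, unit = "volumetric strain")
  attr(out, "final_strain") <- rate * duration * 1e-12
  out
}

#' System-volume bookkeeping during bubble growth
#'
#' The system volume decomposes as
#' `V_system = V_water + V_network + V_bubble`: water is nearly
#' incompressible and the immersed polymer network does not expand, so once
#' growth is under way essentially all additional system volume goes into the
#' bubble. Solves the decomposition for the bubble volume and its equivalent
#' spherical radius.
#'
#' @param v_system,v_water,v_network Volumes in A^3 (network defaults to 0
#'   for a pure-water system).
#' @param tol Accounting tolerance: a residual more negative than
#'   `-tol * v_system` is an error (default 1e-3).
#' @return A one-row tibble: `v_system`, `v_water`, `v_network`, `v_bubble`,
#'   `bubble_radius` (A).
#' @export
#' @examples
#' volume_decomposition(7.5e6, 7.0e6, 1e5)
volume_decomposition <- function(v_system, v_water, v_network = 0, tol = 1e-3) {
  if (any(c(v_system, v_water, v_network) < 0)) {
    stop("volumes must be non-negative.", call. = FALSE)
  }
  v_bubble <- v_system - v_water - v_network
  if (any(v_bubble < -tol * v_system)) {
    stop("accounting error: V_water + V_network exceeds V_system.", call. = FALSE)
  }
  v_bubble <- pmax(v_bubble, 0)
  tibble::tibble(
    v_system = v_system, v_water = v_water, v_network = v_network,
    v_bubble = v_bubble,
    bubble_radius = (3 * v_bubble / (4 * pi))^(1 / 3)
  )
}
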