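#' Per-frame growth analysis of a cavitation trajectory
#'
#' Runs the full per-frame estimator chain over a trajectory: cavity
#' detection ([detect_cavity()]) and surface metrics ([cavity_metrics()]),
#' global virial pressure ([global_pressure()], when the frames carry
#' per-atom stress), and condensed-phase density excluding the cavity volume
#' ([density_excluding_cavity()]). The aligned series expose the three
#' regions of bubble growth -- slow surface-tension-limited onset, sharp
#' negative-pressure rise, then stabilisation -- and feed
#' [threshold_pressure()] for the threshold summary.
#'
#' @param traj A [trajectory()].
#' @param grid_spacing,probe_radius,min_volume Cavity-detection parameters
#'   (A; see [detect_cavity()]).
#' @param smoothing_window Threshold smoothing window, ps.
#' @param species Optional species filter for the pressure sum.
#'
#' @return An object of class `growth_analysis`: a list with `frames` (a
#'   per-frame tibble: `time`, `pressure`, `volume_c`, `radius`,
#'   `sphericity`, `density`, `n_secondary`), the individual
#'   [scalar_series()] (`pressure`, `radius`, `sphericity`, `density`), and
#'   `threshold` (one-row tibble, or `NULL` without stress data).
#' @export
#' @examples
#' sched <- data.frame(time = seq(0, 4, 2), radius = c(15, 16, 17))
#' traj <- make_growth_trajectory(sched, box = c(70, 70, 70), seed = 2)
#' ga <- growth_analysis(traj, grid_spacing = 2.5)
#' ga$frames
growth_analysis <- function(traj, grid_spacing = 2, probe_radius = 3,
                            min_volume = 200, smoothing_window = 1,
                            species = NULL) {
  stopifnot(inherits(traj, "trajectory"))
  frames_list <- unclass(traj)
  rows <- lapply(seq_along(frames_list), function(i) {
    fr <- frames_list[[i]]
    tryCatch({
      has_stress <- all(c("sxx", "syy", "szz") %in% names(fr))
      pres <- if (has_stress) {
        if (!"voro_vol" %in% names(fr)) fr <- voronoi_volumes(fr, grid_spacing)
        global_pressure(fr, species = species)$pressure
      } else {
        NA_real_
      }
      cav <- detect_cavity(fr, grid_spacing = grid_spacing,
                           probe_radius = probe_radius,
                           min_volume = min_volume)
      if (cav$found) {
        cm <- cavity_metrics(cav)
        vol <- cm$volume_c
        rad <- cm$effective_radius
        psi <- cm$sphericity
      } else {
        vol <- 0
        rad <- 0
        psi <- NA_real_
      }
      tibble::tibble(
        time = frame_time(fr), pressure = pres, volume_c = vol,
        radius = rad, sphericity = psi,
        density = density_excluding_cavity(fr, vol),
        n_secondary = cav$n_secondary
      )
    }, error = function(e) {
      stop(sprintf("frame %d (t = %g ps): %s", i, frame_time(fr),
                   conditionMessage(e)), call. = FALSE)
    })
  })
  frames <- dplyr::bind_rows(rows)
  mk <- function(col, unit) scalar_series(frames$time, frames[[col]], unit)
  out <- list(
    frames = frames,
    pressure = if (all(is.na(frames$pressure))) NULL else mk("pressure", "MPa"),
    radius = mk("radius", "A"),
    sphericity = mk("sphericity", ""),
    density = mk("density", "g/cm^3"),
    threshold = NULL
  )
  if (!is.null(out$pressure) && nrow(frames) >= 3 &&
      diff(range(frames$time)) >= smoothing_window) {
    out$threshold <- threshold_pressure(out$pressure, window = smoothing_window)
  }
  structure(out, class = "growth_analysis")
}

#' @export
tidy.growth_analysis <- function(x, ...) x$frames

#' @export
autoplot.growth_analysis <- function(object, ...) {
  long <- tidyr::pivot_longer(
    object$frames[, c("time", "pressure", "radius", "sphericity", "density")],
    -"time", names_to = "quantity", values_to = "value"
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~quantity, scales = "free_y") +
    ggplot2::labs(x = "time (ps)", y = NULL,
                  title = "Cavitation bubble growth analysis")
}

#' Measured vs Rayleigh-Plesset collapse comparison
#'
#' Extracts the cavity-radius history of a (collapsing) trajectory and
#' integrates the Rayleigh-Plesset equation for the same initial radius under
#' the configured medium and driving pressure, reporting both collapse times
#' and their ratio. With the water and gel presets under the same driving
#' pressure, the gel bubble outlives the water bubble because collapse time
#' is dominated by viscosity.
#'
#' The measured collapse time is taken where the measured radius history
#' first falls below `collapse_frac` of its initial value (linear
#' interpolation between frames), or when no cavity is detected any more.
#'
#' @param traj A [trajectory()] of a shrinking cavity.
#' @param medium A [fluid_medium()].
#' @param delta_p Constant driving pressure `P_ext - P_b` in Pa (> 0 drives
#'   collapse).
#' @param grid_spacing,probe_radius,min_volume Cavity-detection parameters.
#' @param collapse_frac Collapse threshold fraction (default 0.25; radii
#'   below the probe scale cannot be resolved on the grid, so a conservative
#'   fraction is used for the measured trace).
#' @return A list of class `collapse_analysis`: `measured` (radius
#'   [scalar_series()], A vs ps), `rp` (an `rp_solution`),
#'   `collapse_time_measured` (ps), `collapse_time_rp` (ps), `ratio`
#'   (measured / predicted).
#' @export
analyze_collapse <- function(traj, medium, delta_p,
                             grid_spacing = 2, probe_radius = 3,
                             min_volume = 200, collapse_frac = 0.25) {
  stopifnot(inherits(traj, "trajectory"))
  medium <- as_medium(medium)
  ga <- growth_analysis(traj, grid_spacing = grid_spacing,
                        probe_radius = probe_radius, min_volume = min_volume)
  rad <- ga$frames$radius
  tms <- ga$frames$time
  if (rad[1] <= 0) stop("no cavity detected in the first frame.", call. = FALSE)
  r0_m <- rad[1] * 1e-10
  # nanoscale collapse is viscously retarded, so allow the prediction ample
  # time beyond the measured trace
  horizon <- (tms[length(tms)] - tms[1]) * 1e-12 * 20
  rp <- solve_rp(medium, radius0 = r0_m,
                 schedule = pressure_schedule(delta_p), horizon = horizon,
                 collapse_frac = 0.01)
  thresh <- collapse_frac * rad[1]
  below <- which(rad < thresh)
  ct_meas <- if (length(below)) {
    i <- below[1]
    if (i == 1L) {
      tms[1]
    } else {
      # linear interpolation between the bracketing frames
      tms[i - 1] + (tms[i] - tms[i - 1]) *
        (rad[i - 1] - thresh) / (rad[i - 1] - rad[i])
    }
  } else {
    NA_real_
  }
  ct_rp <- attr(rp, "collapse_time")
  ct_rp_ps <- if (is.na(ct_rp)) NA_real_ else ct_rp * 1e12
  structure(list(
    measured = ga$radius,
    rp = rp,
    collapse_time_measured = ct_meas,
    collapse_time_rp = ct_rp_ps,
    ratio = ct_meas / ct_rp_ps,
    medium = medium$name
  ), class = "collapse_analysis")
}

#' @export
glance.collapse_analysis <- function(x, ...) {
  tibble::tibble(
    medium = x$medium,
    collapse_time_measured = x$collapse_time_measured,
    collapse_time_rp = x$collapse_time_rp,
    ratio = x$ratio
  )
}

#' @export
autoplot.scalar_series <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$time, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (ps)", y = series_unit(object))
}
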