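#' Construct a particle frame (one trajectory snapshot)
#'
#' A particle frame is a tidy table of particles at one instant inside an
#' orthorhombic, fully periodic box: coordinates in Angstrom, masses in amu,
#' plus optional per-atom virial stress components (in the stress x volume
#' convention of MD dumps, atm.A^3) and per-atom tessellation volumes (A^3).
#'
#' @param coords Data frame or N x 3 matrix of coordinates (A), columns
#'   `x`, `y`, `z`.
#' @param box Length-3 numeric: box edge lengths (A); origin at 0, periodic
#'   in all directions.
#' @param time Frame time in ps.
#' @param mass Per-particle masses (amu), recycled; default 18.0 (a
#'   water-like bead).
#' @param species Per-particle labels, recycled; default `"W"`.
#' @param stress Optional N x 6 matrix or data frame of per-atom stress
#'   components, columns (or order) `sxx, syy, szz, sxy, sxz, syz`, atm.A^3.
#' @param volume Optional per-atom volumes (A^3).
#' @param id Optional particle identifiers (default `1:N`).
#'
#' @return A tibble of class `particle_frame` with one row per particle and
#'   attributes `box` and `time`.
#' @export
#' @examples
#' particle_frame(cbind(x = runif(10, 0, 20), y = runif(10, 0, 20),
#'                      z = runif(10, 0, 20)), box = c(20, 20, 20))
particle_frame <- function(coords, box, time = 0, mass = 18.0, species = "W",
                           stress = NULL, volume = NULL, id = NULL) {
  coords <- as.data.frame(coords)
  if (ncol(coords) < 3L) stop("`coords` needs three columns (x, y, z).", call. = FALSE)
  names(coords)[1:3] <- c("x", "y", "z")
  n <- nrow(coords)
  if (n < 1L) stop("a particle frame needs at least one particle.", call. = FALSE)
  if (!is.numeric(box) || length(box) != 3L || any(box <= 0)) {
    stop("`box` must be three positive edge lengths (A).", call. = FALSE)
  }
  if (any(!is.finite(as.matrix(coords[, 1:3])))) {
    stop("coordinates must be finite.", call. = FALSE)
  }
  out <- tibble::tibble(
    id = if (is.null(id)) seq_len(n) else id,
    x = coords$x, y = coords$y, z = coords$z,
    mass = rep_len(mass, n), species = rep_len(species, n)
  )
  if (!is.null(stress)) {
    stress <- as.data.frame(stress)
    if (nrow(stress) != n || ncol(stress) != 6L) {
      stop("`stress` must have exactly N rows and 6 columns (sxx..syz).", call. = FALSE)
    }
    names(stress) <- c("sxx", "syy", "szz", "sxy", "sxz", "syz")
    out <- dplyr::bind_cols(out, tibble::as_tibble(stress))
  }
  if (!is.null(volume)) {
    if (length(volume) != n) stop("`volume` must have exactly N values.", call. = FALSE)
    out$voro_vol <- as.numeric(volume)
  }
  structure(out, class = c("particle_frame", class(out)),
            box = as.numeric(box), time = as.numeric(time))
}

#' @rdname particle_frame
#' @param frame A `particle_frame`.
#' @export
frame_box <- function(frame) attr(frame, "box")

#' @rdname particle_frame
#' @export
frame_time <- function(frame) attr(frame, "time")

#' @rdname particle_frame
#' @export
box_volume <- function(frame) prod(attr(frame, "box"))

#' Assemble particle frames into a trajectory
#'
#' A trajectory is a list of [particle_frame()]s with strictly increasing
#' times, a constant box and constant particle identity. Particle identity is
#' matched on the `id` column, so frames may drop particles (e.g. atoms
#' removed when a cavity is carved) as long as ids are stable.
#'
#' @param frames A list of `particle_frame` objects.
#' @return An object of class `trajectory` (a list of frames with attributes).
#' @export
#' @examples
#' f <- particle_frame(cbind(x = 1, y = 1, z = 1), box = c(10, 10, 10))
#' g <- particle_frame(cbind(x = 2, y = 1, z = 1), box = c(10, 10, 10), time = 1)
#' trajectory(list(f, g))
trajectory <- function(frames) {
  if (!length(frames)) stop("a trajectory needs at least one frame.", call. = FALSE)
  ok <- vapply(frames, inherits, logical(1), "particle_frame")
  if (!all(ok)) stop("all elements must be particle_frame objects.", call. = FALSE)
  tms <- vapply(frames, frame_time, numeric(1))
  if (length(tms) > 1L && any(diff(tms) <= 0)) {
    stop("frame times must be strictly increasing.", call. = FALSE)
  }
  structure(frames, class = "trajectory", times = tms)
}

#' @rdname trajectory
#' @param traj A `trajectory`.
#' @export
trajectory_times <- function(traj) attr(traj, "times")

#' @rdname trajectory
#' @export
n_frames <- function(traj) length(unclass(traj))

#' Flatten a trajectory to one long tibble
#'
#' @param x A `trajectory`.
#' @param ... Unused.
#' @return A tibble with a `time` column plus the per-particle columns.
#' @export
tidy.trajectory <- function(x, ...) {
  dplyr::bind_rows(lapply(unclass(x), function(f) {
    dplyr::mutate(tibble::as_tibble(f), time = frame_time(f), .before = 1)
  }))
}

# minimum-image displacement between coordinate matrices (per column box)
minimum_image <- function(d, box) {
  for (k in 1:3) d[, k] <- d[, k] - box[k] * round(d[, k] / box[k])
  d
}

# wrap coordinates into [0, box)
wrap_coords <- function(m, box) {
  for (k in 1:3) m[, k] <- m[, k] %% box[k]
  m
}
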