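#' Global virial pressure from per-atom stress
#'
#' Computes the instantaneous global pressure of a frame from per-atom virial
#' stress in the stress-times-volume convention of MD dumps:
#' `P = (sum sxx + sum syy + sum szz) / (3 * sum v_i)`, where `v_i` are the
#' per-atom (Voronoi) volumes. Off-diagonal components do not contribute.
#' Input stress is atm.A^3 and volumes A^3; the result is reported in MPa
#' with tension negative.
#'
#' @param frame A [particle_frame()] with per-atom stress columns
#'   (`sxx, syy, szz, ...`) and a `voro_vol` column (add one with
#'   [voronoi_volumes()] if the dump did not carry volumes).
#' @param species Optional character vector: restrict the sums to particles
#'   of these species (e.g. pressure carried by the water only, or by the
#'   collagen network only).
#'
#' @return A one-row tibble with columns `time` (ps), `pressure` (MPa) and
#'   `n_atoms`.
#' @export
#' @examples
#' f <- particle_frame(cbind(x = 5, y = 5, z = 5), box = c(10, 10, 10),
#'                     stress = matrix(c(rep(-1000, 3), rep(0, 3)), 1),
#'                     volume = 1000)
#' global_pressure(f)
global_pressure <- function(frame, species = NULL) {
  stopifnot(inherits(frame, "particle_frame"))
  need <- c("sxx", "syy", "szz")
  missing_cols <- setdiff(need, names(frame))
  if (length(missing_cols)) {
    stop("frame has no per-atom stress (missing: ",
         paste(missing_cols, collapse = ", "), ").", call. = FALSE)
  }
  if (!"voro_vol" %in% names(frame)) {
    stop("frame has no per-atom volumes (missing: voro_vol); ",
         "run voronoi_volumes() first.", call. = FALSE)
  }
  d <- frame
  if (!is.null(species)) d <- d[d$species %in% species, , drop = FALSE]
  if (!nrow(d)) stop("no particles left after species selection.", call. = FALSE)
  p_atm <- (sum(d$sxx) + sum(d$syy) + sum(d$szz)) / (3 * sum(d$voro_vol))
  tibble::tibble(
    time = frame_time(frame),
    pressure = p_atm * .atm_MPa,
    n_atoms = nrow(d)
  )
}
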