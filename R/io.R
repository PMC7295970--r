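#' Read and write particle trajectories (LAMMPS text dump, extended XYZ)
#'
#' `read_trajectory()` sniffs or is told the format and parses a LAMMPS text
#' dump (`ITEM: TIMESTEP / NUMBER OF ATOMS / BOX BOUNDS / ATOMS` with named
#' columns, including optional `c_stress[1..6]` per-atom stress and
#' `c_voro[1]` per-atom volume columns) or an extended XYZ file (with a
#' `Lattice="..."` comment line) into a [trajectory()]. `write_trajectory()`
#' writes either format losslessly for the supported fields, so
#' `write -> read` round-trips. Only orthorhombic boxes are supported;
#' triclinic `BOX BOUNDS xy xz yz` headers are rejected.
#'
#' @param path File path.
#' @param format `"auto"`, `"lammps"` or `"xyz"`.
#' @return `read_trajectory()` returns a [trajectory()].
#' @export
read_trajectory <- function(path, format = c("auto", "lammps", "xyz")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  if (!length(lines)) stop("empty trajectory file: ", path, call. = FALSE)
  if (format == "auto") {
    format <- if (startsWith(lines[1], "ITEM:")) "lammps" else "xyz"
  }
  frames <- switch(format,
    lammps = parse_lammps_dump(lines, path),
    xyz = parse_extended_xyz(lines, path)
  )
  trajectory(frames)
}

parse_error <- function(path, line, msg) {
  stop(sprintf("%s:%d: %s", path, line, msg), call. = FALSE)
}

.lammps_columns <- c(
  id = "id", element = "species", type = "species", mass = "mass",
  x = "x", y = "y", z = "z",
  `c_stress[1]` = "sxx", `c_stress[2]` = "syy", `c_stress[3]` = "szz",
  `c_stress[4]` = "sxy", `c_stress[5]` = "sxz", `c_stress[6]` = "syz",
  `c_voro[1]` = "voro_vol", ix = "ix", iy = "iy", iz = "iz"
)

parse_lammps_dump <- function(lines, path) {
  i <- 1L
  n_lines <- length(lines)
  frames <- list()
  while (i <= n_lines) {
    if (!grepl("^ITEM: TIMESTEP", lines[i])) {
      parse_error(path, i, "expected 'ITEM: TIMESTEP'")
    }
    tstep <- suppressWarnings(as.numeric(lines[i + 1L]))
    if (is.na(tstep)) parse_error(path, i + 1L, "unreadable timestep")
    if (!grepl("^ITEM: NUMBER OF ATOMS", lines[i + 2L])) {
      parse_error(path, i + 2L, "expected 'ITEM: NUMBER OF ATOMS'")
    }
    nat <- suppressWarnings(as.integer(lines[i + 3L]))
    if (is.na(nat) || nat < 1L) parse_error(path, i + 3L, "unreadable atom count")
    bb <- lines[i + 4L]
    if (!grepl("^ITEM: BOX BOUNDS", bb)) {
      parse_error(path, i + 4L, "expected 'ITEM: BOX BOUNDS'")
    }
    if (grepl("xy|xz|yz", bb)) {
      parse_error(path, i + 4L, "triclinic boxes are not supported")
    }
    box <- numeric(3)
    for (k in 1:3) {
      parts <- strsplit(trimws(lines[i + 4L + k]), "\\s+")[[1]]
      lohi <- suppressWarnings(as.numeric(parts[1:2]))
      if (any(is.na(lohi))) parse_error(path, i + 4L + k, "unreadable box bounds")
      box[k] <- lohi[2] - lohi[1]
    }
    ah <- lines[i + 8L]
    if (!grepl("^ITEM: ATOMS", ah)) parse_error(path, i + 8L, "expected 'ITEM: ATOMS'")
    cols <- strsplit(trimws(sub("^ITEM: ATOMS", "", ah)), "\\s+")[[1]]
    unknown <- setdiff(cols, names(.lammps_columns))
    if (length(unknown)) {
      parse_error(path, i + 8L, paste0("unknown columns: ",
                                       paste(unknown, collapse = ", ")))
    }
    body <- lines[i + 8L + seq_len(nat)]
    if (length(body) < nat || any(is.na(body)) ||
        any(startsWith(body, "ITEM:"))) {
      parse_error(path, i + 8L + nat,
                  "frame truncated: fewer atom lines than the declared count")
    }
    tok <- strsplit(trimws(body), "\\s+")
    bad <- which(lengths(tok) != length(cols))
    if (length(bad)) {
      parse_error(path, i + 8L + bad[1], "wrong number of fields on atom line")
    }
    m <- do.call(rbind, tok)
    df <- as.data.frame(m, stringsAsFactors = FALSE)
    names(df) <- .lammps_columns[cols]
    for (nm in setdiff(names(df), "species")) df[[nm]] <- as.numeric(df[[nm]])
    need <- c("x", "y", "z")
    if (!all(need %in% names(df))) {
      parse_error(path, i + 8L, "ATOMS must include x y z columns")
    }
    stress <- NULL
    if (all(c("sxx", "syy", "szz", "sxy", "sxz", "syz") %in% names(df))) {
      stress <- df[, c("sxx", "syy", "szz", "sxy", "sxz", "syz")]
    }
    fr <- particle_frame(
      df[, c("x", "y", "z")], box = box, time = tstep,
      mass = if ("mass" %in% names(df)) df$mass else 18.0,
      species = if ("species" %in% names(df)) as.character(df$species) else "W",
      stress = stress,
      volume = if ("voro_vol" %in% names(df)) df$voro_vol else NULL,
      id = if ("id" %in% names(df)) df$id else NULL
    )
    for (im in c("ix", "iy", "iz")) if (im %in% names(df)) fr[[im]] <- df[[im]]
    frames[[length(frames) + 1L]] <- fr
    i <- i + 9L + nat
    while (i <= n_lines && !nzchar(trimws(lines[i]))) i <- i + 1L
  }
  frames
}

parse_extended_xyz <- function(lines, path) {
  i <- 1L
  frames <- list()
  while (i <= length(lines)) {
    nat <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(nat) || nat < 1L) parse_error(path, i, "unreadable atom count")
    comment <- lines[i + 1L]
    lat <- regmatches(comment, regexec('Lattice="([^"]+)"', comment))[[1]]
    if (length(lat) < 2L) parse_error(path, i + 1L, 'missing Lattice="..."')
    lv <- as.numeric(strsplit(trimws(lat[2]), "\\s+")[[1]])
    if (length(lv) != 9L) parse_error(path, i + 1L, "Lattice needs 9 numbers")
    if (any(abs(lv[c(2, 3, 4, 6, 7, 8)]) > 1e-12)) {
      parse_error(path, i + 1L, "triclinic boxes are not supported")
    }
    box <- lv[c(1, 5, 9)]
    tm <- regmatches(comment, regexec("Time=([0-9eE.+-]+)", comment))[[1]]
    time <- if (length(tm) >= 2L) as.numeric(tm[2]) else length(frames)
    body <- lines[i + 1L + seq_len(nat)]
    if (length(body) < nat || any(is.na(body))) {
      parse_error(path, i + 1L + nat, "frame truncated")
    }
    tok <- strsplit(trimws(body), "\\s+")
    if (any(lengths(tok) < 4L)) {
      parse_error(path, i + 1L + which(lengths(tok) < 4L)[1],
                  "atom line needs species x y z")
    }
    sp <- vapply(tok, `[[`, character(1), 1L)
    xyz <- t(vapply(tok, function(p) as.numeric(p[2:4]), numeric(3)))
    frames[[length(frames) + 1L]] <- particle_frame(
      xyz, box = box, time = time, species = sp
    )
    i <- i + 2L + nat
    while (i <= length(lines) && !nzchar(trimws(lines[i]))) i <- i + 1L
  }
  frames
}

#' @rdname read_trajectory
#' @param traj A [trajectory()] or a single [particle_frame()].
#' @export
write_trajectory <- function(traj, path, format = c("lammps", "xyz")) {
  format <- match.arg(format)
  if (inherits(traj, "particle_frame")) traj <- trajectory(list(traj))
  stopifnot(inherits(traj, "trajectory"))
  con <- file(path, "w")
  on.exit(close(con))
  for (fr in unclass(traj)) {
    box <- frame_box(fr)
    if (format == "lammps") {
      has_stress <- all(c("sxx", "syy", "szz", "sxy", "sxz", "syz") %in% names(fr))
      has_vol <- "voro_vol" %in% names(fr)
      cols <- c("id", "element", "mass", "x", "y", "z",
                if (has_stress) sprintf("c_stress[%d]", 1:6),
                if (has_vol) "c_voro[1]")
      writeLines(c(
        "ITEM: TIMESTEP", base::format(frame_time(fr), digits = 15),
        "ITEM: NUMBER OF ATOMS", as.character(nrow(fr)),
        "ITEM: BOX BOUNDS pp pp pp",
        sprintf("0 %.10g", box[1]), sprintf("0 %.10g", box[2]),
        sprintf("0 %.10g", box[3]),
        paste("ITEM: ATOMS", paste(cols, collapse = " "))
      ), con)
      num <- function(v) vapply(v, base::format, character(1), digits = 15)
      m <- cbind(
        num(fr$id), fr$species, num(fr$mass), num(fr$x), num(fr$y), num(fr$z),
        if (has_stress) vapply(fr[c("sxx", "syy", "szz", "sxy", "sxz", "syz")],
                               num, character(nrow(fr))),
        if (has_vol) num(fr$voro_vol)
      )
      writeLines(apply(m, 1, paste, collapse = " "), con)
    } else {
      writeLines(as.character(nrow(fr)), con)
      writeLines(sprintf(
        'Lattice="%.10g 0 0 0 %.10g 0 0 0 %.10g" Properties=species:S:1:pos:R:3 Time=%.10g',
        box[1], box[2], box[3], frame_time(fr)
      ), con)
      writeLines(sprintf("%s %.10g %.10g %.10g", fr$species, fr$x, fr$y, fr$z),
                 con)
    }
  }
  invisible(path)
}

#' Write / read a scalar series as CSV with a unit header
#'
#' The CSV carries a `# unit: <label>` comment line before the header, so a
#' series round-trips with its unit.
#'
#' @param series A [scalar_series()].
#' @param path File path.
#' @export
write_series_csv <- function(series, path) {
  stopifnot(is.data.frame(series), all(c("time", "value") %in% names(series)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# unit: ", attr(series, "unit") %||% ""), con)
  utils::write.csv(as.data.frame(series)[, c("time", "value")], con,
                   row.names = FALSE)
  invisible(path)
}

#' @rdname write_series_csv
#' @export
read_series_csv <- function(path) {
  lines <- readLines(path, warn = FALSE)
  unit <- ""
  skip <- 0L
  if (length(lines) && startsWith(lines[1], "# unit:")) {
    unit <- trimws(sub("^# unit:", "", lines[1]))
    skip <- 1L
  }
  df <- utils::read.csv(text = paste(lines[(skip + 1L):length(lines)],
                                     collapse = "\n"))
  scalar_series(df$time, df$value, unit = unit)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Analysis run configuration
#'
#' All analysis parameters with their defaults, optionally overridden from a
#' YAML file and/or an override list (precedence: overrides > file >
#' defaults). A fully defaulted configuration is sufficient to run the demo
#' pipeline end to end.
#'
#' @param path Optional YAML file.
#' @param overrides Optional named list of overrides.
#' @return A named list of class `run_config`.
#' @export
#' @examples
#' run_config(overrides = list(grid_spacing = 1.5))$grid_spacing
run_config <- function(path = NULL, overrides = list()) {
  cfg <- list(
    grid_spacing = 2, probe_radius = 3, min_volume = 200,
    smoothing_window = 1, fit_window = c(0.2, 0.8), cutoff = NULL,
    collapse_frac = 0.01, medium = "water", seed = 1,
    output_dir = ".", log_level = "info"
  )
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
    file_cfg <- yaml::read_yaml(path)
    cfg[names(file_cfg)] <- file_cfg
  }
  cfg[names(overrides)] <- overrides
  structure(cfg, class = "run_config")
}
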