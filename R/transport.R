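# FFT-accelerated mean of x_k x_{k+m} over all time origins, for one signal
fft_origin_products <- function(x) {
  n <- length(x)
  nfft <- 2^ceiling(log2(2 * n))
  fx <- stats::fft(c(x, rep(0, nfft - n)))
  s2 <- Re(stats::fft(fx * Conj(fx), inverse = TRUE))[1:n] / nfft
  s2 # S2(m) = sum_{k} x_k x_{k+m}, m = 0..n-1
}

# MSD of one coordinate signal over all origins (Kneller recursion + FFT)
msd_1d <- function(x) {
  n <- length(x)
  d <- x^2
  s2 <- fft_origin_products(x)
  s1 <- numeric(n)
  s1[1] <- 2 * sum(d)
  for (m in 2:n) s1[m] <- s1[m - 1] - d[m - 1] - d[n - m + 2]
  (s1 - 2 * s2) / (n:1)
}

#' Mean-square displacement of a trajectory
#'
#' `MSD(tau) = < |r(t + tau) - r(t)|^2 >`, averaged over every available time
#' origin and over the selected particles, computed with the FFT-based
#' all-origins algorithm (O(n log n) per particle). Coordinates must be
#' unwrapped: if the trajectory carries periodic image flags (`ix, iy, iz`
#' columns) they are applied; otherwise a frame-to-frame jump larger than
#' half a box edge raises an error asking for unwrap information.
#'
#' @param traj A [trajectory()].
#' @param species Optional species selection (default: all particles).
#' @param max_lag Largest lag in ps (default: half the trajectory span, the
#'   usual point beyond which origin averaging is too poor to use).
#' @return A [scalar_series()] (lag time ps vs MSD A^2) of class
#'   `msd_series`, with attributes `n_particles` and `dt`.
#' @export
#' @examples
#' traj <- make_brownian_trajectory(n_particles = 50, n_steps = 100,
#'                                  dt = 0.1, D = 1e-9, seed = 1)
#' m <- msd(traj)
#' diffusion_coefficient(m)
msd <- function(traj, species = NULL, max_lag = NULL) {
  stopifnot(inherits(traj, "trajectory"))
  frames_list <- unclass(traj)
  nf <- length(frames_list)
  if (nf < 2L) stop("need at least 2 frames.", call. = FALSE)
  tms <- trajectory_times(traj)
  dts <- diff(tms)
  if (max(dts) - min(dts) > 1e-9 * max(dts)) {
    stop("MSD requires equally spaced frames.", call. = FALSE)
  }
  dt <- dts[1]
  box <- frame_box(frames_list[[1]])
  long <- tidy(traj)
  if (!is.null(species)) long <- long[long$species %in% species, , drop = FALSE]
  counts <- table(long$id)
  keep_ids <- as.numeric(names(counts)[counts == nf])
  if (!length(keep_ids)) stop("no particles present in every frame.", call. = FALSE)
  long <- long[long$id %in% keep_ids, , drop = FALSE]
  long <- long[order(long$id, long$time), , drop = FALSE]
  np <- length(keep_ids)
  has_images <- all(c("ix", "iy", "iz") %in% names(long))
  acc <- NULL
  for (ax in c("x", "y", "z")) {
    m <- matrix(long[[ax]], nrow = nf, ncol = np)
    if (has_images) {
      img <- matrix(long[[c(x = "ix", y = "iy", z = "iz")[ax]]], nrow = nf, ncol = np)
      m <- m + img * box[c(x = 1, y = 2, z = 3)[ax]]
    } else {
      jump <- max(abs(diff(m)))
      if (jump > box[c(x = 1, y = 2, z = 3)[ax]] / 2) {
        stop("coordinates appear wrapped (jump > box/2) and no image flags ",
             "(ix, iy, iz) are present; provide unwrapped coordinates.",
             call. = FALSE)
      }
    }
    ax_msd <- rowMeans(apply(m, 2, msd_1d))
    acc <- if (is.null(acc)) ax_msd else acc + ax_msd
  }
  lags <- (seq_len(nf) - 1) * dt
  if (is.null(max_lag)) max_lag <- lags[nf] / 2
  keep <- lags <= max_lag
  out <- scalar_series(lags[keep], acc[keep], unit = "A^2")
  class(out) <- c("msd_series", class(out))
  attr(out, "n_particles") <- np
  attr(out, "dt") <- dt
  out
}

#' Diffusion coefficient from an MSD series
#'
#' For 3D diffusion `MSD = 6 D tau`, so the diffusion coefficient is one
#' sixth of the MSD slope. The slope is a least-squares fit over a window of
#' the lag axis (default the central 20-80%, where origin statistics are good
#' and the ballistic transient is over). A log-log exponent `alpha` is fitted
#' alongside as a diagnostic: `alpha ~ 1` for diffusive motion, `~ 2` for
#' ballistic; the estimate is flagged non-diffusive when `|alpha - 1| > 0.3`.
#'
#' @param msd_series An [msd()] result (or scalar series, lag ps vs A^2).
#' @param fit_window Two fractions of the maximum lag delimiting the fit
#'   window (default `c(0.2, 0.8)`).
#' @return A one-row tibble of class `transport_estimate`: `value` (m^2/s),
#'   `standard_error`, `unit`, `method`, `alpha`, `diffusive`, `n_points`.
#' @export
diffusion_coefficient <- function(msd_series, fit_window = c(0.2, 0.8)) {
  stopifnot(is.data.frame(msd_series), all(c("time", "value") %in% names(msd_series)))
  if (length(fit_window) != 2L || fit_window[1] >= fit_window[2]) {
    stop("`fit_window` must be two increasing fractions.", call. = FALSE)
  }
  tmax <- max(msd_series$time)
  sel <- msd_series$time >= fit_window[1] * tmax &
    msd_series$time <= fit_window[2] * tmax
  d <- msd_series[sel, , drop = FALSE]
  if (nrow(d) < 3L) stop("fit window contains fewer than 3 points.", call. = FALSE)
  fit <- stats::lm(value ~ time, data = d)
  slope <- stats::coef(fit)[["time"]]
  se <- summary(fit)$coefficients["time", "Std. Error"]
  pos <- d$time > 0 & d$value > 0
  alpha <- if (sum(pos) >= 3 && slope > 0) {
    stats::coef(stats::lm(log(value) ~ log(time), data = d[pos, ]))[[2]]
  } else {
    NA_real_
  }
  out <- tibble::tibble(
    value = slope / 6 * .A2ps_to_m2s,
    standard_error = se / 6 * .A2ps_to_m2s,
    unit = "m^2/s",
    method = "msd-slope/6",
    alpha = alpha,
    diffusive = is.finite(alpha) && abs(alpha - 1) <= 0.3,
    n_points = nrow(d)
  )
  class(out) <- c("transport_estimate", class(out))
  out
}

# unnormalised autocorrelation over all origins: C(m) = mean_k x_k x_{k+m}
acf_all_origins <- function(x, max_lag_steps) {
  n <- length(x)
  s2 <- fft_origin_products(x)
  (s2 / (n:1))[1:(max_lag_steps + 1)]
}

#' Green-Kubo shear viscosity from off-diagonal stress fluctuations
#'
#' `eta = V / (kB T) * integral_0^cutoff <P_ab(0) P_ab(t)> dt`, with the
#' autocorrelation averaged over the supplied independent off-diagonal stress
#' components and over all time origins, and the integral taken by the
#' trapezoidal rule. The cutoff defaults to 10x the estimated stress
#' autocorrelation time (integral of the normalised autocorrelation to its
#' first zero crossing); by then the integrand has decayed and further
#' integration only accumulates noise. The standard error comes from block
#' averaging over `n_blocks` contiguous blocks.
#'
#' @param stress A data frame: `time` (ps, equally spaced) plus one column
#'   per off-diagonal stress component (MPa), e.g. `pxy, pxz, pyz`.
#' @param volume System volume in A^3.
#' @param temperature Temperature in K.
#' @param cutoff Integration cutoff in ps (default: 10x the estimated
#'   autocorrelation time). Must be under a tenth of the series length.
#' @param n_blocks Blocks for the error estimate (default 5).
#' @return A one-row tibble of class `transport_estimate`: `value` (Pa.s),
#'   `standard_error`, `unit`, `method`, `cutoff`, `n_components`.
#' @export
#' @examples
#' st <- make_ou_stress_series(n_steps = 20000, dt = 0.01, sd_stress = 2,
#'                             tau = 0.2, seed = 1)
#' green_kubo_viscosity(st, volume = 1e6, temperature = 300)
green_kubo_viscosity <- function(stress, volume, temperature, cutoff = NULL,
                                 n_blocks = 5) {
  stopifnot(is.data.frame(stress), "time" %in% names(stress))
  comps <- setdiff(names(stress), "time")
  comps <- comps[vapply(stress[comps], is.numeric, logical(1))]
  if (!length(comps)) stop("no stress component columns found.", call. = FALSE)
  tt <- stress$time
  n <- length(tt)
  if (n < 100L) stop("stress series too short.", call. = FALSE)
  dt <- stats::median(diff(tt))
  span <- tt[n] - tt[1]
  if (is.null(cutoff)) {
    # autocorrelation time from the first component, normalised, to the
    # first zero crossing
    x <- stress[[comps[1]]]
    x <- x - mean(x)
    ac <- acf_all_origins(x, min(n - 1L, 5000L))
    acn <- ac / ac[1]
    zero <- which(acn <= 0)[1]
    upto <- if (is.na(zero)) length(acn) else zero
    tau_est <- max(dt, sum(acn[1:upto]) * dt)
    cutoff <- min(10 * tau_est, span / 10)
  }
  if (cutoff >= span) stop("`cutoff` must be shorter than the series.", call. = FALSE)
  if (cutoff > span / 10 + 1e-12) {
    stop("series must be at least 10x the cutoff for stable averaging.", call. = FALSE)
  }
  mlag <- max(2L, as.integer(round(cutoff / dt)))
  eta_of <- function(rows) {
    integ <- 0
    for (cc in comps) {
      x <- stress[[cc]][rows]
      x <- x - mean(x)
      ac <- acf_all_origins(x, min(length(x) - 1L, mlag))
      # trapezoid over the lag grid, in MPa^2 ps (numerically equal to SI
      # Pa^2 s after the 1e6^2 x 1e-12 unit factors cancel)
      integ <- integ + (sum(ac) - (ac[1] + ac[length(ac)]) / 2) * dt
    }
    integ <- integ / length(comps)
    volume * 1e-30 * integ / (.kB * temperature)
  }
  eta <- eta_of(seq_len(n))
  # block-averaged error
  bl <- floor(n / n_blocks)
  etas <- vapply(seq_len(n_blocks), function(b) {
    eta_of(((b - 1) * bl + 1):(b * bl))
  }, numeric(1))
  out <- tibble::tibble(
    value = eta,
    standard_error = stats::sd(etas) / sqrt(n_blocks),
    unit = "Pa.s",
    method = "green-kubo",
    cutoff = cutoff,
    n_components = length(comps)
  )
  class(out) <- c("transport_estimate", class(out))
  out
}

#' @export
glance.transport_estimate <- function(x, ...) tibble::as_tibble(unclass(x))
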