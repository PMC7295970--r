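# shared fixtures and independent oracles

# closed-form surface area of a prolate spheroid with equatorial radius a and
# polar radius c > a
prolate_area <- function(a, c) {
  e <- sqrt(1 - a^2 / c^2)
  2 * pi * a^2 * (1 + (c / (a * e)) * asin(e))
}

# 12-triangle cube mesh with edge a, outward-oriented
cube_mesh <- function(a = 1) {
  v <- as.matrix(expand.grid(x = c(0, a), y = c(0, a), z = c(0, a)))
  # vertices: 1:(0,0,0) 2:(a,0,0) 3:(0,a,0) 4:(a,a,0) 5:(0,0,a) 6:(a,0,a)
  #           7:(0,a,a) 8:(a,a,a)
  f <- rbind(
    c(1, 3, 2), c(2, 3, 4),   # z = 0 (normal -z)
    c(5, 6, 7), c(6, 8, 7),   # z = a (+z)
    c(1, 2, 5), c(2, 6, 5),   # y = 0 (-y)
    c(3, 7, 4), c(4, 7, 8),   # y = a (+y)
    c(1, 5, 3), c(3, 5, 7),   # x = 0 (-x)
    c(2, 4, 6), c(4, 8, 6)    # x = a (+x)
  )
  triangle_mesh(v, f)
}

# brute-force all-origins MSD (independent O(n^2) oracle for the FFT path)
brute_msd <- function(coords_by_frame) {
  nf <- length(coords_by_frame)
  vapply(0:(nf - 1), function(lag) {
    if (lag == 0) return(0)
    tot <- 0
    cnt <- 0
    for (k in 1:(nf - lag)) {
      d <- coords_by_frame[[k + lag]] - coords_by_frame[[k]]
      tot <- tot + mean(rowSums(d^2))
      cnt <- cnt + 1
    }
    tot / cnt
  }, numeric(1))
}

# radially perturbed icosphere (star-convex), perturbation amplitude eps
perturbed_sphere <- function(eps, seed, subdivisions = 3) {
  m <- icosphere(radius = 1, subdivisions = subdivisions)
  set.seed(seed)
  v <- m$vertices
  # smooth low-order angular modulation plus mild vertex noise
  a <- stats::runif(3, -1, 1)
  r <- 1 + eps * (a[1] * v[, 1]^2 + a[2] * v[, 2] * v[, 3] + a[3] * v[, 3]) +
    eps * 0.2 * stats::rnorm(nrow(v))
  triangle_mesh(v * r, m$faces)
}
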