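#' Triangle meshes and their geometric moments
#'
#' Minimal triangle-mesh container used for cavity surfaces: a vertex matrix
#' and a face index matrix. [mesh_properties()] returns the enclosed volume
#' (divergence-theorem accumulation of signed tetrahedra) and the total
#' surface area; [sphericity()] evaluates the sphericity index
#' `Psi = pi^(1/3) * (6 V)^(2/3) / A`, which is 1 for a sphere and decreases
#' as the shape departs from sphericity (the sphere minimises area at fixed
#' volume).
#'
#' @param vertices Numeric N x 3 matrix of vertex coordinates.
#' @param faces Integer M x 3 matrix of 1-based vertex indices, consistently
#'   oriented (outward normals).
#' @return `triangle_mesh()` returns an object of class `triangle_mesh`.
#' @export
triangle_mesh <- function(vertices, faces) {
  vertices <- as.matrix(vertices)
  faces <- as.matrix(faces)
  stopifnot(ncol(vertices) == 3L, ncol(faces) == 3L)
  if (nrow(faces) < 4L) {
    stop("open/degenerate mesh: fewer than 4 faces.", call. = FALSE)
  }
  structure(list(vertices = vertices, faces = faces), class = "triangle_mesh")
}

#' @rdname triangle_mesh
#' @param mesh A `triangle_mesh`.
#' @return `mesh_properties()` returns a one-row tibble with `volume`,
#'   `area` and `n_faces` (units follow the vertex coordinates).
#' @export
mesh_properties <- function(mesh) {
  stopifnot(inherits(mesh, "triangle_mesh"))
  v <- mesh$vertices
  a <- v[mesh$faces[, 1], , drop = FALSE]
  b <- v[mesh$faces[, 2], , drop = FALSE]
  c_ <- v[mesh$faces[, 3], , drop = FALSE]
  ab <- b - a
  ac <- c_ - a
  cr <- cbind(
    ab[, 2] * ac[, 3] - ab[, 3] * ac[, 2],
    ab[, 3] * ac[, 1] - ab[, 1] * ac[, 3],
    ab[, 1] * ac[, 2] - ab[, 2] * ac[, 1]
  )
  area <- sum(sqrt(rowSums(cr^2))) / 2
  # signed volume of tetrahedra to the origin; consistent orientation assumed
  vol <- abs(sum(a[, 1] * (b[, 2] * c_[, 3] - b[, 3] * c_[, 2]) +
                 a[, 2] * (b[, 3] * c_[, 1] - b[, 1] * c_[, 3]) +
                 a[, 3] * (b[, 1] * c_[, 2] - b[, 2] * c_[, 1]))) / 6
  tibble::tibble(volume = vol, area = area, n_faces = nrow(mesh$faces))
}

#' @rdname triangle_mesh
#' @param volume,area Enclosed volume and surface area (consistent units).
#' @export
sphericity <- function(volume, area) {
  pi^(1 / 3) * (6 * volume)^(2 / 3) / area
}

#' Icosphere triangulation of a sphere
#'
#' Repeatedly subdivides an icosahedron and projects the vertices to the
#' sphere, giving a near-uniform triangulation with `20 * 4^subdivisions`
#' outward-oriented faces. Used as the reference mesh for sphericity checks
#' and as a base shape for star-convex perturbation studies.
#'
#' @param radius Sphere radius (default 1).
#' @param subdivisions Number of 4-fold subdivisions (default 4).
#' @param center Sphere centre (length-3).
#' @return A [triangle_mesh()].
#' @export
#' @examples
#' m <- icosphere(radius = 50, subdivisions = 3)
#' sphericity(mesh_properties(m)$volume, mesh_properties(m)$area)
icosphere <- function(radius = 1, subdivisions = 4, center = c(0, 0, 0)) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1)
  )
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2)
  )
  for (s in seq_len(subdivisions)) {
    edge_key <- function(i, j) paste(pmin(i, j), pmax(i, j))
    midcache <- new.env(hash = TRUE, parent = emptyenv())
    nv <- nrow(v)
    newv <- list()
    midpoint <- function(i, j) {
      k <- edge_key(i, j)
      hit <- midcache[[k]]
      if (!is.null(hit)) return(hit)
      p <- (v[i, ] + v[j, ]) / 2
      p <- p / sqrt(sum(p^2))
      newv[[length(newv) + 1L]] <<- p
      idx <- nv + length(newv)
      midcache[[k]] <- idx
      idx
    }
    nf <- matrix(0L, nrow(f) * 4L, 3L)
    for (t in seq_len(nrow(f))) {
      i <- f[t, 1]; j <- f[t, 2]; k <- f[t, 3]
      a <- midpoint(i, j); b <- midpoint(j, k); c_ <- midpoint(k, i)
      nf[(t - 1L) * 4L + 1:4, ] <- rbind(
        c(i, a, c_), c(j, b, a), c(k, c_, b), c(a, b, c_)
      )
    }
    v <- rbind(v, do.call(rbind, newv))
    v <- v / sqrt(rowSums(v^2))
    f <- nf
  }
  v <- v * radius
  v <- sweep(v, 2, center, "+")
  triangle_mesh(v, f)
}

# --- marching tetrahedra -----------------------------------------------------

# Kuhn 6-tetrahedra decomposition of the unit cube around diagonal c0-c6;
# corner order: c0=(0,0,0) c1=(1,0,0) c2=(1,1,0) c3=(0,1,0)
#               c4=(0,0,1) c5=(1,0,1) c6=(1,1,1) c7=(0,1,1)
.mt_tets <- rbind(
  c(1, 2, 3, 7), c(1, 3, 4, 7), c(1, 4, 8, 7),
  c(1, 8, 5, 7), c(1, 5, 6, 7), c(1, 6, 2, 7)
)

.mt_corner_off <- rbind(
  c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0),
  c(0, 0, 1), c(1, 0, 1), c(1, 1, 1), c(0, 1, 1)
)

# Per sign-case triangle fans, as pairs of local tet-vertex indices defining
# the crossed edges. One-positive / three-positive cases give one triangle,
# two-positive cases give a cyclically ordered quad (split into 2 triangles).
.mt_cases <- list(
  `1`  = list(tri = list(c(1, 2), c(1, 3), c(1, 4))),
  `2`  = list(tri = list(c(2, 1), c(2, 4), c(2, 3))),
  `4`  = list(tri = list(c(3, 1), c(3, 2), c(3, 4))),
  `8`  = list(tri = list(c(4, 1), c(4, 3), c(4, 2))),
  `14` = list(tri = list(c(2, 1), c(3, 1), c(4, 1))),
  `13` = list(tri = list(c(1, 2), c(4, 2), c(3, 2))),
  `11` = list(tri = list(c(1, 3), c(2, 3), c(4, 3))),
  `7`  = list(tri = list(c(1, 4), c(3, 4), c(2, 4))),
  `3`  = list(quad = list(c(1, 3), c(1, 4), c(2, 4), c(2, 3))),
  `5`  = list(quad = list(c(1, 2), c(1, 4), c(3, 4), c(3, 2))),
  `9`  = list(quad = list(c(1, 2), c(1, 3), c(4, 3), c(4, 2))),
  `6`  = list(quad = list(c(2, 1), c(2, 4), c(3, 4), c(3, 1))),
  `10` = list(quad = list(c(2, 1), c(2, 3), c(4, 3), c(4, 1))),
  `12` = list(quad = list(c(3, 1), c(3, 2), c(4, 2), c(4, 1)))
)

# Isosurface of a 3D scalar field by marching tetrahedra. `field` is an
# (nx, ny, nz) array sampled at node positions ((i-0.5) * spacing); returns a
# triangle_mesh of the level set `field = level`, oriented with normals
# pointing toward the low side (outward if values inside exceed `level`).
mt_isosurface <- function(field, spacing, level = 0) {
  dm <- dim(field)
  nx <- dm[1]; ny <- dm[2]; nz <- dm[3]
  f <- field - level
  # candidate cubes: both signs among the 8 corners
  sub <- function(dx, dy, dz) {
    f[(1:(nx - 1)) + dx, (1:(ny - 1)) + dy, (1:(nz - 1)) + dz]
  }
  cmin <- cmax <- sub(0, 0, 0)
  for (r in 2:8) {
    s <- sub(.mt_corner_off[r, 1], .mt_corner_off[r, 2], .mt_corner_off[r, 3])
    cmin <- pmin(cmin, s)
    cmax <- pmax(cmax, s)
  }
  cand <- which(cmin <= 0 & cmax > 0)
  if (!length(cand)) {
    stop("open/degenerate mesh: the level set does not intersect the grid.",
         call. = FALSE)
  }
  ci <- arrayInd(cand, dm - 1L)
  m <- nrow(ci)
  # 8 corner values and coordinates for the candidate cubes
  corner_vals <- matrix(0, m, 8)
  for (r in 1:8) {
    corner_vals[, r] <- f[cbind(ci[, 1] + .mt_corner_off[r, 1],
                                ci[, 2] + .mt_corner_off[r, 2],
                                ci[, 3] + .mt_corner_off[r, 3])]
  }
  corner_xyz <- function(r) {
    cbind((ci[, 1] - 0.5 + .mt_corner_off[r, 1]) * spacing[1],
          (ci[, 2] - 0.5 + .mt_corner_off[r, 2]) * spacing[2],
          (ci[, 3] - 0.5 + .mt_corner_off[r, 3]) * spacing[3])
  }
  cx <- lapply(1:8, corner_xyz)

  tris <- vector("list", 6L)
  for (tt in 1:6) {
    loc <- .mt_tets[tt, ]
    vv <- corner_vals[, loc, drop = FALSE]          # m x 4
    px <- lapply(1:4, function(r) cx[[loc[r]]])     # positions of tet corners
    pos <- vv > 0
    code <- pos[, 1] + 2L * pos[, 2] + 4L * pos[, 3] + 8L * pos[, 4]
    out <- list()
    for (cs in names(.mt_cases)) {
      rows <- which(code == as.integer(cs))
      if (!length(rows)) next
      spec <- .mt_cases[[cs]]
      interp <- function(e) {
        a <- e[1]; b <- e[2]
        va <- vv[rows, a]; vb <- vv[rows, b]
        t <- va / (va - vb)
        px[[a]][rows, , drop = FALSE] +
          t * (px[[b]][rows, , drop = FALSE] - px[[a]][rows, , drop = FALSE])
      }
      orient <- function(p1, p2, p3) {
        # normal should point from the positive (inside) toward the negative
        # side: use the gradient proxy (negative centroid - positive centroid)
        posm <- pos[rows, , drop = FALSE]
        csum <- Reduce(`+`, lapply(1:4, function(r) px[[r]][rows, , drop = FALSE]))
        psum <- Reduce(`+`, lapply(1:4, function(r) {
          px[[r]][rows, , drop = FALSE] * posm[, r]
        }))
        npos <- rowSums(posm)
        pcen <- psum / npos
        ncen <- (csum - psum) / (4 - npos)
        dirv <- ncen - pcen
        e1 <- p2 - p1
        e2 <- p3 - p1
        nrm <- cbind(
          e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
          e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
          e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]
        )
        flip <- rowSums(nrm * dirv) < 0
        list(
          p1 = p1,
          p2 = ifelse(matrix(flip, length(flip), 3), p3, p2),
          p3 = ifelse(matrix(flip, length(flip), 3), p2, p3)
        )
      }
      if (!is.null(spec$tri)) {
        p <- lapply(spec$tri, interp)
        o <- orient(p[[1]], p[[2]], p[[3]])
        out[[length(out) + 1L]] <- o
      } else {
        q <- lapply(spec$quad, interp)
        o1 <- orient(q[[1]], q[[2]], q[[3]])
        o2 <- orient(q[[1]], q[[3]], q[[4]])
        out[[length(out) + 1L]] <- o1
        out[[length(out) + 1L]] <- o2
      }
    }
    tris[[tt]] <- out
  }
  tris <- unlist(tris, recursive = FALSE)
  p1 <- do.call(rbind, lapply(tris, `[[`, "p1"))
  p2 <- do.call(rbind, lapply(tris, `[[`, "p2"))
  p3 <- do.call(rbind, lapply(tris, `[[`, "p3"))
  keep <- rowSums((p2 - p1)^2) > 0 & rowSums((p3 - p1)^2) > 0 &
    rowSums((p3 - p2)^2) > 0
  p1 <- p1[keep, , drop = FALSE]
  p2 <- p2[keep, , drop = FALSE]
  p3 <- p3[keep, , drop = FALSE]
  n <- nrow(p1)
  triangle_mesh(rbind(p1, p2, p3), cbind(1:n, n + 1:n, 2 * n + 1:n))
}
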