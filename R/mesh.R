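#' Centre of the bud-scar hole
#'
#' The hole in the spherical cap domain is always centred at the South Pole
#' \eqn{(0, 0, -1)}, matching the convention used throughout the package.
#'
#' @return A length-3 numeric unit vector.
#' @export
hole_centre <- function() c(0, 0, -1)

#' Great-circle distance between points on the unit sphere
#'
#' Arc-length (geodesic) distance in radians between two points on the unit
#' sphere. Inputs are normalised internally, so any non-zero 3-vectors may be
#' supplied. `p` may be a matrix with one point per row.
#'
#' @param p A 3-vector, or an `n x 3` matrix of points.
#' @param q A 3-vector.
#' @return Distance(s) in radians, in `[0, pi]`.
#' @examples
#' geodesic_distance(c(0, 0, 1), c(0, 0, -1)) # pi
#' geodesic_distance(c(1, 0, 0), c(0, 1, 0))  # pi/2
#' @export
geodesic_distance <- function(p, q) {
  if (is.null(dim(p))) p <- matrix(p, nrow = 1L)
  stopifnot(ncol(p) == 3L, length(q) == 3L)
  np <- sqrt(rowSums(p^2))
  nq <- sqrt(sum(q^2))
  if (any(np == 0) || nq == 0) {
    stop("geodesic_distance() requires non-zero vectors", call. = FALSE)
  }
  p <- p / np
  q <- q / nq
  dots <- as.vector(p %*% q)
  # atan2 form is accurate near 0 and pi, unlike acos of the dot product
  crosses <- cbind(
    p[, 2L] * q[3L] - p[, 3L] * q[2L],
    p[, 3L] * q[1L] - p[, 1L] * q[3L],
    p[, 1L] * q[2L] - p[, 2L] * q[1L]
  )
  d <- atan2(sqrt(rowSums(crosses^2)), dots)
  if (length(d) == 1L) d[[1L]] else d
}

#' Triangulated mesh of the unit sphere with an optional hole
#'
#' Builds a conforming triangulation of the spherical cap
#' \eqn{\Omega_\varepsilon}: the unit sphere minus a geodesic disc of radius
#' `epsilon` (radians) centred at the South Pole \eqn{(0,0,-1)}. With
#' `epsilon = 0` the mesh is the closed sphere. The domain models a yeast cell
#' membrane carrying one bud scar which activated Cdc42 cannot enter.
#'
#' The construction places vertices on latitude rings spaced by roughly
#' `resolution` radians, with per-ring point counts proportional to the ring
#' circumference, and triangulates adjacent rings by an angular merge. The
#' boundary ring (when `epsilon > 0`) lies exactly on the circle
#' \eqn{z = -\cos\varepsilon}. Meshing is deterministic: the same
#' `(epsilon, resolution)` always yields the identical mesh.
#'
#' @param epsilon Geodesic radius of the hole, in radians (`0 <= epsilon < pi`).
#' @param resolution Target edge length (radians on the unit sphere). The full
#'   sphere has roughly `4*pi/resolution^2` vertices; the default 0.05 gives
#'   about 5000.
#' @return A `surface_mesh` object: a list with
#'   `vertices` (`N x 3` matrix of unit vectors), `triangles`
#'   (`M x 3` integer matrix, outward-oriented), `boundary_vertices`
#'   (integer indices on the hole rim; empty when `epsilon = 0`),
#'   `hole_radius`, and `resolution`.
#' @examples
#' m <- cap_mesh(epsilon = 0.2, resolution = 0.25)
#' mesh_area(m)                  # close to 2*pi*(1 + cos(0.2))
#' length(m$boundary_vertices)   # > 0: the hole rim
#' @export
cap_mesh <- function(epsilon = 0, resolution = 0.05) {
  if (!is.numeric(epsilon) || length(epsilon) != 1L || is.na(epsilon) ||
      epsilon < 0 || epsilon >= pi) {
    stop("`epsilon` must be a single value in [0, pi)", call. = FALSE)
  }
  if (!is.numeric(resolution) || length(resolution) != 1L ||
      is.na(resolution) || resolution <= 0) {
    stop("`resolution` must be a single positive number", call. = FALSE)
  }
  h <- resolution
  theta_max <- pi - epsilon  # colatitude of the hole rim (from the North Pole)
  closed <- epsilon == 0

  n_rings <- max(3L, as.integer(ceiling(theta_max / h)))
  thetas <- seq(0, theta_max, length.out = n_rings + 1L)

  ring_count <- function(theta, boundary = FALSE) {
    n <- max(3L, as.integer(round(2 * pi * sin(theta) / h)))
    if (boundary) n <- max(8L, n)  # resolve even the smallest holes
    n
  }

  verts <- list(c(0, 0, 1))  # North Pole
  ring_idx <- vector("list", n_rings + 1L)
  ring_idx[[1L]] <- 1L
  n_vert <- 1L
  last_interior <- if (closed) n_rings - 1L else n_rings
  for (i in seq_len(n_rings)) {
    th <- thetas[i + 1L]
    if (closed && i == n_rings) {  # South Pole point
      n_vert <- n_vert + 1L
      verts[[n_vert]] <- c(0, 0, -1)
      ring_idx[[i + 1L]] <- n_vert
      next
    }
    ni <- ring_count(th, boundary = (!closed && i == n_rings))
    # stagger alternate rings for better-shaped triangles
    phi <- 2 * pi * (seq_len(ni) - 1L) / ni + (i %% 2L) * pi / ni
    ring <- cbind(sin(th) * cos(phi), sin(th) * sin(phi), rep(cos(th), ni))
    idx <- n_vert + seq_len(ni)
    for (k in seq_len(ni)) verts[[idx[k]]] <- ring[k, ]
    ring_idx[[i + 1L]] <- idx
    n_vert <- n_vert + ni
  }
  vertices <- do.call(rbind, verts)
  vertices <- vertices / sqrt(rowSums(vertices^2))

  phis <- atan2(vertices[, 2L], vertices[, 1L]) %% (2 * pi)

  tris <- list()
  add <- function(t) tris[[length(tris) + 1L]] <<- t

  # fan from the North Pole to the first ring
  r1 <- ring_idx[[2L]]
  n1 <- length(r1)
  for (k in seq_len(n1)) add(c(1L, r1[k], r1[if (k == n1) 1L else k + 1L]))

  # bands between consecutive rings
  for (i in seq_len(n_rings - 1L)) {
    a <- ring_idx[[i + 1L]]
    b <- ring_idx[[i + 2L]]
    if (length(b) == 1L) {  # fan down to the South Pole
      na <- length(a)
      for (k in seq_len(na)) add(c(a[k], b, a[if (k == na) 1L else k + 1L]))
    } else {
      for (t in band_triangles(a, b, phis)) add(t)
    }
  }
  triangles <- do.call(rbind, tris)
  storage.mode(triangles) <- "integer"

  # enforce outward orientation
  p1 <- vertices[triangles[, 1L], , drop = FALSE]
  p2 <- vertices[triangles[, 2L], , drop = FALSE]
  p3 <- vertices[triangles[, 3L], , drop = FALSE]
  nrm <- vec_cross(p2 - p1, p3 - p1)
  centroid <- (p1 + p2 + p3) / 3
  flip <- rowSums(nrm * centroid) < 0
  if (any(flip)) {
    tmp <- triangles[flip, 2L]
    triangles[flip, 2L] <- triangles[flip, 3L]
    triangles[flip, 3L] <- tmp
  }

  boundary_vertices <- if (closed) integer(0) else ring_idx[[n_rings + 1L]]

  mesh <- structure(
    list(
      vertices = vertices,
      triangles = triangles,
      boundary_vertices = as.integer(boundary_vertices),
      hole_radius = epsilon,
      resolution = resolution
    ),
    class = "surface_mesh"
  )
  validate_mesh(mesh)
  mesh
}

# Triangulate the band between two latitude rings by marching both rings in
# azimuthal order. `a`, `b` are vertex-index vectors; `phis` the azimuths.
band_triangles <- function(a, b, phis) {
  p <- length(a)
  q <- length(b)
  ord_a <- order(phis[a])
  ord_b <- order(phis[b])
  a <- a[ord_a]
  b <- b[ord_b]
  pa <- phis[a]
  pb <- phis[b]
  # start b at the point closest (circularly) to a[1]
  dphi <- (pb - pa[1L]) %% (2 * pi)
  j0 <- which.min(pmin(dphi, 2 * pi - dphi))
  b <- c(b[j0:q], b[seq_len(j0 - 1L)])
  pb <- pb[c(j0:q, seq_len(j0 - 1L))]
  # angles relative to a[1], with b's start folded into (-pi, pi] so the
  # two walks begin in phase
  start_b <- (pb[1L] - pa[1L]) %% (2 * pi)
  if (start_b > pi) start_b <- start_b - 2 * pi
  pb <- start_b + cummax_unwrap((pb - pb[1L]) %% (2 * pi))
  pa <- cummax_unwrap((pa - pa[1L]) %% (2 * pi))
  # walks closed by the first point again at +2*pi
  wa <- c(pa, pa[1L] + 2 * pi)
  wb <- c(pb, pb[1L] + 2 * pi)
  ia <- 1L
  ib <- 1L
  out <- vector("list", p + q)
  n_out <- 0L
  while (ia <= p || ib <= q) {
    adv_a <- if (ia > p) FALSE
    else if (ib > q) TRUE
    else wa[ia + 1L] <= wb[ib + 1L]
    n_out <- n_out + 1L
    if (adv_a) {
      out[[n_out]] <- c(a[ia], a[if (ia == p) 1L else ia + 1L],
                        b[if (ib > q) 1L else ib])
      ia <- ia + 1L
    } else {
      out[[n_out]] <- c(a[if (ia > p) 1L else ia],
                        b[if (ib == q) 1L else ib + 1L], b[ib])
      ib <- ib + 1L
    }
  }
  out
}

# make an angle sequence non-decreasing by unwrapping 2*pi jumps
cummax_unwrap <- function(x) {
  for (i in seq_along(x)[-1L]) {
    while (x[i] < x[i - 1L]) x[i] <- x[i] + 2 * pi
  }
  x
}

vec_cross <- function(u, v) {
  cbind(
    u[, 2L] * v[, 3L] - u[, 3L] * v[, 2L],
    u[, 3L] * v[, 1L] - u[, 1L] * v[, 3L],
    u[, 1L] * v[, 2L] - u[, 2L] * v[, 1L]
  )
}

validate_mesh <- function(mesh) {
  v <- mesh$vertices
  if (max(abs(sqrt(rowSums(v^2)) - 1)) > 1e-8) {
    stop("mesh vertices do not lie on the unit sphere", call. = FALSE)
  }
  if (min(triangle_areas(mesh)) <= 0) {
    stop("mesh contains a degenerate (zero-area) triangle", call. = FALSE)
  }
  invisible(mesh)
}

triangle_areas <- function(mesh) {
  tri <- mesh$triangles
  v <- mesh$vertices
  e1 <- v[tri[, 2L], , drop = FALSE] - v[tri[, 1L], , drop = FALSE]
  e2 <- v[tri[, 3L], , drop = FALSE] - v[tri[, 1L], , drop = FALSE]
  0.5 * sqrt(rowSums(vec_cross(e1, e2)^2))
}

#' Total area of a triangulated surface mesh
#'
#' Sum of flat-triangle areas. For the cap mesh this converges to the exact
#' spherical-cap area \eqn{2\pi(1 + \cos\varepsilon)} as the resolution is
#' refined (at rate \eqn{O(h^2)} in the edge length \eqn{h}).
#'
#' @param mesh A `surface_mesh`.
#' @return Positive scalar area (dimensionless; unit-sphere units).
#' @export
mesh_area <- function(mesh) {
  stopifnot(inherits(mesh, "surface_mesh"))
  a <- triangle_areas(mesh)
  if (min(a) <= 0) stop("degenerate triangle in mesh", call. = FALSE)
  sum(a)
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf(
    "<surface_mesh> %d vertices, %d triangles%s\n",
    nrow(x$vertices), nrow(x$triangles),
    if (x$hole_radius > 0) {
      sprintf(", hole radius %.3g rad (%d boundary vertices)",
              x$hole_radius, length(x$boundary_vertices))
    } else ", closed sphere"
  ))
  cat(sprintf("  target edge length %.3g, area %.6g\n",
              x$resolution, mesh_area(x)))
  invisible(x)
}

# undirected edge list (two columns, sorted within rows)
mesh_edges <- function(mesh) {
  tri <- mesh$triangles
  e <- rbind(tri[, c(1L, 2L)], tri[, c(2L, 3L)], tri[, c(3L, 1L)])
  cbind(pmin(e[, 1L], e[, 2L]), pmax(e[, 1L], e[, 2L]))
}

# edges on the boundary (appearing in exactly one triangle)
boundary_edges <- function(mesh) {
  e <- mesh_edges(mesh)
  key <- paste(e[, 1L], e[, 2L])
  tab <- table(key)
  once <- names(tab)[tab == 1L]
  e[key %in% once & !duplicated(key), , drop = FALSE]
}

#' Maximum edge length of a mesh
#'
#' Used to scale the pole-clustering neighbourhood radius.
#'
#' @param mesh A `surface_mesh`.
#' @return Largest Euclidean edge length.
#' @export
max_edge_length <- function(mesh) {
  e <- unique(mesh_edges(mesh))
  v <- mesh$vertices
  max(sqrt(rowSums((v[e[, 1L], , drop = FALSE] -
                      v[e[, 2L], , drop = FALSE])^2)))
}

# one third of incident flat-triangle area per vertex
vertex_areas <- function(mesh) {
  a <- triangle_areas(mesh)
  out <- numeric(nrow(mesh$vertices))
  tri <- mesh$triangles
  for (j in 1:3) {
    s <- rowsum(a, tri[, j])
    idx <- as.integer(rownames(s))
    out[idx] <- out[idx] + s[, 1L]
  }
  out / 3
}
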