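#' Detect concentration poles by density-based clustering
#'
#' A pole is a contiguous high-concentration region of the activator (the
#' site where a yeast bud would form). Nodes with
#' \eqn{u \ge \mathrm{threshold\_fraction} \cdot u_{max}} are extracted and
#' clustered by DBSCAN on their 3D coordinates; each cluster is one pole.
#' The 0.95 default threshold is a calibration choice (the number of clusters
#' then agrees with visual inspection); it is configurable.
#'
#' DBSCAN hyperparameters default to a neighbourhood radius of 2.5 times the
#' mesh's maximum edge length and a minimum cluster size of 3 nodes, so that
#' clusters are connected at mesh scale. If clustering returns no cluster
#' while above-threshold nodes exist (possible only for tiny node sets), the
#' eps-connectivity components are returned instead, so at least one pole is
#' always reported.
#'
#' @param state A `fem_state` (or list with nodal vector `u`).
#' @param mesh The `surface_mesh`.
#' @param threshold_fraction Fraction of the maximum defining "high
#'   concentration" (in `(0, 1]`, default 0.95).
#' @param eps DBSCAN neighbourhood radius; default `2.5 * max_edge_length(mesh)`.
#' @param min_pts Minimum neighbours (including the point itself) for a core
#'   point; default 3.
#' @return A `pole_clusters` list: `clusters` (list of integer node-index
#'   vectors, one per pole), `above_threshold` (all qualifying node indices),
#'   `u_max`, `threshold_used`.
#' @export
detect_poles <- function(state, mesh, threshold_fraction = 0.95,
                         eps = 2.5 * max_edge_length(mesh), min_pts = 3L) {
  stopifnot(inherits(mesh, "surface_mesh"),
            threshold_fraction > 0, threshold_fraction <= 1)
  u <- state$u
  stopifnot(length(u) == nrow(mesh$vertices))
  u_max <- max(u)
  idx <- which(u >= threshold_fraction * u_max)
  pts <- mesh$vertices[idx, , drop = FALSE]
  labels <- dbscan_labels(pts, eps = eps, min_pts = min_pts)
  if (max(labels) == 0L && length(idx) > 0L) {
    labels <- connectivity_components(pts, eps)
  }
  clusters <- lapply(seq_len(max(labels)), function(k) idx[labels == k])
  structure(
    list(clusters = clusters, above_threshold = idx, u_max = u_max,
         threshold_used = threshold_fraction),
    class = "pole_clusters"
  )
}

#' @export
print.pole_clusters <- function(x, ...) {
  cat(sprintf("<pole_clusters> %d pole(s) from %d nodes >= %.2f * u_max (%.4f)\n",
              length(x$clusters), length(x$above_threshold),
              x$threshold_used, x$u_max))
  invisible(x)
}

# Plain DBSCAN (scikit-learn semantics: min_pts counts the point itself).
# Returns 0 for noise, 1..k for clusters. Point sets here are small (the
# above-threshold nodes), so the quadratic distance matrix is fine.
dbscan_labels <- function(pts, eps, min_pts) {
  n <- nrow(pts)
  if (n == 0L) return(integer(0))
  d2 <- as.matrix(stats::dist(pts))^2
  nbr <- lapply(seq_len(n), function(i) which(d2[i, ] <= eps^2))
  core <- vapply(nbr, length, 1L) >= min_pts
  labels <- integer(n)
  cl <- 0L
  for (i in seq_len(n)) {
    if (labels[i] != 0L || !core[i]) next
    cl <- cl + 1L
    queue <- i
    labels[i] <- cl
    while (length(queue)) {
      j <- queue[[1L]]
      queue <- queue[-1L]
      if (!core[j]) next
      for (q in nbr[[j]]) {
        if (labels[q] == 0L) {
          labels[q] <- cl
          queue <- c(queue, q)
        }
      }
    }
  }
  labels
}

# connected components of the eps-neighbourhood graph (DBSCAN with min_pts 1)
connectivity_components <- function(pts, eps) {
  dbscan_labels(pts, eps, min_pts = 1L)
}

#' Fraction of the surface covered by poles
#'
#' Area of the above-threshold region relative to the total mesh area. Each
#' qualifying node is attributed one third of the summed areas of its
#' incident triangles (the standard vertex-area rule for piecewise-linear
#' fields). Non-increasing as the threshold fraction rises.
#'
#' @param poles [detect_poles()] output.
#' @param mesh The same `surface_mesh`.
#' @return Fraction in `[0, 1]`.
#' @export
pole_area_fraction <- function(poles, mesh) {
  stopifnot(inherits(poles, "pole_clusters"), inherits(mesh, "surface_mesh"))
  va <- vertex_areas(mesh)
  sum(va[poles$above_threshold]) / mesh_area(mesh)
}

#' Great-circle distance from the hole centre to the nearest pole
#'
#' Minimum over clustered pole nodes of the geodesic distance to the hole
#' midpoint \eqn{(0,0,-1)}. Undefined for a closed sphere
#' (`hole_radius = 0`): returns `NA` with a warning-free sentinel, since the
#' metric has no meaning without a hole.
#'
#' @param poles [detect_poles()] output.
#' @param mesh The same `surface_mesh`.
#' @return Distance in radians, or `NA_real_` when the mesh has no hole.
#' @export
min_hole_pole_distance <- function(poles, mesh) {
  stopifnot(inherits(poles, "pole_clusters"), inherits(mesh, "surface_mesh"))
  if (mesh$hole_radius == 0) return(NA_real_)
  pole_nodes <- unlist(poles$clusters)
  if (length(pole_nodes) == 0L) return(NA_real_)
  min(geodesic_distance(mesh$vertices[pole_nodes, , drop = FALSE],
                        hole_centre()))
}

#' Quantitative pattern metrics for one simulation
#'
#' Bundles the four pattern descriptors used to characterise a final
#' concentration profile: number of poles, pole-area fraction, maximum
#' activator concentration, and the great-circle distance from the hole
#' centre to the nearest pole.
#'
#' @param state A `fem_state` (typically `sim$state` at the final time).
#' @param mesh The `surface_mesh` the state lives on.
#' @param threshold_fraction Pole threshold (default 0.95, see
#'   [detect_poles()]).
#' @param ... Further arguments passed to [detect_poles()].
#' @return A one-row tibble: `n_poles`, `pole_area_fraction`, `u_max`,
#'   `u_min`, `min_hole_distance`, `threshold_used`.
#' @export
pattern_metrics <- function(state, mesh, threshold_fraction = 0.95, ...) {
  poles <- detect_poles(state, mesh, threshold_fraction, ...)
  tibble::tibble(
    n_poles = length(poles$clusters),
    pole_area_fraction = pole_area_fraction(poles, mesh),
    u_max = poles$u_max,
    u_min = min(state$u),
    min_hole_distance = min_hole_pole_distance(poles, mesh),
    threshold_used = threshold_fraction
  )
}
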