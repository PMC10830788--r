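#' Write a mesh and nodal fields to a legacy-ASCII VTK file
#'
#' Writes the triangulation and any number of nodal scalar fields as a VTK
#' unstructured grid (legacy ASCII format, triangle cells), readable by
#' ParaView and by [read_field()]. Values are printed with 17 significant
#' digits, so a write/read round trip reproduces them to full double
#' precision.
#'
#' @param mesh A `surface_mesh`.
#' @param state Optional `fem_state` (or list of nodal vectors); its `u` and
#'   `v` become POINT_DATA arrays. `NULL` writes the mesh alone.
#' @param path Output file path (conventionally `.vtk`).
#' @return `path`, invisibly.
#' @export
write_field <- function(mesh, state = NULL, path) {
  stopifnot(inherits(mesh, "surface_mesh"))
  n <- nrow(mesh$vertices)
  con <- file(path, "w")
  on.exit(close(con))
  wl <- function(...) writeLines(sprintf(...), con)
  num <- function(x) format(x, digits = 17, scientific = TRUE, trim = TRUE)
  wl("# vtk DataFile Version 3.0")
  wl("surface mesh (hole_radius=%s resolution=%s)",
     num(mesh$hole_radius), num(mesh$resolution))
  wl("ASCII")
  wl("DATASET UNSTRUCTURED_GRID")
  wl("POINTS %d double", n)
  writeLines(apply(mesh$vertices, 1L,
                   function(r) paste(num(r), collapse = " ")), con)
  ntri <- nrow(mesh$triangles)
  wl("CELLS %d %d", ntri, 4L * ntri)
  writeLines(apply(mesh$triangles - 1L, 1L,
                   function(r) paste(c(3L, r), collapse = " ")), con)
  wl("CELL_TYPES %d", ntri)
  writeLines(rep("5", ntri), con)
  fields <- list()
  if (!is.null(state)) {
    for (nm in intersect(c("u", "v"), names(state))) {
      if (is.numeric(state[[nm]]) && length(state[[nm]]) == n) {
        fields[[nm]] <- state[[nm]]
      }
    }
  }
  if (length(fields)) {
    wl("POINT_DATA %d", n)
    for (nm in names(fields)) {
      wl("SCALARS %s double 1", nm)
      wl("LOOKUP_TABLE default")
      writeLines(num(fields[[nm]]), con)
    }
  }
  invisible(path)
}

#' Read a mesh and nodal fields from a legacy-ASCII VTK file
#'
#' Inverse of [write_field()]. Boundary vertices are recovered from the
#' triangulation (edges used by a single triangle); the hole radius and
#' resolution are parsed from the file's title line when present.
#'
#' @param path Path to a `.vtk` file written by [write_field()].
#' @return A list with `mesh` (a `surface_mesh`) and `state` (a `fem_state`
#'   at `t = NA` when both `u` and `v` arrays are present, otherwise `NULL`).
#' @export
read_field <- function(path) {
  lines <- readLines(path)
  grab <- function(pat) grep(pat, lines)[1L]
  header <- lines[2L]
  hole_radius <- as.numeric(sub(".*hole_radius=([^ )]+).*", "\\1", header))
  resolution <- as.numeric(sub(".*resolution=([^ )]+).*", "\\1", header))
  ip <- grab("^POINTS ")
  n <- as.integer(strsplit(lines[ip], " ")[[1L]][2L])
  verts <- matrix(scan(text = lines[(ip + 1L):(ip + n)], quiet = TRUE),
                  ncol = 3L, byrow = TRUE)
  ic <- grab("^CELLS ")
  ntri <- as.integer(strsplit(lines[ic], " ")[[1L]][2L])
  cells <- matrix(scan(text = lines[(ic + 1L):(ic + ntri)], quiet = TRUE),
                  ncol = 4L, byrow = TRUE)
  triangles <- cells[, 2:4, drop = FALSE] + 1L
  storage.mode(triangles) <- "integer"
  mesh <- structure(
    list(vertices = verts, triangles = triangles,
         boundary_vertices = integer(0),
         hole_radius = if (is.na(hole_radius)) 0 else hole_radius,
         resolution = resolution),
    class = "surface_mesh"
  )
  be <- boundary_edges(mesh)
  mesh$boundary_vertices <- sort(unique(as.vector(be)))
  fields <- list()
  for (i in grep("^SCALARS ", lines)) {
    nm <- strsplit(lines[i], " ")[[1L]][2L]
    fields[[nm]] <- scan(text = lines[(i + 2L):(i + 1L + n)], quiet = TRUE)
  }
  state <- if (all(c("u", "v") %in% names(fields))) {
    fem_state(fields$u, fields$v, t = NA_real_)
  } else NULL
  list(mesh = mesh, state = state)
}

#' Write and read run configuration files
#'
#' A run configuration is a flat named list mirroring the arguments of the
#' pipeline functions (mesh, simulation, metrics and ensemble settings) plus
#' a provenance block (package version, seed, timestamp). It round-trips
#' losslessly through a YAML file; unknown keys are rejected on read so that
#' typos fail loudly.
#'
#' @param config Named list of settings.
#' @param path File path.
#' @return `write_run_config()`: `path`, invisibly. `read_run_config()`: the
#'   configuration list.
#' @export
write_run_config <- function(config, path) {
  stopifnot(is.list(config), !is.null(names(config)))
  bad <- setdiff(names(config), known_config_keys())
  if (length(bad)) {
    stop("unknown config keys: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  config$provenance <- list(
    package = "turingcap",
    version = as.character(utils::packageVersion("turingcap")),
    written = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  yaml::write_yaml(config, path, precision = 17L)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  config <- yaml::read_yaml(path)
  config$provenance <- NULL
  bad <- setdiff(names(config), known_config_keys())
  if (length(bad)) {
    stop("unknown config keys: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  config
}

known_config_keys <- function() {
  c("epsilon", "resolution", "a", "b", "gamma", "d", "T_final", "k", "seed",
    "amplitude", "snapshot_times", "lumped", "n_max", "threshold_fraction",
    "radii", "repetitions", "base_seed", "modes", "out", "provenance")
}

#' Generate small deterministic test fixtures
#'
#' Writes the small meshes and synthetic fields used by the test suite and
#' handy for external inspection: a coarse sphere, a coarse cap with
#' `epsilon = 0.2`, a single-triangle mesh, and two synthetic bump fields on
#' the sphere (one Gaussian bump at the North Pole; two antipodal bumps).
#' Everything is generated by code, deterministically.
#'
#' @param out_dir Output directory (created if needed).
#' @return Named character vector of the written file paths, invisibly.
#' @export
make_fixtures <- function(out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c()
  sphere <- cap_mesh(0, 0.3)
  paths["sphere"] <- file.path(out_dir, "sphere_coarse.vtk")
  write_field(sphere, NULL, paths["sphere"])
  cap <- cap_mesh(0.2, 0.3)
  paths["cap"] <- file.path(out_dir, "cap_eps02_coarse.vtk")
  write_field(cap, NULL, paths["cap"])
  tri <- structure(
    list(vertices = diag(3), triangles = matrix(1:3, 1L),
         boundary_vertices = 1:3, hole_radius = 0, resolution = 1),
    class = "surface_mesh"
  )
  paths["triangle"] <- file.path(out_dir, "single_triangle.vtk")
  write_field(tri, NULL, paths["triangle"])
  bump1 <- bump_field(sphere, centres = rbind(c(0, 0, 1)))
  paths["bump1"] <- file.path(out_dir, "bump_single.vtk")
  write_field(sphere, fem_state(bump1, bump1 * 0 + 1, 0), paths["bump1"])
  bump2 <- bump_field(sphere, centres = rbind(c(0, 0, 1), c(0, 0, -1)))
  paths["bump2"] <- file.path(out_dir, "bump_antipodal.vtk")
  write_field(sphere, fem_state(bump2, bump2 * 0 + 1, 0), paths["bump2"])
  invisible(paths)
}

#' Synthetic bump field on a mesh
#'
#' Sum of Gaussian bumps in geodesic distance, a controlled stand-in for a
#' pole pattern when testing the pole-detection metrics.
#'
#' @param mesh A `surface_mesh`.
#' @param centres Matrix of bump centres (rows, 3D unit vectors).
#' @param width Geodesic standard deviation (radians).
#' @param height Bump amplitude added to a unit baseline.
#' @return Nodal vector.
#' @export
bump_field <- function(mesh, centres, width = 0.3, height = 1) {
  out <- rep(1, nrow(mesh$vertices))
  for (r in seq_len(nrow(centres))) {
    d <- geodesic_distance(mesh$vertices, centres[r, ])
    out <- out + height * exp(-d^2 / (2 * width^2))
  }
  out
}
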