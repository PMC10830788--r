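# Shared coarse meshes: built once per test run, deterministic.
coarse_sphere <- function() {
  if (is.null(.fixture_env$sphere)) .fixture_env$sphere <- cap_mesh(0, 0.3)
  .fixture_env$sphere
}

coarse_cap <- function() {
  if (is.null(.fixture_env$cap)) .fixture_env$cap <- cap_mesh(0.2, 0.3)
  .fixture_env$cap
}

fine_sphere <- function() {
  if (is.null(.fixture_env$fine)) .fixture_env$fine <- cap_mesh(0, 0.15)
  .fixture_env$fine
}

.fixture_env <- new.env(parent = emptyenv())

# a single flat unit right triangle as a raw surface_mesh (not on the sphere;
# only used for operators whose formulas are mesh-agnostic)
unit_triangle_mesh <- function() {
  structure(
    list(
      vertices = rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)),
      triangles = matrix(1:3, nrow = 1L),
      boundary_vertices = 1:3,
      hole_radius = 0,
      resolution = 1
    ),
    class = "surface_mesh"
  )
}

mode1_params <- function() schnak_params(0.2, 1, 6.87, 20)
mode2_params <- function() schnak_params(0.2, 1, 20.62, 18)
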