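#' Orthonormal real spherical harmonics
#'
#' Evaluates the real spherical harmonic \eqn{Y_{n,m}} (orthonormal on the
#' unit sphere, no Condon--Shortley phase) at Cartesian points:
#' \deqn{Y_{n,0} = \sqrt{\tfrac{2n+1}{4\pi}}\, P_n^0(\cos\theta), \qquad
#'   Y_{n,m} = \sqrt{2}\sqrt{\tfrac{2n+1}{4\pi}\tfrac{(n-m)!}{(n+m)!}}\,
#'   P_n^m(\cos\theta)\cos(m\varphi), \quad m > 0,}
#' with colatitude \eqn{\theta} measured from the North Pole. Only the
#' \eqn{m \ge 0} (cosine) branch is needed because the projection convention
#' identifies \eqn{Y_n^{-m}} with \eqn{Y_n^m}. Tabulated degrees up to
#' \eqn{n = 5} are supported.
#'
#' @param n Degree, integer in `0:5`.
#' @param m Order, `0 <= m <= n`.
#' @param xyz `N x 3` matrix of points (normalised internally).
#' @return Numeric vector of length `N`.
#' @examples
#' m <- cap_mesh(0, 0.3)
#' y <- real_sph_harm(2, 0, m$vertices)
#' @export
real_sph_harm <- function(n, m, xyz) {
  if (length(n) != 1L || length(m) != 1L || n < 0 || n > 5L || m < 0 || m > n) {
    stop("real_sph_harm(): need 0 <= m <= n <= 5", call. = FALSE)
  }
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1L)
  xyz <- xyz / sqrt(rowSums(xyz^2))
  ct <- pmin(1, pmax(-1, xyz[, 3L]))
  phi <- atan2(xyz[, 2L], xyz[, 1L])
  if (n == 0L) return(rep(1 / (2 * sqrt(pi)), nrow(xyz)))
  # pracma::legendre returns P_n^m (MATLAB convention, Condon-Shortley phase
  # included) for m = 0..n; drop the phase to match the real-harmonic table.
  P <- pracma::legendre(n, ct)
  Pm <- (-1)^m * P[m + 1L, ]
  norm <- sqrt((2 * n + 1) / (4 * pi) *
                 factorial(n - m) / factorial(n + m))
  if (m == 0L) norm * Pm else sqrt(2) * norm * Pm * cos(m * phi)
}

#' Project a nodal field onto the spherical-harmonic basis
#'
#' Computes the projection coefficients
#' \deqn{U_n^m = \int_{\Omega_\varepsilon} u\, Y_n^m \,\mathrm{d}x}
#' of a finite-element field onto the full-sphere real harmonics, with the
#' convention that the \eqn{m > 0} coefficients carry a factor
#' \eqn{1/\sqrt{2}} (the real-part-of-complex-harmonic convention). The
#' integral uses the mesh quadrature: the product \eqn{u Y} is interpolated
#' into the cG(1) space and integrated with the consistent mass matrix.
#'
#' On a punctured sphere the basis is not orthonormal on the domain; the
#' coefficients remain well-defined projections but should be read with care
#' for large holes.
#'
#' @param state A `fem_state` (or any list with a nodal vector `u`).
#' @param mesh The `surface_mesh` the field lives on.
#' @param n_max Largest degree (`<= 5`).
#' @param field Which component to project, `"u"` (default) or `"v"`.
#' @param ops Optional precomputed [assemble_operators()] result.
#' @return A tibble with columns `n`, `m`, `coefficient`.
#' @examples
#' m <- cap_mesh(0, 0.3)
#' st <- list(u = rep(1.2, nrow(m$vertices)))
#' project_harmonics(st, m, n_max = 0)$coefficient # about 1.2 * 2 * sqrt(pi)
#' @export
project_harmonics <- function(state, mesh, n_max = 4L, field = c("u", "v"),
                              ops = NULL) {
  stopifnot(inherits(mesh, "surface_mesh"))
  field <- match.arg(field)
  if (n_max < 0 || n_max > 5L) {
    stop("n_max beyond tabulated harmonics (0..5)", call. = FALSE)
  }
  u <- state[[field]]
  stopifnot(length(u) == nrow(mesh$vertices))
  if (is.null(ops)) ops <- assemble_operators(mesh)
  ones <- rep(1, ops$n)
  rows <- list()
  for (nn in 0:n_max) {
    for (mm in 0:nn) {
      y <- real_sph_harm(nn, mm, mesh$vertices)
      val <- sum(ops$mass %*% (u * y))
      if (mm > 0) val <- val / sqrt(2)
      rows[[length(rows) + 1L]] <-
        tibble::tibble(n = nn, m = mm, coefficient = val)
    }
  }
  dplyr::bind_rows(rows)
}

#' Reconstruct a nodal field from harmonic coefficients
#'
#' Inverse of [project_harmonics()] under the same convention: the field is
#' \eqn{\sum_n U_n^0 Y_{n,0} + \sum_{m>0} \sqrt{2}\, U_n^m Y_{n,m}} (the
#' \eqn{\sqrt 2} undoes the \eqn{1/\sqrt 2} coefficient convention and the
#' doubled \eqn{\pm m} terms). Exact for full-sphere fields synthesised from
#' harmonics up to the projected degree, up to quadrature error.
#'
#' @param coeffs Tibble from [project_harmonics()].
#' @param mesh The target `surface_mesh`.
#' @return Nodal vector over the mesh vertices.
#' @export
reconstruct_harmonics <- function(coeffs, mesh) {
  out <- numeric(nrow(mesh$vertices))
  for (r in seq_len(nrow(coeffs))) {
    y <- real_sph_harm(coeffs$n[r], coeffs$m[r], mesh$vertices)
    w <- if (coeffs$m[r] > 0) sqrt(2) else 1
    out <- out + w * coeffs$coefficient[r] * y
  }
  out
}
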