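#' Schnakenberg kinetic parameters
#'
#' Bundles the kinetic constants of the dimensionless Schnakenberg
#' activator--inhibitor system
#' \deqn{u_t = \Delta u + \gamma(a - u + u^2 v), \quad
#'       v_t = d\Delta v + \gamma(b - u^2 v).}
#' Here `a`, `b` are production rates, `gamma` the reaction strength
#' (scaling with domain size), and `d` the inhibitor/activator diffusion
#' ratio. All must be strictly positive (except that `a = 0` is allowed for
#' the degenerate steady-state check).
#'
#' @param a,b Production rates.
#' @param gamma Reaction strength \eqn{\gamma > 0}.
#' @param d Diffusion ratio \eqn{d > 0}.
#' @return A `schnak_params` list.
#' @examples
#' schnak_params(0.2, 1, gamma = 20.62, d = 18)
#' @export
schnak_params <- function(a, b, gamma, d) {
  vals <- c(a = a, b = b, gamma = gamma, d = d)
  if (any(!is.finite(vals)) || any(vals[c("b", "gamma", "d")] <= 0) || a < 0) {
    stop("Schnakenberg parameters must be positive", call. = FALSE)
  }
  structure(list(a = a, b = b, gamma = gamma, d = d), class = "schnak_params")
}

#' @export
print.schnak_params <- function(x, ...) {
  cat(sprintf("<schnak_params> a=%.4g b=%.4g gamma=%.4g d=%.4g\n",
              x$a, x$b, x$gamma, x$d))
  invisible(x)
}

# reaction terms of the Schnakenberg kinetics
schnak_f <- function(u, v, a) a - u + u^2 * v
schnak_g <- function(u, v, b) b - u^2 * v

#' Homogeneous steady state of the Schnakenberg kinetics
#'
#' The spatially uniform equilibrium \eqn{u_0 = a + b},
#' \eqn{v_0 = b/(a+b)^2}, at which both reaction terms vanish.
#'
#' @param a,b Production rates with `a + b > 0`.
#' @return A one-row tibble with columns `u0`, `v0`.
#' @examples
#' steady_state(0.2, 1) # u0 = 1.2, v0 = 0.6944...
#' @export
steady_state <- function(a, b) {
  if (!is.finite(a) || !is.finite(b) || a + b <= 0) {
    stop("steady_state() requires a + b > 0", call. = FALSE)
  }
  u0 <- a + b
  v0 <- b / (a + b)^2
  tibble::tibble(u0 = u0, v0 = v0)
}

#' Linearised Schnakenberg kinetics at the steady state
#'
#' Partial derivatives of the reaction terms \eqn{f = a - u + u^2v},
#' \eqn{g = b - u^2v} evaluated at the homogeneous steady state, plus the
#' Jacobian determinant. These drive every stability formula in the package.
#'
#' @inheritParams steady_state
#' @return A one-row tibble with columns `f_u`, `f_v`, `g_u`, `g_v`, `det_A`.
#' @examples
#' linearize_kinetics(0.2, 1)
#' @export
linearize_kinetics <- function(a, b) {
  ss <- steady_state(a, b)
  u0 <- ss$u0
  v0 <- ss$v0
  f_u <- -1 + 2 * u0 * v0
  f_v <- u0^2
  g_u <- -2 * u0 * v0
  g_v <- -u0^2
  tibble::tibble(f_u = f_u, f_v = f_v, g_u = g_u, g_v = g_v,
                 det_A = f_u * g_v - f_v * g_u)
}

#' Check the four Turing (diffusion-driven instability) conditions
#'
#' A homogeneous steady state admits diffusion-driven instability when it is
#' linearly stable without diffusion but destabilised by it:
#' \eqn{f_u + g_v < 0}, \eqn{\det A > 0}, \eqn{d f_u + g_v > 0}, and
#' \eqn{(d f_u + g_v)^2 - 4 d \det A > 0}. The reaction strength
#' \eqn{\gamma} plays no role in the conditions themselves.
#'
#' @param params A [schnak_params()] object.
#' @param tol Strictness tolerance for the inequalities (default `1e-12`).
#' @return A one-row tibble with logical columns `trace_negative`,
#'   `det_positive`, `cross_positive`, `discriminant_positive`, and `turing`
#'   (the conjunction), plus the numeric `discriminant`.
#' @examples
#' turing_conditions(schnak_params(0.2, 1, 20.62, 18))
#' @export
turing_conditions <- function(params, tol = 1e-12) {
  stopifnot(inherits(params, "schnak_params"))
  lk <- linearize_kinetics(params$a, params$b)
  d <- params$d
  disc <- (d * lk$f_u + lk$g_v)^2 - 4 * d * lk$det_A
  out <- tibble::tibble(
    trace_negative = lk$f_u + lk$g_v < -tol,
    det_positive = lk$det_A > tol,
    cross_positive = d * lk$f_u + lk$g_v > tol,
    discriminant_positive = disc > tol,
    discriminant = disc
  )
  out$turing <- out$trace_negative & out$det_positive &
    out$cross_positive & out$discriminant_positive
  out
}

#' Critical diffusion ratio for diffusion-driven instability
#'
#' The smallest diffusion ratio at which a Turing instability becomes
#' possible:
#' \deqn{d_c = \frac{(f_u g_v - 2 f_v g_u) +
#'   \sqrt{(f_u g_v - 2 f_v g_u)^2 - f_u^2 g_v^2}}{f_u^2}.}
#' At \eqn{d = d_c} the dispersion-relation discriminant vanishes and the
#' band of unstable eigenvalues degenerates to a single point.
#'
#' @inheritParams steady_state
#' @return The critical diffusion ratio \eqn{d_c} (scalar).
#' @examples
#' critical_diffusion(0.2, 1) # about 17.01
#' @export
critical_diffusion <- function(a, b) {
  lk <- linearize_kinetics(a, b)
  if (abs(lk$f_u) < 1e-14) {
    stop("singular kinetics: f_u = 0, no critical diffusion", call. = FALSE)
  }
  s <- lk$f_u * lk$g_v - 2 * lk$f_v * lk$g_u
  disc <- s^2 - lk$f_u^2 * lk$g_v^2
  if (disc < 0) {
    stop("no criticality: negative discriminant in critical_diffusion()",
         call. = FALSE)
  }
  (s + sqrt(disc)) / lk$f_u^2
}

#' Critical reaction strength isolating eigenmode n
#'
#' Reaction strength \eqn{\gamma_c(n)} placing the spherical-harmonic
#' eigenvalue \eqn{\lambda_n = n(n+1)} exactly at the degenerate point of the
#' unstable interval when \eqn{d = d_c}, so that a single mode is excited:
#' \deqn{\gamma_c(n) = \frac{2 d_c\, n(n+1)}{d_c f_u + g_v}.}
#'
#' The literature sometimes prints this formula with \eqn{n^2(n+1)^2} in the
#' numerator, but the tabulated values it is used to produce (6.87, 20.62,
#' 41.24, 68.73 for \eqn{n = 1,\dots,4} at \eqn{(a,b) = (0.20, 1.00)})
#' correspond to the \eqn{n(n+1)} form, which is therefore the default here.
#' Set `as_printed = TRUE` to evaluate the \eqn{n^2(n+1)^2} variant.
#'
#' @param n Eigenmode degree (positive integer); vectorised.
#' @inheritParams steady_state
#' @param d_c Critical diffusion; defaults to [critical_diffusion()] at
#'   `(a, b)`.
#' @param as_printed Use the \eqn{n^2(n+1)^2} numerator variant.
#' @return \eqn{\gamma_c(n)}, same length as `n`.
#' @examples
#' critical_gamma(1:4, 0.2, 1) # 6.87, 20.62, 41.24, 68.73
#' @export
critical_gamma <- function(n, a, b, d_c = critical_diffusion(a, b),
                           as_printed = FALSE) {
  if (any(n < 1) || any(n != round(n))) {
    stop("`n` must be a positive integer", call. = FALSE)
  }
  lk <- linearize_kinetics(a, b)
  denom <- d_c * lk$f_u + lk$g_v
  if (denom <= 0) {
    stop("d_c * f_u + g_v must be positive for critical_gamma()",
         call. = FALSE)
  }
  lam <- if (as_printed) n^2 * (n + 1)^2 else n * (n + 1)
  2 * d_c * lam / denom
}

#' Unstable eigenvalue interval of the dispersion relation
#'
#' Bounds \eqn{(\gamma L, \gamma M)} such that a Laplace--Beltrami eigenvalue
#' \eqn{\lambda} drives pattern growth iff
#' \eqn{\gamma L < \lambda < \gamma M}, with
#' \deqn{L, M = \frac{d f_u + g_v \mp
#'   \sqrt{(d f_u + g_v)^2 - 4 d \det A}}{2d}.}
#' When the discriminant is negative the interval is empty and both bounds
#' are returned as `NA` (with `empty = TRUE`), not an error.
#'
#' @param params A [schnak_params()] object.
#' @return A one-row tibble with columns `gamma_L`, `gamma_M`, `empty`.
#' @examples
#' unstable_interval(schnak_params(0.2, 1, 20.62, 18)) # contains lambda = 6
#' @export
unstable_interval <- function(params) {
  stopifnot(inherits(params, "schnak_params"))
  lk <- linearize_kinetics(params$a, params$b)
  d <- params$d
  g <- params$gamma
  s <- d * lk$f_u + lk$g_v
  disc <- s^2 - 4 * d * lk$det_A
  if (disc < 0) {
    return(tibble::tibble(gamma_L = NA_real_, gamma_M = NA_real_,
                          empty = TRUE))
  }
  tibble::tibble(
    gamma_L = g * (s - sqrt(disc)) / (2 * d),
    gamma_M = g * (s + sqrt(disc)) / (2 * d),
    empty = FALSE
  )
}

#' Perturbed Laplace--Beltrami eigenvalues of the sphere with a small hole
#'
#' Leading-order asymptotics for the Neumann eigenvalues
#' \eqn{\lambda_n^m(\varepsilon)} of the unit sphere with a geodesic disc of
#' radius \eqn{\varepsilon} removed:
#' \deqn{\lambda_n^0(\varepsilon) = n(n+1) +
#'   (2n+1)\frac{n(n+1)}{4}\varepsilon^2,}
#' \deqn{\lambda_n^m(\varepsilon) = n(n+1) -
#'   (2n+1) c_n^m \varepsilon^{2m}, \quad
#'   c_n^m = \frac{(m+n)!}{4^m\, m!\, (m-1)!\, (n-m)!}, \quad m \ge 1.}
#' The series are truncated at leading order (little-o remainders dropped),
#' so they are quantitative only for small \eqn{\varepsilon}: the zonal
#' branch (\eqn{m = 0}) shifts up, all others shift down.
#'
#' The zonal coefficient is sometimes printed as \eqn{4/(n(n+1))} rather
#' than \eqn{n(n+1)/4}. The discrete Laplace--Beltrami spectrum (see
#' [lb_eigenpairs()]) validates the \eqn{n(n+1)/4} form for every degree
#' tested, so it is the default; the reciprocal variant is available with
#' `as_printed = TRUE`. The two agree for \eqn{n = 1} up to a factor 4 and
#' the choice never affects which modes are excited for small holes.
#'
#' @param n Degree (integer \eqn{\ge 1}); vectorised together with `m` and
#'   `epsilon` in the usual recycling sense.
#' @param m Order, \eqn{0 \le m \le n}.
#' @param epsilon Hole radius in radians (\eqn{\ge 0}).
#' @param as_printed Use the reciprocal \eqn{4/(n(n+1))} zonal coefficient.
#' @return A tibble with columns `n`, `m`, `epsilon`, `c_nm` (expansion
#'   coefficient, `NA` for `m = 0`) and `value` (\eqn{\lambda_n^m(\varepsilon)}).
#' @examples
#' perturbed_eigenvalue(1, 1, 0.2) # 2 - 1.5 * 0.04
#' @export
perturbed_eigenvalue <- function(n, m, epsilon, as_printed = FALSE) {
  k <- max(length(n), length(m), length(epsilon))
  n <- rep_len(as.integer(n), k)
  m <- rep_len(as.integer(m), k)
  epsilon <- rep_len(epsilon, k)
  if (any(n < 1) || any(m < 0) || any(m > n)) {
    stop("require n >= 1 and 0 <= m <= n", call. = FALSE)
  }
  if (any(epsilon < 0)) stop("epsilon must be >= 0", call. = FALSE)
  base <- n * (n + 1)
  c_nm <- ifelse(
    m == 0, NA_real_,
    factorial(m + n) / (4^m * factorial(m) * factorial(pmax(m - 1, 0)) *
                          factorial(n - m))
  )
  zonal_coef <- if (as_printed) 4 / base else base / 4
  value <- ifelse(
    m == 0,
    base + (2 * n + 1) * zonal_coef * epsilon^2,
    base - (2 * n + 1) * c_nm * epsilon^(2 * m)
  )
  tibble::tibble(n = n, m = m, epsilon = epsilon, c_nm = c_nm, value = value)
}

#' Modes excited on the punctured sphere
#'
#' Filters the perturbed eigenvalues \eqn{\lambda_n^m(\varepsilon)} for
#' \eqn{1 \le n \le n_{max}}, \eqn{0 \le m \le n} against the unstable
#' interval of [unstable_interval()]: a mode contributes to the pattern iff
#' \eqn{\gamma L < \lambda_n^m(\varepsilon) < \gamma M}.
#'
#' @param params A [schnak_params()] object.
#' @param epsilon Hole radius in radians.
#' @param n_max Largest degree scanned.
#' @return Tibble of the excited modes: columns `n`, `m`, `lambda`.
#' @examples
#' excited_modes(schnak_params(0.2, 1, 20.62, 18), epsilon = 0, n_max = 4)
#' @export
excited_modes <- function(params, epsilon, n_max) {
  stopifnot(n_max >= 1)
  iv <- unstable_interval(params)
  grid <- do.call(rbind, lapply(seq_len(n_max), function(nn) {
    cbind(n = nn, m = 0:nn)
  }))
  pe <- perturbed_eigenvalue(grid[, "n"], grid[, "m"], epsilon)
  keep <- if (iv$empty) rep(FALSE, nrow(pe)) else
    pe$value > iv$gamma_L & pe$value < iv$gamma_M
  tibble::tibble(n = pe$n[keep], m = pe$m[keep], lambda = pe$value[keep])
}
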