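#' Assemble surface finite-element operators on a mesh
#'
#' Builds the cG(1) (piecewise-linear) mass matrix \eqn{M} and
#' Laplace--Beltrami stiffness matrix \eqn{K} on the flat-triangle
#' approximation of the surface, element by element. Surface gradients live
#' in each triangle's plane; the classical edge formula
#' \eqn{K_{ij} = e_i \cdot e_j / (4A)} (opposite edges \eqn{e_i}) is used for
#' the stiffness and \eqn{A/12\,[2,1,1;1,2,1;1,1,2]} for the consistent mass.
#' Homogeneous Neumann (no-flux) conditions are natural: no boundary rows are
#' modified, so constants lie in the nullspace of \eqn{K}.
#'
#' The returned object also carries the machinery for state-dependent
#' weighted mass matrices \eqn{M_w} (the cG(1)-interpolated products needed by
#' the semi-implicit reaction treatment): a sparse map `S` such that the
#' nonzero slots of \eqn{M_w} equal `S %*% w` for nodal weights `w`, plus the
#' row-sum lumped mass.
#'
#' @param mesh A [cap_mesh()] `surface_mesh`.
#' @return A `fem_operators` list: `mass`, `stiffness` (both
#'   `dgCMatrix`, symmetric), `n` (vertex count), `lumped` (vector of lumped
#'   masses), and internal fields used by [sbem_step()].
#' @examples
#' ops <- assemble_operators(cap_mesh(0, 0.3))
#' sum(ops$mass)      # total area, about 4*pi
#' max(abs(ops$stiffness %*% rep(1, ops$n)))  # ~0: constants are in the nullspace
#' @export
assemble_operators <- function(mesh) {
  stopifnot(inherits(mesh, "surface_mesh"))
  tri <- mesh$triangles
  v <- mesh$vertices
  n <- nrow(v)
  areas <- triangle_areas(mesh)
  if (min(areas) <= 0) {
    stop(sprintf("degenerate triangle %d in mesh", which.min(areas)),
         call. = FALSE)
  }
  p1 <- v[tri[, 1L], , drop = FALSE]
  p2 <- v[tri[, 2L], , drop = FALSE]
  p3 <- v[tri[, 3L], , drop = FALSE]
  # edge opposite vertex i
  e1 <- p3 - p2
  e2 <- p1 - p3
  e3 <- p2 - p1
  ee <- list(e1, e2, e3)

  ii <- jj <- integer(0)
  xk <- xm <- numeric(0)
  loc_i <- rep(1:3, each = 3L)
  loc_j <- rep(1:3, times = 3L)
  ntri <- nrow(tri)
  ii <- as.vector(tri[, loc_i])
  jj <- as.vector(tri[, loc_j])
  xk <- numeric(9L * ntri)
  xm <- numeric(9L * ntri)
  mass_loc <- matrix(c(2, 1, 1, 1, 2, 1, 1, 1, 2), 3, 3) / 12
  for (p in 1:9) {
    i <- loc_i[p]
    j <- loc_j[p]
    rng <- ((p - 1L) * ntri + 1L):(p * ntri)
    xk[rng] <- rowSums(ee[[i]] * ee[[j]]) / (4 * areas)
    xm[rng] <- mass_loc[i, j] * areas
  }
  # reorder so entries are grouped triangle-major (matches ii/jj layout)
  ord <- as.vector(matrix(seq_len(9L * ntri), ntri, 9L, byrow = FALSE))
  K <- Matrix::sparseMatrix(i = ii, j = jj, x = xk, dims = c(n, n))
  M <- Matrix::sparseMatrix(i = ii, j = jj, x = xm, dims = c(n, n))

  # Weighted-mass template: entry (i,j) of M_w with nodal weights w is
  #   sum over incident triangles of A/60 * (coefficients in w at the three
  #   triangle vertices): diagonal (i==j): (6, 2, 2); off-diagonal: (2, 2, 1).
  # Build S with one row per nonzero slot of the (M-pattern) matrix so that
  # Mw@x == S %*% w.
  patt <- M
  patt@x <- rep(1, length(patt@x))
  # slot index of each (ii, jj) triplet within the dgCMatrix
  slot <- slot_index(M, ii, jj)
  si <- integer(27L * ntri)
  sj <- integer(27L * ntri)
  sx <- numeric(27L * ntri)
  pos <- 0L
  for (p in 1:9) {
    i <- loc_i[p]
    j <- loc_j[p]
    k <- 6L - i - j  # remaining local vertex when i != j; unused if i == j
    if (i == j) {
      others <- setdiff(1:3, i)
      cf <- c(6, 2, 2)
      cols <- cbind(tri[, i], tri[, others[1L]], tri[, others[2L]])
    } else {
      cf <- c(2, 2, 1)
      cols <- cbind(tri[, i], tri[, j], tri[, k])
    }
    rng <- ((p - 1L) * ntri + 1L):(p * ntri)
    for (q in 1:3) {
      idx <- pos + seq_len(ntri)
      si[idx] <- slot[rng]
      sj[idx] <- cols[, q]
      sx[idx] <- cf[q] * areas / 60
      pos <- pos + ntri
    }
  }
  S <- Matrix::sparseMatrix(i = si, j = sj, x = sx,
                            dims = c(length(M@x), n))

  structure(
    list(
      mass = M,
      stiffness = K,
      n = n,
      lumped = as.vector(M %*% rep(1, n)),
      weight_map = S,
      mass_x = M@x,
      stiff_x = K@x,
      pattern = M,  # any matrix with the shared sparsity pattern
      diag_slots = slot_index(M, seq_len(n), seq_len(n))
    ),
    class = "fem_operators"
  )
}

# positions of (i, j) entries within a dgCMatrix @x vector
slot_index <- function(A, i, j) {
  dp <- diff(A@p)
  col_of <- rep.int(seq_along(dp), dp)
  key_A <- A@i + 1 + as.numeric(col_of - 1) * nrow(A)
  key_q <- i + as.numeric(j - 1) * nrow(A)
  match(key_q, key_A)
}

#' @export
print.fem_operators <- function(x, ...) {
  cat(sprintf("<fem_operators> %d nodes, mass sum %.6g, %d nonzeros\n",
              x$n, sum(x$mass_x), length(x$mass_x)))
  invisible(x)
}

#' Seeded random initial condition near the homogeneous steady state
#'
#' Perturbs the steady state independently at every node:
#' \eqn{u_i = u_0 + \eta_i}, \eqn{v_i = v_0 + \xi_i} with
#' \eqn{\eta, \xi \sim U[-\mathrm{amplitude}, \mathrm{amplitude})}. The
#' activator perturbations are drawn before the inhibitor ones, in node-index
#' order, so replicates are portable across machines.
#'
#' @param mesh A `surface_mesh`.
#' @param steady One-row tibble/list with `u0`, `v0` (see [steady_state()]).
#' @param amplitude Perturbation half-width (default `1e-4`).
#' @param seed Integer seed; the RNG state of the session is left untouched.
#' @return A `fem_state`: list with nodal vectors `u`, `v` and time `t = 0`.
#' @export
initial_state <- function(mesh, steady, amplitude = 1e-4, seed = 1L) {
  stopifnot(inherits(mesh, "surface_mesh"), amplitude >= 0)
  n <- nrow(mesh$vertices)
  draws <- withr::with_seed(as.integer(seed), stats::runif(2L * n, -1, 1))
  # map [-1, 1) draws onto [-amplitude, amplitude)
  u <- steady$u0 + amplitude * draws[seq_len(n)]
  v <- steady$v0 + amplitude * draws[n + seq_len(n)]
  fem_state(u, v, t = 0)
}

fem_state <- function(u, v, t) {
  stopifnot(length(u) == length(v), all(is.finite(u)), all(is.finite(v)))
  structure(list(u = u, v = v, t = t), class = "fem_state")
}

#' @export
print.fem_state <- function(x, ...) {
  cat(sprintf("<fem_state> t=%.4g, %d nodes, u in [%.4g, %.4g], v in [%.4g, %.4g]\n",
              x$t, length(x$u), min(x$u), max(x$u), min(x$v), max(x$v)))
  invisible(x)
}

# System matrices for one semi-implicit step. The reaction nonlinearities are
# frozen at the previous state, so the activator and inhibitor decouple:
#   (M(1 + k*gamma) + k*K   - k*gamma*M_w ) u_i = M u_{i-1} + k*gamma*a*M*1
#   (M              + k*d*K + k*gamma*M_w2) v_i = M v_{i-1} + k*gamma*b*M*1
# with w = u_{i-1} * v_{i-1}, w2 = u_{i-1}^2, and M_w the cG(1)-consistent
# mass weighted by the nodal interpolant of w.
sbem_matrices <- function(state, ops, params, k, lumped = FALSE) {
  g <- params$gamma
  d <- params$d
  w <- state$u * state$v
  w2 <- state$u^2
  A_u <- ops$pattern
  A_v <- ops$pattern
  if (lumped) {
    xm <- numeric(length(ops$mass_x))
    xm[ops$diag_slots] <- ops$lumped
    xw <- numeric(length(xm))
    xw[ops$diag_slots] <- ops$lumped * w
    xw2 <- numeric(length(xm))
    xw2[ops$diag_slots] <- ops$lumped * w2
  } else {
    xm <- ops$mass_x
    xw <- as.vector(ops$weight_map %*% w)
    xw2 <- as.vector(ops$weight_map %*% w2)
  }
  A_u@x <- (1 + k * g) * xm + k * ops$stiff_x - k * g * xw
  A_v@x <- xm + k * d * ops$stiff_x + k * g * xw2
  mass_mult <- if (lumped) function(z) ops$lumped * z
  else function(z) as.vector(ops$mass %*% z)
  list(A_u = A_u, A_v = A_v, mass_mult = mass_mult)
}

#' One step of the semi-implicit backward-Euler (1-SBEM) scheme
#'
#' Advances the Schnakenberg system by one time step of size `k`. The scheme
#' is backward Euler in time with the reaction nonlinearities linearised
#' about the previous step (\eqn{f \to a - u_i + u_i u_{i-1} v_{i-1}},
#' \eqn{g \to b - u_{i-1}^2 v_i}), so the activator and inhibitor updates
#' decouple into two independent sparse symmetric linear solves. The
#' homogeneous steady state is an exact fixed point of the step.
#'
#' @param state A `fem_state` at time \eqn{t_{i-1}}.
#' @param ops [assemble_operators()] output for the same mesh.
#' @param params A [schnak_params()] object.
#' @param k Step size (> 0).
#' @param lumped Use row-sum mass lumping for all mass terms (faster,
#'   diagonal reaction coupling); default `FALSE` (consistent mass).
#' @return The `fem_state` at time \eqn{t_{i-1} + k}.
#' @export
sbem_step <- function(state, ops, params, k, lumped = FALSE) {
  stopifnot(inherits(state, "fem_state"), inherits(ops, "fem_operators"),
            k > 0, length(state$u) == ops$n)
  mats <- sbem_matrices(state, ops, params, k, lumped)
  g <- params$gamma
  rhs_u <- mats$mass_mult(state$u) + k * g * params$a * ops$lumped
  rhs_v <- mats$mass_mult(state$v) + k * g * params$b * ops$lumped
  u_new <- as.vector(Matrix::solve(mats$A_u, rhs_u))
  v_new <- as.vector(Matrix::solve(mats$A_v, rhs_v))
  fem_state(u_new, v_new, state$t + k)
}

#' Simulate the Schnakenberg system on a surface mesh
#'
#' Runs the full pipeline for one replicate: seeded random initial condition
#' around the homogeneous steady state, then `T/k` steps of the semi-implicit
#' 1-SBEM scheme. No-flux (homogeneous Neumann) conditions on the hole rim
#' are natural to the weak form, so holes need no special treatment.
#'
#' For speed the two system matrices are refactorised each step with a reused
#' symbolic Cholesky analysis (their sparsity pattern never changes).
#'
#' @param mesh A [cap_mesh()] `surface_mesh`.
#' @param params A [schnak_params()] object.
#' @param T_final Final time (default 50, long enough for the pattern to
#'   stabilise).
#' @param k Step size; defaults per excited mode in the source study are
#'   0.01 (modes 1--2) and 0.005 (modes 3--4).
#' @param seed Integer seed for the initial perturbation.
#' @param amplitude Perturbation half-width (default `1e-4`).
#' @param snapshot_times Times (multiples of `k`) at which to store copies of
#'   the state; the default mirrors the reference visualisation times.
#' @param lumped Mass lumping flag passed to the stepper.
#' @param verbose Print min/max of `u`, `v` every 100 steps.
#' @return A `fem_simulation`: list with the final `state`, `snapshots`
#'   (named list of `fem_state`s), `mesh`, `params`, and a one-row tibble
#'   `log` (u/v ranges, step count, runtime in seconds).
#' @examples
#' \donttest{
#' m <- cap_mesh(0, 0.15)
#' sim <- simulate_schnakenberg(m, schnak_params(0.2, 1, 20.62, 18),
#'                              T_final = 5, seed = 1)
#' range(sim$state$u)
#' }
#' @export
simulate_schnakenberg <- function(mesh, params, T_final = 50, k = 0.01,
                                  seed = 1L, amplitude = 1e-4,
                                  snapshot_times = c(0, 32, 35, 37, 50),
                                  lumped = FALSE, verbose = FALSE) {
  stopifnot(inherits(mesh, "surface_mesh"), inherits(params, "schnak_params"))
  t0 <- proc.time()[["elapsed"]]
  ops <- assemble_operators(mesh)
  ss <- steady_state(params$a, params$b)
  state <- initial_state(mesh, ss, amplitude = amplitude, seed = seed)
  n_steps <- as.integer(round(T_final / k))
  if (abs(n_steps * k - T_final) > 1e-9 * max(1, T_final)) {
    stop("T_final must be an integer multiple of the step size k",
         call. = FALSE)
  }
  snapshot_times <- snapshot_times[snapshot_times <= T_final]
  snaps <- list()
  if (0 %in% snapshot_times) snaps[["t=0"]] <- state
  snap_steps <- round(snapshot_times / k)

  g <- params$gamma
  chol_u <- NULL
  chol_v <- NULL
  rhs_a <- k * g * params$a * ops$lumped
  rhs_b <- k * g * params$b * ops$lumped
  for (i in seq_len(n_steps)) {
    mats <- sbem_matrices(state, ops, params, k, lumped)
    if (is.null(chol_u)) {
      chol_u <- Matrix::Cholesky(Matrix::forceSymmetric(mats$A_u),
                                 LDL = FALSE, perm = TRUE)
      chol_v <- Matrix::Cholesky(Matrix::forceSymmetric(mats$A_v),
                                 LDL = FALSE, perm = TRUE)
    } else {
      chol_u <- Matrix::update(chol_u, Matrix::forceSymmetric(mats$A_u))
      chol_v <- Matrix::update(chol_v, Matrix::forceSymmetric(mats$A_v))
    }
    u_new <- as.vector(Matrix::solve(
      chol_u, mats$mass_mult(state$u) + rhs_a, system = "A"))
    v_new <- as.vector(Matrix::solve(
      chol_v, mats$mass_mult(state$v) + rhs_b, system = "A"))
    if (anyNA(u_new) || any(!is.finite(u_new)) || any(!is.finite(v_new))) {
      stop(sprintf("instability: non-finite solution at step %d (t=%.4g)",
                   i, i * k), call. = FALSE)
    }
    state <- fem_state(u_new, v_new, i * k)
    if (verbose && i %% 100L == 0L) {
      message(sprintf("step %d t=%.3f u:[%.4f, %.4f] v:[%.4f, %.4f]",
                      i, state$t, min(u_new), max(u_new),
                      min(v_new), max(v_new)))
    }
    if (i %in% snap_steps) snaps[[sprintf("t=%g", state$t)]] <- state
  }
  elapsed <- proc.time()[["elapsed"]] - t0
  structure(
    list(
      state = state,
      snapshots = snaps,
      mesh = mesh,
      params = params,
      log = tibble::tibble(
        seed = as.integer(seed), epsilon = mesh$hole_radius,
        n_steps = n_steps, k = k, T_final = T_final,
        u_min = min(state$u), u_max = max(state$u),
        v_min = min(state$v), v_max = max(state$v),
        runtime_s = elapsed
      )
    ),
    class = "fem_simulation"
  )
}

#' @export
print.fem_simulation <- function(x, ...) {
  cat(sprintf(
    "<fem_simulation> t=%g on %d nodes (eps=%.3g): u in [%.4f, %.4f]\n",
    x$state$t, length(x$state$u), x$mesh$hole_radius,
    min(x$state$u), max(x$state$u)))
  invisible(x)
}

#' Discrete Laplace--Beltrami eigenpairs
#'
#' Smallest generalized eigenvalues of \eqn{K x = \lambda M x} on the mesh,
#' the discrete counterpart of the Neumann Laplace--Beltrami eigenproblem.
#' On the closed sphere the exact spectrum is \eqn{n(n+1)} with multiplicity
#' \eqn{2n+1}; on the punctured sphere the eigenvalues split according to the
#' perturbation asymptotics of [perturbed_eigenvalue()]. The first eigenvalue
#' is always (numerically) zero with a constant eigenvector.
#'
#' @param ops [assemble_operators()] output.
#' @param n_eigs Number of smallest eigenpairs (default 16: enough for
#'   degrees up to \eqn{n = 3}).
#' @param method `"auto"` (shift-invert ARPACK above 900 nodes, dense below),
#'   `"arpack"`, or `"dense"`.
#' @return List with `values` (ascending) and `vectors`
#'   (`n x n_eigs`, M-orthonormal).
#' @export
lb_eigenpairs <- function(ops, n_eigs = 16L,
                          method = c("auto", "arpack", "dense")) {
  stopifnot(inherits(ops, "fem_operators"), n_eigs >= 1)
  method <- match.arg(method)
  if (method == "auto") method <- if (ops$n > 900) "arpack" else "dense"
  K <- Matrix::forceSymmetric(ops$stiffness)
  M <- Matrix::forceSymmetric(ops$mass)
  if (method == "dense") {
    Md <- as.matrix(M)
    R <- chol(Md)
    Kd <- as.matrix(K)
    A <- backsolve(R, t(backsolve(R, Kd, transpose = TRUE)),
                   transpose = TRUE)
    A <- (A + t(A)) / 2
    ev <- eigen(A, symmetric = TRUE)
    idx <- order(ev$values)[seq_len(min(n_eigs, ops$n))]
    vecs <- backsolve(R, ev$vectors[, idx, drop = FALSE])
    return(list(values = ev$values[idx], vectors = vecs))
  }
  # shift-invert: largest eigenvalues of (K + sigma*M)^{-1} M correspond to
  # the smallest lambda; Rayleigh-Ritz in the returned subspace cleans up
  # ARPACK's nonsymmetric-mode output.
  sigma <- 1
  ch <- Matrix::Cholesky(K + sigma * M, LDL = FALSE, perm = TRUE)
  fn <- function(x, extra) {
    as.vector(Matrix::solve(ch, as.vector(M %*% x), system = "A"))
  }
  nev <- min(n_eigs + 4L, ops$n - 2L)
  res <- igraph::arpack(
    fn, sym = FALSE,
    options = list(n = ops$n, nev = nev, ncv = min(ops$n, max(4L * nev, 40L)),
                   which = "LM", maxiter = 5000)
  )
  X <- Re(res$vectors)
  X <- qr.Q(qr(X))
  B <- crossprod(X, as.matrix(K %*% X))
  C <- crossprod(X, as.matrix(M %*% X))
  B <- (B + t(B)) / 2
  C <- (C + t(C)) / 2
  Rc <- chol(C)
  Ar <- backsolve(Rc, t(backsolve(Rc, B, transpose = TRUE)), transpose = TRUE)
  ev <- eigen((Ar + t(Ar)) / 2, symmetric = TRUE)
  idx <- order(ev$values)[seq_len(min(n_eigs, length(ev$values)))]
  vecs <- X %*% backsolve(Rc, ev$vectors[, idx, drop = FALSE])
  list(values = ev$values[idx], vectors = vecs)
}
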