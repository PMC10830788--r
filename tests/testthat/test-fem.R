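test_that("P1 element matrices match the closed-form single-triangle forms", {
  ops <- assemble_operators(unit_triangle_mesh())
  A <- 0.5
  expect_equal(as.matrix(ops$mass),
               A / 12 * matrix(c(2, 1, 1, 1, 2, 1, 1, 1, 2), 3, 3),
               ignore_attr = TRUE)
  # stiffness of the unit right triangle (hat-function gradients)
  expect_equal(as.matrix(ops$stiffness),
               matrix(c(1, -0.5, -0.5, -0.5, 0.5, 0, -0.5, 0, 0.5), 3, 3),
               ignore_attr = TRUE)
  expect_equal(sum(ops$mass), A)
})

test_that("assembled operators satisfy their invariants on sphere and cap", {
  for (m in list(coarse_sphere(), coarse_cap())) {
    ops <- assemble_operators(m)
    ones <- rep(1, ops$n)
    # constants in the stiffness nullspace (natural Neumann condition)
    expect_lt(max(abs(ops$stiffness %*% ones)), 1e-10)
    # mass sums to the surface area
    expect_equal(sum(ops$mass), mesh_area(m), tolerance = 1e-10)
    # symmetry
    expect_lt(max(abs(ops$stiffness - Matrix::t(ops$stiffness))), 1e-12)
    expect_lt(max(abs(ops$mass - Matrix::t(ops$mass))), 1e-12)
    # weighted-mass template reproduces M at unit weights
    xw <- as.vector(ops$weight_map %*% ones)
    expect_equal(xw, ops$mass_x, tolerance = 1e-12)
    # lumped mass also sums to the area
    expect_equal(sum(ops$lumped), mesh_area(m), tolerance = 1e-10)
  }
})

test_that("initial conditions are seeded, bounded and reproducible", {
  m <- coarse_sphere()
  ss <- steady_state(0.2, 1)
  st0 <- initial_state(m, ss, amplitude = 0, seed = 1)
  expect_equal(st0$u, rep(ss$u0, nrow(m$vertices)))
  expect_equal(st0$v, rep(ss$v0, nrow(m$vertices)))
  st1 <- initial_state(m, ss, seed = 7)
  st2 <- initial_state(m, ss, seed = 7)
  expect_identical(st1, st2)
  expect_false(identical(st1$u, initial_state(m, ss, seed = 8)$u))
  expect_true(all(abs(st1$u - ss$u0) <= 1e-4))
  expect_true(all(abs(st1$v - ss$v0) <= 1e-4))
  # drawing does not disturb the session RNG
  set.seed(123); x <- runif(1)
  set.seed(123); initial_state(m, ss, seed = 5); y <- runif(1)
  expect_identical(x, y)
})

test_that("the homogeneous steady state is a fixed point of the step", {
  m <- coarse_cap()
  ops <- assemble_operators(m)
  ss <- steady_state(0.2, 1)
  st <- turingcap:::fem_state(rep(ss$u0, ops$n), rep(ss$v0, ops$n), 0)
  for (lumped in c(FALSE, TRUE)) {
    st1 <- sbem_step(st, ops, mode2_params(), k = 0.01, lumped = lumped)
    expect_lt(max(abs(st1$u - ss$u0)), 1e-10)
    expect_lt(max(abs(st1$v - ss$v0)), 1e-10)
  }
})

test_that("a uniform state advances exactly like the 0-D scheme", {
  # constants are annihilated by K, so the step must reduce to the scalar
  # semi-implicit update; computed here independently by solving the two
  # 1x1 linearised equations
  m <- coarse_sphere()
  ops <- assemble_operators(m)
  p <- mode2_params()
  k <- 0.02
  u_prev <- 1.05; v_prev <- 0.8
  st <- turingcap:::fem_state(rep(u_prev, ops$n), rep(v_prev, ops$n), 0)
  st1 <- sbem_step(st, ops, p, k)
  u_scalar <- (u_prev + k * p$gamma * p$a) /
    (1 + k * p$gamma * (1 - u_prev * v_prev))
  v_scalar <- (v_prev + k * p$gamma * p$b) / (1 + k * p$gamma * u_prev^2)
  expect_equal(st1$u, rep(u_scalar, ops$n), tolerance = 1e-10)
  expect_equal(st1$v, rep(v_scalar, ops$n), tolerance = 1e-10)
})

test_that("one step agrees with a dense-matrix reference solve", {
  m <- coarse_cap()
  ops <- assemble_operators(m)
  p <- mode2_params()
  k <- 0.01
  st <- initial_state(m, steady_state(p$a, p$b), amplitude = 0.05, seed = 3)
  st1 <- sbem_step(st, ops, p, k)

  # independent dense assembly of the same linear systems
  M <- as.matrix(ops$mass)
  K <- as.matrix(ops$stiffness)
  n <- ops$n
  Mw <- function(w) {
    # consistent mass weighted by the P1 interpolant of w, dense loop
    out <- matrix(0, n, n)
    tri <- m$triangles
    areas <- turingcap:::triangle_areas(m)
    for (t in seq_len(nrow(tri))) {
      id <- tri[t, ]
      wt <- st$u[id] * st$v[id] * 0 + w[id]  # local weights
      loc <- matrix(0, 3, 3)
      for (i in 1:3) for (j in 1:3) {
        if (i == j) {
          oth <- setdiff(1:3, i)
          loc[i, j] <- (6 * wt[i] + 2 * wt[oth[1]] + 2 * wt[oth[2]]) / 60
        } else {
          kk <- setdiff(1:3, c(i, j))
          loc[i, j] <- (2 * wt[i] + 2 * wt[j] + wt[kk]) / 60
        }
      }
      out[id, id] <- out[id, id] + areas[t] * loc
    }
    out
  }
  g <- p$gamma
  A_u <- (1 + k * g) * M + k * K - k * g * Mw(st$u * st$v)
  A_v <- M + k * p$d * K + k * g * Mw(st$u^2)
  ones <- rep(1, n)
  u_ref <- solve(A_u, M %*% st$u + k * g * p$a * (M %*% ones))
  v_ref <- solve(A_v, M %*% st$v + k * g * p$b * (M %*% ones))
  expect_equal(st1$u, as.vector(u_ref), tolerance = 1e-8)
  expect_equal(st1$v, as.vector(v_ref), tolerance = 1e-8)
})

test_that("simulate preserves the steady state and enforces the time grid", {
  m <- coarse_sphere()
  sim <- simulate_schnakenberg(m, mode2_params(), T_final = 0.5, k = 0.01,
                               seed = 1, amplitude = 0,
                               snapshot_times = c(0, 0.25, 0.5))
  ss <- steady_state(0.2, 1)
  expect_lt(max(abs(sim$state$u - ss$u0)), 1e-9)
  expect_named(sim$snapshots, c("t=0", "t=0.25", "t=0.5"))
  expect_error(
    simulate_schnakenberg(m, mode2_params(), T_final = 0.505, k = 0.01),
    "multiple"
  )
})

test_that("discrete sphere spectrum approximates n(n+1) with multiplicities", {
  ops <- assemble_operators(fine_sphere())
  eig <- lb_eigenpairs(ops, 9, method = "arpack")
  expect_lt(abs(eig$values[1]), 1e-8)
  # constant first eigenvector
  v1 <- eig$vectors[, 1]
  expect_lt(diff(range(v1)) / max(abs(v1)), 1e-6)
  expect_equal(eig$values[2:4], rep(2, 3), tolerance = 0.02)
  expect_equal(eig$values[5:9], rep(6, 5), tolerance = 0.02)
  # M-orthonormal eigenvectors
  G <- crossprod(eig$vectors, as.matrix(ops$mass %*% eig$vectors))
  expect_equal(G, diag(9), tolerance = 1e-8, ignore_attr = TRUE)
  # dense and iterative paths agree
  eig_d <- lb_eigenpairs(ops, 9, method = "dense")
  expect_equal(eig$values, eig_d$values, tolerance = 1e-9)
})

test_that("eigenvalue convergence toward the sphere spectrum is quadratic", {
  errs <- vapply(c(0.3, 0.15), function(h) {
    eig <- lb_eigenpairs(assemble_operators(cap_mesh(0, h)), 4)
    mean(eig$values[2:4]) - 2
  }, numeric(1))
  expect_gt(errs[1], 0)   # P1 eigenvalues converge from above
  expect_gt(errs[1] / errs[2], 3)
})

test_that("hole splits the n = 1 triple with the predicted signs", {
  ops <- assemble_operators(cap_mesh(0.2, 0.15))
  eig <- lb_eigenpairs(ops, 4, method = "arpack")
  # m = +-1 branches shift down, zonal branch up
  expect_lt(eig$values[2], 2)
  expect_lt(eig$values[3], 2)
  expect_gt(eig$values[4], 2)
})

test_that("pattern at T = 50 has settled (long-run stationarity)", {
  m <- fine_sphere()
  sim <- simulate_schnakenberg(m, mode1_params(), T_final = 100, k = 0.01,
                               seed = 2, snapshot_times = c(50, 100))
  u50 <- sim$snapshots[["t=50"]]$u
  u100 <- sim$state$u
  rel <- sqrt(sum((u100 - u50)^2) / sum(u50^2))
  expect_lt(rel, 0.01)
})
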