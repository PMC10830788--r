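test_that("steady state solves the kinetics exactly", {
  ss <- steady_state(0.2, 1)
  expect_equal(ss$u0, 1.2)
  expect_equal(ss$v0, 1 / 1.44)
  expect_equal(round(ss$v0, 2), 0.69)
  expect_equal(unlist(steady_state(0, 1)), c(u0 = 1, v0 = 1))
  for (ab in list(c(0.2, 1), c(0.1, 0.9), c(1, 2))) {
    ss <- steady_state(ab[1], ab[2])
    expect_lt(abs(turingcap:::schnak_f(ss$u0, ss$v0, ab[1])), 1e-12)
    expect_lt(abs(turingcap:::schnak_g(ss$u0, ss$v0, ab[2])), 1e-12)
  }
  expect_error(steady_state(0, 0), "a \\+ b > 0")
})

test_that("linearised kinetics match hand-computed derivatives", {
  lk <- linearize_kinetics(0.2, 1)
  expect_equal(lk$f_u, 2 / 3)
  expect_equal(lk$f_v, 1.44)
  expect_equal(lk$g_u, -5 / 3)
  expect_equal(lk$g_v, -1.44)
  expect_equal(lk$det_A, 1.44)
  # cross-check by central finite differences at random parameter values
  set.seed(7)
  for (i in 1:4) {
    a <- runif(1, 0.05, 0.5); b <- runif(1, 0.5, 1.5)
    ss <- steady_state(a, b)
    h <- 1e-6
    fd <- function(fn, wrt) {
      if (wrt == "u") {
        (fn(ss$u0 + h, ss$v0) - fn(ss$u0 - h, ss$v0)) / (2 * h)
      } else {
        (fn(ss$u0, ss$v0 + h) - fn(ss$u0, ss$v0 - h)) / (2 * h)
      }
    }
    f <- function(u, v) turingcap:::schnak_f(u, v, a)
    g <- function(u, v) turingcap:::schnak_g(u, v, b)
    lk <- linearize_kinetics(a, b)
    expect_equal(lk$f_u, fd(f, "u"), tolerance = 1e-6)
    expect_equal(lk$f_v, fd(f, "v"), tolerance = 1e-6)
    expect_equal(lk$g_u, fd(g, "u"), tolerance = 1e-6)
    expect_equal(lk$g_v, fd(g, "v"), tolerance = 1e-6)
    expect_equal(lk$det_A, lk$f_u * lk$g_v - lk$f_v * lk$g_u)
    # activator-inhibitor sign structure
    expect_gt(lk$f_v, 0)
    expect_lt(lk$g_u, 0)
  }
})

test_that("Turing conditions hold for the study parameters, fail for d = 1", {
  tc <- turing_conditions(mode2_params())
  expect_true(all(unlist(tc[c("trace_negative", "det_positive",
                              "cross_positive", "discriminant_positive",
                              "turing")])))
  tc1 <- turing_conditions(schnak_params(0.2, 1, 20.62, 1))
  expect_false(tc1$cross_positive)
  expect_false(tc1$turing)
  # verdict independent of gamma
  for (g in c(0.1, 5, 100)) {
    expect_identical(turing_conditions(schnak_params(0.2, 1, g, 18))$turing,
                     tc$turing)
  }
})

test_that("critical diffusion makes the dispersion discriminant vanish", {
  dc <- critical_diffusion(0.2, 1)
  expect_equal(round(dc, 2), 17.01)
  lk <- linearize_kinetics(0.2, 1)
  disc <- (dc * lk$f_u + lk$g_v)^2 - 4 * dc * lk$det_A
  expect_lt(abs(disc) / (dc * lk$f_u + lk$g_v)^2, 1e-8)
  expect_gt(dc, 1)
  # tangency also at other kinetic parameters
  dc2 <- critical_diffusion(0.1, 0.9)
  lk2 <- linearize_kinetics(0.1, 0.9)
  expect_lt(abs((dc2 * lk2$f_u + lk2$g_v)^2 - 4 * dc2 * lk2$det_A), 1e-8)
})

test_that("critical gamma reproduces the tabulated mode values", {
  expect_equal(round(critical_gamma(1:4, 0.2, 1), 2),
               c(6.87, 20.62, 41.24, 68.73))
  # the printed-formula variant is exposed but differs for n > 1
  gp <- critical_gamma(1:2, 0.2, 1, as_printed = TRUE)
  expect_equal(gp[1] / critical_gamma(1, 0.2, 1), 2)
  expect_gt(gp[2], critical_gamma(2, 0.2, 1))
  expect_error(critical_gamma(0, 0.2, 1), "positive integer")
})

test_that("unstable interval brackets exactly the excited eigenvalue", {
  iv <- unstable_interval(mode2_params())
  expect_false(iv$empty)
  expect_lt(iv$gamma_L, 6); expect_gt(iv$gamma_M, 6)
  expect_gt(iv$gamma_L, 2)   # lambda = 2 excluded
  expect_lt(iv$gamma_M, 12)  # lambda = 12 excluded

  # at criticality the interval degenerates onto n(n+1)
  dc <- critical_diffusion(0.2, 1)
  for (n in 1:3) {
    gc <- critical_gamma(n, 0.2, 1)
    ivc <- unstable_interval(schnak_params(0.2, 1, gc, dc))
    expect_equal(ivc$gamma_L, n * (n + 1), tolerance = 1e-6)
    expect_equal(ivc$gamma_M, n * (n + 1), tolerance = 1e-6)
  }

  # endpoints scale linearly in gamma at fixed d
  iv2 <- unstable_interval(schnak_params(0.2, 1, 2 * 20.62, 18))
  expect_equal(iv2$gamma_L, 2 * iv$gamma_L)
  expect_equal(iv2$gamma_M, 2 * iv$gamma_M)

  # negative discriminant is an empty-interval signal, not an error
  ive <- unstable_interval(schnak_params(0.2, 1, 20.62, 5))
  expect_true(ive$empty)
})

test_that("perturbed eigenvalues follow the small-hole asymptotics", {
  # epsilon = 0 recovers the sphere spectrum for every branch
  grid <- expand.grid(n = 1:4, m = 0:4)
  grid <- grid[grid$m <= grid$n, ]
  pe0 <- perturbed_eigenvalue(grid$n, grid$m, 0)
  expect_equal(pe0$value, pe0$n * (pe0$n + 1))

  # hand-evaluated coefficients
  pe11 <- perturbed_eigenvalue(1, 1, 0.3)
  expect_equal(pe11$c_nm, 0.5)
  expect_equal(pe11$value, 2 - 1.5 * 0.09)
  pe20 <- perturbed_eigenvalue(2, 0, 0.3)
  expect_equal(pe20$value, 6 + 5 * 1.5 * 0.09)
  # the reciprocal zonal variant remains available
  pe20p <- perturbed_eigenvalue(2, 0, 0.3, as_printed = TRUE)
  expect_equal(pe20p$value, 6 + (10 / 3) * 0.09)

  # branch ordering: zonal shifts up, all m >= 1 shift down
  for (n in 1:4) {
    pe <- perturbed_eigenvalue(rep(n, n + 1), 0:n, 0.1)
    expect_gt(pe$value[1], n * (n + 1))
    expect_true(all(pe$value[-1] < n * (n + 1)))
  }
  expect_error(perturbed_eigenvalue(2, 3, 0.1), "m <= n")
  expect_error(perturbed_eigenvalue(0, 0, 0.1), "n >= 1")
})

test_that("excited modes are the n = 2 branches for the study parameters", {
  for (eps in c(0, 0.1)) {
    em <- excited_modes(mode2_params(), eps, n_max = 4)
    expect_equal(em$n, rep(2L, 3))
    expect_equal(em$m, 0:2)
  }
  em0 <- excited_modes(schnak_params(0.2, 1, 1e-6, 18), 0, n_max = 4)
  expect_equal(nrow(em0), 0)
})
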