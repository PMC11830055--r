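test_that("the reaction-free racemic state is recovered exactly", {
  p <- dkr_params(phi2 = 0, b0 = 8.68, theta = 3.27, gamma = 0)
  prof <- solve_profiles(p)
  expect_equal(prof$s1, rep(1, 11), tolerance = 1e-12)
  expect_equal(prof$s2, rep(1, 11), tolerance = 1e-12)
  expect_lte(attr(prof, "max_residual"), 1e-8)
})

test_that("the collocation oracle reproduces the tabulated numerical columns", {
  expect_equal(round(cached_solve(params_t45(8.68))$s1, 6),
               c(0.983745, 0.985246, 0.988083, 0.991549, 0.995528, 1))
  expect_equal(round(cached_solve(params_t45(8.68))$s2, 6),
               c(1.000699, 1.000599, 1.000426, 1.000251, 1.000102, 1))
  expect_equal(round(cached_solve(params_t45(34.72))$s1, 6),
               c(0.994948, 0.995603, 0.996495, 0.997525, 0.998693, 1))
  expect_equal(round(cached_solve(params_t67(10))$s1[1], 6), 0.929737)
  expect_equal(round(cached_solve(params_t67(10))$s2[1], 6), 1.018812)
  expect_equal(round(cached_solve(params_t89(10))$s2, 6),
               c(1.001365, 1.001093, 1.000727, 1.000398, 1.000144, 1))
})

test_that("the solution satisfies the governing equations to 10x tolerance", {
  tol <- 1e-8
  prof <- solve_profiles(params_t67(10), tolerance = tol)
  interp <- attr(prof, "interpolant")
  xg <- seq(1.001, 1.999, length.out = 301)
  v <- interp(xg, 0L)
  dv <- interp(xg, 1L)
  r <- ode_residual(params_t67(10), xg, s = v[, c(1, 3)], ds = v[, c(2, 4)],
                    d2s = dv[, c(2, 4)])
  expect_lt(max(abs(c(r$res1, r$res2))), 10 * tol)
  # boundary conditions to the same tolerance
  vb <- interp(c(1, 2), 0L)
  br <- boundary_residual(vb[1, 2], vb[1, 4], vb[2, 1], vb[2, 3])
  expect_lt(max(abs(br)), 10 * tol)
})

test_that("an independent shooting integration agrees with collocation", {
  skip_if_not_installed("deSolve")
  p <- dkrmr:::param_list(params_t45(8.68))
  rhs <- function(x, y, parms) {
    r1 <- p$phi2 * y[1] / ((1 + y[1] / p$theta) *
                             (1 + p$phi_frac * p$xi2 + p$xi1 * y[3]))
    r2 <- p$gamma * (y[1] - y[3]) / (y[1] + y[3])
    list(c(y[2], r1 - (1 + p$b0) / x * y[2],
           y[4], r2 - (1 + p$b0) / x * y[4]))
  }
  shoot <- function(init) {
    out <- deSolve::lsoda(c(init[1], 0, init[2], 0), c(1, 2), rhs, NULL,
                          rtol = 1e-11, atol = 1e-12)
    unname(out[2, c(2, 4)] - 1)
  }
  init <- c(1, 1)
  for (i in 1:8) {
    f0 <- shoot(init)
    if (max(abs(f0)) < 1e-11) break
    J <- matrix(0, 2, 2)
    for (j in 1:2) {
      d <- c(0, 0); d[j] <- 1e-7
      J[, j] <- (shoot(init + d) - f0) / 1e-7
    }
    init <- init - solve(J, f0)
  }
  prof <- cached_solve(params_t45(8.68))
  expect_equal(init[1], prof$s1[1], tolerance = 1e-7)
  expect_equal(init[2], prof$s2[1], tolerance = 1e-7)
})

test_that("profiles are monotone and ordered as diffusion theory demands", {
  for (p in list(params_t45(8.68), params_t67(10), params_t89(10))) {
    prof <- cached_solve(p)
    expect_true(all(diff(prof$s1) >= -1e-12))  # substrate consumed inward
    expect_true(all(prof$s2 >= 1 - 1e-12))     # racemization feeds S2
    expect_true(all(diff(prof$s2) <= 1e-12))
  }
})

test_that("comparative statics follow the transport picture", {
  s1_inner <- function(phi2, b0) {
    p <- dkr_params(phi2 = phi2, b0 = b0, theta = 5, gamma = 1,
                    xi1 = 7.23, xi2 = 0.25, phi_frac = 1)
    solve_profiles(p, tolerance = 1e-8, output_grid = c(1, 2))$s1[1]
  }
  # deeper diffusion limitation depletes the centreline
  expect_gt(s1_inner(1, 17.34), s1_inner(5, 17.34))
  expect_gt(s1_inner(5, 17.34), s1_inner(10, 17.34))
  # faster through-flow flattens the profile
  expect_gt(s1_inner(5, 34.72), s1_inner(5, 17.34))
  expect_gt(s1_inner(5, 17.34), s1_inner(5, 8.68))
})

test_that("the grid-independence certificate passes at table parameters", {
  prof <- refine_until_converged(params_t45(8.68), tolerance = 1e-7)
  cert <- attr(prof, "certificate")
  expect_true(cert$max_difference <= cert$bound)
})

test_that("an impossibly coarse mesh raises a convergence error", {
  err <- expect_error(solve_profiles(params_t67(10), tolerance = 1e-8,
                                     max_nodes = 8),
                      class = "dkrmr_error_convergence")
  expect_match(conditionMessage(err), "residual")
})

test_that("solver input validation", {
  expect_error(solve_profiles(params_t45(), tolerance = -1),
               class = "dkrmr_error_invalid_parameter")
  expect_error(solve_profiles(params_t45(), output_grid = c(0.5, 1)),
               class = "dkrmr_error_domain")
  # B0 = 2 is regular for the ODE itself (only the closed forms exclude it)
  p2 <- dkr_params(phi2 = 0.5, b0 = 2, theta = 3.27, gamma = 1,
                   xi1 = 2, xi2 = 0.03, phi_frac = 1)
  prof <- solve_profiles(p2, tolerance = 1e-8, output_grid = c(1, 1.5, 2))
  expect_true(all(is.finite(prof$s1)))
})

test_that("repeated solves are bit-identical (deterministic pipeline)", {
  a <- solve_profiles(params_t67(1), tolerance = 1e-8)
  b <- solve_profiles(params_t67(1), tolerance = 1e-8)
  expect_identical(a$s1, b$s1)
  expect_identical(a$s2, b$s2)
})
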