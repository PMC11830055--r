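xs6 <- seq(1, 2, 0.2)

test_that("the (S)-ester series reproduces the tabulated profile columns", {
  expect_equal(round(s1_hpm(params_t45(8.68), xs6), 6),
               c(0.983742, 0.985243, 0.988081, 0.991548, 0.995528, 1))
  expect_equal(round(s1_hpm(params_t45(34.72), xs6), 6),
               c(0.994948, 0.995603, 0.996495, 0.997525, 0.998693, 1))
  expect_equal(round(s1_hpm(params_t67(1), xs6), 6),
               c(0.992697, 0.993530, 0.994832, 0.996350, 0.998072, 1))
  expect_equal(round(s1_hpm(params_t67(10), xs6), 6),
               c(0.929310, 0.937188, 0.949605, 0.964212, 0.980986, 1))
  # independent of gamma, matching the shared column of both racemization
  # variants in the reference table
  expect_equal(round(s1_hpm(params_t89(5), xs6), 6),
               c(0.994733, 0.995334, 0.996274, 0.997369, 0.998611, 1))
  expect_equal(s1_hpm(params_t89(5), xs6), s1_hpm(params_t89(10), xs6))
})

test_that("the printed (R)-ester series is linear in gamma and first == second", {
  p <- params_t45()
  expect_equal(s2_hpm(p, xs6, "first"), s2_hpm(p, xs6, "second"))
  p0 <- p; p0$gamma <- 0
  expect_equal(s2_hpm(p0, xs6), rep(1, 6))
  p2 <- p; p2$gamma <- 2
  expect_lt(max(abs((s2_hpm(p2, xs6) - 1) - 2 * (s2_hpm(p, xs6) - 1))), 1e-15)
})

test_that("the third-order (R)-ester series reproduces the tabulated columns", {
  # the printed second-order form undershoots these columns (it omits the
  # O(p^3) terms); the full truncation matches them
  expect_lt(max(abs(s2_hpm(params_t67(1), xs6, "third") -
                      c(1.001851, 1.001486, 1.000992, 1.000545, 1.000198, 1))),
            1e-6)
  expect_lt(max(abs(s2_hpm(params_t67(10), xs6, "third") -
                      c(1.018490, 1.014835, 1.009894, 1.005427, 1.001968, 1))),
            1e-6)
  expect_lt(max(abs(s2_hpm(params_t89(5), xs6, "third") -
                      c(1.000619, 1.000499, 1.000335, 1.000186, 1.000068, 1))),
            1e-6)
  expect_lt(max(abs(s2_hpm(params_t89(10), xs6, "third") -
                      c(1.001334, 1.001070, 1.000714, 1.000392, 1.000142, 1))),
            1e-6)
  expect_lt(max(abs(s2_hpm(params_t45(34.72), xs6, "third") -
                      c(1.000056, 1.000043, 1.000028, 1.000015, 1.000005, 1))),
            1e-6)
  # printed second order at the same parameters is visibly different
  expect_equal(s2_hpm(params_t45(8.68), 1), 1.000675, tolerance = 1e-6)
  expect_equal(s2_hpm(params_t67(10), 1), 1.015860, tolerance = 1e-6)
})

test_that("the monomial representation agrees with the literal transcription", {
  for (p in list(params_t45(), params_t67(10), params_t89(5))) {
    pl <- dkrmr:::param_list(p)
    xg <- seq(1, 2, length.out = 23)
    expect_equal(1 + dkrmr:::mono_eval(dkrmr:::hpm_s1_mono(pl), xg, pl$b0),
                 s1_hpm(p, xg), tolerance = 1e-14)
    expect_equal(1 + dkrmr:::mono_eval(dkrmr:::hpm_s2_mono(pl), xg, pl$b0),
                 s2_hpm(p, xg), tolerance = 1e-14)
  }
})

test_that("both series have the boundary conditions built in", {
  for (p in draw_params(20)) {
    expect_lt(abs(s1_hpm(p, 2) - 1), 1e-10)
    expect_lt(abs(s2_hpm(p, 2) - 1), 1e-10)
    expect_lt(abs(dkrmr:::hpm_deriv(p, 1, "s1")), 1e-10)
    expect_lt(abs(dkrmr:::hpm_deriv(p, 1, "s2")), 1e-10)
  }
  # the derived third-order (R)-ester terms inherit the same boundaries
  p <- params_t67(10)
  expect_lt(abs(s2_hpm(p, 2, "third") - 1), 1e-12)
  expect_lt(abs(dkrmr:::hpm_deriv(p, 1, "s2", order = "third")), 1e-12)
})

test_that("the series residual shrinks at the expected order in Phi^2", {
  # the (S)-ester hierarchy is derived with the (R)-ester at its bulk value
  # (the printed brackets carry xi1 * 1), so its residual is measured with
  # S2 = 1; the first neglected term is O(Phi^6), i.e. cubic in Phi^2
  slope <- hpm_residual_slope(dkr_params(phi2 = 0.5, b0 = 8.68, theta = 3.27,
                                         gamma = 1, xi1 = 2, xi2 = 0.03,
                                         phi_frac = 1))
  expect_gte(slope, 2)
  expect_gt(slope, 2.8)
  # the coupled residual of the printed (R)-series against the full source
  # has a gamma^2 Phi^2 defect (the omitted third-order term), so the pair
  # (s1, s2) at second order is only O(Phi^2) accurate in the S2 equation;
  # the third-order form removes it
  p <- params_t67(10)
  res2_of <- function(order) {
    xg <- seq(1, 2, length.out = 41)
    s <- cbind(dkrmr:::hpm_deriv(p, xg, "s1", 0L),
               dkrmr:::hpm_deriv(p, xg, "s2", 0L, order = order))
    ds <- cbind(dkrmr:::hpm_deriv(p, xg, "s1", 1L),
                dkrmr:::hpm_deriv(p, xg, "s2", 1L, order = order))
    d2s <- cbind(dkrmr:::hpm_deriv(p, xg, "s1", 2L),
                 dkrmr:::hpm_deriv(p, xg, "s2", 2L, order = order))
    max(abs(ode_residual(p, xg, s, ds, d2s)$res2))
  }
  expect_lt(res2_of("third"), res2_of("second") / 5)
})

test_that("conversion degree is the bulk-referenced depletion fraction", {
  expect_equal(conversion_degree(2, 2), 0)
  expect_equal(conversion_degree(2, 0), 1)
  expect_equal(conversion_degree(2, 1), 0.5)
  expect_error(conversion_degree(0, 1), class = "dkrmr_error_invalid_parameter")
})

test_that("the consistent conversion form reduces exactly to the standard series", {
  xg <- seq(1, 2, length.out = 101)
  for (p in list(params_t45(), params_t67(10), params_t89(5))) {
    expect_lt(max(abs(s1_hpm_conversion(p, xg) - s1_hpm(p, xg))), 1e-12)
  }
  # the literally printed second-order term does not reduce (degree slip:
  # Theta^2 over squared factors instead of Theta^3 over the cube)
  expect_gt(max(abs(s1_hpm_conversion(params_t45(), xg, form = "printed") -
                      s1_hpm(params_t45(), xg))), 1e-6)
  # but both forms share the first-order term and the outer boundary
  expect_equal(s1_hpm_conversion(params_t45(), 2, form = "printed"), 1,
               tolerance = 1e-12)
  expect_equal(s1_hpm_conversion(params_t45(), 2), 1, tolerance = 1e-12)
})

test_that("the conversion forms respond correctly to the bulk state", {
  p <- dkr_params(phi2 = 1, b0 = 8.68, theta = 5, gamma = 7, xi1 = 7.23,
                  xi2 = 0.25, phi_frac = 1, s1b = 2, s2b = 1.5, x_conv = 0.3)
  xg <- seq(1, 2, 0.1)
  # (R)-ester: both terms carry gamma, and the driving factor
  # (1 + S1b(X - 1)) kills the deviation at X = 0, S1b = 1
  p0 <- p; p0$gamma <- 0
  expect_equal(s2_hpm_conversion(p0, xg), rep(1, length(xg)))
  pr <- p; pr$x_conv <- 0; pr$s1b <- 1
  expect_equal(s2_hpm_conversion(pr, xg), rep(1, length(xg)))
  # as printed, the outer boundary is NOT satisfied for generic bulk states
  expect_gt(abs(s2_hpm_conversion(p, 2) - 1), 0.1)
  # the (S)-ester deviation shrinks with deeper conversion (rate denominator
  # factors grow with (1-X) S_b)
  p_hi <- p; p_hi$x_conv <- 0.9
  dev0 <- abs(s1_hpm_conversion(p, 1) - 1)
  dev9 <- abs(s1_hpm_conversion(p_hi, 1) - 1)
  expect_gt(dev9, dev0)
})

test_that("singular and out-of-domain inputs are rejected", {
  p2 <- dkr_params(phi2 = 1, b0 = 2 + 1e-8, theta = 1)
  expect_error(s1_hpm(p2, 1), class = "dkrmr_error_singular_parameter")
  expect_error(s2_hpm(p2, 1), class = "dkrmr_error_singular_parameter")
  expect_error(s1_hpm_conversion(p2, 1), class = "dkrmr_error_singular_parameter")
  p <- params_t45()
  expect_error(s1_hpm(p, 0.5), class = "dkrmr_error_domain")
  expect_error(s2_hpm(p, 2.2), class = "dkrmr_error_domain")
  # the third-order construction additionally excludes resonant B0 values
  p4 <- dkr_params(phi2 = 1, b0 = 4, theta = 1, gamma = 1)
  expect_error(s2_hpm(p4, 1, "third"), class = "dkrmr_error_singular_parameter")
  expect_silent(s2_hpm(p4, 1, "second"))
})

test_that("hpm_profile returns a tidy profile with the series values", {
  p <- params_t45()
  prof <- hpm_profile(p, x = xs6)
  expect_s3_class(prof, "dkr_profile")
  expect_equal(prof$s1, s1_hpm(p, xs6))
  expect_equal(prof$s2, s2_hpm(p, xs6))
  expect_equal(prof$method, rep("hpm", 6))
  prof3 <- hpm_profile(p, x = xs6, order = "third")
  expect_equal(prof3$s2, s2_hpm(p, xs6, "third"))
  expect_equal(prof3$s1, s1_hpm(p, xs6, "second"))
})
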