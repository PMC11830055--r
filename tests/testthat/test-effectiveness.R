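# literal transcription of the printed closed-form effectiveness factor,
# kept here as an independent oracle for the packaged eta0 * (1 - K Phi^2)
# factorisation
eta_literal <- function(p, phi2, consistent = FALSE) {
  th <- p$theta; b0 <- p$b0; x1 <- p$xi1; x2 <- p$xi2; ph <- p$phi_frac
  s1b <- p$s1b; s2b <- p$s2b
  lin <- if (consistent) 9 * phi2 / 2 else 9 * phi2 / 4
  br <- 3 * 2^(-b0) * b0 * th^2 * phi2 -
    3 * (1 + x1 + ph * x2) * (th + 1)^2 * b0^3 +
    (12 * (th + 1)^2 * x1 + 12 * ph * x2 * (th + 1)^2 +
       (12 - lin) * th^2 + 24 * th + 12) * b0 +
    (2^(1 - b0) - 2) * th^2 * phi2 + (9 / 4) * th^2 * phi2 * b0^2
  -(th + s1b) * (1 + s2b * x1 + ph * x2) * br /
    (3 * b0 * s1b * (b0 + 2) * (b0 - 2) * (1 + x1 + ph * x2)^2 * (th + 1)^3)
}

test_that("the deficit factorisation equals the literal closed form", {
  grid <- expand.grid(phi2 = c(0, 0.5, 3, 25), theta = c(1, 5),
                      s1b = c(1, 2.5), s2b = c(1, 1.4), b0 = c(8.68, 17.34))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    p <- dkr_params(phi2 = g$phi2, b0 = g$b0, theta = g$theta, xi1 = 7.23,
                    xi2 = 0.25, phi_frac = 1, s1b = g$s1b, s2b = g$s2b)
    pl <- dkrmr:::param_list(p)
    expect_equal(mief_closed_form(p, "printed")$eta_m,
                 eta_literal(pl, g$phi2), tolerance = 1e-12)
    expect_equal(mief_closed_form(p, "table_consistent")$eta_m,
                 eta_literal(pl, g$phi2, consistent = TRUE),
                 tolerance = 1e-12)
  }
})

test_that("the zero-Thiele limit is the bulk rate ratio", {
  p <- params_mief(s1b = 1)
  expect_equal(mief_zero_thiele_limit(p)$eta_m, 1)
  p15 <- params_mief(s1b = 1.5)
  expect_equal(mief_zero_thiele_limit(p15)$eta_m, 6.5 / 9, tolerance = 1e-12)
  p2 <- params_mief(s1b = 2)
  expect_equal(mief_zero_thiele_limit(p2)$eta_m, 7 / 12, tolerance = 1e-12)
  # equals v(1,1)/v(s1b, s2b)
  pl <- dkrmr:::param_list(p2)
  expect_equal(mief_zero_thiele_limit(p2)$eta_m,
               reaction_rate_s1(p2, 1, 1) / reaction_rate_s1(p2, 2, 1),
               tolerance = 1e-12)
  # the local rate-ratio at a unit profile value gives the same number
  expect_equal(local_effectiveness(p2, 1.3, function(x)
    list(s1 = rep(1, length(x)), s2 = rep(1, length(x))), "rate"),
    7 / 12, tolerance = 1e-12)
})

test_that("both closed forms are linear decreasing deficits in Phi^2", {
  p <- params_mief()
  for (variant in c("table_consistent", "printed")) {
    etas <- effectiveness_sweep(p, c(0, 1, 2, 4), variant = variant)$eta_m
    expect_equal(etas[1], mief_zero_thiele_limit(p)$eta_m)   # exact at 0
    d <- diff(etas)
    expect_true(all(d < 0))
    expect_equal(d[3], 2 * d[1], tolerance = 1e-10)          # linearity
  }
})

test_that("the table-consistent form reproduces the effectiveness tables", {
  for (id in c("table2", "table3")) {
    preset <- dkr_preset(id)
    got <- dkrmr:::regenerate_table(preset)
    expect_lt(max(abs(got$eta_m - preset$reference$eta_m)), 5e-5)
  }
  # spot cells, tabulated modulus m entering as Phi^2 = m^2
  p <- params_mief()
  cell <- function(m, s1b = 1, theta = 5) {
    effectiveness_sweep(p, m, modulus = "phi", s1b = s1b,
                        theta = theta)$eta_m
  }
  expect_equal(cell(10), 0.433430, tolerance = 5e-5)
  expect_equal(cell(0.1, s1b = 2), 0.583300, tolerance = 5e-5)
  expect_equal(cell(10, s1b = 4), 0.162536, tolerance = 5e-5)
  expect_equal(cell(10, theta = 1), 0.796035, tolerance = 5e-5)
})

test_that("quadrature normalisation and oracles", {
  # unit profile: eta_m = (2/3) * int x dx = 1 under both definitions
  unit <- function(x) list(s1 = rep(1, length(x)), s2 = rep(1, length(x)))
  p0 <- dkr_params(phi2 = 0, b0 = 8.68, theta = 5, xi1 = 7.23, xi2 = 0.25,
                   phi_frac = 1)
  expect_equal(mief_quadrature(p0, unit, "rate")$eta_m, 1, tolerance = 1e-10)
  expect_equal(mief_quadrature(p0, unit, "concentration")$eta_m, 1,
               tolerance = 1e-10)
  # brute-force trapezoid on 1e5 points agrees with adaptive quadrature
  p <- params_mief(phi2 = 1)
  adapt <- mief_quadrature(p, "hpm", "rate")$eta_m
  xg <- seq(1, 2, length.out = 1e5)
  eta <- local_effectiveness(p, xg, "hpm", "rate")
  h <- xg[2] - xg[1]
  trap <- 2 / 3 * (sum(xg * eta) - (xg[1] * eta[1] + xg[1e5] * eta[1e5]) / 2) * h
  expect_lt(abs(adapt - trap), 1e-8)
})

test_that("rate-definition quadrature cross-validates the table-consistent form", {
  # first-order series profile, rate ratio: the linearised deficit slope is
  # the table-consistent K (about -5.666e-3 per unit Phi^2 here)
  p <- params_mief(phi2 = 1)
  K <- dkrmr:::eta_deficit_k(5, 8.68, 7.23, 0.25, 1, "table_consistent")
  expect_equal(K, 5.666e-3, tolerance = 1e-4)
  q1 <- mief_quadrature(p, "hpm_first", "rate")$eta_m
  expect_equal(1 - q1, K, tolerance = 2e-3)
  # agreement with the closed form to 2e-4 relative for Phi^2 <= 1
  for (phi2 in c(0.25, 0.5, 1)) {
    pq <- params_mief(phi2 = phi2)
    expect_equal(mief_quadrature(pq, "hpm_first", "rate")$eta_m,
                 mief_closed_form(pq)$eta_m,
                 tolerance = 2e-4)
  }
})

test_that("local effectiveness honours the Dirichlet normaliser", {
  p <- params_mief(phi2 = 2)
  expect_equal(local_effectiveness(p, 2, "hpm", "concentration"), 1,
               tolerance = 1e-12)
  xg <- seq(1, 2, 0.25)
  expect_equal(local_effectiveness(p, xg, "hpm", "concentration"),
               s1_hpm(p, xg))
})

test_that("closed-form guards reject singular Bodenstein numbers", {
  p2 <- dkr_params(phi2 = 1, b0 = 2, theta = 5)
  expect_error(mief_closed_form(p2), class = "dkrmr_error_singular_parameter")
  expect_error(effectiveness_sweep(p2, 1),
               class = "dkrmr_error_singular_parameter")
})
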