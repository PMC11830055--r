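# shared parameter sets (the caption sets of the comparison tables) and a
# small cache so the collocation oracle is solved once per parameter set

params_t45 <- function(b0 = 8.68) {
  dkr_params(phi2 = 0.5, b0 = b0, theta = 3.27, gamma = 1,
             xi1 = 2, xi2 = 0.03, phi_frac = 1)
}

params_t67 <- function(phi2 = 10) {
  dkr_params(phi2 = phi2, b0 = 17.34, theta = 5, gamma = 10,
             xi1 = 7.23, xi2 = 0.25, phi_frac = 1)
}

params_t89 <- function(gamma = 10) {
  dkr_params(phi2 = 1, b0 = 17.34, theta = 1.5, gamma = gamma,
             xi1 = 7.23, xi2 = 0.25, phi_frac = 1)
}

params_mief <- function(phi2 = 1, theta = 5, s1b = 1) {
  dkr_params(phi2 = phi2, b0 = 8.68, theta = theta, gamma = 0,
             xi1 = 7.23, xi2 = 0.25, phi_frac = 1, s1b = s1b)
}

.solve_cache <- new.env(parent = emptyenv())

cached_solve <- function(params, tolerance = 1e-10,
                         output_grid = seq(1, 2, 0.2)) {
  key <- paste(c(unlist(params[1, ]), tolerance, output_grid), collapse = "|")
  if (is.null(.solve_cache[[key]])) {
    .solve_cache[[key]] <- solve_profiles(params, tolerance = tolerance,
                                          output_grid = output_grid)
  }
  .solve_cache[[key]]
}

# log-log slope of the (S)-equation residual of the series (with the
# (R)-ester at its bulk value, as in the series derivation) under repeated
# halving of Phi^2
hpm_residual_slope <- function(base, n_half = 4L) {
  xg <- seq(1, 2, length.out = 41)
  phi2s <- base$phi2 / 2^(0:n_half)
  res <- vapply(phi2s, function(ph) {
    p <- base; p$phi2 <- ph
    one <- rep(1, length(xg)); zero <- rep(0, length(xg))
    s <- cbind(dkrmr:::hpm_deriv(p, xg, "s1", 0L), one)
    ds <- cbind(dkrmr:::hpm_deriv(p, xg, "s1", 1L), zero)
    d2s <- cbind(dkrmr:::hpm_deriv(p, xg, "s1", 2L), zero)
    max(abs(ode_residual(p, xg, s, ds, d2s)$res1))
  }, numeric(1))
  unname(coef(lm(log(res) ~ log(phi2s)))[2])
}

# random valid parameter draws (away from the B0 = 2 singular line)
draw_params <- function(n, seed = 421) {
  withr::with_seed(seed, {
    purrr::map(seq_len(n), function(i) {
      dkr_params(
        phi2 = stats::runif(1, 0, 12),
        b0 = stats::runif(1, 3, 35),
        theta = stats::runif(1, 0.5, 10),
        gamma = stats::runif(1, 0, 20),
        xi1 = stats::runif(1, 0, 10),
        xi2 = stats::runif(1, 0, 10),
        phi_frac = stats::runif(1, 0, 2))
    })
  })
}
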