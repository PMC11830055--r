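# Closed-form homotopy-perturbation (HPM) solutions of the coupled
# steady-state system.  The printed series are transcribed term for term;
# `hpm_s1_mono()` / `hpm_s2_mono()` hold the same expressions in monomial
# form, used for analytic derivatives and for the third-order (R)-ester
# truncation.

# quartic bracket ((x^2-4)B0 + 2x^2 - 24)(x^2-4) shared by the second-order terms
p_quartic <- function(x, b0) ((x^2 - 4) * b0 + 2 * x^2 - 24) * (x^2 - 4)

pw <- function(base, expo) exp(expo * log(base))  # powers via exp/log

hpm_denominator_group <- function(p) 1 + p$phi_frac * p$xi2 + p$xi1

# first-order bracket of the (S)-ester series and its prefactor
hpm_c1 <- function(p) {
  p$phi2 * p$theta /
    (2 * p$b0 * (2 + p$b0) * (1 + p$theta) * hpm_denominator_group(p))
}

hpm_f_bracket <- function(x, b0) {
  x^2 * b0 - 4 * b0 - pw(2, 1 - b0) + 2 * pw(x, -b0)
}

# second-order bracket of the (S)-ester series and its prefactor
hpm_c2 <- function(p) {
  p$phi2^2 * p$theta^3 /
    (8 * p$b0^2 * (4 + p$b0) * (-2 + p$b0) * (2 + p$b0)^2 *
       (1 + p$theta)^3 * hpm_denominator_group(p)^2)
}

hpm_s1_second_bracket <- function(x, b0) {
  (-4 * b0^3 - 24 * b0^2 - 32 * b0) * pw(x, 2 - b0) +
    ((-8 * b0^2 - 16 * b0 + 64) * pw(x, -b0) - 4 * x^2 * b0^3 -
       8 * x^2 * b0^2 + 32 * x^2 * b0 +
       40 * b0^3 + 144 * b0^2 - 96 * b0 + 64) * pw(2, -b0) +
    (-2 + b0) * ((-8 * b0^2 - 32 * b0 + 32) * pw(x, -b0) +
                   (8 * b0 + 32) * pw(4, -b0) + p_quartic(x, b0) * b0^2)
}

# bracket of the printed (R)-ester series (the gamma Phi^2 Theta term)
hpm_c3 <- function(p) {
  p$gamma * p$phi2 * p$theta /
    (2 * p$b0^2 * (4 + p$b0) * (-2 + p$b0) * (2 + p$b0)^2 *
       (1 + p$theta) * hpm_denominator_group(p))
}

hpm_s2_bracket <- function(x, b0) {
  (-3 * b0^2 - 4 * b0 - 0.5 * b0^3) * pw(x, 2 - b0) +
    ((-b0^2 - 2 * b0 + 8) * pw(x, -b0) - x^2 * b0^3 / 2 - x^2 * b0^2 +
       4 * x^2 * b0 + 5 * b0^3 + 18 * b0^2 - 12 * b0 + 8) * pw(2, -b0) +
    (-2 + b0) * ((-b0^2 - 4 * b0 + 4) * pw(x, -b0) + (b0 + 4) * pw(4, -b0) +
                   p_quartic(x, b0) * b0^2 / 8)
}

# --- monomial forms of the same brackets -------------------------------------

mono_f <- function(b0) {
  mono(m = c(2, 0, 0), n = c(0, 0, 1),
       c = c(b0, -4 * b0 - 2^(1 - b0), 2))
}

mono_s1_second <- function(b0) {
  tb <- 2^(-b0)
  mono(m = c(2, 0, 2, 0, 4),
       n = c(1, 1, 0, 0, 0),
       c = c(-4 * b0^3 - 24 * b0^2 - 32 * b0,
             (-8 * b0^2 - 16 * b0 + 64) * tb + (b0 - 2) * (-8 * b0^2 - 32 * b0 + 32),
             (-4 * b0^3 - 8 * b0^2 + 32 * b0) * tb - (b0 - 2) * b0^2 * (8 * b0 + 32),
             (40 * b0^3 + 144 * b0^2 - 96 * b0 + 64) * tb +
               (b0 - 2) * (8 * b0 + 32) * tb^2 + (b0 - 2) * b0^2 * (16 * b0 + 96),
             (b0 - 2) * b0^2 * (b0 + 2)))
}

# (S)-ester series (deviation from 1) in monomial form
hpm_s1_mono <- function(p, order = "second") {
  out <- mono_scale(mono_f(p$b0), hpm_c1(p))
  if (identical(order, "second")) {
    out <- mono_add(out, mono_scale(mono_s1_second(p$b0), hpm_c2(p)))
  }
  out
}

# (R)-ester series (deviation from 1) in monomial form; the printed series
# is a single term linear in gamma ("first" and "second" coincide), and
# "third" appends the O(p^3) contributions (gamma Phi^4 coupling and the
# gamma^2 racemization iterate) obtained by exact inversion of the radial
# operator with the same boundary conditions.
hpm_s2_mono <- function(p, order = "second") {
  b0 <- p$b0
  c1 <- hpm_c1(p)
  Lf <- mono_linv(mono_f(b0), b0)
  u <- mono_scale(Lf, c1 / 2)           # == printed series deviation / gamma
  if (order %in% c("first", "second")) {
    return(mono_scale(u, p$gamma))
  }
  # third order
  w <- mono_add(
    mono_scale(mono_linv(mono_s1_second(b0), b0), hpm_c2(p) / 2),
    mono_scale(mono_linv(mono_mul(mono_f(b0), mono_f(b0)), b0), -c1^2 / 4))
  v <- mono_scale(mono_linv(Lf, b0), c1 / 4)
  mono_add(mono_scale(mono_add(u, w), p$gamma),
           mono_scale(v, -p$gamma^2))
}

#' Closed-form series solution for the (S)-ester profile
#'
#' Evaluates the second-order homotopy-perturbation solution of the
#' (S)-ester transport equation, exactly as printed:
#' \deqn{S_1(x) = 1 + \frac{\Phi^2\Theta\,(x^2 B_0 - 4B_0 - 2^{1-B_0} +
#'   2x^{-B_0})}{2B_0(2+B_0)(1+\Theta)(1+\phi\xi_2+\xi_1)} + O(\Phi^4),}
#' with the \eqn{\Phi^4\Theta^3} second-order bracket included for
#' `order = "second"`. The series has the boundary conditions built in
#' (value 1 at `x = 2`, zero slope at `x = 1`). A factor \eqn{(B_0 - 2)}
#' appears in the second-order denominator, so `b0` within 1e-6 of 2 is
#' rejected.
#'
#' @param params A [dkr_params()] tibble.
#' @param x Radial coordinate(s) in `[1, 2]`.
#' @param order `"second"` (default, the full printed expression) or
#'   `"first"` (leading correction only).
#' @return Numeric vector of \eqn{S_1} values.
#' @examples
#' p <- dkr_params(phi2 = 0.5, b0 = 8.68, theta = 3.27, gamma = 1,
#'                 xi1 = 2, xi2 = 0.03, phi_frac = 1)
#' s1_hpm(p, 1)   # 0.983742
#' @export
s1_hpm <- function(params, x, order = c("second", "first")) {
  order <- match.arg(order)
  p <- param_list(params, need_hpm = TRUE)
  assert_domain_x(x)
  out <- 1 + hpm_c1(p) * hpm_f_bracket(x, p$b0)
  if (order == "second") out <- out + hpm_c2(p) * hpm_s1_second_bracket(x, p$b0)
  out
}

#' Closed-form series solution for the (R)-ester profile
#'
#' For `order = "first"` or `"second"` (which coincide: the printed series
#' carries a single correction term, linear in \eqn{\gamma\Phi^2\Theta}),
#' evaluates the printed closed form. For `order = "third"` the two
#' third-order contributions are appended: the \eqn{\gamma\Phi^4} coupling
#' to the second-order (S)-ester deviation and the \eqn{\gamma^2} term from
#' one more iteration of the racemization source. Both are constructed by
#' exact inversion of the radial operator \eqn{u'' + (1+B_0)/x\,u'} under
#' the same boundary conditions, so the third-order form also satisfies
#' them identically. The comparison tables for the (R)-ester were evidently
#' computed at third order (see the package vignette), so `"third"` is what
#' table-reproduction mode uses.
#'
#' @inheritParams s1_hpm
#' @param order `"second"` (printed form, default), `"first"` (identical),
#'   or `"third"`.
#' @return Numeric vector of \eqn{S_2} values.
#' @examples
#' p <- dkr_params(phi2 = 0.5, b0 = 8.68, theta = 3.27, gamma = 1,
#'                 xi1 = 2, xi2 = 0.03, phi_frac = 1)
#' s2_hpm(p, 1)                    # printed closed form: 1.000675
#' s2_hpm(p, 1, order = "third")   # full truncation:     1.000698
#' @export
s2_hpm <- function(params, x, order = c("second", "first", "third")) {
  order <- match.arg(order)
  p <- param_list(params, need_hpm = TRUE)
  assert_domain_x(x)
  if (order %in% c("first", "second")) {
    1 + hpm_c3(p) * hpm_s2_bracket(x, p$b0)
  } else {
    1 + mono_eval(hpm_s2_mono(p, "third"), x, p$b0)
  }
}

#' Conversion degree of the (S)-ester
#'
#' \eqn{X = (S_{1b} - S_1)/S_{1b}}: the fraction of the bulk (S)-ester
#' converted.
#'
#' @param s1b Dimensionless bulk (S)-ester concentration (> 0).
#' @param s1 Dimensionless (S)-ester concentration.
#' @return Numeric vector of conversion degrees.
#' @export
conversion_degree <- function(s1b, s1) {
  if (any(!is.finite(s1b)) || any(s1b <= 0)) {
    abort_dkr("`s1b` must be finite and > 0",
              class = "dkrmr_error_invalid_parameter")
  }
  (s1b - s1) / s1b
}

#' Conversion-degree series solution for the (S)-ester profile
#'
#' The bulk-referenced form of the (S)-ester series, parameterised by the
#' conversion degree `x_conv` and the bulk concentrations `s1b`, `s2b`
#' carried in `params`. Its first-order term is printed with the factors
#' \eqn{((X-1)S_{1b} - \Theta)} and \eqn{(-1 - \phi\xi_2 + (X-1)S_{2b}\xi_1)}
#' in the denominator and is algebraically identical to the standard form's
#' first-order term at `x_conv = 0`, `s1b = s2b = 1`.
#'
#' The second-order term as printed carries \eqn{\Phi^4\Theta^2} over the
#' *squares* of those factors, which breaks both the reduction to the
#' standard series at the racemic reference state and the order bookkeeping
#' of the expansion (each order must gain one factor of
#' \eqn{\Theta/[(\Theta + (1-X)S_{1b})(\cdots)]}). `form = "consistent"`
#' (default) therefore evaluates the second-order term with
#' \eqn{\Phi^4\Theta^3} over the *cube* of the Michaelis factor, which
#' restores the exact reduction; `form = "printed"` evaluates the
#' expression literally.
#'
#' @inheritParams s1_hpm
#' @param form `"consistent"` (default) or `"printed"`; see Details.
#' @return Numeric vector of \eqn{S_1} values.
#' @export
s1_hpm_conversion <- function(params, x, form = c("consistent", "printed")) {
  form <- match.arg(form)
  p <- param_list(params, need_hpm = TRUE)
  assert_domain_x(x)
  b0 <- p$b0
  dA <- (p$x_conv - 1) * p$s1b - p$theta
  dB <- -1 - p$phi_frac * p$xi2 + (p$x_conv - 1) * p$s2b * p$xi1
  t1 <- p$phi2 * p$theta *
    (-0.5 * x^2 * b0 + 2 * b0 + pw(2, -b0) - pw(x, -b0)) /
    (b0 * (2 + b0) * dA * dB)
  if (form == "printed") {
    n17 <- (0.5 * b0^3 + 3 * b0^2 + 4 * b0) * pw(x, 2 - b0) +
      ((b0^2 + 2 * b0 - 8) * pw(x, -b0) + 0.5 * x^2 * b0^3 + x^2 * b0^2 -
         4 * x^2 * b0 - 5 * b0^3 - 18 * b0^2 + 12 * b0 - 8) * pw(2, -b0) -
      (-2 + b0) * ((-b0^2 - 4 * b0 + 4) * pw(x, -b0) + (b0 + 4) * pw(4, -b0) +
                     0.125 * p_quartic(x, b0) * b0^2)
    t2 <- -p$phi2^2 * p$theta^2 * n17 /
      (b0^2 * (4 + b0) * (-2 + b0) * (2 + b0)^2 * dA^2 * dB^2)
  } else {
    t2 <- p$phi2^2 * p$theta^3 * hpm_s1_second_bracket(x, b0) /
      (8 * b0^2 * (4 + b0) * (-2 + b0) * (2 + b0)^2 * (-dA)^3 * dB^2)
  }
  1 - t1 + t2
}

#' Conversion-degree series solution for the (R)-ester profile
#'
#' Evaluates the printed bulk-referenced (R)-ester expression (a
#' \eqn{\gamma} first-order and a \eqn{\gamma^2} second-order term), exactly
#' as printed. Both terms carry the factor \eqn{(1 + S_{1b}(X - 1))}, so
#' the expression is identically 1 when `gamma = 0` or when `x_conv = 0`
#' and `s1b = 1`. Note that, as printed, the expression satisfies the outer
#' boundary condition \eqn{S_2(2) = 1} only in those special cases; for
#' generic bulk states the printed formula does not return to 1 at `x = 2`
#' (see the vignette).
#'
#' @inheritParams s1_hpm
#' @return Numeric vector of \eqn{S_2} values.
#' @export
s2_hpm_conversion <- function(params, x) {
  p <- param_list(params, need_hpm = TRUE)
  assert_domain_x(x)
  b0 <- p$b0; X <- p$x_conv; s1b <- p$s1b; s2b <- p$s2b; g <- p$gamma
  if (s1b + s2b <= 0) {
    abort_dkr("`s1b + s2b` must be > 0", class = "dkrmr_error_degenerate_state")
  }
  D <- s2b * X * b0 + s1b * X * b0 + 2 * s2b * X + 2 * s1b * X -
    s2b * b0 - s1b * b0 - 2 * s2b - 2 * s1b
  top <- g * x^2 * (1 + (X - 1) * s1b) / 2 +
    g * (1 + s1b * (X - 1)) *
      ((2 + b0) * (X - 1) * (s2b + s1b) * pw(x, -b0) - (pw(2, -b0) + 2 * b0)) /
      (b0 * D)
  t1 <- top / ((2 + b0) * (X - 1) * (s1b + s2b))
  n18 <- (b0^3 + 6 * b0^2 + 8 * b0) * pw(x, 2 - b0) +
    ((2 * b0^2 + 4 * b0 - 16) * pw(x, -b0) + x^2 * b0^3 + 2 * x^2 * b0^2 -
       8 * x^2 * b0 - 10 * b0^3 - 36 * b0^2 + 24 * b0 - 16) * pw(2, -b0) -
    (-2 + b0) * ((-2 * b0^2 - 8 * b0 + 8) * pw(x, -b0) +
                   (2 * b0 + 8) * pw(4, -b0) + 0.25 * p_quartic(x, b0) * b0^2)
  t2 <- g^2 * (1 + s1b * (X - 1)) * n18 /
    (2 * b0^2 * (4 + b0) * (-2 + b0) * (2 + b0)^2 * ((X - 1) * (s1b + s2b))^2)
  1 + t1 - t2
}

# analytic radial derivatives of the series solutions (monomial route)
hpm_deriv <- function(params, x, species = c("s1", "s2"), deriv = 1L,
                      order = "second") {
  species <- match.arg(species)
  p <- param_list(params, need_hpm = TRUE)
  mo <- if (species == "s1") hpm_s1_mono(p, order) else hpm_s2_mono(p, order)
  mono_eval(mo, x, p$b0, deriv = deriv) + if (deriv == 0L) 1 else 0
}

#' Closed-form concentration profiles on a radial grid
#'
#' Convenience wrapper evaluating both series solutions on a grid,
#' returning a tidy profile table.
#'
#' @inheritParams s1_hpm
#' @param x Radial grid in `[1, 2]`; default 101 equispaced points.
#' @param order Truncation passed to [s1_hpm()] and [s2_hpm()];
#'   `"third"` affects the (R)-ester only.
#' @return A tibble of class `dkr_profile` with columns `x`, `s1`, `s2`,
#'   `method` (`"hpm"`).
#' @export
hpm_profile <- function(params, x = seq(1, 2, length.out = 101),
                        order = c("second", "first", "third")) {
  order <- match.arg(order)
  s1 <- s1_hpm(params, x, order = if (order == "third") "second" else order)
  s2 <- s2_hpm(params, x, order = order)
  out <- tibble::tibble(x = x, s1 = s1, s2 = s2, method = "hpm")
  attr(out, "params") <- tibble::as_tibble(params)
  attr(out, "order") <- order
  class(out) <- c("dkr_profile", class(out))
  out
}
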