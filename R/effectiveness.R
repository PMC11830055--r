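# Local and mean integrated effectiveness factors (MIEF) for the (S)-ester.
# The mean factor over the hollow cross-section (inner radius x = 1, outer
# x = 2) is eta_m = 2 * int_1^2 x eta(x) dx / (2^2 - 1^2); the closed forms
# are linear deficits eta0 * (1 - K * Phi^2) about the zero-Thiele limit.

eta_zero_thiele <- function(theta, s1b, s2b, xi1, xi2, phi_frac) {
  (theta + s1b) * (1 + s2b * xi1 + phi_frac * xi2) /
    (s1b * (1 + xi1 + phi_frac * xi2) * (theta + 1))
}

eta_deficit_k <- function(theta, b0, xi1, xi2, phi_frac,
                          variant = c("table_consistent", "printed")) {
  variant <- match.arg(variant)
  lin <- if (variant == "table_consistent") -(9 / 2) else -(9 / 4)
  k0 <- 3 * 2^(-b0) * b0 + lin * b0 + 2^(1 - b0) - 2 + (9 / 4) * b0^2
  theta^2 * k0 /
    (3 * (1 + xi1 + phi_frac * xi2) * (theta + 1)^2 * b0 * (b0^2 - 4))
}

new_effectiveness <- function(df, variant, params) {
  attr(df, "params") <- tibble::as_tibble(params)
  attr(df, "variant") <- variant
  class(df) <- c("dkr_effectiveness", class(df))
  df
}

#' Zero-Thiele limit of the mean integrated effectiveness factor
#'
#' The \eqn{\Phi^2 \to 0} limit
#' \deqn{\eta_0 = \frac{(\Theta + S_{1b})(1 + S_{2b}\xi_1 + \phi\xi_2)}
#'   {S_{1b}(1 + \xi_1 + \phi\xi_2)(\Theta + 1)},}
#' which equals the rate ratio \eqn{v(1, 1)/v(S_{1b}, S_{2b})} and is
#' exactly 1 at the racemic reference state \eqn{S_{1b} = S_{2b} = 1}.
#'
#' @param params A [dkr_params()] tibble (bulk state taken from it).
#' @return A one-row tibble of class `dkr_effectiveness` with columns
#'   `phi2`, `s1b`, `s2b`, `theta`, `eta_m`, `variant`.
#' @export
mief_zero_thiele_limit <- function(params) {
  p <- param_list(params)
  eta <- eta_zero_thiele(p$theta, p$s1b, p$s2b, p$xi1, p$xi2, p$phi_frac)
  new_effectiveness(
    tibble::tibble(phi2 = 0, s1b = p$s1b, s2b = p$s2b, theta = p$theta,
                   eta_m = eta, variant = "zero_thiele_limit"),
    "zero_thiele_limit", params)
}

#' Closed-form mean integrated effectiveness factor
#'
#' Both closed-form variants are linear deficits
#' \eqn{\eta_m = \eta_0 (1 - K\,\Phi^2)} about the zero-Thiele limit
#' \eqn{\eta_0} (see [mief_zero_thiele_limit()]), with
#' \deqn{K = \frac{\Theta^2 K_0}
#'   {3(1 + \xi_1 + \phi\xi_2)(\Theta + 1)^2 B_0 (B_0^2 - 4)},}
#' and \eqn{K_0 = 3\cdot 2^{-B_0}B_0 + c\,B_0 + 2^{1-B_0} - 2 +
#' \tfrac94 B_0^2}. The `"printed"` variant evaluates the published
#' closed form literally (\eqn{c = -9/4}); the `"table_consistent"` variant
#' (default) uses \eqn{c = -9/2}, the unique single-coefficient change under
#' which the formula reproduces every cell of the reference effectiveness
#' tables to 5e-5 (the printed coefficient does not; see the vignette).
#' A factor \eqn{(B_0 - 2)} sits in the denominator, so `b0` near 2 is
#' rejected.
#'
#' Note on the modulus convention: `phi2` here is the true Thiele modulus
#' squared. The reference effectiveness tables label their columns with the
#' modulus \eqn{m} such that \eqn{\Phi^2 = m^2}; use
#' [effectiveness_sweep()] with `modulus = "phi"` to apply that convention
#' explicitly.
#'
#' @param params A [dkr_params()] tibble; `phi2` and the bulk state are
#'   taken from it.
#' @param variant `"table_consistent"` (default) or `"printed"`.
#' @return A one-row tibble of class `dkr_effectiveness`.
#' @examples
#' p <- dkr_params(phi2 = 100, b0 = 8.68, theta = 5, xi1 = 7.23,
#'                 xi2 = 0.25, phi_frac = 1)
#' mief_closed_form(p)$eta_m   # 0.433430
#' @export
mief_closed_form <- function(params,
                             variant = c("table_consistent", "printed")) {
  variant <- match.arg(variant)
  p <- param_list(params)
  assert_hpm_regular(p$b0)
  eta0 <- eta_zero_thiele(p$theta, p$s1b, p$s2b, p$xi1, p$xi2, p$phi_frac)
  K <- eta_deficit_k(p$theta, p$b0, p$xi1, p$xi2, p$phi_frac, variant)
  new_effectiveness(
    tibble::tibble(phi2 = p$phi2, s1b = p$s1b, s2b = p$s2b, theta = p$theta,
                   eta_m = eta0 * (1 - K * p$phi2), variant = variant),
    variant, params)
}

#' Sweep the closed-form effectiveness factor over parameter values
#'
#' Evaluates a closed-form variant over the outer product of supplied
#' `phi2` (or modulus), `s1b` and `theta` values, holding the remaining
#' groups at the values in `params`. `modulus = "phi"` declares that
#' `modulus_values` are moduli \eqn{m} entering as \eqn{\Phi^2 = m^2}
#' (the labelling convention of the reference effectiveness tables);
#' `modulus = "phi2"` (default) uses them as \eqn{\Phi^2} directly. The
#' convention is always explicit, never guessed.
#'
#' @inheritParams mief_closed_form
#' @param modulus_values Numeric vector of moduli.
#' @param modulus `"phi2"` or `"phi"`; see Details.
#' @param s1b,theta Optional numeric vectors overriding the corresponding
#'   single values in `params`.
#' @return A tibble of class `dkr_effectiveness`, one row per combination.
#' @export
effectiveness_sweep <- function(params, modulus_values,
                                modulus = c("phi2", "phi"),
                                s1b = NULL, theta = NULL,
                                variant = c("table_consistent",
                                            "printed")) {
  modulus <- match.arg(modulus)
  variant <- match.arg(variant)
  p <- param_list(params)
  assert_hpm_regular(p$b0)
  grid <- tidyr::expand_grid(
    modulus_value = as.numeric(modulus_values),
    s1b = if (is.null(s1b)) p$s1b else as.numeric(s1b),
    theta = if (is.null(theta)) p$theta else as.numeric(theta))
  phi2 <- if (modulus == "phi") grid$modulus_value^2 else grid$modulus_value
  eta0 <- eta_zero_thiele(grid$theta, grid$s1b, p$s2b, p$xi1, p$xi2,
                          p$phi_frac)
  K <- eta_deficit_k(grid$theta, p$b0, p$xi1, p$xi2, p$phi_frac, variant)
  out <- tibble::tibble(
    modulus_value = grid$modulus_value, phi2 = phi2, s1b = grid$s1b,
    s2b = p$s2b, theta = grid$theta, eta_m = eta0 * (1 - K * phi2),
    variant = variant)
  new_effectiveness(out, variant, params)
}

# resolve a profile source to a function(x) -> list(s1, s2)
resolve_profile_fun <- function(params, profile, order = "second") {
  if (is.function(profile)) return(profile)
  if (inherits(profile, "dkr_profile")) {
    interp <- attr(profile, "interpolant")
    if (!is.null(interp)) {
      return(function(x) {
        v <- interp(x, 0L)
        list(s1 = v[, 1], s2 = v[, 3])
      })
    }
    pp <- attr(profile, "params")
    ord <- attr(profile, "order") %||% order
    return(function(x) list(s1 = s1_hpm(pp, x, if (ord == "third") "second" else ord),
                            s2 = s2_hpm(pp, x, ord)))
  }
  if (is.character(profile) && length(profile) == 1) {
    if (profile %in% c("hpm", "hpm_first")) {
      ord <- if (profile == "hpm_first") "first" else "second"
      return(function(x) list(s1 = s1_hpm(params, x, ord),
                              s2 = s2_hpm(params, x, ord)))
    }
    if (profile == "numeric") {
      prof <- solve_profiles(params, tolerance = 1e-9)
      return(resolve_profile_fun(params, prof))
    }
  }
  abort_dkr("`profile` must be \"hpm\", \"hpm_first\", \"numeric\", a dkr_profile, or a function",
            class = "dkrmr_error_invalid_parameter")
}

#' Local effectiveness factor
#'
#' Two local definitions are supported. `"concentration"` is the
#' concentration ratio \eqn{\eta(x) = S_1(x) / S_1(\mathrm{bulk\
#' interface})} with the bulk-interface value \eqn{S_1(2) = 1} fixed by the
#' outer boundary condition. `"rate"` is the reaction-rate ratio
#' \eqn{\eta(x) = v(S_1(x), S_2(x)) / v(S_{1b}, S_{2b})} with the
#' hydrolysis rate of [reaction_rate_s1()].
#'
#' @param params A [dkr_params()] tibble (bulk state from it).
#' @param x Radial coordinate(s) in `[1, 2]`.
#' @param profile Profile source: `"hpm"` (default), `"hpm_first"`,
#'   `"numeric"`, a `dkr_profile`, or a `function(x)` returning
#'   `list(s1, s2)`.
#' @param definition `"concentration"` or `"rate"`.
#' @return Numeric vector of local effectiveness values.
#' @export
local_effectiveness <- function(params, x, profile = "hpm",
                                definition = c("concentration", "rate")) {
  definition <- match.arg(definition)
  p <- param_list(params)
  assert_domain_x(x)
  fn <- resolve_profile_fun(params, profile)
  st <- fn(x)
  if (definition == "concentration") {
    return(st$s1 / 1)
  }
  # the Thiele factor cancels in the rate ratio, so the shape function is
  # used directly and the ratio is well defined at phi2 = 0 too
  shape <- function(s1, s2) {
    s1 / ((1 + s1 / p$theta) * (1 + p$phi_frac * p$xi2 + p$xi1 * s2))
  }
  vb <- shape(p$s1b, p$s2b)
  if (!is.finite(vb) || vb <= 0) {
    abort_dkr("bulk reaction rate is zero; the rate-ratio definition is degenerate",
              class = "dkrmr_error_degenerate_parameter")
  }
  shape(st$s1, st$s2) / vb
}

#' Mean integrated effectiveness factor by quadrature
#'
#' Evaluates \eqn{\eta_m = \frac{2}{3}\int_1^2 x\,\eta(x)\,dx} by adaptive
#' quadrature of a chosen local definition over a chosen profile source,
#' to an absolute accuracy of about 1e-10. Useful as an independent check
#' on the closed forms: with the rate definition on the first-order series
#' profile it reproduces the `table_consistent` deficit slope.
#'
#' @inheritParams local_effectiveness
#' @return A one-row tibble of class `dkr_effectiveness` (variant
#'   `"quadrature_rate"` or `"quadrature_concentration"`).
#' @export
mief_quadrature <- function(params, profile = "hpm",
                            definition = c("concentration", "rate")) {
  definition <- match.arg(definition)
  p <- param_list(params)
  fn <- resolve_profile_fun(params, profile)
  eta_fun <- function(x) {
    local_effectiveness(params, x, profile = fn, definition = definition)
  }
  val <- stats::integrate(function(x) x * eta_fun(x), 1, 2,
                          rel.tol = 1e-12, abs.tol = 1e-12,
                          subdivisions = 500L)
  eta <- 2 * val$value / 3
  new_effectiveness(
    tibble::tibble(phi2 = p$phi2, s1b = p$s1b, s2b = p$s2b, theta = p$theta,
                   eta_m = eta, variant = paste0("quadrature_", definition)),
    paste0("quadrature_", definition), params)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
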