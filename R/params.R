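#' Dimensionless parameter set for the membrane DKR model
#'
#' Bundles the seven dimensionless groups governing the steady-state
#' reaction--diffusion--convection system for the (S)- and (R)-ester
#' concentrations across the membrane (`1 <= x <= 2`), together with the
#' bulk state used by the conversion-degree forms and the effectiveness
#' factor.
#'
#' The groups are:
#' \describe{
#'   \item{`phi2`}{Thiele modulus squared, \eqn{\Phi^2 = a^2 \alpha_p
#'     v_{max} / (D_{eff} K_{mA})}. Ratio of hydrolysis rate to radial
#'     diffusion rate; \eqn{\Phi^2 \gg 1} means diffusion-limited operation.}
#'   \item{`b0`}{Bodenstein number \eqn{B_0 = r\,u(r)/D_{eff} =
#'     F/(2\pi L N D_{eff})}; convective over diffusive transport,
#'     proportional to the volumetric flow rate.}
#'   \item{`theta`}{Michaelis--Menten group \eqn{\Theta = K_{mA}/s_{A0}}.}
#'   \item{`gamma`}{Racemization group \eqn{\gamma = a^2 r_{rac} /
#'     (D_{eff} s_{T0})}.}
#'   \item{`xi1`}{Uncompetitive substrate-inhibition group by the (R)-ester,
#'     \eqn{\xi_1 = s_{B0}/K_{uS1}}.}
#'   \item{`xi2`}{Non-competitive by-product (alcohol) inhibition group,
#'     \eqn{\xi_2 = s_{A0}/K_{nI1}}.}
#'   \item{`phi_frac`}{Molar fraction of by-product to substrate,
#'     \eqn{\phi = s_I/s_{A0}}; enters the kinetics only through the
#'     product \eqn{\phi \xi_2}.}
#' }
#' The bulk state consists of the dimensionless bulk concentrations `s1b`,
#' `s2b` (> 0) and the conversion degree `x_conv` (\eqn{0 \le X < 1};
#' the conversion-degree closed forms carry factors of \eqn{(X - 1)} in
#' denominators, so `x_conv = 1` is excluded).
#'
#' @param phi2 Thiele modulus squared (>= 0).
#' @param b0 Bodenstein number (> 0).
#' @param theta Michaelis--Menten group (> 0).
#' @param gamma Racemization group (>= 0). Default 0 (no racemization).
#' @param xi1,xi2 Inhibition groups (>= 0). Default 0.
#' @param phi_frac By-product molar fraction (>= 0). Default 0.
#' @param s1b,s2b Dimensionless bulk concentrations (> 0). Default 1.
#' @param x_conv Conversion degree, in `[0, 1)`. Default 0.
#'
#' @return A one-row tibble of class `dkr_params` with the ten columns above.
#' @examples
#' p <- dkr_params(phi2 = 0.5, b0 = 8.68, theta = 3.27, gamma = 1,
#'                 xi1 = 2, xi2 = 0.03, phi_frac = 1)
#' hpm_profile(p, x = seq(1, 2, 0.2))
#' @export
dkr_params <- function(phi2, b0, theta, gamma = 0, xi1 = 0, xi2 = 0,
                       phi_frac = 0, s1b = 1, s2b = 1, x_conv = 0) {
  p <- tibble::tibble(
    phi2 = as.numeric(phi2), b0 = as.numeric(b0), theta = as.numeric(theta),
    gamma = as.numeric(gamma), xi1 = as.numeric(xi1), xi2 = as.numeric(xi2),
    phi_frac = as.numeric(phi_frac), s1b = as.numeric(s1b),
    s2b = as.numeric(s2b), x_conv = as.numeric(x_conv)
  )
  validate_params(p)
  class(p) <- c("dkr_params", class(p))
  p
}

validate_params <- function(p) {
  if (nrow(p) != 1L) {
    abort_dkr("`params` must be a single parameter set (one row)",
              class = "dkrmr_error_invalid_parameter")
  }
  vals <- unlist(p[1, ])
  if (any(!is.finite(vals))) {
    abort_dkr(paste0("non-finite parameter value in: ",
                     paste(names(vals)[!is.finite(vals)], collapse = ", ")),
              class = "dkrmr_error_invalid_parameter")
  }
  chk <- function(ok, msg) {
    if (!ok) abort_dkr(msg, class = "dkrmr_error_invalid_parameter")
  }
  chk(p$phi2 >= 0, "`phi2` must be >= 0")
  chk(p$b0 > 0, "`b0` must be > 0")
  chk(p$theta > 0, "`theta` must be > 0")
  chk(p$gamma >= 0, "`gamma` must be >= 0")
  chk(p$xi1 >= 0, "`xi1` must be >= 0")
  chk(p$xi2 >= 0, "`xi2` must be >= 0")
  chk(p$phi_frac >= 0, "`phi_frac` must be >= 0")
  chk(p$s1b > 0, "`s1b` must be > 0")
  chk(p$s2b > 0, "`s2b` must be > 0")
  chk(p$x_conv >= 0 && p$x_conv < 1,
      "`x_conv` must lie in [0, 1) (factors of (X - 1) appear in denominators)")
  invisible(p)
}

# single-row params -> plain named list, with optional HPM singularity guard
param_list <- function(p, need_hpm = FALSE) {
  if (!inherits(p, "dkr_params")) {
    if (is.data.frame(p)) {
      p <- tibble::as_tibble(p)
      validate_params(p)
    } else {
      abort_dkr("`params` must be a `dkr_params` tibble (see `dkr_params()`)",
                class = "dkrmr_error_invalid_parameter")
    }
  }
  if (need_hpm) assert_hpm_regular(p$b0)
  as.list(p[1, ])
}

assert_hpm_regular <- function(b0) {
  if (abs(b0 - 2) < 1e-6) {
    abort_dkr(
      "`b0` within 1e-6 of 2: the closed-form series have a factor (B0 - 2) in denominators",
      class = "dkrmr_error_singular_parameter")
  }
  invisible(b0)
}

assert_domain_x <- function(x) {
  if (any(!is.finite(x)) || any(x < 1 - 1e-12) || any(x > 2 + 1e-12)) {
    abort_dkr("radial coordinate `x` must lie within [1, 2]",
              class = "dkrmr_error_domain")
  }
  invisible(x)
}

abort_dkr <- function(msg, class) {
  rlang::abort(msg, class = c(class, "dkrmr_error"))
}

#' Physical (dimensional) parameter set of the hollow-fibre reactor
#'
#' Holds the dimensional kinetic, transport and geometric parameters from
#' which the dimensionless groups are derived. Concentrations are in mM,
#' radii and lengths in cm, diffusivity in cm^2/min, flow in cm^3/min.
#' Kinetic rates (`v_max`, `K_rac`) are given per hour by default, matching
#' the usual reporting convention for this system, and are converted to a
#' per-minute base internally so that all groups are formed on a single time
#' base; set `rate_units = "per_min"` if they are already per minute.
#'
#' @param s_OH Base (tri-octylamine) concentration, mM.
#' @param s_A0,s_B0 Initial (S)- and (R)-ester concentrations, mM.
#' @param s_I Alcohol (non-competitive inhibitor) concentration, mM.
#' @param K_rac Racemization rate constant, mM/h per mM base (the
#'   racemization rate is `r_rac = K_rac * s_OH`).
#' @param K_mA,K_mB Michaelis--Menten constants of the (S)- and (R)-esters, mM.
#' @param v_max Maximum reaction rate, mM/h.
#' @param K_uS1,K_uS1_prime Uncompetitive substrate-inhibition constants, mM.
#' @param K_nI1 Non-competitive inhibition constant, mM.
#' @param D_eff Effective diffusivity, cm^2/min.
#' @param a,c Inner and outer fibre radii, cm. The closed forms assume the
#'   geometry `c/a = 2`; other ratios draw a warning.
#' @param L Effective fibre length, cm.
#' @param N Number of fibres.
#' @param alpha_p Membrane porosity, in (0, 1].
#' @param F_flow Volumetric flow rate, cm^3/min.
#' @param s_T0 Initial racemic substrate concentration, mM; defaults to
#'   `2 * s_B0` when omitted.
#' @param rate_units Either `"per_hour"` (default) or `"per_min"`, the time
#'   base in which `v_max` and `K_rac` are supplied.
#'
#' @return A one-row tibble of class `dkr_physical`.
#' @seealso [to_dimensionless()]
#' @export
dkr_physical <- function(s_OH, s_A0, s_B0, s_I, K_rac, K_mA, v_max,
                         K_uS1, K_nI1, D_eff, a, c, L, N, alpha_p, F_flow,
                         s_T0 = NULL, K_mB = K_mA, K_uS1_prime = K_uS1,
                         rate_units = c("per_hour", "per_min")) {
  rate_units <- match.arg(rate_units)
  if (is.null(s_T0)) s_T0 <- 2 * s_B0
  p <- tibble::tibble(
    s_OH = as.numeric(s_OH), s_T0 = as.numeric(s_T0), s_A0 = as.numeric(s_A0),
    s_B0 = as.numeric(s_B0), s_I = as.numeric(s_I), K_rac = as.numeric(K_rac),
    K_mA = as.numeric(K_mA), K_mB = as.numeric(K_mB),
    v_max = as.numeric(v_max), K_uS1 = as.numeric(K_uS1),
    K_uS1_prime = as.numeric(K_uS1_prime), K_nI1 = as.numeric(K_nI1),
    D_eff = as.numeric(D_eff), a = as.numeric(a), c = as.numeric(c),
    L = as.numeric(L), N = as.numeric(N), alpha_p = as.numeric(alpha_p),
    F_flow = as.numeric(F_flow), rate_units = rate_units
  )
  validate_physical(p)
  class(p) <- c("dkr_physical", class(p))
  p
}

validate_physical <- function(p) {
  num <- unlist(p[1, setdiff(names(p), "rate_units")])
  if (any(!is.finite(num))) {
    abort_dkr(paste0("non-finite value in: ",
                     paste(names(num)[!is.finite(num)], collapse = ", ")),
              class = "dkrmr_error_invalid_parameter")
  }
  strict_pos <- c("s_OH", "s_T0", "s_A0", "s_B0", "s_I", "K_rac", "K_mA",
                  "K_mB", "v_max", "K_uS1", "K_uS1_prime", "K_nI1", "D_eff",
                  "a", "c", "L", "F_flow")
  bad <- strict_pos[unlist(p[1, strict_pos]) <= 0]
  if (length(bad)) {
    abort_dkr(paste0("field(s) must be strictly positive: ",
                     paste(bad, collapse = ", ")),
              class = "dkrmr_error_invalid_parameter")
  }
  if (p$N < 1 || p$N != round(p$N)) {
    abort_dkr("`N` must be an integer >= 1",
              class = "dkrmr_error_invalid_parameter")
  }
  if (p$alpha_p <= 0 || p$alpha_p > 1) {
    abort_dkr("`alpha_p` must lie in (0, 1]",
              class = "dkrmr_error_invalid_parameter")
  }
  if (p$c <= p$a) {
    abort_dkr("outer radius `c` must exceed inner radius `a`",
              class = "dkrmr_error_invalid_parameter")
  }
  if (abs(p$c / p$a - 2) > 1e-8) {
    rlang::warn(sprintf(
      "c/a = %.4g: the closed forms and the x in [1, 2] domain assume c/a = 2",
      p$c / p$a))
  }
  invisible(p)
}

#' Map physical parameters to the dimensionless groups
#'
#' Forms the seven dimensionless groups from a dimensional parameter set,
#' after converting all kinetic rates to a per-minute base:
#' \deqn{\Phi^2 = a^2 \alpha_p v_{max} / (D_{eff} K_{mA}), \quad
#'       B_0 = F/(2\pi L N D_{eff}),}
#' \deqn{\Theta = K_{mA}/s_{A0}, \quad \xi_1 = s_{B0}/K_{uS1}, \quad
#'       \xi_2 = s_{A0}/K_{nI1}, \quad \phi = s_I/s_{A0},}
#' \deqn{\gamma = a^2 K_{rac} s_{OH} / (D_{eff} s_{T0}).}
#' The Bodenstein number is formed from \eqn{B_0 = r\,u(r)/D_{eff}} with the
#' radial velocity \eqn{u(r) = F/(2\pi r L N)}, so the radius cancels and
#' \eqn{B_0} is a constant of the geometry and flow.
#'
#' @param phys A [dkr_physical()] tibble.
#' @param ... Bulk-state overrides (`s1b`, `s2b`, `x_conv`) passed to
#'   [dkr_params()].
#' @return A [dkr_params()] tibble.
#' @examples
#' phys <- dkr_physical(s_OH = 50, s_A0 = 6.1, s_B0 = 6.1, s_I = 6.1,
#'                      K_rac = 1, K_mA = 20, v_max = 60, K_uS1 = 50,
#'                      K_nI1 = 100, D_eff = 3.2653e-4, a = 0.056, c = 0.112,
#'                      L = 43.2, N = 65, alpha_p = 0.8, F_flow = 50)
#' to_dimensionless(phys)
#' @export
to_dimensionless <- function(phys, ...) {
  if (!inherits(phys, "dkr_physical")) {
    if (is.data.frame(phys)) {
      phys <- tibble::as_tibble(phys)
      validate_physical(phys)
    } else {
      abort_dkr("`phys` must be a `dkr_physical` tibble",
                class = "dkrmr_error_invalid_parameter")
    }
  }
  q <- as.list(phys[1, ])
  to_min <- if (identical(q$rate_units, "per_hour")) 1 / 60 else 1
  v_max <- q$v_max * to_min
  r_rac <- q$K_rac * q$s_OH * to_min
  p <- dkr_params(
    phi2 = q$a^2 * q$alpha_p * v_max / (q$D_eff * q$K_mA),
    b0 = q$F_flow / (2 * pi * q$L * q$N * q$D_eff),
    theta = q$K_mA / q$s_A0,
    gamma = q$a^2 * r_rac / (q$D_eff * q$s_T0),
    xi1 = q$s_B0 / q$K_uS1,
    xi2 = q$s_A0 / q$K_nI1,
    phi_frac = q$s_I / q$s_A0,
    ...
  )
  rlang::inform(
    sprintf("derived groups: phi2 = %.6g, b0 = %.6g, theta = %.6g, gamma = %.6g",
            p$phi2, p$b0, p$theta, p$gamma),
    class = "dkrmr_debug", .frequency = "once", .frequency_id = "to_dimensionless")
  p
}

#' Read a flat key-value parameter configuration
#'
#' Parses a minimal `key=value` configuration (whitespace- or
#' newline-separated pairs, `#` comments allowed) into a parameter bundle.
#' Keys may be the dimensionless names (`phi2`, `b0`, `theta`, `gamma`,
#' `xi1`, `xi2`, `phi_frac`, `s1b`, `s2b`, `x_conv`) or the physical names
#' accepted by [dkr_physical()]; mixing the two families, or any unknown
#' key, is an error. Physical keys are mapped through [to_dimensionless()].
#'
#' @param text Configuration text, or a path to a file containing it.
#' @return A [dkr_params()] tibble.
#' @examples
#' load_config("phi2=0.5 b0=8.68 theta=3.27 gamma=1 xi1=2 xi2=0.03 phi_frac=1")
#' @export
load_config <- function(text) {
  if (length(text) == 1 && !grepl("=", text) && file.exists(text)) {
    text <- readLines(text, warn = FALSE)
  }
  text <- gsub("#.*$", "", text)
  toks <- unlist(strsplit(paste(text, collapse = "\n"), "[[:space:],;]+"))
  toks <- toks[nzchar(toks)]
  if (!length(toks)) {
    rlang::warn("empty configuration: using all-default parameters")
    return(dkr_params(phi2 = 0, b0 = 8.68, theta = 1))
  }
  bad <- toks[!grepl("^[^=]+=[^=]*$", toks)]
  if (length(bad)) {
    abort_dkr(paste0("malformed entries (expected key=value): ",
                     paste(bad, collapse = ", ")),
              class = "dkrmr_error_config")
  }
  keys <- sub("=.*$", "", toks)
  vals <- suppressWarnings(as.numeric(sub("^[^=]*=", "", toks)))
  if (anyDuplicated(keys)) {
    abort_dkr(paste0("duplicated key(s): ",
                     paste(unique(keys[duplicated(keys)]), collapse = ", ")),
              class = "dkrmr_error_config")
  }
  if (any(is.na(vals))) {
    abort_dkr(paste0("non-numeric value for key(s): ",
                     paste(keys[is.na(vals)], collapse = ", ")),
              class = "dkrmr_error_config")
  }
  dimless <- c("phi2", "b0", "theta", "gamma", "xi1", "xi2", "phi_frac",
               "s1b", "s2b", "x_conv")
  physical <- c("s_OH", "s_T0", "s_A0", "s_B0", "s_I", "K_rac", "K_mA",
                "K_mB", "v_max", "K_uS1", "K_uS1_prime", "K_nI1", "D_eff",
                "a", "c", "L", "N", "alpha_p", "F_flow")
  unknown <- setdiff(keys, c(dimless, physical))
  if (length(unknown)) {
    abort_dkr(paste0("unknown key(s): ", paste(unknown, collapse = ", "),
                     "; valid keys are the dimensionless or physical parameter names"),
              class = "dkrmr_error_config")
  }
  if (any(keys %in% physical)) {
    if (any(keys %in% setdiff(dimless, c("s1b", "s2b", "x_conv")))) {
      abort_dkr("cannot mix physical and dimensionless parameter keys",
                class = "dkrmr_error_config")
    }
    args <- as.list(vals[keys %in% physical])
    names(args) <- keys[keys %in% physical]
    phys <- do.call(dkr_physical, args)
    bulk <- as.list(vals[keys %in% c("s1b", "s2b", "x_conv")])
    names(bulk) <- keys[keys %in% c("s1b", "s2b", "x_conv")]
    return(do.call(to_dimensionless, c(list(phys), bulk)))
  }
  args <- as.list(vals)
  names(args) <- keys
  do.call(dkr_params, args)
}
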