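# Internal exact algebra on functions of the form sum_j c_j * x^(m_j - n_j*B0),
# represented as lists with integer vectors m, n and numeric coefficients c
# (numeric once B0 is fixed). Used for analytic radial derivatives of the
# series solutions and for inverting the radial transport operator
# L[u] = u'' + (1 + B0)/x u' when building higher-order series terms.

mono <- function(m, n, c) {
  stopifnot(length(m) == length(n), length(n) == length(c))
  list(m = as.numeric(m), n = as.numeric(n), c = as.numeric(c))
}

mono_eval <- function(mo, x, b0, deriv = 0L) {
  k <- mo$m - mo$n * b0
  out <- numeric(length(x))
  for (j in seq_along(k)) {
    cf <- mo$c[j]
    kk <- k[j]
    if (deriv >= 1L) { cf <- cf * kk; kk <- kk - 1 }
    if (deriv >= 2L) { cf <- cf * (kk); kk <- kk - 1 }
    if (cf != 0) out <- out + cf * exp(kk * log(x))
  }
  out
}

mono_scale <- function(mo, s) mono(mo$m, mo$n, mo$c * s)

mono_add <- function(a, b) {
  m <- c(a$m, b$m); n <- c(a$n, b$n); cc <- c(a$c, b$c)
  key <- paste(m, n)
  agg <- rowsum(cc, key)
  parts <- strsplit(rownames(agg), " ", fixed = TRUE)
  mono(vapply(parts, function(z) as.numeric(z[1]), 0),
       vapply(parts, function(z) as.numeric(z[2]), 0),
       as.numeric(agg))
}

mono_mul <- function(a, b) {
  m <- outer(a$m, b$m, `+`)
  n <- outer(a$n, b$n, `+`)
  cc <- outer(a$c, b$c)
  out <- mono(as.numeric(m), as.numeric(n), as.numeric(cc))
  mono_add(out, mono(numeric(0), numeric(0), numeric(0)))
}

# Invert L[u] = f with u'(1) = 0, u(2) = 0.  Particular solution of a
# monomial c x^k is c x^(k+2) / ((k+2)(k+2+B0)); homogeneous solutions are
# 1 and x^(-B0).  Resonant exponents (k = -2 or k = -2 - B0, i.e. B0 at a
# small set of low integers for the terms arising here) are rejected.
mono_linv <- function(mo, b0) {
  k <- mo$m - mo$n * b0
  d1 <- k + 2
  d2 <- k + 2 + b0
  if (any(abs(d1) < 1e-6) || any(abs(d2) < 1e-6)) {
    abort_dkr(
      "resonant Bodenstein number for the higher-order series construction",
      class = "dkrmr_error_singular_parameter")
  }
  part <- mono(mo$m + 2, mo$n, mo$c / (d1 * d2))
  dp1 <- sum(part$c * (part$m - part$n * b0))      # u_p'(1)
  C <- dp1 / b0                                    # coefficient of x^(-B0)
  val2 <- sum(part$c * 2^(part$m - part$n * b0))   # u_p(2)
  A <- -(val2 + C * 2^(-b0))
  mono_add(part, mono(c(0, 0), c(0, 1), c(A, C)))
}
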