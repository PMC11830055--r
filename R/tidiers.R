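# broom-style tidiers for the result objects

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a concentration profile
#'
#' @param x A `dkr_profile`.
#' @param ... Unused.
#' @return A long tibble with columns `x`, `species`, `value`, `method`.
#' @export
tidy.dkr_profile <- function(x, ...) {
  out <- tidyr::pivot_longer(tibble::as_tibble(x), c("s1", "s2"),
                             names_to = "species", values_to = "value")
  dplyr::select(out, "x", "species", "value", "method")
}

#' Summarise a concentration profile
#'
#' @param x A `dkr_profile`.
#' @param ... Unused.
#' @return One row with the method, achieved residual (numeric profiles),
#'   mesh size, and the inner-radius values of both species.
#' @export
glance.dkr_profile <- function(x, ...) {
  tibble::tibble(
    method = x$method[1],
    max_residual = attr(x, "max_residual") %||% NA_real_,
    mesh_points = attr(x, "mesh_points") %||% NA_integer_,
    s1_inner = x$s1[which.min(x$x)],
    s2_inner = x$s2[which.min(x$x)]
  )
}

#' Tidy a series-vs-numeric comparison
#'
#' @param x A `dkr_comparison`.
#' @param ... Unused.
#' @return The per-point tibble (`x`, `hpm`, `numeric`, `pct_error`).
#' @export
tidy.dkr_comparison <- function(x, ...) tibble::as_tibble(x)

#' Summarise a series-vs-numeric comparison
#'
#' @param x A `dkr_comparison`.
#' @param ... Unused.
#' @return One row with `species`, `order`, `n`, `average_pct_error`,
#'   `max_pct_error`.
#' @export
glance.dkr_comparison <- function(x, ...) {
  tibble::tibble(
    species = attr(x, "species"),
    order = attr(x, "order"),
    n = nrow(x),
    average_pct_error = attr(x, "average_pct_error"),
    max_pct_error = max(x$pct_error)
  )
}

#' Tidy a validity map
#'
#' @param x A `dkr_validity`.
#' @param ... Unused.
#' @return The cell tibble (`bulk`, `modulus`, `valid`).
#' @export
tidy.dkr_validity <- function(x, ...) tibble::as_tibble(x)

#' Summarise a validity map
#'
#' @param x A `dkr_validity`.
#' @param ... Unused.
#' @return One row with the species, conversion degree, criterion, cell
#'   counts and valid fraction.
#' @export
glance.dkr_validity <- function(x, ...) {
  tibble::tibble(
    species = attr(x, "species"),
    x_conv = attr(x, "x_conv"),
    criterion = attr(x, "criterion"),
    n_cells = nrow(x),
    n_valid = sum(x$valid),
    valid_fraction = mean(x$valid)
  )
}

#' Tidy a fitted validity frontier
#'
#' @param x A `dkr_validity_fit`.
#' @param ... Unused.
#' @return A term/estimate tibble for the fitted line.
#' @export
tidy.dkr_validity_fit <- function(x, ...) {
  tibble::tibble(term = c("slope", "intercept"),
                 estimate = c(x$slope, x$intercept))
}

#' Summarise a fitted validity frontier
#'
#' @param x A `dkr_validity_fit`.
#' @param ... Unused.
#' @return The one-row fit tibble (`slope`, `intercept`, `residual_rms`,
#'   `n_columns`).
#' @export
glance.dkr_validity_fit <- function(x, ...) tibble::as_tibble(x)

#' Tidy a sensitivity report
#'
#' @param x A `dkr_sensitivity`.
#' @param ... Unused.
#' @return The per-parameter tibble.
#' @export
tidy.dkr_sensitivity <- function(x, ...) tibble::as_tibble(x)

#' Summarise a sensitivity report
#'
#' @param x A `dkr_sensitivity`.
#' @param ... Unused.
#' @return One row with the dominant parameter, the variant and the step.
#' @export
glance.dkr_sensitivity <- function(x, ...) {
  tibble::tibble(
    dominant = x$parameter[which.max(x$normalized_pct)],
    variant = attr(x, "variant"),
    step = attr(x, "step"),
    n_parameters = nrow(x)
  )
}

#' Tidy an effectiveness result
#'
#' @param x A `dkr_effectiveness`.
#' @param ... Unused.
#' @return The row tibble.
#' @export
tidy.dkr_effectiveness <- function(x, ...) tibble::as_tibble(x)

#' Summarise an effectiveness result
#'
#' @param x A `dkr_effectiveness`.
#' @param ... Unused.
#' @return One row with the variant, the number of evaluations and the
#'   range of `eta_m`.
#' @export
glance.dkr_effectiveness <- function(x, ...) {
  tibble::tibble(
    variant = attr(x, "variant"),
    n = nrow(x),
    eta_min = min(x$eta_m),
    eta_max = max(x$eta_m)
  )
}
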