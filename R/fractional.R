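#' Grünwald–Letnikov fractional-difference coefficients
#'
#' The G-L derivative of order `alpha` applies the binomial-type weights
#' w_k = (-1)^k C(alpha, k) over a signal's left history. Weights are
#' computed by the stable recurrence w_0 = 1,
#' w_k = w_{k-1} (k - 1 - alpha) / k, equivalent to the Gamma closed form
#' (-1)^k Gamma(alpha + 1) / (k! Gamma(alpha - k + 1)). Integer orders
#' collapse to the classical difference stencils: alpha = 1 gives
#' (1, -1, 0, ...), alpha = 2 gives (1, -2, 1, 0, ...).
#'
#' @param alpha Differentiation order (>= 0); non-integer orders allowed.
#' @param m Truncation length; `m + 1` weights are returned.
#' @return Numeric vector `w_0 .. w_m` with attribute `alpha`.
#' @export
gl_coefficients <- function(alpha, m) {
  if (alpha < 0) abort("`alpha` must be >= 0.")
  if (m < 0) abort("`m` must be >= 0.")
  w <- numeric(m + 1)
  w[1] <- 1
  for (k in seq_len(m)) w[k + 1] <- w[k] * (k - 1 - alpha) / k
  attr(w, "alpha") <- alpha
  w
}

# Upper-triangular Toeplitz operator: (R %*% M)[, i] = sum_k w_k R[, i - k] / h^alpha.
gl_operator <- function(k, alpha, step_h) {
  w <- gl_coefficients(alpha, k - 1) / step_h^alpha
  M <- matrix(0, k, k)
  lag <- outer(seq_len(k), seq_len(k), function(row, col) col - row + 1)
  keep <- lag >= 1
  M[keep] <- w[lag[keep]]
  M
}

#' Fractional-order derivative of spectra
#'
#' Applies the Grünwald–Letnikov fractional difference along wavelength with
#' an expanding left-history window: channel i receives
#' sum_{k=0..i} w_k r(i-k) / h^alpha, so channel 0 equals r(0) / h^alpha.
#' Order 0 is the identity; orders 1 and 2 equal the backward first and
#' second differences away from the left edge. Requires a uniform grid.
#'
#' @param data A spectra table on a uniform wavelength grid.
#' @param alpha Differentiation order (>= 0).
#' @param step_h Grid spacing h in nm; defaults to the grid's spacing. After
#'   1 nm resampling h = 1 and the h^alpha scaling drops out.
#' @param edge_width Number of leading channels annotated as edge-affected
#'   (short history window); recorded as the `edge_channels` attribute so
#'   downstream band selection can optionally mask them.
#' @return A spectra table with derivative values (wavelengths unchanged)
#'   and an `edge_channels` attribute.
#' @export
fractional_derivative <- function(data, alpha, step_h = NULL,
                                  edge_width = 20) {
  check_spectra(data)
  wl <- spectra_wavelengths(data)
  d <- diff(wl)
  if (length(d) && max(abs(d - d[1])) > 1e-8 * max(d[1], 1)) {
    abort("Wavelength grid is not uniform; resample_to_grid() first.")
  }
  if (is.null(step_h)) step_h <- if (length(d)) d[1] else 1
  m <- spectra_matrix(data)
  out <- set_spectra_matrix(data, m %*% gl_operator(ncol(m), alpha, step_h))
  attr(out, "edge_channels") <- seq_len(min(edge_width, ncol(m)))
  out
}

#' Sweep of fractional differentiation orders
#'
#' Transforms the set at each order on an arithmetic grid of orders
#' (inclusive endpoint, tolerance 1e-9). The default grid 0 to 2 in steps of
#' 0.1 yields 21 transforms; order labels are rounded to one decimal.
#'
#' @param data A spectra table on a uniform grid.
#' @param lo,hi,step Order grid.
#' @inheritParams fractional_derivative
#' @return A tibble with columns `order` (numeric label) and `spectra`
#'   (list of transformed spectra tables), one row per order.
#' @examples
#' sw <- generate_dataset(synth_config(n_per_group = 3)) |>
#'   derivative_sweep(lo = 0, hi = 1, step = 0.5)
#' sw$order
#' @export
derivative_sweep <- function(data, lo = 0, hi = 2, step = 0.1, step_h = NULL) {
  if (lo > hi) abort("`lo` must be <= `hi`.")
  if (step <= 0) abort("`step` must be > 0.")
  n <- floor((hi - lo) / step + 1e-9)
  orders <- lo + step * (0:n)
  tibble::tibble(
    order = round(orders, 1),
    spectra = purrr::map(orders, ~ fractional_derivative(data, .x, step_h))
  )
}
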