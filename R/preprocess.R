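#' Quality-filter a spectra set
#'
#' Removes pathological samples before modelling: spectra with missing
#' channels (unless `allow_missing`), reflectance outside plausible physical
#' bounds, or abnormal adjacent-channel jumps.
#'
#' @param data A spectra table.
#' @param max_abs_jump Largest allowed absolute difference between adjacent
#'   channels (reflectance units).
#' @param allow_missing Keep samples with missing channels?
#' @param bounds Length-2 numeric; reflectance outside this interval marks a
#'   sample invalid.
#' @return A list with `spectra` (the retained samples) and `report`, a list
#'   holding `n_input`, `n_removed` and a `removal_reasons` tibble
#'   (`sample_id`, `reason` in `"missing"`, `"bounds"`, `"jump"`).
#' @export
quality_filter <- function(data, max_abs_jump = 0.3, allow_missing = FALSE,
                           bounds = c(-0.05, 1.5)) {
  check_spectra(data)
  if (max_abs_jump <= 0) abort("`max_abs_jump` must be > 0.")
  m <- spectra_matrix(data)

  missing <- apply(m, 1, anyNA)
  oob <- apply(m, 1, function(r) any(!is.na(r) & (r < bounds[1] | r > bounds[2])))
  jump <- apply(m, 1, function(r) {
    d <- abs(diff(r))
    any(!is.na(d) & d > max_abs_jump)
  })

  reason <- rep(NA_character_, nrow(m))
  if (!allow_missing) reason[missing] <- "missing"
  reason[is.na(reason) & oob] <- "bounds"
  reason[is.na(reason) & jump] <- "jump"

  drop <- !is.na(reason)
  if (all(drop)) {
    abort(paste0("quality_filter() removed every sample; review ",
                 "`max_abs_jump` and `bounds` against the data."))
  }
  list(
    spectra = data[!drop, , drop = FALSE],
    report = list(
      n_input = nrow(m),
      n_removed = sum(drop),
      removal_reasons = tibble::tibble(
        sample_id = data$sample_id[drop],
        reason = reason[drop]
      )
    )
  )
}

#' Write a QC report as JSON
#'
#' @param report The `report` element returned by [quality_filter()].
#' @param path File path.
#' @export
write_qc_report <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", pretty = TRUE)
  invisible(report)
}

#' Five-point weighted moving-average smoothing
#'
#' Smooths each spectrum with a symmetric five-channel weighted window; the
#' first and last two channels use the truncated, renormalized window so
#' spectrum length is preserved. The default kernel (1, 2, 4, 2, 1)/10 is the
#' standard centre-weighted five-point choice.
#'
#' @param data A spectra table (>= 5 channels).
#' @param weights Length-5 non-negative weights with positive sum.
#' @return A spectra table of the same shape.
#' @export
smooth_five_point <- function(data, weights = c(1, 2, 4, 2, 1)) {
  check_spectra(data)
  if (length(weights) != 5 || any(weights < 0) || sum(weights) <= 0) {
    abort("`weights` must be 5 non-negative values with positive sum.")
  }
  m <- spectra_matrix(data)
  k <- ncol(m)
  if (k < 5) abort("Spectra must have at least 5 channels to smooth.")
  # Column j of S holds the (truncated, renormalized) kernel centred at j,
  # so smoothed = m %*% S in one BLAS call.
  S <- matrix(0, k, k)
  for (j in seq_len(k)) {
    idx <- (j - 2):(j + 2)
    ok <- idx >= 1 & idx <= k
    S[idx[ok], j] <- weights[ok] / sum(weights[ok])
  }
  set_spectra_matrix(data, m %*% S)
}

#' Resample spectra onto a new wavelength grid
#'
#' Linear interpolation; exact where grid points coincide with the input
#' wavelengths. Extrapolation is refused.
#'
#' @param data A spectra table.
#' @param grid Strictly increasing wavelengths (nm) inside the input span.
#' @return A spectra table on `grid`.
#' @export
resample_to_grid <- function(data, grid) {
  check_spectra(data)
  wl <- spectra_wavelengths(data)
  if (any(diff(grid) <= 0)) abort("`grid` must be strictly increasing.")
  if (min(grid) < min(wl) || max(grid) > max(wl)) {
    abort("`grid` extends beyond the measured span; extrapolation is not supported.")
  }
  m <- spectra_matrix(data)
  out <- t(apply(m, 1, function(r) approx(wl, r, xout = grid)$y))
  set_spectra_matrix(data, out, grid)
}

#' Crop spectra to a wavelength range
#'
#' @param data A spectra table.
#' @param lo,hi Range bounds in nm (`lo < hi`); channels with
#'   `lo <= wavelength <= hi` are kept, metadata untouched.
#' @return A spectra table.
#' @export
crop_range <- function(data, lo = 400, hi = 1350) {
  check_spectra(data)
  if (lo >= hi) abort("`lo` must be < `hi`.")
  wl <- spectra_wavelengths(data)
  keep <- wl >= lo & wl <= hi
  if (!any(keep)) abort("Crop range has no overlap with the wavelength grid.")
  wc <- wavelength_cols(data)
  data[c(intersect(meta_cols, names(data)), wc[keep])]
}

#' Standard preprocessing chain
#'
#' Quality filter, five-point weighted smoothing, and range crop, in that
#' order. The default analysis range 400-1350 nm drops the noisiest
#' short-wave channels of the measured 350-1350 nm span.
#'
#' @inheritParams quality_filter
#' @inheritParams smooth_five_point
#' @inheritParams crop_range
#' @return A list with `spectra` (preprocessed table) and `report` (QC
#'   report from [quality_filter()]).
#' @export
preprocess_spectra <- function(data, max_abs_jump = 0.3,
                               weights = c(1, 2, 4, 2, 1),
                               lo = 400, hi = 1350) {
  qc <- quality_filter(data, max_abs_jump = max_abs_jump)
  out <- qc$spectra |>
    smooth_five_point(weights = weights) |>
    crop_range(lo = lo, hi = hi)
  list(spectra = out, report = qc$report)
}
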