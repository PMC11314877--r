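#' Spectra tables
#'
#' A spectra table is the package's central container: a wide tibble with one
#' row per sample and columns `sample_id`, `group`, `spad`, followed by one
#' reflectance column per wavelength, named by its position in nanometres
#' (e.g. `"550"`). All set-level operations take and return this shape so
#' calls chain with the pipe.
#'
#' @param data A spectra table.
#' @return `spectra_matrix()` returns the sample-by-wavelength numeric matrix
#'   (rownames = sample ids, colnames = wavelengths in nm);
#'   `spectra_wavelengths()` the numeric wavelength grid;
#'   `spectra_longer()` a long tibble with columns `sample_id`, `group`,
#'   `spad`, `wavelength`, `reflectance`.
#' @name spectra-table
NULL

meta_cols <- c("sample_id", "group", "spad")

wavelength_cols <- function(data) {
  nm <- names(data)
  nm[grepl("^[0-9]+(\\.[0-9]+)?$", nm)]
}

check_spectra <- function(data) {
  if (!is.data.frame(data)) {
    abort("`data` must be a spectra table (a data frame).")
  }
  wc <- wavelength_cols(data)
  if (length(wc) == 0) {
    abort("`data` has no wavelength columns (numeric nm names such as \"550\").")
  }
  wl <- as.numeric(wc)
  if (any(diff(wl) <= 0)) {
    abort("Wavelength columns must be in strictly increasing nm order.")
  }
  invisible(data)
}

#' @rdname spectra-table
#' @export
spectra_matrix <- function(data) {
  check_spectra(data)
  wc <- wavelength_cols(data)
  m <- as.matrix(data[wc])
  storage.mode(m) <- "double"
  if ("sample_id" %in% names(data)) rownames(m) <- data$sample_id
  m
}

#' @rdname spectra-table
#' @export
spectra_wavelengths <- function(data) {
  check_spectra(data)
  as.numeric(wavelength_cols(data))
}

# Rebuild a spectra table from metadata columns and a reflectance matrix.
set_spectra_matrix <- function(data, mat, wavelengths = NULL) {
  if (is.null(wavelengths)) wavelengths <- spectra_wavelengths(data)
  stopifnot(ncol(mat) == length(wavelengths))
  meta <- data[intersect(meta_cols, names(data))]
  refl <- tibble::as_tibble(as.data.frame(mat), .name_repair = "minimal")
  names(refl) <- format_wavelength(wavelengths)
  dplyr::bind_cols(meta, refl)
}

format_wavelength <- function(wl) {
  ifelse(wl == round(wl), as.character(as.integer(round(wl))), as.character(wl))
}

#' @rdname spectra-table
#' @export
spectra_longer <- function(data) {
  check_spectra(data)
  wc <- wavelength_cols(data)
  tidyr::pivot_longer(data, cols = dplyr::all_of(wc),
                      names_to = "wavelength", values_to = "reflectance") |>
    dplyr::mutate(wavelength = as.numeric(.data$wavelength))
}

#' Read and write spectra tables as CSV
#'
#' The on-disk format is the wide CSV described in [spectra-table]:
#' `sample_id`, `group`, `spad`, then one column per wavelength named by
#' integer nanometres.
#'
#' @param data A spectra table.
#' @param path File path.
#' @return `write_spectra()` returns `data` invisibly; `read_spectra()`
#'   returns a spectra table.
#' @export
write_spectra <- function(data, path) {
  check_spectra(data)
  readr::write_csv(data, path)
  invisible(data)
}

#' @rdname write_spectra
#' @export
read_spectra <- function(path) {
  data <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  check_spectra(data)
  data
}
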