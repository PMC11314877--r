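#' Synthetic-data generator configuration
#'
#' Builds the configuration for the synthetic canopy-spectra generator. The
#' generator emulates winter-wheat canopy reflectance under four CO2
#' microleakage treatments (control and 1/3/5 L min^-1): per-group SPAD
#' distributions matching the field study's descriptive statistics, and
#' reflectance curves carrying the spectral features the estimation method
#' relies on — a green peak near 550 nm whose height falls as SPAD rises, a
#' red absorption valley near 680 nm, a logistic red edge in 700-750 nm whose
#' inflection shifts blue as SPAD falls, an NIR plateau, water dips near 970
#' and 1200 nm, additive Gaussian channel noise, and optional "burr" spikes.
#'
#' @param group_params Tibble with columns `group`, `spad_mean`, `spad_sd`,
#'   `spad_min`, `spad_max`, one row per treatment. Defaults reproduce the
#'   field study's SPAD summary (control 59.5 +/- 3.7 in \[51.1, 65.5\];
#'   1 L 42.9 +/- 15.6 in \[10.2, 62.0\]; 3 L 36.6 +/- 17.7 in \[5.5, 60.1\];
#'   5 L 35.3 +/- 18.3 in \[7.0, 60.2\]).
#' @param n_per_group Samples per treatment group.
#' @param wavelength_lo,wavelength_hi,step Wavelength grid in nm.
#' @param noise_sd Standard deviation of additive Gaussian channel noise
#'   (reflectance units).
#' @param burr_rate Per-channel probability of an additive spike.
#' @param burr_amplitude Spike magnitude (reflectance units); sign is
#'   equiprobable.
#' @param red_edge_base,red_edge_shift_per_spad Red-edge inflection model:
#'   inflection = `red_edge_base` + `red_edge_shift_per_spad` * SPAD (nm).
#'   Defaults keep the inflection inside 700-750 nm over the SPAD ranges
#'   above.
#' @param red_edge_scale Logistic transition scale of the red edge (nm).
#' @param nir_plateau,vis_base NIR plateau and visible baseline reflectance.
#' @param green_peak_max,green_peak_k Green-peak height model:
#'   height = `green_peak_max` * k / (k + SPAD), strictly decreasing in SPAD.
#' @param well_depth_blue,well_depth_red,well_k Chlorophyll absorption wells
#'   at 450 and 680 nm: depth = d_max * SPAD / (SPAD + `well_k`), a bounded
#'   saturating increasing function of SPAD.
#' @param seed Integer seed fixing the whole dataset.
#' @return A list of class `synth_config`.
#' @seealso [generate_dataset()], [generate_spectrum()], [sample_spad()]
#' @export
synth_config <- function(group_params = default_group_params(),
                         n_per_group = 30,
                         wavelength_lo = 350, wavelength_hi = 1350, step = 1,
                         noise_sd = 0.01,
                         burr_rate = 0.01, burr_amplitude = 0.05,
                         red_edge_base = 700, red_edge_shift_per_spad = 0.4,
                         red_edge_scale = 8,
                         nir_plateau = 0.5, vis_base = 0.08,
                         green_peak_max = 0.25, green_peak_k = 25,
                         well_depth_blue = 0.05, well_depth_red = 0.06,
                         well_k = 20,
                         seed = 1L) {
  cfg <- list(
    group_params = tibble::as_tibble(group_params),
    n_per_group = n_per_group,
    wavelength_lo = wavelength_lo, wavelength_hi = wavelength_hi, step = step,
    noise_sd = noise_sd,
    burr_rate = burr_rate, burr_amplitude = burr_amplitude,
    red_edge_base = red_edge_base,
    red_edge_shift_per_spad = red_edge_shift_per_spad,
    red_edge_scale = red_edge_scale,
    nir_plateau = nir_plateau, vis_base = vis_base,
    green_peak_max = green_peak_max, green_peak_k = green_peak_k,
    well_depth_blue = well_depth_blue, well_depth_red = well_depth_red,
    well_k = well_k,
    seed = as.integer(seed)
  )
  class(cfg) <- "synth_config"
  validate_config(cfg)
}

#' @rdname synth_config
#' @export
default_group_params <- function() {
  tibble::tibble(
    group     = c("1L", "3L", "5L", "control"),
    spad_mean = c(42.9, 36.6, 35.3, 59.5),
    spad_sd   = c(15.6, 17.7, 18.3, 3.7),
    spad_min  = c(10.2, 5.5, 7.0, 51.1),
    spad_max  = c(62.0, 60.1, 60.2, 65.5)
  )
}

validate_config <- function(cfg) {
  gp <- cfg$group_params
  need <- c("group", "spad_mean", "spad_sd", "spad_min", "spad_max")
  if (!all(need %in% names(gp))) {
    abort(paste0("`group_params` must have columns ",
                 paste(need, collapse = ", "), "."))
  }
  if (any(gp$spad_min >= gp$spad_max)) abort("spad_min must be < spad_max.")
  if (any(gp$spad_sd < 0)) abort("spad_sd must be >= 0.")
  if (cfg$step <= 0) abort("`step` must be > 0.")
  if (cfg$wavelength_lo >= cfg$wavelength_hi) {
    abort("`wavelength_lo` must be < `wavelength_hi`.")
  }
  if (cfg$noise_sd < 0) abort("`noise_sd` must be >= 0.")
  if (cfg$burr_rate < 0 || cfg$burr_rate > 1) {
    abort("`burr_rate` must lie in [0, 1].")
  }
  if (cfg$n_per_group < 1) abort("`n_per_group` must be >= 1.")
  cfg
}

config_grid <- function(cfg) {
  seq(cfg$wavelength_lo, cfg$wavelength_hi, by = cfg$step)
}

#' Save or load a generator configuration as JSON
#'
#' @param cfg A `synth_config`.
#' @param path File path.
#' @export
write_config <- function(cfg, path) {
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", pretty = TRUE)
  invisible(cfg)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  raw$group_params <- tibble::as_tibble(raw$group_params)
  do.call(synth_config, raw)
}

#' Draw SPAD values for one treatment group
#'
#' Samples from a normal distribution truncated to the group's observed SPAD
#' range, by rejection (exact). SPAD is the unitless leaf-greenness reading of
#' a handheld chlorophyll meter, used throughout as the chlorophyll proxy.
#'
#' @param group Treatment label present in `config$group_params`.
#' @param n Number of draws.
#' @param config A [synth_config()].
#' @param seed Integer seed; the draw is deterministic given the seed and
#'   leaves the caller's RNG stream untouched.
#' @return Numeric vector of length `n`, all values inside
#'   `[spad_min, spad_max]`.
#' @export
sample_spad <- function(group, n, config = synth_config(), seed = config$seed) {
  if (n < 1) abort("`n` must be >= 1.")
  with_seed(seed, sample_spad_impl(group, n, config))
}

sample_spad_impl <- function(group, n, config) {
  gp <- config$group_params
  row <- gp[gp$group == group, ]
  if (nrow(row) != 1) {
    abort(paste0("Unknown treatment group \"", group, "\"; expected one of ",
                 paste0('"', gp$group, '"', collapse = ", "), "."))
  }
  if (row$spad_sd == 0) return(rep(row$spad_mean, n))
  out <- numeric(0)
  while (length(out) < n) {
    x <- rnorm(max(n, 32), row$spad_mean, row$spad_sd)
    out <- c(out, x[x >= row$spad_min & x <= row$spad_max])
  }
  out[seq_len(n)]
}

# Noise-free reflectance profile for one SPAD value on the config grid.
# Plateau + logistic red edge + Gaussian green peak - saturating chlorophyll
# wells - fixed water dips; clipped to [0, 1.2].
spectrum_profile <- function(spad, config, wl = config_grid(config)) {
  if (spad < 0) abort("`spad` must be >= 0.")
  edge_c <- config$red_edge_base + config$red_edge_shift_per_spad * spad
  well <- function(d_max) d_max * spad / (spad + config$well_k)
  r <- config$vis_base +
    (config$nir_plateau - config$vis_base) *
      plogis((wl - edge_c) / config$red_edge_scale) +
    config$green_peak_max * config$green_peak_k /
      (config$green_peak_k + spad) * exp(-(wl - 550)^2 / (2 * 20^2)) -
    well(config$well_depth_blue) * exp(-(wl - 450)^2 / (2 * 30^2)) -
    well(config$well_depth_red) * exp(-(wl - 680)^2 / (2 * 25^2)) -
    0.03 * exp(-(wl - 970)^2 / (2 * 20^2)) -
    0.05 * exp(-(wl - 1200)^2 / (2 * 25^2))
  pmin(pmax(r, 0), 1.2)
}

#' Generate one synthetic canopy spectrum
#'
#' Builds the noise-free reflectance profile for a SPAD value and adds
#' Gaussian channel noise (`config$noise_sd`). Burr spikes are not added here;
#' see [add_burr_noise()] and [generate_dataset()].
#'
#' @inheritParams sample_spad
#' @param spad SPAD value (>= 0).
#' @param sample_id,group Metadata stored with the spectrum.
#' @return A one-row spectra table (see [spectra-table]).
#' @export
generate_spectrum <- function(spad, config = synth_config(), seed = config$seed,
                              sample_id = "s1", group = NA_character_) {
  wl <- config_grid(config)
  r <- spectrum_profile(spad, config, wl)
  if (config$noise_sd > 0) {
    r <- with_seed(seed, r + rnorm(length(wl), 0, config$noise_sd))
    r <- pmin(pmax(r, 0), 1.2)
  }
  out <- tibble::tibble(sample_id = sample_id, group = group, spad = spad)
  out[format_wavelength(wl)] <- as.list(r)
  out
}

#' Generate a full synthetic dataset
#'
#' Draws `n_per_group` SPAD values per treatment group (truncated normal) and
#' one spectrum per sample on the shared wavelength grid, with Gaussian noise
#' and, when `burr_rate > 0`, burr spikes. Bit-reproducible from
#' `config$seed`.
#'
#' @param config A [synth_config()].
#' @return A spectra table with `n_per_group * nrow(group_params)` rows.
#' @examples
#' set <- generate_dataset(synth_config(n_per_group = 5))
#' dplyr::count(set, group)
#' @export
generate_dataset <- function(config = synth_config()) {
  validate_config(config)
  wl <- config_grid(config)
  with_seed(config$seed, {
    rows <- purrr::map(config$group_params$group, function(g) {
      spad <- sample_spad_impl(g, config$n_per_group, config)
      refl <- vapply(spad, spectrum_profile, numeric(length(wl)),
                     config = config, wl = wl)
      refl <- t(refl)
      if (config$noise_sd > 0) {
        refl <- refl + matrix(rnorm(length(refl), 0, config$noise_sd),
                              nrow(refl))
      }
      if (config$burr_rate > 0) {
        refl <- refl + burr_matrix(dim(refl), config$burr_rate,
                                   config$burr_amplitude)
      }
      refl <- pmin(pmax(refl, 0), 1.2)
      meta <- tibble::tibble(
        sample_id = sprintf("%s_%02d", g, seq_along(spad)),
        group = g, spad = spad
      )
      set_spectra_matrix(meta, refl, wl)
    })
    dplyr::bind_rows(rows)
  })
}

burr_matrix <- function(dim, rate, amplitude) {
  hit <- matrix(rbinom(prod(dim), 1, rate), dim[1])
  sign <- matrix(sample(c(-1, 1), prod(dim), replace = TRUE), dim[1])
  hit * sign * amplitude
}

#' Add burr (spike) noise to spectra
#'
#' Each channel of each sample independently receives a spike of
#' `+/- amplitude` with probability `rate` (sign equiprobable) — the isolated
#' single-channel artifacts field spectroradiometer traces often carry.
#'
#' @param data A spectra table.
#' @param rate Per-channel spike probability in \[0, 1\].
#' @param amplitude Spike magnitude (reflectance units).
#' @param seed Integer seed.
#' @return A spectra table of the same shape.
#' @export
add_burr_noise <- function(data, rate, amplitude, seed = 1L) {
  check_spectra(data)
  if (rate < 0 || rate > 1) abort("`rate` must lie in [0, 1].")
  if (rate == 0) return(data)
  m <- spectra_matrix(data)
  m <- m + with_seed(seed, burr_matrix(dim(m), rate, amplitude))
  set_spectra_matrix(data, m)
}
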