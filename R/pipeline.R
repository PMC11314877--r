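#' Train/validation split
#'
#' Random assignment of samples to a training and a validation set, by
#' default stratified by treatment group so every group contributes
#' proportionally.
#'
#' @param data A spectra table.
#' @param ratio Training fraction in (0, 1); the default 2/3 gives the 2:1
#'   calibration:validation split used throughout the package.
#' @param seed Integer seed; the split is deterministic given the seed.
#' @param stratify Stratify by `group`? Each stratum must have >= 3 samples.
#' @return A tibble with `sample_id`, `group`, `subset`
#'   (`"train"`/`"validation"`); attributes `ratio` and `seed`.
#' @export
split_train_validation <- function(data, ratio = 2 / 3, seed = 1L,
                                   stratify = TRUE) {
  if (ratio <= 0 || ratio >= 1) abort("`ratio` must lie strictly in (0, 1).")
  meta <- tibble::tibble(
    sample_id = data$sample_id,
    group = if ("group" %in% names(data)) data$group else "all"
  )
  strata <- if (stratify) split(seq_len(nrow(meta)), meta$group) else
    list(all = seq_len(nrow(meta)))
  out <- with_seed(seed, {
    subset <- character(nrow(meta))
    for (idx in strata) {
      if (stratify && length(idx) < 3) {
        abort("Each stratum needs >= 3 samples for a stratified split.")
      }
      n_tr <- round(ratio * length(idx))
      tr <- sample(idx, n_tr)
      subset[idx] <- "validation"
      subset[tr] <- "train"
    }
    subset
  })
  res <- dplyr::mutate(meta, subset = out)
  attr(res, "ratio") <- ratio
  attr(res, "seed") <- as.integer(seed)
  res
}

#' Descriptive SPAD statistics
#'
#' Minimum, maximum, mean and standard deviation (denominator n - 1) of the
#' measured SPAD values, per treatment group or pooled.
#'
#' @param data A spectra table with a `spad` column.
#' @param by_group Summarize per group?
#' @return A tibble of (`group`,) `n`, `min`, `max`, `mean`, `sd`.
#' @export
spad_summary <- function(data, by_group = TRUE) {
  if (!"spad" %in% names(data)) abort("`data` has no `spad` column.")
  grouped <- if (by_group && "group" %in% names(data)) {
    dplyr::group_by(data, .data$group)
  } else {
    data
  }
  dplyr::summarise(
    grouped,
    n = dplyr::n(),
    min = min(.data$spad),
    max = max(.data$spad),
    mean = mean(.data$spad),
    sd = sd(.data$spad),
    .groups = "drop"
  )
}

#' Spectral features: green peak, red valley, red edge
#'
#' Extracts, per sample, the classical chlorophyll-sensitive landmarks of a
#' vegetation reflectance curve: the green peak (reflectance maximum in
#' 500-600 nm), the red valley (minimum in 640-700 nm), and the red-edge
#' position (wavelength of the largest first difference in 680-760 nm, taken
#' at the midpoint of the steepest interval). Ties resolve to the lowest
#' wavelength.
#'
#' @param data A spectra table whose grid covers 500-760 nm.
#' @return A tibble with one row per sample: `sample_id`, `group`, `spad`,
#'   `green_peak_position`, `green_peak_height`, `red_valley_position`,
#'   `red_valley_height`, `red_edge_position` (positions in nm).
#' @export
spectral_features <- function(data) {
  check_spectra(data)
  wl <- spectra_wavelengths(data)
  if (min(wl) > 500 || max(wl) < 760) {
    abort("Wavelength grid must cover 500-760 nm for feature extraction.")
  }
  m <- spectra_matrix(data)
  gp <- wl >= 500 & wl <= 600
  rv <- wl >= 640 & wl <= 700
  mid <- (wl[-length(wl)] + wl[-1]) / 2
  re <- mid >= 680 & mid <= 760

  feat <- function(r) {
    d <- diff(r)
    i_gp <- which(gp)[which.max(r[gp])]
    i_rv <- which(rv)[which.min(r[rv])]
    i_re <- which(re)[which.max(d[re])]
    c(wl[i_gp], r[i_gp], wl[i_rv], r[i_rv], mid[i_re])
  }
  f <- t(apply(m, 1, feat))
  out <- tibble::tibble(
    sample_id = data$sample_id,
    group = if ("group" %in% names(data)) data$group else NA_character_,
    spad = if ("spad" %in% names(data)) data$spad else NA_real_,
    green_peak_position = f[, 1],
    green_peak_height = f[, 2],
    red_valley_position = f[, 3],
    red_valley_height = f[, 4],
    red_edge_position = f[, 5]
  )
  out
}

#' Per-order, per-model accuracy sweep
#'
#' The package's core experiment: for every treatment group and every
#' differentiation order, transform the group's spectra, select
#' SPAD-sensitive bands with SPA on the training split, fit the requested
#' calibration models on those bands, and score both splits. One model is
#' fitted per treatment group, mirroring per-stress-rate calibration.
#'
#' @param data A preprocessed spectra table.
#' @param split A [split_train_validation()] result covering `data`.
#' @param orders Differentiation orders; default 0 to 2 in steps of 0.1
#'   (21 transforms). Labels are rounded to one decimal.
#' @param models Any of `"mlr"`, `"plsr"`.
#' @param n_bands Bands selected by SPA at every order.
#' @param step_h Grid spacing passed to [fractional_derivative()].
#' @param starts Candidate SPA chain seeds (see [spa_select()]).
#' @param mask_edges Exclude the derivative's edge-affected leading channels
#'   from band selection? Off by default.
#' @param max_plsr_components Cap for PLSR component selection.
#' @return A tibble of class `spad_sweep`: one row per (group, order, model,
#'   subset) with `r2`, `rmse`, `n`, `n_components`, `wavelengths` (list
#'   column of selected bands) and `predictions` (list column;
#'   observed/predicted pairs, validation rows only).
#' @export
run_order_sweep <- function(data, split, orders = seq(0, 2, by = 0.1),
                            models = c("mlr", "plsr"), n_bands = 10,
                            step_h = NULL, starts = NULL, mask_edges = FALSE,
                            max_plsr_components = 10) {
  check_spectra(data)
  models <- match.arg(models, c("mlr", "plsr"), several.ok = TRUE)
  if (length(models) == 0) abort("`models` must name at least one model.")
  groups <- unique(data$group)
  labels <- round(orders, 1)

  rows <- purrr::map(groups, function(g) {
    gdat <- data[data$group == g, , drop = FALSE]
    purrr::map2(orders, labels, function(a, lab) {
      dset <- fractional_derivative(gdat, a, step_h)
      parts <- split_spectra(dset, split)
      sel <- spa_select(parts$X_train, parts$y_train,
                        parts$X_val, parts$y_val,
                        fixed_n = n_bands, n_max = n_bands, starts = starts,
                        exclude = if (mask_edges) attr(dset, "edge_channels"))
      idx <- sel$selected_indices[[1]]
      wls <- sel$selected_wavelengths[[1]]
      Xtr <- parts$X_train[, idx, drop = FALSE]
      Xva <- parts$X_val[, idx, drop = FALSE]
      purrr::map(models, function(kind) {
        if (kind == "mlr") {
          fit <- mlr_fit(Xtr, parts$y_train)
          ncomp <- NA_integer_
        } else {
          pick <- select_plsr_components(Xtr, parts$y_train, Xva, parts$y_val,
                                         max_components = max_plsr_components)
          fit <- pick$model
          ncomp <- pick$n_components
        }
        pred_va <- predict(fit, Xva)
        sc_tr <- fit$train_score
        sc_va <- score(parts$y_val, pred_va)
        tibble::tibble(
          group = g, order = lab, model = kind,
          subset = c("train", "validation"),
          r2 = c(sc_tr$r2, sc_va$r2),
          rmse = c(sc_tr$rmse, sc_va$rmse),
          n = c(sc_tr$n, sc_va$n),
          n_components = ncomp,
          wavelengths = list(wls, wls),
          predictions = list(NULL, tibble::tibble(
            sample_id = parts$id_val,
            observed = parts$y_val,
            predicted = pred_va
          ))
        )
      }) |> dplyr::bind_rows()
    }) |> dplyr::bind_rows()
  }) |> dplyr::bind_rows()

  class(rows) <- c("spad_sweep", class(rows))
  attr(rows, "n_bands") <- n_bands
  rows
}

#' Optimal differentiation order per group and model
#'
#' Picks, for each (group, model), the order maximizing validation R2; ties
#' resolve to the lower order. The result is invariant to the row order of
#' the sweep.
#'
#' @param sweep A [run_order_sweep()] result.
#' @return A tibble of `group`, `model`, `order`, `r2`, `rmse`.
#' @export
select_optimal_order <- function(sweep) {
  if (nrow(sweep) == 0) abort("`sweep` is empty.")
  sweep |>
    dplyr::filter(.data$subset == "validation") |>
    dplyr::group_by(.data$group, .data$model) |>
    dplyr::arrange(dplyr::desc(.data$r2), .data$order, .by_group = TRUE) |>
    dplyr::slice_head(n = 1) |>
    dplyr::ungroup() |>
    dplyr::select("group", "model", "order", "r2", "rmse")
}

#' Accuracy change relative to the raw (order 0) spectra
#'
#' Percentage change of R2 and RMSE at each order relative to the same
#' group/model/subset at order 0:
#' 100 * (value - value_at_0) / value_at_0. A zero order-0 value yields `NA`.
#'
#' @param sweep A [run_order_sweep()] result containing order 0.
#' @return A tibble of `group`, `model`, `subset`, `order`, `r2`, `rmse`,
#'   `r2_pct_change`, `rmse_pct_change`.
#' @export
improvement_over_raw <- function(sweep) {
  base <- sweep |>
    dplyr::filter(.data$order == 0) |>
    dplyr::select("group", "model", "subset",
                  r2_0 = "r2", rmse_0 = "rmse")
  if (nrow(base) == 0) abort("`sweep` has no order-0 rows.")
  pct <- function(v, v0) ifelse(v0 == 0, NA_real_, 100 * (v - v0) / v0)
  sweep |>
    dplyr::select("group", "model", "subset", "order", "r2", "rmse") |>
    dplyr::left_join(base, by = c("group", "model", "subset")) |>
    dplyr::mutate(
      r2_pct_change = pct(.data$r2, .data$r2_0),
      rmse_pct_change = pct(.data$rmse, .data$rmse_0)
    ) |>
    dplyr::select(-"r2_0", -"rmse_0")
}

#' Run the full estimation pipeline on a dataset
#'
#' Convenience wrapper: preprocessing (QC, five-point smoothing, 400-1350 nm
#' crop), stratified 2:1 split, the per-order/per-model sweep, optimal-order
#' selection, improvement over the raw spectra, SPAD summary and spectral
#' features.
#'
#' @param data A spectra table; generated from `config` when omitted.
#' @param config A [synth_config()]; supplies the data (when `data` is
#'   missing) and the split seed.
#' @param split_seed Seed for the train/validation split.
#' @param ... Passed to [run_order_sweep()].
#' @return A list of class `spad_run`: `data` (preprocessed), `qc_report`,
#'   `split`, `sweep`, `optimal`, `improvement`, `summary`, `features`.
#' @examples
#' \donttest{
#' run <- run_spad_pipeline(config = synth_config(n_per_group = 12, seed = 7),
#'                          orders = c(0, 0.5, 1))
#' run$optimal
#' }
#' @export
run_spad_pipeline <- function(data = NULL, config = synth_config(),
                              split_seed = config$seed, ...) {
  if (is.null(data)) data <- generate_dataset(config)
  prep <- preprocess_spectra(data)
  split <- split_train_validation(prep$spectra, seed = split_seed)
  sweep <- run_order_sweep(prep$spectra, split, ...)
  structure(list(
    data = prep$spectra,
    qc_report = prep$report,
    split = split,
    sweep = sweep,
    optimal = select_optimal_order(sweep),
    improvement = improvement_over_raw(sweep),
    summary = spad_summary(data),
    features = spectral_features(data)
  ), class = "spad_run")
}

#' @export
print.spad_run <- function(x, ...) {
  cat("<spad_run>\n")
  cat(sprintf("  %d samples, %d groups, %d sweep rows\n",
              nrow(x$data), length(unique(x$data$group)), nrow(x$sweep)))
  print(x$optimal)
  invisible(x)
}

#' Write a pipeline run to disk
#'
#' Persists the sweep, the optimal-order table, the improvement table, the
#' selected-band map, per-group feature summaries, measured-vs-predicted
#' scatter data for the optimal models, and a JSON run manifest. Outputs are
#' deterministic (no timestamps), so re-running an identical seeded pipeline
#' reproduces them bit-identically.
#'
#' @param run A [run_spad_pipeline()] result.
#' @param out_dir Output directory (created if absent).
#' @param config Optional [synth_config()] echoed into the manifest.
#' @return Invisibly, the named character vector of files written.
#' @export
write_report <- function(run, out_dir, config = NULL) {
  if (!inherits(run, "spad_run")) abort("`run` must be a `spad_run`.")
  if (nrow(run$sweep) == 0) abort("Empty sweep; nothing to report.")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) abort(paste0("Cannot create `", out_dir, "`."))

  flat_sweep <- run$sweep |>
    dplyr::mutate(wavelengths = purrr::map_chr(
      .data$wavelengths, ~ paste(.x, collapse = ";"))) |>
    dplyr::select(-"predictions")

  bands <- run$sweep |>
    dplyr::filter(.data$subset == "validation", .data$model == .data$model[1]) |>
    dplyr::distinct(.data$group, .data$order, .keep_all = TRUE) |>
    dplyr::select("group", "order", "wavelengths") |>
    tidyr::unnest_longer("wavelengths", values_to = "wavelength_nm") |>
    dplyr::group_by(.data$group, .data$order) |>
    dplyr::mutate(rank = dplyr::row_number()) |>
    dplyr::ungroup()

  scatter <- run$optimal |>
    dplyr::inner_join(run$sweep |> dplyr::filter(.data$subset == "validation"),
                      by = c("group", "model", "order"),
                      suffix = c("", ".sweep")) |>
    dplyr::select("group", "model", "order", "predictions") |>
    tidyr::unnest("predictions")

  feature_summary <- run$features |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(dplyr::across(dplyr::where(is.numeric), mean),
                     .groups = "drop")

  files <- c(
    sweep = file.path(out_dir, "sweep.csv"),
    optimal = file.path(out_dir, "optimal_orders.csv"),
    improvement = file.path(out_dir, "improvement.csv"),
    bands = file.path(out_dir, "selected_bands.csv"),
    features = file.path(out_dir, "feature_summary.csv"),
    spad = file.path(out_dir, "spad_summary.csv"),
    scatter = file.path(out_dir, "scatter.csv"),
    manifest = file.path(out_dir, "manifest.json")
  )
  readr::write_csv(flat_sweep, files[["sweep"]])
  readr::write_csv(run$optimal, files[["optimal"]])
  readr::write_csv(run$improvement, files[["improvement"]])
  readr::write_csv(bands, files[["bands"]])
  readr::write_csv(feature_summary, files[["features"]])
  readr::write_csv(run$summary, files[["spad"]])
  readr::write_csv(scatter, files[["scatter"]])
  manifest <- list(
    package = "spadspec",
    version = as.character(packageVersion("spadspec")),
    split_seed = attr(run$split, "seed"),
    split_ratio = attr(run$split, "ratio"),
    n_samples = nrow(run$data),
    groups = sort(unique(run$data$group)),
    files = basename(unname(files)),
    config = if (!is.null(config)) unclass(config)
  )
  jsonlite::write_json(manifest, files[["manifest"]], auto_unbox = TRUE,
                       digits = NA, dataframe = "columns", pretty = TRUE)
  invisible(files)
}
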