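#' Plot reflectance curves
#'
#' Mean reflectance per treatment group (default) or individual sample
#' curves, against wavelength.
#'
#' @param data A spectra table.
#' @param by `"group"` for group means, `"sample"` for individual curves.
#' @return A ggplot.
#' @export
plot_spectra <- function(data, by = c("group", "sample")) {
  by <- match.arg(by)
  long <- spectra_longer(data)
  if (by == "group") {
    long <- long |>
      dplyr::group_by(.data$group, .data$wavelength) |>
      dplyr::summarise(reflectance = mean(.data$reflectance),
                       .groups = "drop")
    ggplot2::ggplot(long, ggplot2::aes(.data$wavelength, .data$reflectance,
                                       colour = .data$group)) +
      ggplot2::geom_line() +
      ggplot2::labs(x = "Wavelength (nm)", y = "Reflectance",
                    colour = "Treatment")
  } else {
    ggplot2::ggplot(long, ggplot2::aes(.data$wavelength, .data$reflectance,
                                       group = .data$sample_id,
                                       colour = .data$group)) +
      ggplot2::geom_line(alpha = 0.4) +
      ggplot2::labs(x = "Wavelength (nm)", y = "Reflectance",
                    colour = "Treatment")
  }
}

#' Plot the per-order accuracy sweep
#'
#' R2 (or RMSE) against differentiation order, one line per model, one panel
#' per treatment group.
#'
#' @param sweep A [run_order_sweep()] result.
#' @param metric `"r2"` or `"rmse"`.
#' @param subset `"validation"` or `"train"`.
#' @return A ggplot.
#' @export
plot_sweep <- function(sweep, metric = c("r2", "rmse"),
                       subset = c("validation", "train")) {
  metric <- match.arg(metric)
  subset <- match.arg(subset)
  d <- dplyr::filter(sweep, .data$subset == !!subset)
  ggplot2::ggplot(d, ggplot2::aes(.data$order, .data[[metric]],
                                  colour = .data$model)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::facet_wrap(ggplot2::vars(.data$group)) +
    ggplot2::labs(x = "Differentiation order",
                  y = if (metric == "r2") expression(R^2) else "RMSE (SPAD)",
                  colour = "Model")
}

#' @rdname plot_sweep
#' @param object,... `autoplot` method arguments (passed to [plot_sweep()]).
#' @importFrom ggplot2 autoplot
#' @export
autoplot.spad_sweep <- function(object, ...) plot_sweep(object, ...)

#' Plot SPA-selected wavelengths across orders
#'
#' The per-order map of selected bands: wavelength against differentiation
#' order, per treatment group.
#'
#' @param bands The band table written by [write_report()] or built from a
#'   sweep: columns `group`, `order`, `wavelength_nm`.
#' @return A ggplot.
#' @export
plot_selected_bands <- function(bands) {
  ggplot2::ggplot(bands, ggplot2::aes(.data$wavelength_nm, .data$order)) +
    ggplot2::geom_point(shape = 15, colour = "firebrick", size = 1.5) +
    ggplot2::facet_wrap(ggplot2::vars(.data$group)) +
    ggplot2::labs(x = "Wavelength (nm)", y = "Differentiation order")
}

#' Measured vs predicted SPAD for the optimal models
#'
#' Scatter of validation-set predictions against measurements with the 1:1
#' line, per treatment group.
#'
#' @param run A [run_spad_pipeline()] result.
#' @param model Model kind to display.
#' @return A ggplot.
#' @export
plot_predictions <- function(run, model = "mlr") {
  scatter <- run$optimal |>
    dplyr::filter(.data$model == !!model) |>
    dplyr::inner_join(
      dplyr::filter(run$sweep, .data$subset == "validation",
                    .data$model == !!model),
      by = c("group", "model", "order"), suffix = c("", ".sweep")
    ) |>
    dplyr::select("group", "order", "predictions") |>
    tidyr::unnest("predictions")
  ggplot2::ggplot(scatter, ggplot2::aes(.data$observed, .data$predicted)) +
    ggplot2::geom_abline(linetype = "dashed") +
    ggplot2::geom_point(colour = "steelblue") +
    ggplot2::facet_wrap(ggplot2::vars(.data$group), scales = "free") +
    ggplot2::labs(x = "Measured SPAD", y = "Predicted SPAD")
}
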