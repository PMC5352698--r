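# ggplot2 displays for the package's result types.

#' Stick plot of an in silico spectrum
#'
#' @param object A one-row record tibble (from [generate_spectrum()]).
#' @param label_min Label peaks with intensity at or above this value.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.spectrum_record <- function(object, label_min = 300, ...) {
  plot_spectrum(object, label_min = label_min)
}

#' @rdname autoplot.spectrum_record
#' @param record A one-row record tibble.
#' @export
plot_spectrum <- function(record, label_min = 300) {
  stopifnot(nrow(record) == 1)
  pk <- record$peaks[[1]]
  lab <- pk[pk$intensity >= label_min, ]
  ggplot2::ggplot(pk, ggplot2::aes(x = .data$mz, y = .data$intensity)) +
    ggplot2::geom_segment(ggplot2::aes(xend = .data$mz, yend = 0)) +
    ggplot2::geom_text(data = lab,
                       ggplot2::aes(label = sprintf("%.4f", .data$mz)),
                       angle = 90, hjust = -0.1, size = 2.8) +
    ggplot2::scale_y_continuous(limits = c(0, 1100), expand = c(0, 0)) +
    ggplot2::labs(title = paste0(record$name, "  ", record$adduct),
                  x = "m/z", y = "relative intensity (0-999)") +
    ggplot2::theme_minimal()
}

#' AIC trace of a forward stepwise fit
#'
#' @param object An `rt_stepwise` object.
#' @param ... Unused.
#' @return A ggplot of AIC against selection step.
#' @export
autoplot.rt_stepwise <- function(object, ...) {
  tr <- object$aic_trace
  ggplot2::ggplot(tr, ggplot2::aes(x = .data$step, y = .data$aic)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_text(ggplot2::aes(label = .data$added), na.rm = TRUE,
                       vjust = -0.8, size = 3) +
    ggplot2::labs(x = "forward step", y = "AIC") +
    ggplot2::theme_minimal()
}

#' Predicted-vs-observed RT plot
#'
#' @param descriptors Descriptor table.
#' @param rt Observed retention times (minutes).
#' @param model An `rt_model`.
#' @return A ggplot with the identity line.
#' @export
plot_rt_fit <- function(descriptors, rt, model = rt_model_published()) {
  pred <- predict_rt(descriptors, model)
  df <- tibble::tibble(observed = rt, predicted = pred$rt_pred,
                       segment = pred$rt_segment)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$observed, y = .data$predicted,
                                   colour = .data$segment)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(x = "observed RT (min)", y = "predicted RT (min)") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
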