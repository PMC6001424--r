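#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a max-normalized histogram
#'
#' @param object A [compute_histogram()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ivim_histogram <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$bin_mid, y = .data$norm_count)) +
    ggplot2::geom_col(width = object$bin_end[1] - object$bin_start[1],
                      fill = "grey35") +
    ggplot2::labs(x = "parameter value", y = "normalized frequency") +
    ggplot2::theme_minimal()
}

#' Plot an ROC curve with its Youden-optimal operating point
#'
#' @param object A [roc_youden()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.roc_result <- function(object, ...) {
  curve <- dplyr::arrange(object$curve, 1 - .data$specificity,
                          .data$sensitivity)
  best <- which.min(abs(object$curve$cutoff - object$cutoff))
  ggplot2::ggplot(curve, ggplot2::aes(x = 1 - .data$specificity,
                                      y = .data$sensitivity)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey60") +
    ggplot2::geom_step(colour = "steelblue") +
    ggplot2::annotate("point", x = 1 - object$curve$specificity[best],
                      y = object$curve$sensitivity[best], colour = "firebrick") +
    ggplot2::labs(x = "1 - specificity", y = "sensitivity",
                  title = sprintf("AUC = %.3f [%.3f, %.3f]", object$auc,
                                  object$ci_low, object$ci_high)) +
    ggplot2::coord_equal() +
    ggplot2::theme_minimal()
}

#' Plot a group-average histogram with its between-case spread
#'
#' @param avg An [average_group_histogram()] result.
#' @param title Optional plot title (e.g. the group label).
#' @return A ggplot with the mean curve and a +/- 1 SD ribbon.
#' @export
plot_group_histogram <- function(avg, title = NULL) {
  ggplot2::ggplot(avg, ggplot2::aes(x = .data$bin_mid, y = .data$mean)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = pmax(.data$mean - .data$sd, 0),
                                      ymax = .data$mean + .data$sd),
                         fill = "grey80") +
    ggplot2::geom_line(colour = "black") +
    ggplot2::labs(x = "parameter value", y = "normalized frequency",
                  title = title) +
    ggplot2::theme_minimal()
}

#' Plot one axial slice of a parameter map
#'
#' @param maps A [parameter_maps()] object.
#' @param parameter One of `"ADC"`, `"D"`, `"Dstar"`, `"f"`.
#' @param slice Slice index along the third axis; defaults to the middle
#'   in-mask slice.
#' @return A ggplot raster in display units.
#' @export
plot_map_slice <- function(maps, parameter = "f", slice = NULL) {
  stopifnot(inherits(maps, "parameter_maps"))
  arr <- switch(parameter, ADC = maps$adc, D = maps$d, Dstar = maps$dstar,
                f = maps$f,
                stop("unknown parameter: ", parameter, call. = FALSE))
  if (is.null(slice)) {
    filled <- which(apply(!is.na(arr), 3, any))
    slice <- if (length(filled)) filled[ceiling(length(filled) / 2)] else
      ceiling(dim(arr)[3] / 2)
  }
  sl <- arr[, , slice] * display_scale(parameter)
  df <- expand.grid(x = seq_len(nrow(sl)), y = seq_len(ncol(sl)))
  df$value <- as.vector(sl)
  unit <- if (parameter == "f") "f (%)" else
    sprintf("%s (1e-6 mm^2/s)", parameter)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(na.value = "black", name = unit) +
    ggplot2::coord_equal() +
    ggplot2::labs(title = sprintf("%s, slice %d", parameter, slice)) +
    ggplot2::theme_void()
}
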