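#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Bland–Altman plot
#'
#' Scatter of per-pair differences against pair means with the mean
#' difference (solid), its confidence band, and the limits of agreement
#' (dashed).
#'
#' @param object a `paft_bland_altman`.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.paft_bland_altman <- function(object, ...) {
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$mean, y = .data$diff)) +
    ggplot2::geom_hline(yintercept = 0, colour = "steelblue") +
    ggplot2::geom_hline(yintercept = object$mean_diff, linewidth = 0.7) +
    ggplot2::annotate("rect", xmin = -Inf, xmax = Inf,
                      ymin = object$mean_diff_ci[1], ymax = object$mean_diff_ci[2],
                      alpha = 0.15) +
    ggplot2::geom_hline(yintercept = c(object$loa_low, object$loa_high),
                        linetype = "dashed") +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(x = "Mean of paired measurements",
                  y = "Difference (native - corrected arterial)",
                  title = sprintf("Bland-Altman: mean difference %.3g [%.3g, %.3g]",
                                  object$mean_diff, object$mean_diff_ci[1],
                                  object$mean_diff_ci[2])) +
    ggplot2::theme_minimal()
}

#' Passing–Bablok plot
#'
#' Scatter of the two methods with the identity line (dotted) and the fitted
#' Passing–Bablok line (solid).
#'
#' @param object a `paft_passing_bablok`.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.paft_passing_bablok <- function(object, ...) {
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$a, y = .data$b)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted") +
    ggplot2::geom_abline(slope = object$slope, intercept = object$intercept,
                         linewidth = 0.7, colour = "firebrick") +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(x = "Method 1", y = "Method 2",
                  title = sprintf("Passing-Bablok: slope %.3f [%.3f, %.3f]",
                                  object$slope, object$slope_ci[1],
                                  object$slope_ci[2])) +
    ggplot2::theme_minimal()
}

#' Periaortic HU histogram of a paired study
#'
#' Histogram of HU values inside the periaortic ROI for both phases, with the
#' upper fat threshold marked; the native lumen mode sits near 40 HU, the
#' arterial one near the contrast attenuation, while the sub-threshold fat
#' mode barely moves.
#'
#' @param pair a `ct_study_pair`.
#' @param rois an `aorto_periaortic_roi`.
#' @param hu_window fat window to mark (default `c(-195, -45)`).
#' @return A ggplot object.
#' @export
plot_periaortic_histogram <- function(pair, rois, hu_window = c(-195, -45)) {
  df <- dplyr::bind_rows(
    tibble::tibble(phase = "native", hu = pair$native$voxels[rois$periaortic_mask]),
    tibble::tibble(phase = "arterial", hu = pair$arterial$voxels[rois$periaortic_mask])
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$hu, fill = .data$phase)) +
    ggplot2::geom_histogram(binwidth = 10, alpha = 0.6, position = "identity") +
    ggplot2::geom_vline(xintercept = hu_window[2], colour = "red") +
    ggplot2::labs(x = "HU", y = "Voxels", fill = NULL) +
    ggplot2::theme_minimal()
}
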