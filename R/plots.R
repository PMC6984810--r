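#' Plot a power surface
#'
#' Heat map of statistical power over the sample-size by effect-size grid,
#' with the conventional 80% contour of interest highlighted by the fill
#' scale midpoint.
#'
#' @param object A [power_grid()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.power_grid <- function(object, ...) {
  ggplot2::ggplot(object$grid,
                  ggplot2::aes(x = factor(.data$n), y = factor(.data$effect),
                               fill = .data$power)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "white", mid = "steelblue",
                                  high = "navy", midpoint = 0.8,
                                  limits = c(0, 1)) +
    ggplot2::labs(x = "replicates per condition",
                  y = expression(Delta ~ log[10] ~ "Hz"),
                  fill = "power") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot array firing-rate distributions
#'
#' Histogram of array MFRs on the linear and log10 scale side by side; the
#' linear scale is heavily right-skewed while the log scale is
#' approximately normal, which is why log10 Hz is the recommended metric.
#'
#' @param activity Tibble from [array_activity()].
#' @return A ggplot.
#' @export
plot_mfr_distribution <- function(activity) {
  long <- dplyr::bind_rows(
    activity %>% mutate(scale = "MFR (Hz)", value = .data$mfr),
    activity %>% mutate(scale = "log10 MFR", value = .data$log_mfr))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$value)) +
    ggplot2::geom_histogram(bins = 30, fill = "steelblue",
                            colour = "white") +
    ggplot2::facet_wrap(~scale, scales = "free") +
    ggplot2::labs(x = NULL, y = "arrays") +
    ggplot2::theme_minimal()
}

#' Plot a sorted electrode's PC embedding
#'
#' Scatter of the log-PCA embedding coloured by cluster, with cluster modes
#' marked.
#'
#' @param embedding Matrix from [embed_features()].
#' @param labels Integer cluster labels from [mean_shift()].
#' @param modes Mode matrix from [mean_shift()].
#' @return A ggplot.
#' @export
plot_embedding <- function(embedding, labels, modes = NULL) {
  d <- tibble(PC1 = embedding[, 1], PC2 = embedding[, 2],
              cluster = factor(labels))
  p <- ggplot2::ggplot(d, ggplot2::aes(.data$PC1, .data$PC2,
                                       colour = .data$cluster)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::theme_minimal()
  if (!is.null(modes)) {
    m <- tibble(PC1 = modes[, 1], PC2 = modes[, 2])
    p <- p + ggplot2::geom_point(data = m, colour = "black", shape = 3,
                                 size = 3, stroke = 1.2)
  }
  p
}

#' Plot a duration-correlation curve
#'
#' Day-to-day Pearson correlation of array log rates against accumulated
#' recording length, with the fitted rho ~ ln(minutes) curve overlaid.
#'
#' @param object A [duration_correlation_curve()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.correlation_curve <- function(object, ...) {
  cv <- object$curve
  fitline <- tibble(minutes = cv$minutes,
                    rho = object$log_fit["intercept"] +
                      object$log_fit["slope"] * log(cv$minutes))
  ggplot2::ggplot(cv, ggplot2::aes(.data$minutes, .data$rho)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = fitline, colour = "firebrick") +
    ggplot2::labs(x = "recording length (min)",
                  y = expression(rho)) +
    ggplot2::theme_minimal()
}
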