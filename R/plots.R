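#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a step's force-time curve
#'
#' @param object A [step_signal()].
#' @param ... Unused.
#' @return A ggplot: force (N) against time (s), stance shaded.
#' @export
autoplot.step_signal <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$force)) +
    ggplot2::annotate("rect", xmin = 0,
                      xmax = object$stance_len * object$dt,
                      ymin = -Inf, ymax = Inf, alpha = 0.08) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (s)", y = "plantar force (N)",
                  title = "Spatially integrated plantar force") +
    ggplot2::theme_minimal()
}

#' Plot DMD eigenvalues in the complex plane
#'
#' @param object A `dmd_model`.
#' @param ... Unused.
#' @return A ggplot of the eigenvalues with the unit circle; zero-padded
#'   decaying steps keep all eigenvalues inside it.
#' @export
autoplot.dmd_model <- function(object, ...) {
  df <- tidy(object)
  circ <- tibble::tibble(theta = seq(0, 2 * pi, length.out = 200))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$eig_re, y = .data$eig_im)) +
    ggplot2::geom_path(data = circ,
                       ggplot2::aes(x = cos(.data$theta),
                                    y = sin(.data$theta)),
                       linetype = "dashed", colour = "grey50") +
    ggplot2::geom_point(ggplot2::aes(size = .data$energy), alpha = 0.8) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "Re", y = "Im", size = "|v b|",
                  title = "DMD eigenvalues") +
    ggplot2::theme_minimal()
}

#' Feature-space scatter of mode triplets
#'
#' Initial condition against frequency, one point per step and mode,
#' coloured by mode rank: well-separated per-mode clusters are what the
#' centroid baselines summarize.
#'
#' @param features Long feature tibble (from [featurize_steps()]).
#' @return A ggplot.
#' @export
plot_feature_modes <- function(features) {
  ggplot2::ggplot(features,
                  ggplot2::aes(x = .data$freq, y = .data$s0,
                               colour = factor(.data$mode_rank))) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::labs(x = "frequency (Hz)", y = "initial condition |s0| (N)",
                  colour = "mode",
                  title = "Mode feature triplets across steps") +
    ggplot2::theme_minimal()
}

#' Confusion heatmap of an identification evaluation
#'
#' @param object A `gait_eval` report.
#' @param ... Unused.
#' @return A ggplot faceted by stratum.
#' @export
autoplot.gait_eval <- function(object, ...) {
  df <- object$confusion
  strata <- intersect(c("foot", "speed"), names(df))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$predicted,
                                        y = .data$true,
                                        fill = .data$n)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(title = "Identification confusion counts") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90))
  if (length(strata) > 0) {
    p <- p + ggplot2::facet_wrap(strata)
  }
  p
}
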