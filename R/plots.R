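#' Violin/box plot of ratings by condition
#'
#' Mirrors the study's rating figures: per-condition distributions of a
#' trial-level variable, split by face (x axis) and control (fill).
#'
#' @param trials A trial tibble.
#' @param value Column name (string) to plot (default `"agency"`).
#' @return A ggplot object.
#' @export
plot_condition_ratings <- function(trials, value = "agency") {
  if (!value %in% names(trials)) stopf("column '%s' not in trial table", value)
  ggplot2::ggplot(trials, ggplot2::aes(
    x = .data$face, y = .data[[value]], fill = .data$control
  )) +
    ggplot2::geom_violin(alpha = 0.4, position = ggplot2::position_dodge(0.8)) +
    ggplot2::geom_boxplot(width = 0.15, outlier.size = 0.6,
                          position = ggplot2::position_dodge(0.8)) +
    ggplot2::labs(x = "face", y = value, fill = "control") +
    ggplot2::theme_minimal()
}

#' Plot motion channels over time
#'
#' @param object A [motion_channels][compute_channels] object.
#' @param ... Unused.
#' @return A ggplot object: per-channel magnitude time series, faceted.
#' @export
autoplot.motion_channels <- function(object, ...) {
  as_tibble(object) |>
    ggplot2::ggplot(ggplot2::aes(.data$time_s, .data$magnitude)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~channel, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "time (s)", y = "motion magnitude") +
    ggplot2::theme_minimal()
}

#' Plot fitted agency curves over the rating data
#'
#' @param object An [agency_fit][fit_curves] object.
#' @param ... Unused.
#' @return A ggplot object: per-mode ratings against consistency with the
#'   fitted four-parameter logistic curves overlaid.
#' @export
autoplot.agency_fit <- function(object, ...) {
  grid <- tidyr::expand_grid(consistency = seq(0, 1, length.out = 200),
                             mode = c("exploit", "explore"))
  grid$rating <- NA_real_
  for (m in c("exploit", "explore")) {
    f <- object$fits[[m]]
    if (f$converged) {
      e <- f$estimate
      sel <- grid$mode == m
      grid$rating[sel] <- e[["b"]] +
        e[["A"]] / (1 + exp(-e[["k"]] * (grid$consistency[sel] - e[["c0"]])))
    }
  }
  ggplot2::ggplot(object$data,
                  ggplot2::aes(.data$consistency, .data$rating, colour = .data$mode)) +
    ggplot2::geom_point(alpha = 0.25, size = 0.8) +
    ggplot2::geom_line(data = grid, linewidth = 0.9) +
    ggplot2::labs(x = "sensorimotor consistency", y = "agency rating",
                  colour = "mode") +
    ggplot2::theme_minimal()
}

#' Plot the peak sequence behind a diversity index
#'
#' @param object A [diversity_result][diversity_index] object.
#' @param ... Unused.
#' @return A ggplot object: peak times per channel; switches of the
#'   peak-bearing channel drive the index.
#' @export
autoplot.diversity_result <- function(object, ...) {
  if (!nrow(object$peaks)) {
    return(ggplot2::ggplot() + ggplot2::theme_void() +
             ggplot2::labs(title = "no peaks detected"))
  }
  ggplot2::ggplot(object$peaks,
                  ggplot2::aes(.data$time_s, .data$channel)) +
    ggplot2::geom_point(ggplot2::aes(size = .data$prominence), alpha = 0.8) +
    ggplot2::labs(
      x = "time (s)", y = NULL,
      title = sprintf("%d switches / %.0f s = %.2f per minute",
                      object$switch_count, object$duration_s, object$index)
    ) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
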