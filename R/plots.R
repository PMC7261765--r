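# Plotting: grayscale positional variance diagrams (inferred order down the
# y-axis, darker = higher posterior confidence) and per-group stage-proportion
# bar charts.

#' @export
autoplot.ebm_pvd <- function(object, title = NULL, ...) {
  df <- tidy(object)
  df$region <- factor(df$region, levels = rev(rownames(object)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$position, y = .data$region,
                                   fill = .data$probability)) +
    ggplot2::geom_tile(colour = "grey80", linewidth = 0.2) +
    ggplot2::scale_fill_gradient(low = "white", high = "black",
                                 limits = c(0, 1), name = "Posterior\nconfidence") +
    ggplot2::scale_x_continuous(breaks = seq_len(ncol(object)), expand = c(0, 0)) +
    ggplot2::labs(x = "Sequence position", y = NULL, title = title) +
    ggplot2::theme_minimal() +
    ggplot2::theme(panel.grid = ggplot2::element_blank())
}

#' Plot a positional variance diagram
#'
#' @param pvd An [positional_variance()] matrix.
#' @param title Optional plot title.
#' @return A ggplot object.
#' @export
plot_pvd <- function(pvd, title = NULL) {
  autoplot(pvd, title = title)
}

#' @export
autoplot.ebm_posterior <- function(object, ...) {
  autoplot(positional_variance(object), ...)
}

#' @export
autoplot.ebm_stage_proportions <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = factor(.data$stage), y = .data$proportion,
                               fill = .data$group)) +
    ggplot2::geom_col(position = ggplot2::position_dodge()) +
    ggplot2::scale_fill_manual(values = c(control = "grey65", patient = "grey20"),
                               name = NULL) +
    ggplot2::labs(x = "Biomarker stage", y = "Proportion of group") +
    ggplot2::theme_minimal()
}

#' Plot per-group stage proportions
#'
#' @param proportions An [stage_proportions()] result.
#' @return A ggplot object.
#' @export
plot_stage_proportions <- function(proportions) {
  autoplot(proportions)
}

#' @export
autoplot.ebm_mixture_fits <- function(object, ...) {
  grid <- tidy(object) |>
    dplyr::rowwise() |>
    dplyr::reframe(
      region = .data$region,
      x = seq(min(.data$mu_d - 4 * .data$sigma_d, .data$mu_h - 4 * .data$sigma_h),
              max(.data$mu_d + 4 * .data$sigma_d, .data$mu_h + 4 * .data$sigma_h),
              length.out = 200),
      healthy = .data$theta * dnorm(x, .data$mu_h, .data$sigma_h),
      diseased = (1 - .data$theta) * dnorm(x, .data$mu_d, .data$sigma_d)
    ) |>
    tidyr::pivot_longer(c("healthy", "diseased"),
                        names_to = "component", values_to = "density")
  ggplot2::ggplot(grid, ggplot2::aes(x = .data$x, y = .data$density,
                                     colour = .data$component)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~region, scales = "free") +
    ggplot2::labs(x = "Biomarker value", y = "Weighted density", colour = NULL) +
    ggplot2::theme_minimal()
}
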