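#' Plot diversity and adaptation trajectories
#'
#' Builds the two standard trajectory grids from a sweep: replicate-mean
#' Gini-Simpson diversity and mean variant payoff over time, one line per
#' learner type, panelled by payoff bias (rows) and population size or
#' neighbourhood sigma (columns). With `out_path` the figures are also
#' written to `<out_path>-diversity.png` and `<out_path>-payoff.png`.
#'
#' @param result A [run_sweep()] result.
#' @param out_path Optional output path prefix for PNG files.
#' @param width,height Device size in inches when writing files.
#' @return Invisibly, a named list of the two ggplot objects.
#' @export
plot_trajectories <- function(result, out_path = NULL, width = 9,
                              height = 7) {
  stopifnot(inherits(result, "cultsel_sweep_result"))
  df <- result$summary
  if (nrow(df) == 0) stop("empty sweep result")
  structured <- result$grid$kind == "structure"
  df$panel_col <- if (structured) {
    factor(paste0("sigma = ", df$sigma), levels = paste0("sigma = ", sort(unique(df$sigma))))
  } else {
    factor(paste0("N = ", df$population_size),
           levels = paste0("N = ", sort(unique(df$population_size))))
  }
  df$panel_row <- factor(paste0("b = ", df$payoff_bias),
                         levels = paste0("b = ", sort(unique(df$payoff_bias))))
  base <- function(yvar, ylab) {
    ggplot2::ggplot(df, ggplot2::aes(x = .data$time_step,
                                     y = .data[[yvar]],
                                     colour = .data$learner_type)) +
      ggplot2::geom_line() +
      ggplot2::facet_grid(panel_row ~ panel_col) +
      ggplot2::labs(x = "time step", y = ylab, colour = "learner type") +
      ggplot2::theme_minimal()
  }
  plots <- list(
    diversity = base("mean_diversity", "Gini-Simpson diversity"),
    payoff = base("mean_payoff", "mean variant payoff")
  )
  if (!is.null(out_path)) {
    for (nm in names(plots)) {
      f <- paste0(out_path, "-", nm, ".png")
      grDevices::png(f, width = width, height = height, units = "in",
                     res = 150)
      print(plots[[nm]])
      grDevices::dev.off()
    }
  }
  invisible(plots)
}

#' @importFrom rlang .data
NULL
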