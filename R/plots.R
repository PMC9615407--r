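# Optional figures; ggplot2 is suggested, not imported.

#' Forest plot of per-trial and pooled O/E SAE ratios
#'
#' @param trials data frame with `trial_id`, `ratio`, `lower`, `upper`
#'   (e.g. the `oe_trials` table from [run_pipeline()], one condition).
#' @param pooled optional `pooled_oe` object drawn as a summary row.
#' @param log_scale put the ratio axis on the log scale (default TRUE).
#' @return a ggplot object.
#' @export
plot_oe_forest <- function(trials, pooled = NULL, log_scale = TRUE) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plot_oe_forest needs the ggplot2 package", call. = FALSE)
  d <- data.frame(label = trials$trial_id, ratio = trials$ratio,
                  lower = trials$lower, upper = trials$upper,
                  what = "trial", stringsAsFactors = FALSE)
  if (!is.null(pooled)) {
    d <- rbind(d, data.frame(label = "pooled", ratio = pooled$ratio,
                             lower = pooled$lower, upper = pooled$upper,
                             what = "pooled", stringsAsFactors = FALSE))
  }
  d$label <- factor(d$label, levels = rev(d$label))
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$ratio, y = .data$label,
                                       shape = .data$what)) +
    ggplot2::geom_vline(xintercept = 1, linetype = "dotted") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$lower,
                                         xmax = .data$upper),
                            height = 0.15) +
    ggplot2::geom_point(size = 2.2) +
    ggplot2::scale_shape_manual(values = c(trial = 16, pooled = 18),
                                guide = "none") +
    ggplot2::labs(x = "observed/expected SAE ratio", y = NULL) +
    ggplot2::theme_minimal()
  if (log_scale) p <- p + ggplot2::scale_x_log10()
  p
}
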