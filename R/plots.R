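#' Plot a fitted VE estimate
#'
#' Forest-style display of the log risk ratio term(s) with Wald limits,
#' annotated with the implied vaccine effectiveness.
#'
#' @param object A `tnd_ve` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.tnd_ve <- function(object, ...) {
  td <- tidy(object)
  ggplot2::ggplot(td, ggplot2::aes(x = .data$estimate, y = .data$term)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$conf.low,
                                          xmax = .data$conf.high)) +
    ggplot2::labs(
      x = "log risk ratio",
      y = NULL,
      title = sprintf("VE = %.1f%% (%d%% CI %.1f%%, %.1f%%)",
                      100 * object$ve, round(100 * (1 - object$alpha)),
                      100 * object$ve_ci[1], 100 * object$ve_ci[2])
    ) +
    ggplot2::theme_minimal()
}
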