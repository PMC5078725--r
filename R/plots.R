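#' Plot conditional accuracy functions
#'
#' Group-mean accuracy per RT septile with SEM error bars, one panel per
#' condition, coloured by group.
#'
#' @param object A `caf_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot caf_result
#' @export
autoplot.caf_result <- function(object, ...) {
  d <- object$by_group
  ggplot2::ggplot(d, ggplot2::aes(x = .data$mean_rt_ms,
                                  y = .data$mean_accuracy,
                                  colour = .data$group)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean_accuracy - .data$sem_accuracy,
                   ymax = .data$mean_accuracy + .data$sem_accuracy),
      width = 0) +
    ggplot2::facet_wrap(~condition) +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "Mean RT per septile (ms)", y = "Accuracy",
                  colour = "Group",
                  title = "Conditional accuracy functions") +
    ggplot2::theme_minimal()
}

#' Plot delta functions (congruence effect across the RT distribution)
#'
#' Group-mean delta (incongruent minus congruent correct RT) per septile
#' against the bin midpoint, with SEM error bars.
#'
#' @param object A `delta_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot delta_result
#' @export
autoplot.delta_result <- function(object, ...) {
  d <- object$by_group
  ggplot2::ggplot(d, ggplot2::aes(x = .data$mean_midpoint_ms,
                                  y = .data$mean_delta_ms,
                                  colour = .data$group)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean_delta_ms - .data$sem_delta_ms,
                   ymax = .data$mean_delta_ms + .data$sem_delta_ms),
      width = 0) +
    ggplot2::labs(x = "Septile midpoint RT (ms)", y = "Delta RT (ms)",
                  colour = "Group", title = "Delta plot") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.caf_result
#' @param caf A `caf_result`.
#' @export
plot_caf <- function(caf, ...) autoplot.caf_result(caf, ...)

#' @rdname autoplot.delta_result
#' @param delta A `delta_result`.
#' @export
plot_delta <- function(delta, ...) autoplot.delta_result(delta, ...)
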