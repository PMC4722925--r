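#' Plot predicted survival against overall treatment time
#'
#' Convenience visualisation of a result grid: surviving fraction vs
#' overall treatment time, one line per method, faceted by cell line.
#' Requires ggplot2.
#'
#' @param predictions A result grid from [predict_grid()], typically
#'   filtered to one total dose and subfraction count.
#' @return A ggplot object.
#' @export
plot_time_response <- function(predictions) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    lq_abort("plot_time_response() requires the ggplot2 package",
             "lqfrac_usage_error")
  }
  d <- predictions[predictions$feasible, ]
  ggplot2::ggplot(
    d,
    ggplot2::aes(x = overall_time, y = survival, colour = method)
  ) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::facet_wrap(~cell_line) +
    ggplot2::labs(x = "Overall treatment time (min)",
                  y = "Surviving fraction", colour = "Method")
}
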