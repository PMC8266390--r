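#' Plot a corrected photometry trace
#'
#' Z-scored dF/F over the session, with raw dF/F available via
#' `which = "dff"`.
#'
#' @param object a `corrected_trace`.
#' @param which `"zdff"` (default) or `"dff"`.
#' @param ... unused.
#' @return A ggplot.
#' @method autoplot corrected_trace
#' @export
autoplot.corrected_trace <- function(object, which = c("zdff", "dff"), ...) {
  which <- match.arg(which)
  ggplot2::ggplot(object, ggplot2::aes(x = .data$time_s,
                                       y = .data[[which]])) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "time (s)",
                  y = if (which == "zdff") "Z-scored dF/F" else "dF/F") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Mean peri-event trace with between-trial standard error
#'
#' @param tensor a `peri_event_tensor`.
#' @return A ggplot of the trial-averaged Z-scored dF/F against time from
#'   the event, with an s.e.m. ribbon and a vertical marker at the event.
#' @export
plot_peri_event <- function(tensor) {
  stopifnot(inherits(tensor, "peri_event_tensor"))
  rel <- attr(tensor, "relative_time_s")
  m <- colMeans(tensor)
  sem <- apply(tensor, 2, stats::sd) / sqrt(nrow(tensor))
  df <- tibble::tibble(relative_time_s = rel, mean = m,
                       lo = m - sem, hi = m + sem)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$relative_time_s,
                                   y = .data$mean)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lo, ymax = .data$hi),
                         alpha = 0.3) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed") +
    ggplot2::labs(x = "time from event (s)", y = "Z-scored dF/F") +
    ggplot2::theme_minimal()
}

#' Elevation ratios across conditioning sessions
#'
#' One line per subject plus the group mean; the 0.5 line marks no
#' elevation.
#'
#' @param elevation tibble with columns `subject`, `session`,
#'   `elevation_ratio` (as produced by [run_experiment()]).
#' @return A ggplot.
#' @export
plot_elevation <- function(elevation) {
  ggplot2::ggplot(elevation,
                  ggplot2::aes(x = .data$session, y = .data$elevation_ratio,
                               group = .data$subject)) +
    ggplot2::geom_line(alpha = 0.3) +
    ggplot2::stat_summary(ggplot2::aes(group = 1), fun = mean,
                          geom = "line", linewidth = 1.2) +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dashed") +
    ggplot2::labs(x = "conditioning session", y = "elevation ratio") +
    ggplot2::theme_minimal()
}
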