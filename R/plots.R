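#' Plot a harvest-rate series
#'
#' Cumulative harvest rate at the end of each interval, with the mean
#' interval-end rate as a dashed line.
#'
#' @param object A `harvest_series` from [harvest_rate()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.harvest_series <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$interval, y = .data$hr)) +
    ggplot2::geom_line(color = "steelblue") +
    ggplot2::geom_point(size = 1) +
    ggplot2::geom_hline(yintercept = attr(object, "mean_hr"),
                        linetype = "dashed") +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "interval", y = "cumulative harvest rate",
                  title = "Harvest rate over the crawl",
                  subtitle = sprintf("mean of interval-end rates: %.3f",
                                     attr(object, "mean_hr"))) +
    ggplot2::theme_minimal()
}

#' Plot the relevance-probability histogram of a crawl
#'
#' For a well-separated classifier the distribution is bimodal: most pages
#' sit near probability 0 or 1.
#'
#' @param object A `crawl_result`.
#' @param bins Histogram bins.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.crawl_result <- function(object, bins = 30, ...) {
  df <- object$records[object$records$status == "ok", ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$prob_h)) +
    ggplot2::geom_histogram(bins = bins, fill = "steelblue",
                            color = "white") +
    ggplot2::labs(x = "P(H)", y = "fetched pages",
                  title = "Relevance probability of fetched pages") +
    ggplot2::theme_minimal()
}

#' Plot the degree distribution of a host graph
#'
#' @param object A `host_graph`.
#' @param ... Unused.
#' @return A ggplot object (log-scaled counts of total degree).
#' @export
autoplot.host_graph <- function(object, ...) {
  deg <- igraph::degree(object$graph, mode = "all")
  df <- tibble::tibble(degree = deg)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$degree)) +
    ggplot2::geom_bar(fill = "steelblue") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "host degree", y = "hosts (log scale)",
                  title = "Host-graph degree distribution") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
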