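#' Histogram of unitig lengths
#'
#' @param x A \code{cdbg} object.
#' @param bins Number of histogram bins.
#' @return A ggplot object.
#' @export
plot_unitig_lengths <- function(x, bins = 30) {
  stopifnot(inherits(x, "cdbg"))
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plot_unitig_lengths() needs the ggplot2 package")
  un <- unitigs(x)
  ggplot2::ggplot(data.frame(length = nchar(un$seq)),
                  ggplot2::aes(x = .data$length)) +
    ggplot2::geom_histogram(bins = bins, fill = "steelblue", colour = "grey20") +
    ggplot2::labs(x = "unitig length (bp)", y = "count",
                  title = sprintf("%d unitigs (k = %d)", nrow(un), x$k)) +
    ggplot2::theme_minimal()
}
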