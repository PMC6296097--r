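#' @importFrom ggplot2 autoplot ggplot aes geom_step geom_hline geom_rect
#'   geom_col labs theme_minimal annotate
#' @export
ggplot2::autoplot

#' Plot a coverage profile
#'
#' Depth summarised as window means (per-base plotting is illegible at
#' Mbp scale), with the accession mean and the 1- and 2-SD bands that the
#' anomaly rule thresholds against, and optionally the called regions.
#'
#' @param object A [coverage_profile()].
#' @param stats Optional [depth_stats()] row; drawn as mean line and SD
#'   bands.
#' @param regions Optional anomaly regions ([call_coverage_anomalies()])
#'   shaded along the x axis.
#' @param window Plot bin width in bp (default 1000).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.coverage_profile <- function(object, stats = NULL,
                                      regions = NULL, window = 1000,
                                      ...) {
  L <- length(object$depth)
  nw <- ceiling(L / window)
  idx <- rep(seq_len(nw), each = window, length.out = L)
  df <- tibble(
    pos = (seq_len(nw) - 0.5) * window,
    depth = as.numeric(tapply(object$depth, idx, mean))
  )
  p <- ggplot(df, aes(x = .data$pos, y = .data$depth)) +
    geom_step(colour = "grey30") +
    labs(x = sprintf("position on %s (bp)", object$part),
         y = "mean depth", title = object$part) +
    theme_minimal()
  if (!is.null(stats)) {
    mu <- stats$mean[1]; sd <- stats$sd[1]
    for (kk in 1:2) {
      p <- p + annotate("rect", xmin = -Inf, xmax = Inf,
                        ymin = max(0, mu - kk * sd), ymax = mu + kk * sd,
                        alpha = 0.08, fill = "grey40")
    }
    p <- p + geom_hline(yintercept = mu, colour = "goldenrod")
  }
  if (!is.null(regions) && nrow(regions) > 0) {
    p <- p + geom_rect(
      data = as_tibble(regions),
      aes(xmin = .data$start, xmax = .data$end,
          fill = .data$direction),
      ymin = -Inf, ymax = Inf, alpha = 0.25, inherit.aes = FALSE
    )
  }
  p
}

#' Plot a variant-density track
#'
#' Window counts as columns, with the mean and 2-SD exceedance threshold
#' when statistics are supplied.
#'
#' @param track A [variant_density()] track (one part).
#' @param stats Optional [density_stats()] row.
#' @param k SD multiplier for the threshold line (default 2).
#' @return A ggplot object.
#' @export
plot_density_track <- function(track, stats = NULL, k = 2) {
  check_columns(track, c("part", "start", "end", "count"), "track")
  p <- ggplot(as_tibble(track),
              aes(x = (.data$start + .data$end) / 2, y = .data$count)) +
    geom_col(width = NULL, fill = "steelblue") +
    labs(x = sprintf("position on %s (bp)", track$part[1]),
         y = "variants / window") +
    theme_minimal()
  if (!is.null(stats)) {
    p <- p +
      geom_hline(yintercept = stats$mean[1], colour = "goldenrod") +
      geom_hline(yintercept = stats$mean[1] + k * stats$sd[1],
                 linetype = "dashed", colour = "firebrick")
  }
  p
}
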