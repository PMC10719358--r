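#' Plot the carrier-frequency spectrum
#' @param x An [af_spectrum()] object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.af_spectrum <- function(x, ...) {
  d <- tidy(x)
  d$level <- factor(d$level, levels = d$level)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$level, y = .data$count)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::labs(x = "carrier-frequency level", y = "SV count") +
    ggplot2::theme_minimal()
}

#' Plot saturation curves
#' @param x A [saturation_curve()] object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.saturation_curve <- function(x, ...) {
  ggplot2::ggplot(x$curves,
                  ggplot2::aes(x = .data$k, y = .data$cumulative,
                               group = .data$order)) +
    ggplot2::geom_line(alpha = 0.3) +
    ggplot2::geom_line(data = x$mean_curve,
                       ggplot2::aes(y = .data$mean_cumulative,
                                    group = NULL),
                       linewidth = 1) +
    ggplot2::labs(x = "samples added", y = "distinct SVs") +
    ggplot2::theme_minimal()
}

#' Plot PCA sample scores
#' @param x An [presence_pca()] object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.sv_pca <- function(x, ...) {
  d <- tidy(x)
  aes <- if ("population" %in% names(d)) {
    ggplot2::aes(x = .data$PC1, y = .data$PC2, colour = .data$population)
  } else {
    ggplot2::aes(x = .data$PC1, y = .data$PC2)
  }
  ggplot2::ggplot(d, aes) +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = sprintf("PC1 (%.1f%%)", 100 * x$explained[1]),
      y = sprintf("PC2 (%.1f%%)", 100 * x$explained[2])) +
    ggplot2::theme_minimal()
}

#' Manhattan-style plot of per-site F_ST
#' @param x An [weir_cockerham_fst()] result.
#' @param coords Optional SV tibble giving `chrom`/`start` per id.
#' @param threshold Horizontal reference line (default 0.1).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.fst_result <- function(x, coords = NULL, threshold = 0.1, ...) {
  d <- tidy(x)
  if (!is.null(coords)) {
    d <- inner_join(d, as_tibble(coords)[, c("id", "chrom", "start")],
                    by = "id")
  } else {
    d$chrom <- "all"
    d$start <- seq_len(nrow(d))
  }
  ggplot2::ggplot(filter(d, !is.na(.data$theta)),
                  ggplot2::aes(x = .data$start, y = .data$theta,
                               colour = .data$chrom)) +
    ggplot2::geom_point(size = 0.6, show.legend = FALSE) +
    ggplot2::geom_hline(yintercept = threshold, linetype = 2) +
    ggplot2::facet_grid(cols = ggplot2::vars(.data$chrom),
                        scales = "free_x", space = "free_x") +
    ggplot2::labs(x = "position (bp)", y = expression(hat(theta))) +
    ggplot2::theme_minimal()
}

#' Plot binned SV density along the genome
#' @param bins Output of [binned_density()].
#' @param column Count column to draw (default `"total"`).
#' @return A ggplot.
#' @export
plot_sv_density <- function(bins, column = "total") {
  ggplot2::ggplot(bins,
                  ggplot2::aes(x = .data$bin_start / 1e6,
                               y = .data[[column]])) +
    ggplot2::geom_step() +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$chrom)) +
    ggplot2::labs(x = "position (Mb)", y = paste(column, "per bin")) +
    ggplot2::theme_minimal()
}
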