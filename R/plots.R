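#' Diagnostic plots
#'
#' ggplot2 views of the core QC results: `plot_composition()` shows the
#' per-position nucleotide fractions (the classic digestion-diagnostic
#' panel, with the windowed GC annotated), `plot_length_distribution()` the
#' footprint length histogram with its modal length, `plot_metagene()` a
#' smoothed coverage profile with CDS boundaries, and `plot_titration()` the
#' GC / length trends across a titration series.
#'
#' @param composition A `composition_matrix` from [nucleotide_composition()].
#' @param gc_window Optional window annotated on the composition plot.
#' @return A ggplot object.
#' @export
plot_composition <- function(composition, gc_window = c(10L, 20L)) {
  long <- composition %>%
    tidyr::pivot_longer(c("A", "C", "G", "T"), names_to = "base",
                        values_to = "fraction")
  p <- ggplot2::ggplot(long, ggplot2::aes(.data$position, .data$fraction,
                                          colour = .data$base)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "position from 5' end (nt)", y = "base fraction") +
    ggplot2::theme_minimal()
  if (!is.null(gc_window) &&
      max(composition$position) >= gc_window[2]) {
    gc <- windowed_gc(composition, gc_window)
    p <- p +
      ggplot2::annotate("rect", xmin = gc_window[1], xmax = gc_window[2],
                        ymin = -Inf, ymax = Inf, alpha = 0.08) +
      ggplot2::ggtitle(sprintf("GC %.1f%% in window [%d, %d]",
                               gc, gc_window[1], gc_window[2]))
  }
  p
}

#' @rdname plot_composition
#' @param x Footprint tibble or length histogram (see [length_histogram()]).
#' @export
plot_length_distribution <- function(x) {
  h <- length_histogram(x)
  peak <- length_peak(h)
  ggplot2::ggplot(h, ggplot2::aes(.data$length, .data$count)) +
    ggplot2::geom_col() +
    ggplot2::geom_vline(xintercept = peak, linetype = 2) +
    ggplot2::labs(x = "footprint length (nt)", y = "reads",
                  title = sprintf("modal length %d nt", peak)) +
    ggplot2::theme_minimal()
}

#' @rdname plot_composition
#' @param profile Tibble from [metagene_profile()].
#' @param transcripts,transcript Optional annotation to mark start/stop.
#' @export
plot_metagene <- function(profile, transcript = NULL, transcripts = NULL) {
  p <- ggplot2::ggplot(profile, ggplot2::aes(.data$position, .data$density)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "transcript position (nt)", y = "normalised density") +
    ggplot2::theme_minimal()
  if (!is.null(transcript) && !is.null(transcripts)) {
    i <- match(transcript, transcripts$id)
    p <- p + ggplot2::geom_vline(xintercept = transcripts$utr5_end[i],
                                 colour = "darkgreen", linetype = 3) +
      ggplot2::geom_vline(xintercept = transcripts$cds_end[i],
                          colour = "red", linetype = 3)
  }
  p
}

#' @rdname plot_composition
#' @param results Per-step metric tibble (see [correlate_metrics()]).
#' @param fold Fold factor of the series.
#' @export
plot_titration <- function(results, fold = 5) {
  long <- results %>%
    select("step", "gc_window_mean", "length_peak") %>%
    mutate(length_peak = as.numeric(.data$length_peak)) %>%
    tidyr::pivot_longer(-"step", names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(.data$step - 1, .data$value)) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         linewidth = 0.4) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = sprintf("log%d(relative RNase concentration)", round(fold)),
                  y = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname plot_composition
#' @param object,... `autoplot.qc_report`: composition panel of a
#'   [qc_report()].
#' @export
autoplot.qc_report <- function(object, ...) {
  plot_composition(object$composition, object$gc_window)
}
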