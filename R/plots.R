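#' Plot a k-mer frequency spectrum
#'
#' Distinct-k-mer counts against occurrence frequency on log scales, with the
#' estimated k-mer depth marked. A positively skewed spectrum with heavy
#' high-frequency mass is the signature of a repeat-rich genome.
#'
#' @param object A `kmer_spectrum`.
#' @param error_cutoff Error cutoff used for the depth line (default 3).
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.kmer_spectrum <- function(object, error_cutoff = 3, ...) {
  df <- as_tibble(object)
  d <- tryCatch(estimate_depth(object, error_cutoff), error = function(e) NA)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$frequency,
                                        y = .data$n_kmers)) +
    ggplot2::geom_line() +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "k-mer frequency",
                  y = "distinct k-mers",
                  title = sprintf("k-mer spectrum (k = %d)", attr(object, "k")))
  if (!is.na(d)) {
    p <- p + ggplot2::geom_vline(xintercept = d, linetype = "dashed")
  }
  p
}

#' Plot a repeat-content table
#'
#' @param object A `repeat_content_table`.
#' @param ... Ignored.
#' @return A ggplot object (assembly percentage per repeat class).
#' @export
autoplot.repeat_content_table <- function(object, ...) {
  df <- as_tibble(object) |>
    filter(!.data$class %in% c("classified_total", "total"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$class, y = .data$assembly_pct)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "% of assembly (non-ambiguous)",
                  title = "repeat content by class")
}

#' Plot synteny blocks along query scaffolds
#'
#' Linear block map: one horizontal track per query scaffold, blocks colored
#' by target linkage group.
#'
#' @param blocks Block tibble from [build_blocks()].
#' @return A ggplot object.
#' @export
plot_synteny_blocks <- function(blocks) {
  blocks <- as_tibble(blocks)
  ggplot2::ggplot(blocks,
                  ggplot2::aes(xmin = .data$start, xmax = .data$end,
                               ymin = as.integer(factor(.data$scaffold)) - 0.4,
                               ymax = as.integer(factor(.data$scaffold)) + 0.4,
                               fill = .data$target_lg)) +
    ggplot2::geom_rect() +
    ggplot2::scale_y_continuous(
      breaks = seq_along(unique(blocks$scaffold)),
      labels = sort(unique(blocks$scaffold))) +
    ggplot2::labs(x = "position (bp)", y = NULL, fill = "target LG",
                  title = "synteny haplotype blocks")
}
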