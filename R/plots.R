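#' Plot per-haploid copy-number estimates by gene and reproductive mode
#'
#' Box-and-jitter view of the lineage x gene copy-number table, split by
#' reproductive mode, on a log axis (copy numbers span more than an order
#' of magnitude between modes).
#'
#' @param cn_tbl Long copy-number table (`lineage`, `gene`, `copy_number`).
#' @param metadata Lineage metadata (`lineage`, `mode`).
#' @return A ggplot object.
#' @export
plot_copy_number <- function(cn_tbl, metadata) {
  df <- dplyr::inner_join(cn_tbl, metadata, by = "lineage") %>%
    dplyr::filter(!is.na(.data$copy_number))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$gene, y = .data$copy_number,
                                   fill = .data$mode)) +
    ggplot2::geom_boxplot(outlier.shape = NA, alpha = 0.6,
                          position = ggplot2::position_dodge(width = 0.8)) +
    ggplot2::geom_point(position = ggplot2::position_jitterdodge(
      jitter.width = 0.1, dodge.width = 0.8), size = 0.8, alpha = 0.7) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = NULL, y = "per-haploid copy number", fill = "mode") +
    ggplot2::theme_minimal()
}

#' Plot genomic proportion of the repeat locus by reproductive mode
#'
#' @param prop_tbl [proportion_table()] output (`lineage`,
#'   `proportion_pct`).
#' @param metadata Lineage metadata (`lineage`, `mode`).
#' @return A ggplot object.
#' @export
plot_genomic_proportion <- function(prop_tbl, metadata) {
  df <- dplyr::inner_join(prop_tbl, metadata, by = "lineage")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mode, y = .data$proportion_pct,
                                   fill = .data$mode)) +
    ggplot2::geom_boxplot(alpha = 0.6, outlier.shape = NA) +
    ggplot2::geom_jitter(width = 0.1, size = 1) +
    ggplot2::labs(x = NULL, y = "% of mapped reads in one repeat unit") +
    ggplot2::guides(fill = "none") +
    ggplot2::theme_minimal()
}

#' Schematic of an inferred repeat unit
#'
#' Draws the consensus genes as arrows at their offsets within one unit,
#' pointing with their transcriptional orientation.
#'
#' @param object A `repeat_unit_model`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.repeat_unit_model <- function(object, ...) {
  cons <- object$consensus %>%
    dplyr::mutate(
      xstart = ifelse(.data$orientation == "+", .data$offset, .data$offset + 200),
      xend = ifelse(.data$orientation == "+", .data$offset + 200, .data$offset)
    )
  ggplot2::ggplot(cons) +
    ggplot2::geom_segment(
      ggplot2::aes(x = .data$xstart, xend = .data$xend, y = 1, yend = 1),
      arrow = ggplot2::arrow(length = ggplot2::unit(0.1, "inches")),
      linewidth = 2, lineend = "butt"
    ) +
    ggplot2::geom_text(ggplot2::aes(x = .data$offset + 100, y = 1.1,
                                    label = .data$gene), size = 3) +
    ggplot2::scale_y_continuous(limits = c(0.8, 1.3), breaks = NULL) +
    ggplot2::labs(
      x = "offset from anchor (bp)", y = NULL,
      title = if (is.na(object$period)) "single repeat unit (period undefined)"
      else sprintf("repeat unit: period %s bp, %d copies",
                   format(object$period), object$n_units)
    ) +
    ggplot2::theme_minimal()
}
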