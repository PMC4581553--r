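#' Bar chart of gene-action mode counts
#'
#' @param object A `mode_summary` from [summarize_modes()].
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.mp_mode_summary <- function(object, ...) {
  d <- dplyr::filter(object, .data$group != "rollup")
  ggplot2::ggplot(d, ggplot2::aes(
    x = factor(.data$mode, levels = .modes), y = .data$n, fill = .data$group
  )) +
    ggplot2::geom_col() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f%%", .data$percent)),
                       vjust = -0.4, size = 3) +
    ggplot2::labs(x = "gene-action mode", y = "genes", fill = NULL,
                  title = "Dominance patterns of differentially expressed genes") +
    ggplot2::theme_minimal()
}

#' Heat map of an enrichment scan
#'
#' Tiles of -log10(p) per (unit, gene-set) pair, the matrix view behind a
#' GO- or chromosome-enrichment heat map.
#'
#' @param object An `enrichment` tibble ([go_enrich()], [chromosome_scan()]).
#' @param ... Unused.
#' @param max_units Cap on displayed units, smallest FDR first (default 30).
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.mp_enrichment <- function(object, ..., max_units = 30) {
  units <- utils::head(unique(object$unit[order(object$fdr %||% object$p_value)]),
                       max_units)
  d <- dplyr::filter(tibble::as_tibble(object), .data$unit %in% units)
  ggplot2::ggplot(d, ggplot2::aes(
    x = .data$gene_set_label, y = factor(.data$unit, levels = rev(units)),
    fill = -log10(.data$p_value)
  )) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = "-log10 p") +
    ggplot2::labs(x = NULL, y = NULL, title = "Enrichment") +
    ggplot2::theme_minimal()
}

#' Bar chart of the expressed-set Venn regions
#'
#' @param object A `venn_partition` from [venn_partition()].
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.mp_venn <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(
    x = factor(.data$region, levels = .venn_regions), y = .data$n
  )) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = NULL, y = "genes",
                  title = "Expressed-gene sets across P1, P2 and F1") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
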