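#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot the permutation null against the observed overlap
#'
#' Histogram of the permuted base-pair overlaps with the observed overlap
#' marked; the gap between them is the visual counterpart of the fold
#' enrichment and empirical p-value.
#'
#' @param object An `overlap_enrichment` object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.overlap_enrichment <- function(object, ...) {
  ggplot2::ggplot(tibble(null_bp = object$null_bp), ggplot2::aes(x = .data$null_bp)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey70", colour = "grey40") +
    ggplot2::geom_vline(xintercept = object$observed_bp, colour = "firebrick",
                        linewidth = 1) +
    ggplot2::labs(
      x = "base-pair overlap per permutation",
      y = "permutations",
      title = sprintf("observed %s bp, fold = %.1f, p = %.3g",
                      format(object$observed_bp, big.mark = ","),
                      object$fold_enrichment, object$empirical_p)
    ) +
    ggplot2::theme_minimal()
}

#' Plot per-sample EMT scores
#'
#' @param object An `emt_score` object.
#' @param ... Unused.
#' @return A ggplot of scores per sample, coloured by the
#'   epithelial/mesenchymal call.
#' @export
autoplot.emt_score <- function(object, ...) {
  d <- object$scores
  ggplot2::ggplot(d, ggplot2::aes(x = factor(.data$sample, levels = .data$sample),
                                  y = .data$score, fill = .data$call)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::labs(x = NULL, y = "EMT score (positive = epithelial)") +
    ggplot2::theme_minimal()
}

#' Gap-length distributions per condition
#'
#' @param gaps A gap tibble from [gap_lengths()], optionally with a
#'   `condition` column (bind several conditions with
#'   `dplyr::bind_rows(.id = "condition")`).
#' @return A ggplot boxplot of log10 gap lengths.
#' @export
plot_gap_lengths <- function(gaps) {
  if (!"condition" %in% names(gaps)) gaps$condition <- "all"
  ggplot2::ggplot(gaps, ggplot2::aes(x = .data$condition, y = .data$gap_length)) +
    ggplot2::geom_boxplot(outlier.size = 0.4) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = NULL, y = "inter-peak gap length (bp)") +
    ggplot2::theme_minimal()
}

#' Condition-by-condition correlation heatmap
#'
#' @param cor_matrix Output of [correlation_matrix()].
#' @return A ggplot tile heatmap of pairwise Pearson correlations.
#' @export
plot_correlation_heatmap <- function(cor_matrix) {
  d <- as_tibble(cor_matrix, rownames = "a") |>
    tidyr::pivot_longer(-"a", names_to = "b", values_to = "r")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$a, y = .data$b, fill = .data$r)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", .data$r)), size = 3) +
    ggplot2::scale_fill_gradient2(low = "steelblue", mid = "white",
                                  high = "firebrick", midpoint = 0.5, limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "Pearson r") +
    ggplot2::theme_minimal()
}

#' MPS versus DPS accessibility-change scatter
#'
#' @param changes Output of [classify_change()].
#' @param dps_major Major-change threshold drawn as guides (default 2).
#' @return A ggplot scatter of DPS against MPS with major changes
#'   highlighted.
#' @export
plot_mps_dps <- function(changes, dps_major = 2) {
  ggplot2::ggplot(changes, ggplot2::aes(x = .data$mps, y = .data$dps,
                                        colour = .data$major_change)) +
    ggplot2::geom_point(alpha = 0.5, size = 0.8) +
    ggplot2::geom_hline(yintercept = c(-dps_major, dps_major), linetype = 2) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60", `TRUE` = "goldenrod")) +
    ggplot2::labs(x = "mean peak score (MPS)", y = "differential peak score (DPS)") +
    ggplot2::theme_minimal()
}

#' Motif percentage-change bars across conditions
#'
#' @param enrichment Output of [motif_enrichment_table()].
#' @return A ggplot of percentage-point change versus the control condition,
#'   faceted by motif.
#' @export
plot_motif_change <- function(enrichment) {
  ggplot2::ggplot(enrichment, ggplot2::aes(x = .data$condition,
                                           y = .data$percentage_change)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::facet_wrap(~motif) +
    ggplot2::labs(x = NULL, y = "motif target % change vs control") +
    ggplot2::theme_minimal()
}

#' Expression fold change versus TSS distance
#'
#' @param fc_table Output of [fc_vs_tss_table()].
#' @return A ggplot scatter of log2 expression fold change against signed
#'   TSS distance for differential peaks.
#' @export
plot_fc_vs_tss <- function(fc_table) {
  d <- dplyr::filter(fc_table, !.data$missing_expression)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$tss_distance,
                                  y = log2(.data$expression_fc))) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::labs(x = "distance from TSS (bp, signed)",
                  y = "log2 expression fold change") +
    ggplot2::theme_minimal()
}
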