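#' Volcano plot of old/young differential expression
#'
#' @param object an [age_de_test()] table.
#' @param lfc_threshold,alpha thresholds drawn and used to colour calls.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.vasc_deg <- function(object, lfc_threshold = 0.5, alpha = 0.05, ...) {
  d <- dplyr::filter(tibble::as_tibble(object), !.data$skipped)
  d$called <- abs(d$avg_logFC) >= lfc_threshold & d$p_adj <= alpha
  ggplot2::ggplot(d, ggplot2::aes(.data$avg_logFC, -log10(pmax(.data$p_adj, 1e-300)),
                                  colour = .data$called)) +
    ggplot2::geom_point(alpha = 0.6, size = 0.8) +
    ggplot2::geom_vline(xintercept = c(-1, 1) * lfc_threshold, linetype = 2) +
    ggplot2::geom_hline(yintercept = -log10(alpha), linetype = 2) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60", `TRUE` = "firebrick")) +
    ggplot2::facet_wrap(ggplot2::vars(.data$cell_type)) +
    ggplot2::labs(x = "avg logFC (old - young)", y = "-log10 adjusted p",
                  colour = "DEG") +
    ggplot2::theme_bw()
}

#' Transcriptional-noise boxplots by cell type and age group
#'
#' @param object a [transcriptional_noise()] table.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.vasc_noise <- function(object, ...) {
  d <- dplyr::filter(tibble::as_tibble(object), !.data$flagged)
  d$age_group <- factor(d$age_group, levels = c("young", "old"))
  ggplot2::ggplot(d, ggplot2::aes(.data$cell_type, .data$noise_ratio,
                                  fill = .data$age_group)) +
    ggplot2::geom_boxplot(outlier.size = 0.5) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = NULL, y = "noise ratio (bio / ERCC technical distance)",
                  fill = NULL) +
    ggplot2::theme_bw()
}

#' Hub-degree versus regulon-activity plot for master-regulator results
#'
#' @param object a [candidate_mrs()] table.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.vasc_mr <- function(object, ...) {
  d <- tibble::as_tibble(object)
  ggplot2::ggplot(d, ggplot2::aes(.data$n_deg_targets, .data$activity_z,
                                  colour = .data$candidate)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_text(ggplot2::aes(label = .data$tf), vjust = -0.8, size = 3,
                       show.legend = FALSE) +
    ggplot2::labs(x = "DEG targets in regulon (hub degree)",
                  y = "regulon activity z", colour = "candidate MR") +
    ggplot2::theme_bw()
}
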