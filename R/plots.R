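# ggplot2 visualizations of the result classes.

#' Volcano plot of differential splicing results
#'
#' Delta PSI against -log10 q, colored by significance.
#'
#' @param object A [differential_splicing()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot ss_diff
#' @export
autoplot.ss_diff <- function(object, ...) {
  d <- as_tibble(object) %>% filter(!is.na(.data$q))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$delta_psi,
                                  y = -log10(pmax(.data$q, 1e-300)),
                                  color = .data$significant)) +
    ggplot2::geom_point(alpha = 0.6, size = 0.9) +
    ggplot2::scale_color_manual(values = c(`FALSE` = "grey60", `TRUE` = "firebrick")) +
    ggplot2::facet_wrap(~fraction) +
    ggplot2::labs(x = expression(Delta * "PSI (mutant - control)"),
                  y = expression(-log[10] ~ italic(q)),
                  color = "significant") +
    ggplot2::theme_bw()
}

#' Volcano plot of canonical-expression results
#'
#' @param object An [nb_glm_lrt()] result.
#' @param highlight Optional character vector of gene ids drawn in red
#'   (e.g. targets of mutant-associated truncating events).
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot ss_expression
#' @export
autoplot.ss_expression <- function(object, highlight = NULL, ...) {
  d <- as_tibble(object) %>%
    filter(.data$converged) %>%
    mutate(target = .data$gene_id %in% (highlight %||% character(0)))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$log2_fc,
                                  y = -log10(pmax(.data$q, 1e-300)))) +
    ggplot2::geom_point(data = ~ filter(.x, !.data$target),
                        color = "grey60", alpha = 0.6, size = 0.9) +
    ggplot2::geom_point(data = ~ filter(.x, .data$target),
                        color = "firebrick", size = 1.3) +
    ggplot2::labs(x = expression(log[2] ~ "fold change"),
                  y = expression(-log[10] ~ italic(q))) +
    ggplot2::theme_bw()
}

#' Forest plot of positional motif enrichment
#'
#' Relative motif frequency per exon segment with 95% CIs, the layout
#' of an exon-quarter enrichment analysis.
#'
#' @param object A [motif_segment_enrichment()] result (rows may mix
#'   motifs).
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot ss_motif
#' @export
autoplot.ss_motif <- function(object, ...) {
  d <- as_tibble(object)
  ggplot2::ggplot(d, ggplot2::aes(x = factor(.data$segment),
                                  y = .data$relative_frequency,
                                  color = .data$motif)) +
    ggplot2::geom_hline(yintercept = 1, linetype = 2, color = "grey50") +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$ci_lo, ymax = .data$ci_hi),
                             position = ggplot2::position_dodge(width = 0.4)) +
    ggplot2::labs(x = "exon segment (5' to 3')", y = "relative frequency") +
    ggplot2::theme_bw()
}

#' PSI by group, one panel per event
#'
#' Boxplots of per-sample PSI stratified by genotype group.
#'
#' @param psi PSI tibble.
#' @param sheet Sample sheet.
#' @param event_ids Events to show.
#' @return A ggplot.
#' @export
plot_psi_by_group <- function(psi, sheet, event_ids) {
  d <- psi %>%
    filter(.data$event_id %in% event_ids, !is.na(.data$psi)) %>%
    left_join(sheet %>% select("sample_id", "genotype"), by = "sample_id")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$genotype, y = .data$psi)) +
    ggplot2::geom_boxplot(outlier.shape = NA, fill = "grey90") +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.5, size = 0.8) +
    ggplot2::facet_wrap(~event_id, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "PSI (%)") +
    ggplot2::theme_bw() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}
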