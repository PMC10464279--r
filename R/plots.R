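#' Manhattan panel of association records
#'
#' Plots -log10(p) by genomic position, faceted by sleep measure, with
#' chromosomes laid side by side and the nominal and FDR thresholds drawn
#' as reference lines. This is a working plot for synthetic and cohort
#' runs, not publication graphics; the same numbers are exported by
#' `run_pipeline()` as `manhattan.tsv`.
#'
#' @param ewas An `ewas_result` or its records tibble.
#' @param p_threshold Nominal threshold line (drawn dashed).
#' @return A ggplot object.
#' @export
plot_manhattan <- function(ewas, p_threshold = 0.05) {
  records <- if (inherits(ewas, "ewas_result")) ewas$records else ewas
  chroms <- sort(unique(records$chrom))
  offs <- cumsum(c(0, vapply(chroms, function(cn)
    max(records$pos[records$chrom == cn]) + 1, numeric(1))))[seq_along(chroms)]
  records$xpos <- records$pos + offs[match(records$chrom, chroms)]
  ggplot2::ggplot(records,
                  ggplot2::aes(x = .data$xpos,
                               y = -log10(pmax(.data$p.value, 1e-300)),
                               colour = .data$chrom)) +
    ggplot2::geom_point(size = 0.6, show.legend = FALSE) +
    ggplot2::geom_hline(yintercept = -log10(p_threshold),
                        linetype = "dashed") +
    ggplot2::facet_wrap(ggplot2::vars(.data$measure)) +
    ggplot2::labs(x = "genomic position (chromosomes concatenated)",
                  y = expression(-log[10](p))) +
    ggplot2::theme_minimal()
}

#' @rdname run_ewas
#' @param object An `ewas_result`.
#' @export
autoplot.ewas_result <- function(object, ...) plot_manhattan(object, ...)

#' Enrichment p-values across measures
#'
#' Side-by-side -log10 p of the hypergeometric and permutation tests per
#' sleep measure, with the 0.05 reference line.
#'
#' @param object An enrichment report from [enrichment_report()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot_enrichment <- function(object, ...) {
  long <- tidyr::pivot_longer(
    object[c("measure", "p_hypergeometric", "p_permutation")],
    cols = c("p_hypergeometric", "p_permutation"),
    names_to = "test", values_to = "p")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$measure,
                                     y = -log10(.data$p),
                                     fill = .data$test)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_hline(yintercept = -log10(0.05), linetype = "dashed") +
    ggplot2::labs(x = NULL, y = expression(-log[10](p))) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}
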