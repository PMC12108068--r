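#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot the probes-per-gene distribution of a panel
#'
#' @param object A `tealseq_panel`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.tealseq_panel <- function(object, ...) {
  s <- panel_summary(object)
  ggplot2::ggplot(s$histogram,
                  ggplot2::aes(x = factor(.data$n_probes),
                               y = .data$n_genes)) +
    ggplot2::geom_col(fill = "grey30") +
    ggplot2::labs(
      x = "probes per gene", y = "genes",
      title = sprintf("%s panel, %s: %d probes, %.0f%% of target genes covered",
                      toupper(object$architecture), object$species_id,
                      s$n_probes, 100 * s$coverage)) +
    ggplot2::theme_minimal()
}

#' Volcano plot of probe-level differential expression
#'
#' @param object A `tealseq_de`.
#' @param lfc_thresh,p_thresh Thresholds drawn as guide lines (the
#'   gene-level calling rule).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.tealseq_de <- function(object, lfc_thresh = 2, p_thresh = 0.05,
                                ...) {
  d <- object$probes |>
    dplyr::mutate(status = dplyr::case_when(
      .data$log2fc > lfc_thresh & .data$adj_p < p_thresh ~ "up",
      .data$log2fc < -lfc_thresh & .data$adj_p < p_thresh ~ "down",
      .default = "ns"))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$log2fc,
                                  y = -log10(.data$adj_p),
                                  colour = .data$status)) +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::geom_vline(xintercept = c(-lfc_thresh, lfc_thresh),
                        linetype = "dashed", colour = "grey50") +
    ggplot2::geom_hline(yintercept = -log10(p_thresh),
                        linetype = "dashed", colour = "grey50") +
    ggplot2::scale_colour_manual(values = c(up = "firebrick",
                                            down = "steelblue",
                                            ns = "grey70")) +
    ggplot2::labs(x = "probe log2 fold change",
                  y = "-log10 adjusted p") +
    ggplot2::theme_minimal()
}

#' Heatmap of a sample correlation matrix
#'
#' @param object A `tealseq_cor`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.tealseq_cor <- function(object, ...) {
  s <- colnames(object$r)
  d <- tibble::tibble(
    sample_x = rep(s, times = length(s)),
    sample_y = rep(s, each = length(s)),
    r = as.vector(object$r))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$sample_x, y = .data$sample_y,
                                  fill = .data$r)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "steelblue", mid = "white",
                                  high = "firebrick", midpoint = 0,
                                  limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "Pearson R") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Squared-error distributions of an SSE comparison
#'
#' @param object A `tealseq_sse`.
#' @param ... Unused.
#' @return A ggplot (log10-scaled squared errors by comparison).
#' @export
autoplot.tealseq_sse <- function(object, ...) {
  ggplot2::ggplot(object$errors,
                  ggplot2::aes(x = .data$comparison, y = .data$sq_err)) +
    ggplot2::geom_boxplot(outlier.alpha = 0.3) +
    ggplot2::scale_y_continuous(trans = "log1p") +
    ggplot2::labs(x = NULL, y = "per-CDS squared error (log2 CPM)",
                  subtitle = sprintf("two-sided Wilcoxon p = %.3g",
                                     object$wilcoxon_p)) +
    ggplot2::theme_minimal()
}
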