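#' SAM plot: observed versus expected order statistics
#'
#' The classic diagnostic: sorted observed d-scores against the expected
#' order statistics from the permutation null, with the identity line and
#' a band at the given delta.
#'
#' @param object A `sam_result`.
#' @param delta Half-width of the significance band (default: the
#'   smallest delta in the FDR table with FDR below 0.05, if any).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.sam_result <- function(object, delta = NULL, ...) {
  df <- tibble(dbar = object$dbar, d = object$d_sorted)
  if (is.null(delta)) {
    ok <- object$fdr_table$fdr <= 0.05 & object$fdr_table$n_called > 0
    delta <- if (any(ok)) min(object$fdr_table$delta[ok]) else NA_real_
  }
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$dbar, y = .data$d)) +
    ggplot2::geom_point(size = 0.6, alpha = 0.6) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "grey40") +
    ggplot2::labs(x = "expected d (permutation null)", y = "observed d",
                  title = sprintf("SAM plot (s0 = %.3g)", object$s0))
  if (!is.na(delta)) {
    p <- p +
      ggplot2::geom_abline(slope = 1, intercept = c(-delta, delta),
                           linetype = "dashed", colour = "firebrick")
  }
  p
}

#' Volcano-style view of a consensus result
#'
#' Plots every probe's full-data fold change against its q-value, with
#' consensus survivors highlighted.
#'
#' @param object A `consensus_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.consensus_result <- function(object, ...) {
  full_id <- if (object$params$include_full_dataset) "full" else
    object$runs$run_id[1]
  base <- object$trace %>%
    filter(.data$run_id == full_id) %>%
    mutate(consensus = .data$probe_id %in% object$table$probe_id)
  ggplot2::ggplot(base,
                  ggplot2::aes(x = sign(.data$fold_change) *
                                 log2(abs(.data$fold_change)),
                               y = -log10(pmax(.data$q_value, 1e-4)),
                               colour = .data$consensus)) +
    ggplot2::geom_point(size = 0.8, alpha = 0.7) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60",
                                            `TRUE` = "firebrick")) +
    ggplot2::labs(x = "signed log2 |fold change|", y = "-log10 q",
                  colour = "consensus",
                  title = sprintf("%d consensus probes (|FC| >= %.2f, q <= %g)",
                                  nrow(object$table), object$params$fc_min,
                                  object$params$fdr_max))
}

#' MA plot of one array before and after dye correction
#'
#' @param corrected Output tibble of [lowess_dye_correct()].
#' @return A ggplot object with raw ratios, the fitted trend and the
#'   corrected ratios.
#' @export
plot_ma <- function(corrected) {
  long <- dplyr::bind_rows(
    tibble(A = corrected$A, M = corrected$M_raw, which = "raw"),
    tibble(A = corrected$A, M = corrected$M, which = "corrected")
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$A, y = .data$M)) +
    ggplot2::geom_point(size = 0.4, alpha = 0.4) +
    ggplot2::geom_line(data = tibble(A = sort(corrected$A),
                                     M = corrected$trend[order(corrected$A)],
                                     which = "raw"),
                       colour = "firebrick") +
    ggplot2::geom_hline(yintercept = 0, colour = "grey40") +
    ggplot2::facet_wrap(~which, ncol = 1) +
    ggplot2::labs(x = "A = mean log2 intensity", y = "M = log2(Cy5/Cy3)")
}

#' Heatmap of consensus probes with UPGMA-ordered samples
#'
#' Row-standardized (z-score) expression of the consensus probes, sample
#' columns ordered by the UPGMA dendrogram on correlation distance —
#' the usual signature display (red above, green below the probe mean).
#'
#' @param expr An [expr_matrix()] or matrix.
#' @param consensus A `consensus_result`.
#' @return A ggplot object.
#' @export
plot_consensus_heatmap <- function(expr, consensus) {
  mat <- if (inherits(expr, "expr_matrix")) expr$values else as.matrix(expr)
  sig <- consensus$table$probe_id
  if (length(sig) < 1) abort("empty consensus: nothing to plot")
  z <- zscore_matrix(mat[sig, , drop = FALSE])
  ord <- upgma_order(mat[sig, , drop = FALSE])$order
  df <- as_tibble(z, rownames = "probe_id") %>%
    tidyr::pivot_longer(-"probe_id", names_to = "sample_id",
                        values_to = "z") %>%
    mutate(sample_id = factor(.data$sample_id, levels = ord),
           probe_id = factor(.data$probe_id, levels = rev(sig)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$sample_id, y = .data$probe_id,
                                   fill = .data$z)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "green4", mid = "black",
                                  high = "red2", midpoint = 0) +
    ggplot2::labs(x = NULL, y = NULL, fill = "z") +
    ggplot2::theme(axis.text.y = ggplot2::element_blank(),
                   axis.ticks.y = ggplot2::element_blank())
}

#' Bar chart comparing qPCR and array signed fold changes
#'
#' @param comparison Output of [compare_with_array()].
#' @return A ggplot object.
#' @export
plot_qpcr_comparison <- function(comparison) {
  df <- comparison$table %>%
    select("gene", qPCR = "qpcr_signed_fc", array = "array_fold_change") %>%
    tidyr::pivot_longer(-"gene", names_to = "assay", values_to = "signed_fc")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$gene, y = .data$signed_fc,
                                   fill = .data$assay)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_hline(yintercept = 0) +
    ggplot2::labs(x = NULL, y = "signed fold change", fill = NULL)
}
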