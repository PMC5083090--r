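#' Contrast co-elution correlations between pair sets
#'
#' Two-dimensional histograms of the maximal SEC versus HIC CC values, one
#' facet per pair set. Sets of genuine complex members pile up in the
#' top-right corner (high CC in both dimensions); random co-occurring pairs
#' spread over the whole plane, with the -1 sentinel rows collecting pairs
#' seen in only one dimension.
#'
#' @param features Feature tibble from [assemble_features()].
#' @param pair_sets Named list of pair tibbles to contrast; the full feature
#'   table is shown as `"all co-occurring"` when the list is empty.
#' @param bins Number of bins per axis.
#' @return A ggplot object.
#' @export
plot_cc_contrast <- function(features, pair_sets = list(), bins = 20) {
  if (length(pair_sets) == 0) {
    pair_sets <- list("all co-occurring" = features)
  }
  long <- purrr::imap_dfr(pair_sets, function(set, nm) {
    semi_join(features, as_pair_set(set),
              by = c("protein_a", "protein_b")) |>
      mutate(set = nm)
  })
  ggplot2::ggplot(long, ggplot2::aes(x = .data$cc_sec, y = .data$cc_hic)) +
    ggplot2::geom_bin2d(bins = bins) +
    ggplot2::scale_fill_viridis_c(trans = "log10") +
    ggplot2::facet_wrap(ggplot2::vars(.data$set)) +
    ggplot2::labs(x = "max CC (SEC)", y = "max CC (HIC)",
                  fill = "pairs") +
    ggplot2::theme_minimal()
}

#' Plot PPI fold enrichments
#'
#' @param enrichments Tibble of rows from [ppi_fold_enrichment()].
#' @return A ggplot object (horizontal bars, reference line at 1).
#' @export
plot_fold_enrichment <- function(enrichments) {
  ggplot2::ggplot(enrichments,
                  ggplot2::aes(x = .data$fold_enrichment,
                               y = stats::reorder(.data$set_name,
                                                  .data$fold_enrichment))) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed") +
    ggplot2::labs(x = "PPI fold enrichment", y = NULL) +
    ggplot2::theme_minimal()
}

#' FDR staircase of a prediction set
#'
#' Gold-count FDR as a function of the score threshold, with the chosen
#' threshold and the target FDR marked.
#'
#' @param object A `ppi_predictions`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ppi_predictions <- function(object, ...) {
  ggplot2::ggplot(object$curve,
                  ggplot2::aes(x = .data$threshold, y = .data$fdr)) +
    ggplot2::geom_step() +
    ggplot2::geom_hline(yintercept = object$target_fdr,
                        linetype = "dashed", color = "grey40") +
    ggplot2::geom_vline(xintercept = object$threshold,
                        color = "firebrick") +
    ggplot2::scale_x_reverse() +
    ggplot2::labs(x = "score threshold", y = "estimated FDR") +
    ggplot2::theme_minimal()
}
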