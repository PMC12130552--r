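#' Volcano plot of gene-pair interaction scores
#'
#' dLFC against -log10 adjusted p at the scoring timepoint, coloured by the
#' final call. With several replicates the replicate-averaged dLFC and the
#' worst (largest) padj per pair are shown — the quantities the unanimity
#' rule acts on.
#'
#' @param object A `gi_result` from [score_screen()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.gi_result <- function(object, ...) {
  calls <- object$calls
  thr <- object$config$dlfc_threshold
  ggplot2::ggplot(calls,
                  ggplot2::aes(x = .data$dlfc,
                               y = -log10(pmax(.data$padj_worst, 1e-300)),
                               colour = .data$call_filtered)) +
    ggplot2::geom_point(alpha = 0.7, na.rm = TRUE) +
    ggplot2::geom_vline(xintercept = c(-thr, thr), linetype = "dashed") +
    ggplot2::geom_hline(yintercept = -log10(object$config$alpha),
                        linetype = "dashed") +
    ggplot2::scale_colour_manual(values = c(
      SYNTHETIC_LETHAL = "#c0392b", SYNTHETIC_VIABLE = "#2e86c1",
      NONE = "grey60"), name = "call") +
    ggplot2::labs(x = "dLFC (log2)", y = "-log10 padj (worst replicate)") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Time-course of gene-pair dLFC
#'
#' Replicate-mean dLFC (with range) per timepoint for selected gene pairs;
#' the week1 -> week3 change this shows is what the time-course filter tests.
#'
#' @param scores Output of [score_gene_pairs()] (all timepoints retained).
#' @param pairs Optional two-column data frame (`gene_a`, `gene_b`) selecting
#'   pairs; default: the 9 pairs with largest |dLFC| at the latest timepoint.
#' @return A ggplot object.
#' @export
plot_timecourse <- function(scores, pairs = NULL) {
  if (is.null(pairs)) {
    last <- max(scores$timepoint_weeks)
    pairs <- scores |>
      dplyr::filter(.data$timepoint_weeks == last) |>
      dplyr::group_by(.data$gene_a, .data$gene_b) |>
      dplyr::summarise(a = abs(mean(.data$dlfc)), .groups = "drop") |>
      dplyr::slice_max(.data$a, n = 9, with_ties = FALSE) |>
      dplyr::select("gene_a", "gene_b")
  }
  d <- scores |>
    dplyr::inner_join(tibble::as_tibble(pairs), by = c("gene_a", "gene_b")) |>
    dplyr::group_by(.data$gene_a, .data$gene_b, .data$condition,
                    .data$timepoint_weeks) |>
    dplyr::summarise(dlfc_mean = mean(.data$dlfc),
                     dlfc_min = min(.data$dlfc), dlfc_max = max(.data$dlfc),
                     .groups = "drop") |>
    dplyr::mutate(pair = paste(.data$gene_a, .data$gene_b, sep = "-"))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$timepoint_weeks,
                                  y = .data$dlfc_mean,
                                  colour = .data$condition)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey70") +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$dlfc_min,
                                      ymax = .data$dlfc_max,
                                      fill = .data$condition),
                         alpha = 0.2, colour = NA) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::facet_wrap(~pair) +
    ggplot2::labs(x = "weeks after transduction", y = "dLFC (log2)") +
    ggplot2::theme_minimal()
}
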