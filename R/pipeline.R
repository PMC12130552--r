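#' Run the full scoring pipeline on one screen
#'
#' Depth normalization, OR x OR-anchored observed LFCs, OR-pairing single-KO
#' estimates, additive expected effects and dLFC, gene-pair paired t-tests
#' with BKY adjustment, interaction calls, and the saturation / time-course /
#' essential-gene filters — in one call.
#'
#' @param counts Long count tibble (from [read_counts()] or a
#'   [simulate_counts()] result's `counts`).
#' @param design A [gi_design].
#' @param meta Sample metadata.
#' @param config A [scoring_config()].
#' @param filters A [filter_config()].
#' @param pseudocount Passed to [compute_lfc_obs()].
#' @return An object of class `gi_result`: a list with `lfc`, `guide_effects`,
#'   `gene_ko`, `dlfc`, `scores`, `calls`, `config`, `filters`, and `report`
#'   (run metadata: offsets, family sizes, filter counts).
#' @export
score_screen <- function(counts, design, meta, config = scoring_config(),
                         filters = filter_config(), pseudocount = 1) {
  meta <- validate_sample_meta(meta)
  cpm <- normalize_depth(counts)
  lfc <- compute_lfc_obs(cpm, design, meta, pseudocount = pseudocount)
  effects <- estimate_guide_effects(lfc, design)
  gene_ko <- gene_level_single_ko(effects, design)
  dlfc <- compute_expected(lfc, effects, design)
  scores <- score_gene_pairs(dlfc, design, meta, config, gene_ko = gene_ko)
  calls <- call_interactions(scores, config)

  gene_ko_screen <- gene_ko |>
    dplyr::inner_join(dplyr::select(meta, "sample_id", "screen_id",
                                    "timepoint_weeks"), by = "sample_id") |>
    dplyr::filter(.data$timepoint_weeks == config$scoring_timepoint_weeks) |>
    dplyr::group_by(.data$screen_id, .data$gene_id) |>
    dplyr::summarise(lfc_single_gene = mean(.data$lfc_single_gene),
                     .groups = "drop")
  calls <- apply_filters(calls, scores, filters,
                         gene_ko_by_screen = gene_ko_screen)

  fam_sizes <- scores |>
    dplyr::filter(!is.na(.data$p)) |>
    dplyr::count(.data$screen_id, .data$condition, .data$replicate,
                 .data$timepoint_weeks, name = "family_size")
  report <- list(
    lfc_offsets = attr(lfc, "offsets"),
    dlfc_offsets = attr(dlfc, "dlfc_offsets"),
    pseudocount = pseudocount,
    family_sizes = fam_sizes,
    n_saturation_filtered = sum(calls$saturation_filtered),
    n_timecourse_filtered = sum(calls$timecourse_filtered),
    n_essential_flagged = sum(calls$essential_flag))

  structure(list(lfc = lfc, guide_effects = effects, gene_ko = gene_ko,
                 dlfc = dlfc, scores = scores, calls = calls,
                 config = config, filters = filters, report = report),
            class = "gi_result")
}

#' @export
print.gi_result <- function(x, ...) {
  n_call <- sum(x$calls$call_filtered != .call_none)
  cat("<gi_result> ", dplyr::n_distinct(paste(x$calls$gene_a,
                                              x$calls$gene_b)),
      " gene pairs tested; ", n_call, " interactions after filters (",
      sum(x$calls$call_filtered == .call_lethal), " lethal, ",
      sum(x$calls$call_filtered == .call_viable), " viable)\n", sep = "")
  invisible(x)
}

#' Tidy an interaction-scoring result
#'
#' @param x A `gi_result` from [score_screen()].
#' @param level `"calls"` (default): one row per gene pair with the final
#'   call and filter provenance; `"scores"`: per-replicate test statistics.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.gi_result <- function(x, level = c("calls", "scores"), ...) {
  level <- match.arg(level)
  if (level == "calls") x$calls else x$scores
}

#' One-row summary of an interaction-scoring result
#'
#' @param x A `gi_result`.
#' @param ... Unused.
#' @return A one-row tibble: pairs tested, calls before/after filters, lethal
#'   and viable counts, filter counts.
#' @export
glance.gi_result <- function(x, ...) {
  tibble::tibble(
    n_pairs = nrow(x$calls),
    n_called_raw = sum(x$calls$call != .call_none),
    n_called = sum(x$calls$call_filtered != .call_none),
    n_lethal = sum(x$calls$call_filtered == .call_lethal),
    n_viable = sum(x$calls$call_filtered == .call_viable),
    n_saturation_filtered = x$report$n_saturation_filtered,
    n_timecourse_filtered = x$report$n_timecourse_filtered,
    n_essential_flagged = x$report$n_essential_flagged,
    alpha = x$config$alpha,
    dlfc_threshold = x$config$dlfc_threshold,
    scoring_timepoint_weeks = x$config$scoring_timepoint_weeks,
    mode = x$config$mode)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
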