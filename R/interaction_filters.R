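#' Filter configuration
#'
#' Defaults follow the scoring scheme's printed thresholds: viable calls with
#' an additive expectation below -0.3 log2 are candidates for saturation
#' filtering; calls whose dLFC changed by less than 0.1 log2 between the
#' reference week and the scoring week are removed as likely transduction
#' artifacts; genes with a single-KO LFC below -2 in every provided screen are
#' flagged essential.
#'
#' @param saturation_lfc_exp_threshold Default -0.3 (log2).
#' @param timecourse_min_delta Default 0.1 (log2).
#' @param timecourse_reference_weeks Default 1.
#' @param timecourse_directional Require the week1->week3 change to move in the
#'   direction of the called effect? Off by default (literal absolute-change
#'   rule).
#' @param essential_single_ko_threshold Default -2 (log2).
#' @param exclude Which flags remove a call (set its `call` to `NONE` in the
#'   filtered view) rather than annotate only. Essential flagging is
#'   annotation-only by default.
#' @return A list of class `filter_config`.
#' @export
filter_config <- function(saturation_lfc_exp_threshold = -0.3,
                          timecourse_min_delta = 0.1,
                          timecourse_reference_weeks = 1,
                          timecourse_directional = FALSE,
                          essential_single_ko_threshold = -2,
                          exclude = c("saturation", "timecourse")) {
  stopifnot(timecourse_min_delta > 0)
  structure(list(
    saturation_lfc_exp_threshold = saturation_lfc_exp_threshold,
    timecourse_min_delta = timecourse_min_delta,
    timecourse_reference_weeks = timecourse_reference_weeks,
    timecourse_directional = timecourse_directional,
    essential_single_ko_threshold = essential_single_ko_threshold,
    exclude = exclude), class = "filter_config")
}

#' Saturation filter for synthetic-viable calls
#'
#' When both partners are strongly deleterious, cells carrying the double KO
#' are already dying or arrested and cannot show the summed effect, producing
#' spurious positive dLFC. A synthetic-viable call is therefore removed when
#' the additive expectation is below the threshold (default -0.3) AND the
#' observed double-KO LFC is strictly below both single-KO LFCs (no genuine
#' rescue). Lethal calls and non-calls are never touched; undefined single-KO
#' values retain the call.
#'
#' @param call Character vector of call states.
#' @param lfc_obs,lfc_exp Pair-level observed / expected LFC (log2).
#' @param single_ko_a,single_ko_b Gene-level single-KO LFCs (log2).
#' @param config A [filter_config()].
#' @return Logical vector: `TRUE` where the call is filtered out.
#' @export
saturation_filter <- function(call, lfc_obs, lfc_exp, single_ko_a,
                              single_ko_b, config = filter_config()) {
  out <- call == .call_viable &
    !is.na(lfc_exp) & lfc_exp < config$saturation_lfc_exp_threshold &
    !is.na(single_ko_a) & !is.na(single_ko_b) &
    lfc_obs < single_ko_a & lfc_obs < single_ko_b
  out[is.na(out)] <- FALSE
  out
}

#' Time-course consistency filter
#'
#' Interactions whose dLFC did not change between the reference week (default
#' week 1) and the scoring week by at least `timecourse_min_delta` are removed:
#' a guide-pair abundance shift already present at week 1 and constant
#' thereafter is indistinguishable from variable transduction efficiency.
#' Applies to both call signs.
#'
#' @param dlfc_scoring,dlfc_reference Replicate-averaged pair dLFC at the
#'   scoring and reference weeks.
#' @param call Call states (only needed for the directional variant).
#' @param config A [filter_config()].
#' @return Logical vector: `TRUE` where the call is filtered out. `NA`
#'   reference values never filter (the filter is skipped, not failed).
#' @export
timecourse_filter <- function(dlfc_scoring, dlfc_reference, call = NULL,
                              config = filter_config()) {
  delta <- dlfc_scoring - dlfc_reference
  out <- !is.na(delta) & abs(delta) < config$timecourse_min_delta
  if (config$timecourse_directional && !is.null(call)) {
    # change must move in the called direction (more negative for lethal,
    # more positive for viable); otherwise filtered as well
    wrong_way <- !is.na(delta) &
      ((call == .call_lethal & delta > -config$timecourse_min_delta) |
         (call == .call_viable & delta < config$timecourse_min_delta))
    out <- out | (call %in% c(.call_lethal, .call_viable) & wrong_way)
  }
  out
}

#' Flag interactions touching screen-essential genes
#'
#' A gene is essential when its single-KO LFC falls below the threshold
#' (default -2) in ALL provided screens; calls touching such a gene are
#' flagged. Whether flagged calls are also excluded is decided by
#' `filter_config(exclude = ...)`.
#'
#' @param calls An interaction-call tibble (with `gene_a`, `gene_b`).
#' @param gene_ko_by_screen Tibble with columns `screen_id`, `gene_id`,
#'   `lfc_single_gene` (gene-level single-KO LFC at the scoring timepoint,
#'   one row per gene per screen); typically stacked from
#'   [gene_level_single_ko()] outputs of one or more screens.
#' @param config A [filter_config()].
#' @return `calls` with `essential_flag` set.
#' @export
flag_essential <- function(calls, gene_ko_by_screen,
                           config = filter_config()) {
  ess <- essential_genes(gene_ko_by_screen, config)
  calls$essential_flag <- calls$gene_a %in% ess | calls$gene_b %in% ess
  calls
}

#' Genes essential in every provided screen
#'
#' @inheritParams flag_essential
#' @return Character vector of gene ids with single-KO LFC below the
#'   threshold in all screens where they were measured in `gene_ko_by_screen`.
#' @export
essential_genes <- function(gene_ko_by_screen, config = filter_config()) {
  n_screens <- length(unique(gene_ko_by_screen$screen_id))
  gene_ko_by_screen |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::summarise(
      all_below = dplyr::n() == .env$n_screens &
        all(.data$lfc_single_gene < .env$config$essential_single_ko_threshold),
      .groups = "drop") |>
    dplyr::filter(.data$all_below) |>
    dplyr::pull(.data$gene_id)
}

#' Apply all post-hoc filters to an interaction-call table
#'
#' Sets the three provenance flags (`saturation_filtered`,
#' `timecourse_filtered`, `essential_flag`) and adds `call_filtered`: the call
#' after removing interactions disqualified by the flags named in
#' `config$exclude`. The flags are pure predicates on the annotated fields, so
#' they are order-independent and the flagged table remains a superset view of
#' the final edge list.
#'
#' @param calls Output of [call_interactions()] (needs `lfc_obs`, `lfc_exp`,
#'   `single_ko_a`, `single_ko_b` columns for the saturation filter).
#' @param scores Output of [score_gene_pairs()], used to look up the
#'   replicate-averaged dLFC at the reference week. If the reference week is
#'   absent the time-course filter is skipped with a warning.
#' @param config A [filter_config()].
#' @param gene_ko_by_screen Optional; see [flag_essential()]. When `NULL`,
#'   essential flagging is skipped.
#' @return `calls` with flags and `call_filtered`.
#' @export
apply_filters <- function(calls, scores, config = filter_config(),
                          gene_ko_by_screen = NULL) {
  if (all(c("single_ko_a", "single_ko_b") %in% names(calls))) {
    calls$saturation_filtered <- saturation_filter(
      calls$call, calls$lfc_obs, calls$lfc_exp,
      calls$single_ko_a, calls$single_ko_b, config)
  } else {
    warn("calls lack single-KO columns; saturation filter skipped")
  }

  ref_week <- config$timecourse_reference_weeks
  if (ref_week %in% scores$timepoint_weeks) {
    ref <- scores |>
      dplyr::filter(.data$timepoint_weeks == ref_week) |>
      dplyr::group_by(.data$screen_id, .data$condition, .data$gene_a,
                      .data$gene_b) |>
      dplyr::summarise(dlfc_reference = mean(.data$dlfc), .groups = "drop")
    calls <- dplyr::left_join(calls, ref,
                              by = c("screen_id", "condition", "gene_a",
                                     "gene_b"))
    calls$timecourse_filtered <- calls$call != .call_none &
      timecourse_filter(calls$dlfc, calls$dlfc_reference, calls$call, config)
  } else {
    warn(paste0("reference week ", ref_week,
                " absent from scores; time-course filter skipped"))
  }

  if (!is.null(gene_ko_by_screen)) {
    calls <- flag_essential(calls, gene_ko_by_screen, config)
  }

  drop <- rep(FALSE, nrow(calls))
  if ("saturation" %in% config$exclude) {
    drop <- drop | calls$saturation_filtered
  }
  if ("timecourse" %in% config$exclude) {
    drop <- drop | calls$timecourse_filtered
  }
  if ("essential" %in% config$exclude) drop <- drop | calls$essential_flag
  calls$call_filtered <- ifelse(drop, .call_none, calls$call)
  calls
}
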