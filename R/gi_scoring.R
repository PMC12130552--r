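#' Scoring configuration
#'
#' @param mode `"per_replicate"`: each replicate is tested separately and a
#'   pair is called only if every replicate is independently significant.
#'   `"merged"`: constructs x replicates are concatenated as pairs and tested
#'   once, at a more stringent alpha.
#' @param alpha FDR level for calling; defaults to 0.1 for per-replicate mode
#'   and 0.005 for merged mode.
#' @param dlfc_threshold Minimum |dLFC| (log2 units) for a call. Default 0.3.
#' @param scoring_timepoint_weeks Timepoint used for calling. Default week 3.
#' @param min_constructs Minimum guide pairs per gene pair for a test;
#'   smaller sets are recorded as untestable (`NA`), never silently dropped.
#' @param include_self_pairs Score same-gene "pairs"? Default `FALSE`.
#' @return A list of class `scoring_config`.
#' @export
scoring_config <- function(mode = c("per_replicate", "merged"),
                           alpha = NULL,
                           dlfc_threshold = 0.3,
                           scoring_timepoint_weeks = 3,
                           min_constructs = 2,
                           include_self_pairs = FALSE) {
  mode <- match.arg(mode)
  if (is.null(alpha)) alpha <- if (mode == "per_replicate") 0.1 else 0.005
  stopifnot(alpha > 0, alpha < 1, dlfc_threshold > 0, min_constructs >= 2)
  structure(list(mode = mode, alpha = alpha,
                 dlfc_threshold = dlfc_threshold,
                 scoring_timepoint_weeks = scoring_timepoint_weeks,
                 min_constructs = min_constructs,
                 include_self_pairs = include_self_pairs),
            class = "scoring_config")
}

#' Paired t-test of observed versus expected LFC
#'
#' Classic two-tailed paired Student t-test on the per-construct differences
#' `obs - exp` (via [stats::t.test()]). Degenerate zero-variance inputs follow
#' a fixed convention: identically zero differences give `p = 1` (no evidence
#' of interaction), constant nonzero differences give `p = 0` with a
#' degenerate-variance flag.
#'
#' @param obs,exp Numeric vectors of equal length, paired by construct.
#' @return A one-row tibble: `n`, `t`, `df`, `p`, `degenerate`.
#' @export
paired_test <- function(obs, exp) {
  stopifnot(length(obs) == length(exp))
  keep <- !is.na(obs) & !is.na(exp)
  d <- obs[keep] - exp[keep]
  n <- length(d)
  if (n < 2) {
    return(tibble::tibble(n = n, t = NA_real_, df = NA_real_, p = NA_real_,
                          degenerate = FALSE))
  }
  if (isTRUE(all.equal(stats::sd(d), 0)) || stats::sd(d) == 0) {
    if (all(d == 0)) {
      return(tibble::tibble(n = n, t = 0, df = n - 1, p = 1,
                            degenerate = TRUE))
    }
    return(tibble::tibble(n = n, t = sign(mean(d)) * Inf, df = n - 1, p = 0,
                          degenerate = TRUE))
  }
  tt <- t.test(obs[keep], exp[keep], paired = TRUE)
  tibble::tibble(n = n, t = unname(tt$statistic),
                 df = unname(tt$parameter), p = tt$p.value,
                 degenerate = FALSE)
}

# BH-style step-up adjusted values with an effective number of hypotheses m0:
# adj_i = min_{j >= i} m0 * p_(j) / j, returned in input order.
.bh_adjust_m0 <- function(p, m0) {
  m <- length(p)
  o <- order(p, decreasing = TRUE)
  i <- m:1L
  pmin(1, cummin(m0 * p[o] / i))[order(o)]
}

#' Two-stage step-up FDR adjustment (Benjamini-Krieger-Yekutieli)
#'
#' Stage 1 runs linear (BH) step-up at level `q' = q / (1 + q)`; the rejection
#' count r1 estimates the number of true nulls as `m0 = m - r1`. Stage 2 reruns
#' linear step-up with multiplier `m0`. Adjusted values are scaled so that
#' thresholding `padj <= q` reproduces the two-stage rejection set at level
#' `q`; because `m0` depends on `q`, the adjusted values are valid for the
#' given `q` only. Unlike plain BH, adjusted values may fall below the raw p
#' (when `m0 < m`); they are monotone in p-rank.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @param q Target FDR level. Default 0.1.
#' @return Adjusted values in input order, with attributes `m0` and `q`.
#' @export
bky_adjust <- function(p, q = 0.1) {
  if (any(is.na(p)) || any(p < 0 | p > 1)) {
    abort("p-values must lie in [0, 1] with no NA",
          class = "gipairs_data_error")
  }
  stopifnot(q > 0, q < 1)
  m <- length(p)
  if (m == 0) return(numeric(0))
  q1 <- q / (1 + q)
  r1 <- sum(.bh_adjust_m0(p, m) <= q1)
  m0 <- m - r1
  padj <- if (m0 == 0) rep(0, m) else pmin(1, (1 + q) * .bh_adjust_m0(p, m0))
  attr(padj, "m0") <- m0
  attr(padj, "q") <- q
  padj
}

#' Score gene pairs: aggregate construct dLFC, test, and adjust
#'
#' For every gene pair, the observed and additive-expected LFCs of all guide
#' pairs targeting it are compared with a paired t-test, per replicate and
#' timepoint (`per_replicate` mode) or pooled across replicates (`merged`).
#' The pair dLFC is the mean per-construct difference, identical to
#' `mean(lfc_obs) - mean(lfc_exp)` over the same construct set. P-values are
#' BKY-adjusted within the family of all pairs tested in the same screen /
#' condition / replicate / timepoint.
#'
#' @param dlfc Output of [compute_expected()].
#' @param design A [gi_design].
#' @param meta Validated sample metadata.
#' @param config A [scoring_config()].
#' @param gene_ko Optional output of [gene_level_single_ko()]; if given, the
#'   replicate-averaged single-KO LFCs of both genes are attached per row.
#' @return Tibble with one row per gene pair per replicate (or merged) per
#'   timepoint: `screen_id`, `condition`, `replicate`, `timepoint_weeks`,
#'   `gene_a`, `gene_b`, `n_constructs`, `lfc_obs`, `lfc_exp`, `dlfc`, `t`,
#'   `p`, `padj`, `degenerate` (+ `single_ko_a`/`_b` when `gene_ko` is given).
#' @export
score_gene_pairs <- function(dlfc, design, meta, config = scoring_config(),
                             gene_ko = NULL) {
  meta <- validate_sample_meta(meta)
  cons <- design$constructs

  tt <- dlfc |>
    dplyr::inner_join(dplyr::select(cons, "construct_id", "gene_pos1",
                                    "gene_pos2", "role_pos1", "role_pos2"),
                      by = "construct_id") |>
    dplyr::filter(.data$role_pos1 == .role_target,
                  .data$role_pos2 == .role_target) |>
    dplyr::inner_join(dplyr::select(meta, "sample_id", "screen_id",
                                    "condition", "replicate",
                                    "timepoint_weeks"),
                      by = "sample_id") |>
    dplyr::filter(!is.na(.data$dlfc))
  if (!config$include_self_pairs) {
    tt <- dplyr::filter(tt, .data$gene_pos1 != .data$gene_pos2)
  }
  tt <- tt |>
    dplyr::mutate(gene_a = pmin(.data$gene_pos1, .data$gene_pos2),
                  gene_b = pmax(.data$gene_pos1, .data$gene_pos2))

  # check every replicate carries the scoring timepoint
  have <- meta |>
    dplyr::filter(.data$sample_kind == .kind_gdna) |>
    dplyr::group_by(.data$screen_id, .data$condition, .data$replicate) |>
    dplyr::summarise(
      ok = any(.data$timepoint_weeks == config$scoring_timepoint_weeks),
      .groups = "drop")
  if (any(!have$ok)) {
    bad <- have[!have$ok, ]
    abort(paste0("replicate(s) missing the scoring timepoint (week ",
                 config$scoring_timepoint_weeks, "): ",
                 paste(paste0(bad$screen_id, "/", bad$condition, "/rep",
                              bad$replicate), collapse = ", ")),
          class = "gipairs_data_error")
  }

  grp <- c("screen_id", "condition", "timepoint_weeks", "gene_a", "gene_b")
  if (config$mode == "per_replicate") grp <- c(grp, "replicate")

  scores <- tt |>
    dplyr::group_by(dplyr::across(dplyr::all_of(grp))) |>
    dplyr::summarise(
      n_constructs = dplyr::n(),
      test = list(paired_test(.data$lfc_obs, .data$lfc_exp)),
      dlfc = mean(.data$lfc_obs) - mean(.data$lfc_exp),
      lfc_obs = mean(.data$lfc_obs),
      lfc_exp = mean(.data$lfc_exp),
      .groups = "drop") |>
    tidyr::unnest("test", names_sep = "_") |>
    dplyr::rename(t = "test_t", df = "test_df", p = "test_p",
                  degenerate = "test_degenerate") |>
    dplyr::select(-"test_n") |>
    dplyr::mutate(p = ifelse(.data$n_constructs < config$min_constructs,
                             NA_real_, .data$p))
  if (config$mode == "merged") scores$replicate <- NA_integer_

  # multiplicity family: all pairs tested together
  fam <- c("screen_id", "condition", "timepoint_weeks")
  if (config$mode == "per_replicate") fam <- c(fam, "replicate")
  scores <- scores |>
    dplyr::group_by(dplyr::across(dplyr::all_of(fam))) |>
    dplyr::mutate(padj = {
      ok <- !is.na(.data$p)
      out <- rep(NA_real_, dplyr::n())
      if (any(ok)) out[ok] <- as.numeric(bky_adjust(.data$p[ok],
                                                    q = config$alpha))
      out
    }) |>
    dplyr::ungroup()

  if (!is.null(gene_ko)) {
    ko <- gene_ko |>
      dplyr::inner_join(dplyr::select(meta, "sample_id", "screen_id",
                                      "condition", "timepoint_weeks"),
                        by = "sample_id") |>
      dplyr::group_by(.data$gene_id, .data$screen_id, .data$condition,
                      .data$timepoint_weeks) |>
      dplyr::summarise(single_ko = mean(.data$lfc_single_gene),
                       .groups = "drop")
    scores <- scores |>
      dplyr::left_join(dplyr::rename(ko, gene_a = "gene_id",
                                     single_ko_a = "single_ko"),
                       by = c("gene_a", "screen_id", "condition",
                              "timepoint_weeks")) |>
      dplyr::left_join(dplyr::rename(ko, gene_b = "gene_id",
                                     single_ko_b = "single_ko"),
                       by = c("gene_b", "screen_id", "condition",
                              "timepoint_weeks"))
  }

  front <- c("screen_id", "condition", "replicate", "timepoint_weeks",
             "gene_a", "gene_b")
  dplyr::relocate(scores, dplyr::all_of(front))
}

#' Call synthetic-lethal / synthetic-viable interactions
#'
#' At the scoring timepoint, a pair is called if every tested unit -- each
#' replicate in `per_replicate` mode, the single merged test in `merged` mode
#' -- is independently significant AND beyond the |dLFC| threshold with a
#' common sign. This conservative unanimity makes the per-replicate call set a
#' subset of every individual replicate's call set at the same thresholds.
#' The reported dLFC is the replicate mean; its sign gives the direction:
#' negative `SYNTHETIC_LETHAL`, positive `SYNTHETIC_VIABLE`. Filter
#' provenance flags are initialised here and populated by [apply_filters()].
#'
#' @param scores Output of [score_gene_pairs()].
#' @param config The [scoring_config()] used to produce `scores`.
#' @return Tibble with one row per gene pair per screen/condition: `call`,
#'   `dlfc`, `padj_worst`, `n_replicates`, mean `lfc_obs` / `lfc_exp`, filter
#'   flags (`saturation_filtered`, `timecourse_filtered`, `essential_flag`),
#'   and single-KO columns when present in `scores`.
#' @export
call_interactions <- function(scores, config = scoring_config()) {
  sc <- dplyr::filter(scores,
                      .data$timepoint_weeks == config$scoring_timepoint_weeks)
  has_ko <- all(c("single_ko_a", "single_ko_b") %in% names(sc))

  calls <- sc |>
    dplyr::group_by(.data$screen_id, .data$condition, .data$gene_a,
                    .data$gene_b) |>
    dplyr::summarise(
      n_replicates = dplyr::n(),
      n_constructs = sum(.data$n_constructs),
      lfc_obs = mean(.data$lfc_obs),
      lfc_exp = mean(.data$lfc_exp),
      dlfc = mean(.data$dlfc),
      padj_worst = suppressWarnings(max(.data$padj)),
      significant = all(!is.na(.data$padj) & .data$padj < config$alpha) &
        all(abs(.data$dlfc) > config$dlfc_threshold) &
        dplyr::n_distinct(sign(.data$dlfc)) == 1,
      dplyr::across(dplyr::any_of(c("single_ko_a", "single_ko_b")), mean),
      .groups = "drop") |>
    dplyr::mutate(
      padj_worst = ifelse(is.finite(.data$padj_worst), .data$padj_worst,
                          NA_real_),
      call = dplyr::case_when(
        .data$significant & .data$dlfc < -config$dlfc_threshold ~ .call_lethal,
        .data$significant & .data$dlfc > config$dlfc_threshold ~ .call_viable,
        TRUE ~ .call_none),
      saturation_filtered = FALSE,
      timecourse_filtered = FALSE,
      essential_flag = FALSE) |>
    dplyr::select(-"significant")

  front <- c("screen_id", "condition", "gene_a", "gene_b", "call", "dlfc",
             "padj_worst")
  dplyr::relocate(calls, dplyr::all_of(front))
}
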