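#' Estimate per-guide single-knockout effects from OR pairings
#'
#' A guide's single-KO effect at a position, in a sample, is the average
#' observed LFC of the constructs where it sits at that position paired with an
#' olfactory-receptor control guide at the other position. Effects are
#' position- (orientation-) specific. Guides without any OR pairing at a
#' position get no record there and propagate as undefined downstream.
#'
#' @param lfc Output of [compute_lfc_obs()].
#' @param design A [gi_design].
#' @param stat Averaging statistic, `"mean"` (default) or `"median"`.
#' @return Tibble (`guide_id`, `position` in `"pos1"`/`"pos2"`, `sample_id`,
#'   `lfc_single`, `n_or_pairs`).
#' @export
estimate_guide_effects <- function(lfc, design, stat = c("mean", "median")) {
  stat <- match.arg(stat)
  agg <- if (stat == "mean") mean else median
  cons <- design$constructs

  with_or2 <- cons |>
    dplyr::filter(.data$role_pos2 == .role_or) |>
    dplyr::select("construct_id", guide_id = "guide_pos1") |>
    dplyr::mutate(position = "pos1")
  with_or1 <- cons |>
    dplyr::filter(.data$role_pos1 == .role_or) |>
    dplyr::select("construct_id", guide_id = "guide_pos2") |>
    dplyr::mutate(position = "pos2")

  dplyr::bind_rows(with_or2, with_or1) |>
    dplyr::inner_join(lfc, by = "construct_id",
                      relationship = "many-to-many") |>
    dplyr::group_by(.data$guide_id, .data$position, .data$sample_id) |>
    dplyr::summarise(lfc_single = agg(.data$lfc_obs),
                     n_or_pairs = dplyr::n(), .groups = "drop")
}

#' Additive expected double-KO effects and dLFC
#'
#' Under additivity the expected double-KO effect of a construct is the sum of
#' its two guides' single-KO effects in their respective positions:
#' `lfc_exp = lfc_single(guide_pos1, pos1) + lfc_single(guide_pos2, pos2)`.
#' `dlfc = lfc_obs - lfc_exp`; negative dLFC marks a synthetic-lethal
#' candidate (double KO worse than expected), positive a synthetic-viable one.
#' Per sample, dLFC is re-centered so the median dLFC of constructs carrying at
#' least one OR guide -- the built-in null set, for which observed and expected
#' effects coincide up to noise -- is zero. The centering is implemented as a
#' per-sample calibration of `lfc_exp` (the offset is added to it), so the
#' identity `dlfc = lfc_obs - lfc_exp` is preserved and the downstream paired
#' tests of observed against expected see centered differences; offsets are
#' recorded.
#'
#' Constructs whose guides lack a single-KO estimate in the needed position get
#' `NA` rather than an implicit zero.
#'
#' @param lfc Output of [compute_lfc_obs()].
#' @param effects Output of [estimate_guide_effects()].
#' @param design A [gi_design].
#' @return Tibble (`construct_id`, `sample_id`, `lfc_obs`, `lfc_exp`, `dlfc`)
#'   with attribute `dlfc_offsets`.
#' @export
compute_expected <- function(lfc, effects, design) {
  cons <- design$constructs
  eff1 <- effects |>
    dplyr::filter(.data$position == "pos1") |>
    dplyr::select(guide_pos1 = "guide_id", "sample_id", eff1 = "lfc_single")
  eff2 <- effects |>
    dplyr::filter(.data$position == "pos2") |>
    dplyr::select(guide_pos2 = "guide_id", "sample_id", eff2 = "lfc_single")

  dlfc <- lfc |>
    dplyr::left_join(dplyr::select(cons, "construct_id", "guide_pos1",
                                   "guide_pos2", "role_pos1", "role_pos2"),
                     by = "construct_id") |>
    dplyr::left_join(eff1, by = c("guide_pos1", "sample_id")) |>
    dplyr::left_join(eff2, by = c("guide_pos2", "sample_id")) |>
    dplyr::mutate(lfc_exp = .data$eff1 + .data$eff2,
                  dlfc = .data$lfc_obs - .data$lfc_exp,
                  has_or = .data$role_pos1 == .role_or |
                    .data$role_pos2 == .role_or)

  offsets <- dlfc |>
    dplyr::filter(.data$has_or, !is.na(.data$dlfc)) |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::summarise(offset = median(.data$dlfc), .groups = "drop")
  if (nrow(offsets) == 0) {
    warn("no OR-containing constructs with defined dLFC; skipping dLFC centering")
    offsets <- tibble::tibble(sample_id = unique(dlfc$sample_id), offset = 0)
  }

  # the centering is folded into the expectation itself so that
  # dlfc == lfc_obs - lfc_exp holds exactly for everything downstream
  # (including the paired tests on obs vs exp)
  out <- dlfc |>
    dplyr::left_join(offsets, by = "sample_id") |>
    dplyr::mutate(lfc_exp = .data$lfc_exp + dplyr::coalesce(.data$offset, 0),
                  dlfc = .data$lfc_obs - .data$lfc_exp) |>
    dplyr::select("construct_id", "sample_id", "lfc_obs", "lfc_exp", "dlfc")
  attr(out, "dlfc_offsets") <- offsets
  out
}

#' Gene-level single-knockout effects
#'
#' Unweighted mean of a gene's per-guide single-KO effects over its guides and
#' both positions, per sample. Defined for every gene with at least one
#' OR-anchored guide.
#'
#' @param effects Output of [estimate_guide_effects()].
#' @param design A [gi_design].
#' @return Tibble (`gene_id`, `sample_id`, `lfc_single_gene`, `n_guide_effects`).
#' @export
gene_level_single_ko <- function(effects, design) {
  effects |>
    dplyr::inner_join(dplyr::select(design$guides, "guide_id", "gene_id"),
                      by = "guide_id") |>
    dplyr::group_by(.data$gene_id, .data$sample_id) |>
    dplyr::summarise(lfc_single_gene = mean(.data$lfc_single),
                     n_guide_effects = dplyr::n(), .groups = "drop")
}
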