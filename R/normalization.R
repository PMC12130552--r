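#' Depth-normalize raw counts to counts per million
#'
#' Each sample's counts are scaled to sum to one million, removing differences
#' in sequencing depth between samples.
#'
#' @param counts Long tibble (`construct_id`, `sample_id`, `count`).
#' @return Long tibble with an added `cpm` column.
#' @export
normalize_depth <- function(counts) {
  totals <- counts |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::summarise(total = sum(.data$count), .groups = "drop")
  zero <- totals$sample_id[totals$total <= 0]
  if (length(zero) > 0) {
    abort(paste0("sample(s) with zero total counts: ",
                 paste(zero, collapse = ", ")),
          class = "gipairs_data_error")
  }
  counts |>
    dplyr::left_join(totals, by = "sample_id") |>
    dplyr::mutate(cpm = .data$count / .data$total * 1e6) |>
    dplyr::select(-"total")
}

#' Observed log2 fold changes versus plasmid input, OR x OR centered
#'
#' For every gDNA sample, `lfc_obs = log2((cpm + pseudocount) /
#' (cpm_input + pseudocount))` against that screen's plasmid-input sample (the
#' replicate-matched input if the screen carries one input per replicate).
#' Each sample is then centered so the median LFC of double-OR control
#' constructs is exactly zero; double-OR constructs carry no knockout and
#' define the null. If the design has no OR x OR constructs, centering falls
#' back to the whole-library median with a warning.
#'
#' @param cpm Output of [normalize_depth()].
#' @param design A [gi_design].
#' @param meta Validated sample metadata.
#' @param pseudocount Pseudo-CPM added to numerator and denominator; keeps LFC
#'   finite for dropout constructs. Default 1; 0 is allowed for analytic
#'   (noise-free) inputs.
#' @return Tibble (`construct_id`, `sample_id`, `lfc_obs`) covering gDNA
#'   samples, with attributes `offsets` (per-sample centering offsets, log2
#'   units) and `pseudocount`.
#' @export
compute_lfc_obs <- function(cpm, design, meta, pseudocount = 1) {
  stopifnot(pseudocount >= 0)
  meta <- validate_sample_meta(meta)
  inputs <- meta[meta$sample_kind == .kind_input, ]

  # map every gDNA sample to its input sample (shared or replicate-matched)
  gdna <- meta[meta$sample_kind == .kind_gdna, ]
  input_map <- purrr::map_chr(seq_len(nrow(gdna)), function(i) {
    cand <- inputs[inputs$screen_id == gdna$screen_id[i], ]
    if (nrow(cand) > 1) cand <- cand[cand$replicate == gdna$replicate[i], ]
    if (nrow(cand) != 1) {
      abort(paste0("cannot resolve input sample for '", gdna$sample_id[i], "'"),
            class = "gipairs_validation_error")
    }
    cand$sample_id
  })
  map_tbl <- tibble::tibble(sample_id = gdna$sample_id, input_id = input_map)

  input_cpm <- cpm |>
    dplyr::select("construct_id", input_id = "sample_id", cpm_input = "cpm") |>
    dplyr::filter(.data$input_id %in% inputs$sample_id)

  lfc <- cpm |>
    dplyr::filter(.data$sample_id %in% gdna$sample_id) |>
    dplyr::left_join(map_tbl, by = "sample_id") |>
    dplyr::left_join(input_cpm, by = c("construct_id", "input_id")) |>
    dplyr::mutate(lfc_obs = log2((.data$cpm + .env$pseudocount) /
                                   (.data$cpm_input + .env$pseudocount))) |>
    dplyr::select("construct_id", "sample_id", "lfc_obs")
  if (any(!is.finite(lfc$lfc_obs))) {
    abort("non-finite LFC; use a positive pseudocount with zero counts",
          class = "gipairs_data_error")
  }

  or_or <- design$constructs$construct_id[
    design$constructs$role_pos1 == .role_or &
      design$constructs$role_pos2 == .role_or]
  if (length(or_or) == 0) {
    warn("design has no OR x OR constructs; centering on whole-library median")
    null_set <- design$constructs$construct_id
  } else {
    null_set <- or_or
  }

  offsets <- lfc |>
    dplyr::filter(.data$construct_id %in% null_set) |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::summarise(offset = median(.data$lfc_obs), .groups = "drop")

  lfc <- lfc |>
    dplyr::left_join(offsets, by = "sample_id") |>
    dplyr::mutate(lfc_obs = .data$lfc_obs - .data$offset) |>
    dplyr::select(-"offset")

  attr(lfc, "offsets") <- offsets
  attr(lfc, "pseudocount") <- pseudocount
  lfc
}
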