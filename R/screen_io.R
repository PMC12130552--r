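#' Assemble and validate a guide-pair library design
#'
#' A library design couples every guide-pair construct to its two guides, the
#' genes they target, and each gene's role (screen target vs olfactory-receptor
#' control). OR controls are assumed phenotypically neutral: pairings with them
#' anchor single-knockout effect estimates and OR x OR constructs define the
#' null used for normalization.
#'
#' @param constructs A data frame with columns `construct_id`, `guide_pos1`,
#'   `guide_pos2`, `gene_pos1`, `gene_pos2`, `role_pos1`, `role_pos2`. Roles are
#'   `"TARGET"` or `"OR_CONTROL"`.
#' @return An object of class `gi_design`: a list with tibbles `guides`
#'   (guide_id, gene_id, role, n_or_pos1, n_or_pos2), `constructs`, and
#'   `gene_summary` (per-gene guide counts).
#' @export
gi_design <- function(constructs) {
  constructs <- tibble::as_tibble(constructs)
  required <- c("construct_id", "guide_pos1", "guide_pos2",
                "gene_pos1", "gene_pos2", "role_pos1", "role_pos2")
  missing <- setdiff(required, names(constructs))
  if (length(missing) > 0) {
    abort(paste0("library design is missing column(s): ",
                 paste(missing, collapse = ", ")),
          class = "gipairs_format_error")
  }
  if (anyDuplicated(constructs$construct_id)) {
    dup <- unique(constructs$construct_id[duplicated(constructs$construct_id)])
    abort(paste0("duplicate construct_id in library design: ",
                 paste(head(dup, 5), collapse = ", ")),
          class = "gipairs_validation_error")
  }
  bad_role <- setdiff(unique(c(constructs$role_pos1, constructs$role_pos2)),
                      c(.role_target, .role_or))
  if (length(bad_role) > 0) {
    abort(paste0("unknown guide role(s): ", paste(bad_role, collapse = ", ")),
          class = "gipairs_validation_error")
  }

  guides <- dplyr::bind_rows(
    dplyr::distinct(constructs, guide_id = .data$guide_pos1,
                    gene_id = .data$gene_pos1, role = .data$role_pos1),
    dplyr::distinct(constructs, guide_id = .data$guide_pos2,
                    gene_id = .data$gene_pos2, role = .data$role_pos2)
  ) |>
    dplyr::distinct() |>
    dplyr::arrange(.data$guide_id)
  if (anyDuplicated(guides$guide_id)) {
    dup <- unique(guides$guide_id[duplicated(guides$guide_id)])
    abort(paste0("guide(s) mapped to more than one gene/role: ",
                 paste(head(dup, 5), collapse = ", ")),
          class = "gipairs_validation_error")
  }

  # OR-anchoring coverage: how many OR pairings each guide has per position.
  n_or1 <- constructs |>
    dplyr::filter(.data$role_pos2 == .role_or) |>
    dplyr::count(guide_id = .data$guide_pos1, name = "n_or_pos1")
  n_or2 <- constructs |>
    dplyr::filter(.data$role_pos1 == .role_or) |>
    dplyr::count(guide_id = .data$guide_pos2, name = "n_or_pos2")
  guides <- guides |>
    dplyr::left_join(n_or1, by = "guide_id") |>
    dplyr::left_join(n_or2, by = "guide_id") |>
    dplyr::mutate(dplyr::across(c("n_or_pos1", "n_or_pos2"),
                                ~ dplyr::coalesce(.x, 0L)))

  unanchored <- guides$guide_id[guides$n_or_pos1 + guides$n_or_pos2 == 0]
  if (length(unanchored) > 0) {
    warn(paste0(length(unanchored),
                " guide(s) have no OR pairing at any position; their",
                " single-KO effects are not estimable: ",
                paste(head(unanchored, 5), collapse = ", ")))
  }

  gene_summary <- guides |>
    dplyr::count(.data$gene_id, .data$role, name = "n_guides")

  structure(list(guides = guides, constructs = constructs,
                 gene_summary = gene_summary),
            class = "gi_design")
}

#' @export
print.gi_design <- function(x, ...) {
  cat("<gi_design> ", nrow(x$constructs), " constructs, ",
      nrow(x$guides), " guides, ",
      sum(x$gene_summary$role == .role_target), " target genes, ",
      sum(x$gene_summary$role == .role_or), " OR control genes\n", sep = "")
  invisible(x)
}

#' Read a library design TSV
#'
#' Expects a tab-delimited file with a header row and columns `construct_id`,
#' `guide_pos1`, `guide_pos2`, `gene_pos1`, `gene_pos2`, `role_pos1`,
#' `role_pos2` (one row per guide-pair construct).
#'
#' @param path Path to the TSV file.
#' @return A [gi_design] object.
#' @export
read_library_design <- function(path) {
  constructs <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                                progress = FALSE)
  gi_design(constructs)
}

#' Write a library design TSV
#'
#' @param design A [gi_design] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_library_design <- function(design, path) {
  readr::write_tsv(design$constructs, path, na = "NA", progress = FALSE)
  invisible(path)
}

#' Validate a sample metadata table
#'
#' @param meta Data frame with columns `sample_id`, `sample_kind`
#'   (`"PLASMID_INPUT"` or `"GDNA"`), `replicate`, `timepoint_weeks`,
#'   `condition`, `screen_id`.
#' @return The validated metadata as a tibble.
#' @export
validate_sample_meta <- function(meta) {
  meta <- tibble::as_tibble(meta)
  required <- c("sample_id", "sample_kind", "replicate", "timepoint_weeks",
                "condition", "screen_id")
  missing <- setdiff(required, names(meta))
  if (length(missing) > 0) {
    abort(paste0("sample metadata is missing column(s): ",
                 paste(missing, collapse = ", ")),
          class = "gipairs_format_error")
  }
  if (anyDuplicated(meta$sample_id)) {
    abort("duplicate sample_id in sample metadata",
          class = "gipairs_validation_error")
  }
  bad_kind <- setdiff(unique(meta$sample_kind), c(.kind_input, .kind_gdna))
  if (length(bad_kind) > 0) {
    abort(paste0("unknown sample_kind: ", paste(bad_kind, collapse = ", ")),
          class = "gipairs_validation_error")
  }
  meta$replicate <- as.integer(meta$replicate)
  meta$timepoint_weeks <- as.numeric(meta$timepoint_weeks)
  inputs <- meta[meta$sample_kind == .kind_input, ]
  n_in <- table(inputs$screen_id)
  for (scr in unique(meta$screen_id)) {
    n <- sum(inputs$screen_id == scr)
    n_rep <- length(unique(meta$replicate[meta$screen_id == scr &
                                            meta$sample_kind == .kind_gdna]))
    if (n == 0) {
      abort(paste0("screen '", scr, "' has no PLASMID_INPUT sample"),
            class = "gipairs_validation_error")
    }
    # one shared input per screen, or one per replicate
    if (n != 1 && n != n_rep) {
      abort(paste0("screen '", scr, "' must have exactly one PLASMID_INPUT ",
                   "sample or one per replicate (found ", n, ")"),
            class = "gipairs_validation_error")
    }
  }
  gdna <- meta[meta$sample_kind == .kind_gdna, ]
  key <- paste(gdna$screen_id, gdna$replicate, gdna$timepoint_weeks,
               gdna$condition)
  if (anyDuplicated(key)) {
    abort("duplicate (screen, replicate, timepoint, condition) in metadata",
          class = "gipairs_validation_error")
  }
  meta
}

#' Read sample metadata from a TSV
#'
#' @param path Path to a tab-delimited file with the columns documented in
#'   [validate_sample_meta()].
#' @return A validated tibble.
#' @export
read_sample_meta <- function(path) {
  meta <- readr::read_tsv(path, col_types = readr::cols(
    sample_id = "c", sample_kind = "c", replicate = "i",
    timepoint_weeks = "d", condition = "c", screen_id = "c"
  ), progress = FALSE)
  validate_sample_meta(meta)
}

#' Read a guide-pair count table
#'
#' Consumes the wide layout produced by standard pooled-screen counters: first
#' column the construct id, remaining columns one per sequenced sample. Rows
#' whose construct id is not in the library design are dropped and counted;
#' more than 10% unmatched rows is treated as an error (wrong library).
#'
#' @param path Path to the TSV count file.
#' @param design A [gi_design]; counts are intersected against its constructs.
#' @param meta Validated sample metadata; every count column must appear in it.
#' @return A long tibble (`construct_id`, `sample_id`, `count`) with attributes
#'   `n_unmatched` (rows dropped) and `unmatched_ids`.
#' @export
read_counts <- function(path, design, meta) {
  meta <- validate_sample_meta(meta)
  header <- names(readr::read_tsv(path, n_max = 0, col_types = readr::cols(),
                                  progress = FALSE))
  wide <- readr::read_tsv(
    path, progress = FALSE,
    col_types = do.call(readr::cols,
                        c(setNames(list("c"), header[1]), .default = "d")))
  names(wide)[1] <- "construct_id"
  sample_cols <- setdiff(names(wide), "construct_id")
  unknown <- setdiff(sample_cols, meta$sample_id)
  if (length(unknown) > 0) {
    abort(paste0("count file sample(s) absent from metadata: ",
                 paste(unknown, collapse = ", ")),
          class = "gipairs_validation_error")
  }
  matched <- wide$construct_id %in% design$constructs$construct_id
  n_unmatched <- sum(!matched)
  if (n_unmatched > 0.1 * nrow(wide)) {
    abort(paste0(n_unmatched, "/", nrow(wide), " construct ids in count file ",
                 "not found in library design (likely wrong library)"),
          class = "gipairs_validation_error")
  }
  unmatched_ids <- wide$construct_id[!matched]
  counts <- wide[matched, ] |>
    tidyr::pivot_longer(dplyr::all_of(sample_cols), names_to = "sample_id",
                        values_to = "count")
  if (any(counts$count < 0, na.rm = TRUE)) {
    abort("negative counts in count file", class = "gipairs_validation_error")
  }
  attr(counts, "n_unmatched") <- n_unmatched
  attr(counts, "unmatched_ids") <- unmatched_ids
  counts
}

#' Write a long count table as a wide (counter-style) TSV
#'
#' Inverse of [read_counts()]: one row per construct, one column per sample.
#'
#' @param counts Long tibble with `construct_id`, `sample_id`, `count`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_counts <- function(counts, path) {
  wide <- counts |>
    tidyr::pivot_wider(id_cols = "construct_id", names_from = "sample_id",
                       values_from = "count")
  readr::write_tsv(wide, path, na = "NA", progress = FALSE)
  invisible(path)
}

#' Write a scores or calls table as TSV
#'
#' Column order is preserved as in the input table; missing numeric values are
#' written as `NA`. An empty table yields a header-only file.
#'
#' @param scores A gene-pair score or interaction-call tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_scores <- function(scores, path) {
  readr::write_tsv(tibble::as_tibble(scores), path, na = "NA", progress = FALSE)
  invisible(path)
}

#' Read a scores or calls TSV written by [write_scores()]
#'
#' @param path Path to the TSV file.
#' @return A tibble.
#' @export
read_scores <- function(path) {
  readr::read_tsv(path, na = "NA", progress = FALSE,
                  show_col_types = FALSE)
}
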