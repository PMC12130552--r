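#' Fuse interaction-call tables from multiple screens into a network
#'
#' One edge per unordered gene pair per condition; an edge exists iff at least
#' one contributing screen called the pair. Discordant-sign edges (lethal in
#' one system, viable in the other) are retained and marked
#' `sign_concordant = FALSE`. Fusion is commutative and associative over the
#' input tables.
#'
#' @param call_tables A list of interaction-call tibbles (each with
#'   `screen_id`, `condition`, `gene_a`, `gene_b`, a call column, `dlfc`,
#'   `padj_worst`).
#' @param exclude_genes Character vector of genes (e.g. screen-essential ones)
#'   whose edges are dropped at fusion; equivalent to dropping them per table
#'   first.
#' @param call_col Call column to fuse on; default `"call_filtered"` when
#'   present in every table, else `"call"`.
#' @return A `GiEdge` tibble: `condition`, `gene_a`, `gene_b`, `n_screens`
#'   (calling screens), `screens`, `calls`, `dlfc` (mean over calling
#'   screens), `padj_worst`, `consensus` (`BOTH_SCREENS` / `SINGLE_SCREEN`),
#'   `sign_concordant`.
#' @export
fuse_screens <- function(call_tables, exclude_genes = character(),
                         call_col = NULL) {
  stacked <- dplyr::bind_rows(lapply(call_tables, tibble::as_tibble))
  call_col <- call_col %||%
    (if ("call_filtered" %in% names(stacked)) "call_filtered" else "call")

  roles <- stacked |>
    dplyr::distinct(.data$gene_a, .data$gene_b)
  # namespace sanity: a gene id must not appear under conflicting call tables'
  # roles; with calls tables roles are implicit, so only id collisions with
  # differing case are realistic — left to the caller's design validation.

  stacked |>
    dplyr::mutate(call_use = .data[[call_col]]) |>
    dplyr::filter(.data$call_use != .call_none,
                  !(.data$gene_a %in% exclude_genes),
                  !(.data$gene_b %in% exclude_genes)) |>
    dplyr::group_by(.data$condition, .data$gene_a, .data$gene_b) |>
    dplyr::summarise(
      n_screens = dplyr::n_distinct(.data$screen_id),
      screens = paste(sort(unique(.data$screen_id)), collapse = ";"),
      calls = paste(.data$call_use[order(.data$screen_id)], collapse = ";"),
      dlfc = mean(.data$dlfc),
      padj_worst = {
        v <- suppressWarnings(max(as.numeric(.data$padj_worst), na.rm = TRUE))
        if (is.finite(v)) v else NA_real_
      },
      sign_concordant = dplyr::n_distinct(.data$call_use) == 1,
      .groups = "drop") |>
    dplyr::mutate(consensus = ifelse(.data$n_screens > 1, "BOTH_SCREENS",
                                     "SINGLE_SCREEN"))
}

#' Compare interaction calls across growth conditions
#'
#' A gene pair "changes" in a condition when its call state (`NONE` /
#' `SYNTHETIC_LETHAL` / `SYNTHETIC_VIABLE`) differs from the reference
#' condition's state; a dLFC-magnitude variant is available via
#' `min_dlfc_change`.
#'
#' @param calls An interaction-call tibble covering several conditions of the
#'   same library/screen.
#' @param reference Reference condition label.
#' @param call_col Call column; default as in [fuse_screens()].
#' @param min_dlfc_change Optional: additionally require |dLFC difference vs
#'   reference| above this value for a pair to count as changed.
#' @return Tibble per gene pair x non-reference condition with `call`,
#'   `call_reference`, `changed`, `dlfc`, `dlfc_reference`; summary counts in
#'   attribute `summary` (per condition: `n_pairs`, `n_changed`).
#' @export
condition_compare <- function(calls, reference, call_col = NULL,
                              min_dlfc_change = NULL) {
  call_col <- call_col %||%
    (if ("call_filtered" %in% names(calls)) "call_filtered" else "call")
  if (!reference %in% calls$condition) {
    abort(paste0("reference condition '", reference, "' not present"),
          class = "gipairs_data_error")
  }
  calls <- dplyr::mutate(calls, call_use = .data[[call_col]])
  ref <- calls |>
    dplyr::filter(.data$condition == reference) |>
    dplyr::select("gene_a", "gene_b", call_reference = "call_use",
                  dlfc_reference = "dlfc")
  out <- calls |>
    dplyr::filter(.data$condition != reference) |>
    dplyr::select("condition", "gene_a", "gene_b", call = "call_use",
                  "dlfc") |>
    dplyr::full_join(tidyr::expand_grid(
      condition = setdiff(unique(calls$condition), reference),
      ref), by = c("condition", "gene_a", "gene_b")) |>
    dplyr::mutate(call = dplyr::coalesce(.data$call, .call_none),
                  call_reference = dplyr::coalesce(.data$call_reference,
                                                   .call_none),
                  changed = .data$call != .data$call_reference)
  if (!is.null(min_dlfc_change)) {
    out$changed <- out$changed &
      !is.na(out$dlfc) & !is.na(out$dlfc_reference) &
      abs(out$dlfc - out$dlfc_reference) >= min_dlfc_change
  }
  summary <- out |>
    dplyr::group_by(.data$condition) |>
    dplyr::summarise(n_pairs = dplyr::n(), n_changed = sum(.data$changed),
                     .groups = "drop")
  attr(out, "summary") <- summary
  out
}

#' Export a genetic-interaction network
#'
#' @param edges A `GiEdge` tibble from [fuse_screens()] (or any tibble with
#'   `gene_a`, `gene_b` plus edge attributes).
#' @param path Output file path.
#' @param format `"tsv"` (edge list), `"graphml"`, or `"sif"`.
#' @param node_attrs Optional tibble (`gene_id`, attribute columns such as
#'   single-KO LFC or substrate class) attached to nodes in GraphML output.
#' @return `path`, invisibly.
#' @export
export_network <- function(edges, path, format = c("tsv", "graphml", "sif"),
                           node_attrs = NULL) {
  format <- match.arg(format)
  if (nrow(edges) == 0 && format != "tsv") {
    abort("cannot export an empty network", class = "gipairs_data_error")
  }
  if (format == "tsv") {
    readr::write_tsv(edges, path, na = "NA", progress = FALSE)
  } else if (format == "sif") {
    rel <- if ("calls" %in% names(edges)) {
      ifelse(grepl(.call_lethal, edges$calls), "synthetic_lethal",
             "synthetic_viable")
    } else rep("interacts", nrow(edges))
    writeLines(paste(edges$gene_a, rel, edges$gene_b, sep = "\t"), path)
  } else {
    g <- igraph::graph_from_data_frame(
      dplyr::relocate(edges, "gene_a", "gene_b"), directed = FALSE)
    if (!is.null(node_attrs)) {
      idx <- match(igraph::V(g)$name, node_attrs$gene_id)
      for (col in setdiff(names(node_attrs), "gene_id")) {
        g <- igraph::set_vertex_attr(g, col, value = node_attrs[[col]][idx])
      }
    }
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}

#' Cross-screen / cross-orientation concordance of gene-pair scores
#'
#' Pearson correlation and R^2 of a chosen value (default `dlfc`) over the
#' gene pairs shared by two score or call tables, at one timepoint when the
#' tables carry several.
#'
#' @param x,y Two tibbles with `gene_a`, `gene_b` and the value column
#'   (replicate-level rows are averaged first).
#' @param value Column to correlate. Default `"dlfc"`.
#' @return A one-row tibble: `n_shared`, `pcc`, `r_squared`; `NA` with a
#'   warning when fewer than 3 shared pairs.
#' @export
concordance <- function(x, y, value = "dlfc") {
  collapse <- function(tab) {
    tab |>
      dplyr::group_by(.data$gene_a, .data$gene_b) |>
      dplyr::summarise(v = mean(.data[[value]], na.rm = TRUE),
                       .groups = "drop")
  }
  joined <- dplyr::inner_join(collapse(x), collapse(y),
                              by = c("gene_a", "gene_b"),
                              suffix = c("_x", "_y")) |>
    dplyr::filter(is.finite(.data$v_x), is.finite(.data$v_y))
  if (nrow(joined) < 3) {
    warn("fewer than 3 shared gene pairs; concordance undefined")
    return(tibble::tibble(n_shared = nrow(joined), pcc = NA_real_,
                          r_squared = NA_real_))
  }
  pcc <- cor(joined$v_x, joined$v_y)
  tibble::tibble(n_shared = nrow(joined), pcc = pcc, r_squared = pcc^2)
}

#' Orientation concordance of construct-level values
#'
#' Splits an all-by-all design's target-target constructs by orientation
#' (which gene occupies position 1 of the cassette) and reports the
#' concordance of per-ordered-pair mean values between the two orientations.
#'
#' @param dlfc Output of [compute_expected()] (or [compute_lfc_obs()]).
#' @param design A [gi_design] with both orientations present.
#' @param value Column of `dlfc` to compare (e.g. `"lfc_obs"`, `"dlfc"`).
#' @param samples Optional sample ids to restrict to (e.g. the scoring
#'   timepoint's samples).
#' @return A one-row tibble as in [concordance()].
#' @export
orientation_concordance <- function(dlfc, design, value = "lfc_obs",
                                    samples = NULL) {
  cons <- design$constructs |>
    dplyr::filter(.data$role_pos1 == .role_target,
                  .data$role_pos2 == .role_target,
                  .data$gene_pos1 != .data$gene_pos2)
  d <- dlfc |>
    dplyr::inner_join(dplyr::select(cons, "construct_id", "gene_pos1",
                                    "gene_pos2"), by = "construct_id")
  if (!is.null(samples)) d <- dplyr::filter(d, .data$sample_id %in% samples)
  d <- d |>
    dplyr::mutate(gene_a = pmin(.data$gene_pos1, .data$gene_pos2),
                  gene_b = pmax(.data$gene_pos1, .data$gene_pos2),
                  orient = ifelse(.data$gene_pos1 == .data$gene_a, "fwd",
                                  "rev"))
  split_tab <- function(o) {
    d |>
      dplyr::filter(.data$orient == o) |>
      dplyr::group_by(.data$gene_a, .data$gene_b) |>
      dplyr::summarise(!!value := mean(.data[[value]], na.rm = TRUE),
                       .groups = "drop")
  }
  concordance(split_tab("fwd"), split_tab("rev"), value = value)
}
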