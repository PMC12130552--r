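#' Read a structured run configuration (YAML or JSON)
#'
#' Top-level keys: `seed`, `out_dir`, `paths` (design / counts / meta /
#' calls), `simulate` (fields of [sim_config()]), `score` (fields of
#' [scoring_config()]), `filters` (fields of [filter_config()]),
#' `integrate` (`calls`: list of call-table paths, `exclude_genes`,
#' `format`). Unknown keys raise a configuration error.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A validated list of class `run_config`.
#' @export
read_run_config <- function(path) {
  cfg <- if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  known <- c("seed", "out_dir", "paths", "simulate", "score", "filters",
             "integrate", "pseudocount", "log_level")
  unknown <- setdiff(names(cfg), known)
  if (length(unknown) > 0) {
    abort(paste0("unknown run-config key(s): ",
                 paste(unknown, collapse = ", ")),
          class = "gipairs_config_error")
  }
  cfg$seed <- as.integer(cfg$seed %||% 1L)
  structure(cfg, class = "run_config")
}

.resolve_out_dir <- function(cfg) {
  out <- cfg$out_dir %||% "."
  if (!dir.exists(out)) dir.create(out, recursive = TRUE)
  out
}

# echo the resolved configuration next to the outputs, for provenance
.echo_config <- function(cfg, out) {
  jsonlite::write_json(unclass(cfg), file.path(out, "run_config.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null")
}

#' Simulate a screen from a run configuration
#'
#' Writes `design.tsv`, `counts.tsv`, `sample_meta.tsv` (the same layouts the
#' readers consume) and the ground-truth tables (`truth_genes.tsv`,
#' `truth_guides.tsv`, `truth_pairs.tsv`, `truth_construct_lfc.tsv`) into the
#' output directory. Deterministic given config + seed.
#'
#' @param cfg A [read_run_config()] result (or equivalent list) with a
#'   `simulate` block.
#' @return The `gi_sim` object, invisibly.
#' @export
run_simulate <- function(cfg) {
  if (is.null(cfg$simulate)) {
    abort("run config has no 'simulate' block", class = "gipairs_config_error")
  }
  scfg <- do.call(sim_config, cfg$simulate)
  design <- generate_design(scfg)
  sim <- simulate_counts(design, scfg, seed = cfg$seed %||% 1L)
  out <- .resolve_out_dir(cfg)
  write_library_design(design, file.path(out, "design.tsv"))
  write_counts(sim$counts, file.path(out, "counts.tsv"))
  readr::write_tsv(sim$meta, file.path(out, "sample_meta.tsv"),
                   progress = FALSE)
  readr::write_tsv(sim$truth$genes, file.path(out, "truth_genes.tsv"),
                   progress = FALSE)
  readr::write_tsv(sim$truth$guides, file.path(out, "truth_guides.tsv"),
                   progress = FALSE)
  readr::write_tsv(sim$truth$pairs, file.path(out, "truth_pairs.tsv"),
                   progress = FALSE)
  readr::write_tsv(sim$truth$construct_lfc,
                   file.path(out, "truth_construct_lfc.tsv"),
                   progress = FALSE)
  .echo_config(cfg, out)
  invisible(sim)
}

#' Score a screen from a run configuration
#'
#' Reads the design, counts and metadata named under `paths`, runs
#' [score_screen()], and writes `scores.tsv`, `calls.tsv` and
#' `run_report.json` (offsets, family sizes, filter counts).
#'
#' @param cfg A [read_run_config()] result with a `paths` block
#'   (`design`, `counts`, `meta`).
#' @return The `gi_result`, invisibly.
#' @export
run_score <- function(cfg) {
  p <- cfg$paths
  if (is.null(p$design) || is.null(p$counts) || is.null(p$meta)) {
    abort("run config 'paths' must name design, counts and meta files",
          class = "gipairs_config_error")
  }
  design <- read_library_design(p$design)
  meta <- read_sample_meta(p$meta)
  counts <- read_counts(p$counts, design, meta)
  sc <- do.call(scoring_config, cfg$score %||% list())
  fc <- do.call(filter_config, cfg$filters %||% list())
  res <- score_screen(counts, design, meta, config = sc, filters = fc,
                      pseudocount = cfg$pseudocount %||% 1)
  out <- .resolve_out_dir(cfg)
  write_scores(res$scores, file.path(out, "scores.tsv"))
  write_scores(res$calls, file.path(out, "calls.tsv"))
  jsonlite::write_json(res$report, file.path(out, "run_report.json"),
                       auto_unbox = TRUE, pretty = TRUE, dataframe = "rows")
  .echo_config(cfg, out)
  invisible(res)
}

#' Fuse call tables from a run configuration and export the network
#'
#' @param cfg A [read_run_config()] result with an `integrate` block
#'   (`calls`: paths of call TSVs; optional `exclude_genes`, `format`).
#' @return The fused edge tibble, invisibly.
#' @export
run_integrate <- function(cfg) {
  ib <- cfg$integrate
  if (is.null(ib$calls) || length(ib$calls) == 0) {
    abort("run config 'integrate' must list call-table paths",
          class = "gipairs_config_error")
  }
  tables <- lapply(ib$calls, read_scores)
  edges <- fuse_screens(tables,
                        exclude_genes = ib$exclude_genes %||% character())
  out <- .resolve_out_dir(cfg)
  export_network(edges, file.path(out, "network_edges.tsv"), format = "tsv")
  fmt <- ib$format %||% "graphml"
  if (fmt != "tsv" && nrow(edges) > 0) {
    export_network(edges, file.path(out, paste0("network.", fmt)),
                   format = fmt)
  }
  .echo_config(cfg, out)
  invisible(edges)
}
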