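#' Simulation configuration for a pooled double-knockout screen
#'
#' The generative model: each guide edits its target with a fixed per-guide
#' efficiency drawn at transduction (outcomes fixed thereafter, as in a
#' puromycin-selected pool). A cell lineage's fitness on the log2-per-week
#' scale is `clamp(s1*I1 + s2*I2 + eps*I1*I2 + condition modifier, floor)`
#' where `I` are the editing outcomes; the floor models death/arrest
#' saturation. Expected construct abundance at week t mixes the four outcome
#' classes weighted by their probabilities, times a log-normal plasmid
#' abundance. Observed counts are multinomial at the sample's depth after
#' multiplicative gamma overdispersion.
#'
#' @param n_target_genes Number of target genes.
#' @param guides_per_gene Guides per target gene. Default 3.
#' @param n_or_guides Total number of olfactory-receptor control guides.
#'   Default 3.
#' @param or_guides_per_gene How many OR guides target the same OR gene
#'   (`n_or_guides` must be a multiple). Default 1 (one OR gene per guide).
#' @param orientations 2 (default): all ordered guide pairs; 1: unordered
#'   pairs (upper triangle incl. diagonal).
#' @param gene_fitness Optional named vector of per-gene fitness `s` (log2 per
#'   week). Default: mixture of 85% near-neutral (sd 0.05), 10% mildly
#'   deleterious (mean -0.5, sd 0.2), 5% essential (mean -2.5, sd 0.3).
#' @param guide_efficiency Optional editing efficiencies in \[0,1\]: a named
#'   per-guide vector, or a single unnamed value shared by all guides.
#'   Default Beta(8, 2) draws (mean 0.8). Forced to 1 when `noise = FALSE`.
#' @param interactions Data frame (`gene_a`, `gene_b`, `epsilon`, optional
#'   `conditions` — comma-separated condition labels, `NA` = all) of planted
#'   pairwise interaction terms (log2 per week).
#' @param fitness_floor Clamp on total lineage fitness. Default -3.
#' @param timepoints_weeks Harvest weeks. Default `c(1, 2, 3, 5)`.
#' @param replicates Default 3.
#' @param conditions Growth-condition labels. Default `"standard"`.
#' @param condition_modifiers Data frame (`gene_id`, `condition`, `delta`)
#'   of per-gene fitness shifts under non-reference conditions.
#' @param plasmid_sigma Log-normal sdlog of plasmid library abundance skew.
#'   Default 0.5.
#' @param depth Reads per sample; default 500 x number of constructs.
#' @param overdispersion Gamma dispersion (squared CV of the multiplicative
#'   noise). Default 0.04 (CV 0.2).
#' @param transduction_sd SD of construct-specific abundance offsets (log2)
#'   present from week 1 onward, emulating variable transduction efficiency.
#'   Default 0.
#' @param noise `FALSE` gives the analytic mode: efficiencies 1, no abundance
#'   skew, no counting noise — expected counts exactly.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_target_genes,
                       guides_per_gene = 3,
                       n_or_guides = 3,
                       or_guides_per_gene = 1,
                       orientations = 2,
                       gene_fitness = NULL,
                       guide_efficiency = NULL,
                       interactions = NULL,
                       fitness_floor = -3,
                       timepoints_weeks = c(1, 2, 3, 5),
                       replicates = 3,
                       conditions = "standard",
                       condition_modifiers = NULL,
                       plasmid_sigma = 0.5,
                       depth = NULL,
                       overdispersion = 0.04,
                       transduction_sd = 0,
                       noise = TRUE) {
  if (n_target_genes < 1) {
    abort("n_target_genes must be >= 1", class = "gipairs_config_error")
  }
  if (n_or_guides %% or_guides_per_gene != 0) {
    abort("n_or_guides must be a multiple of or_guides_per_gene",
          class = "gipairs_config_error")
  }
  stopifnot(orientations %in% c(1, 2), fitness_floor < 0,
            replicates >= 1, plasmid_sigma >= 0, overdispersion >= 0,
            is.null(depth) || depth > 0)
  if (!is.null(guide_efficiency) &&
      any(guide_efficiency < 0 | guide_efficiency > 1)) {
    abort("guide efficiencies must lie in [0, 1]",
          class = "gipairs_config_error")
  }
  if (!is.null(interactions)) interactions <- tibble::as_tibble(interactions)
  structure(list(n_target_genes = n_target_genes,
                 guides_per_gene = guides_per_gene,
                 n_or_guides = n_or_guides,
                 or_guides_per_gene = or_guides_per_gene,
                 orientations = orientations,
                 gene_fitness = gene_fitness,
                 guide_efficiency = guide_efficiency,
                 interactions = interactions, fitness_floor = fitness_floor,
                 timepoints_weeks = timepoints_weeks,
                 replicates = replicates, conditions = conditions,
                 condition_modifiers = condition_modifiers,
                 plasmid_sigma = plasmid_sigma, depth = depth,
                 overdispersion = overdispersion,
                 transduction_sd = transduction_sd, noise = noise),
            class = "sim_config")
}

#' Generate an all-by-all guide-pair library design
#'
#' Target guides and OR control guides are pooled and paired exhaustively:
#' with two orientations every ordered pair appears (n^2 constructs for n
#' guides, 2 x g1 x g2 constructs per gene pair), including target-OR, OR-
#' target and OR-OR anchor constructs.
#'
#' @param config A [sim_config()].
#' @return A [gi_design].
#' @export
generate_design <- function(config) {
  genes <- sprintf("GENE%03d", seq_len(config$n_target_genes))
  tg <- tidyr::expand_grid(gene_id = genes,
                           k = seq_len(config$guides_per_gene)) |>
    dplyr::mutate(guide_id = sprintf("%s_g%d", .data$gene_id, .data$k),
                  role = .role_target)
  gpo <- config$or_guides_per_gene %||% 1
  or_gene_idx <- rep(seq_len(config$n_or_guides %/% gpo), each = gpo)
  or <- tibble::tibble(
    gene_id = sprintf("OR%02d", or_gene_idx),
    guide_id = sprintf("OR%02d_g%d", or_gene_idx,
                       sequence(rle(or_gene_idx)$lengths)),
    role = .role_or)
  guides <- dplyr::bind_rows(dplyr::select(tg, "guide_id", "gene_id", "role"),
                             or)

  idx <- seq_len(nrow(guides))
  if (config$orientations == 2) {
    pairs <- tidyr::expand_grid(i = idx, j = idx)
  } else {
    pairs <- tidyr::expand_grid(i = idx, j = idx) |>
      dplyr::filter(.data$i <= .data$j)
  }
  constructs <- tibble::tibble(
    construct_id = paste(guides$guide_id[pairs$i], guides$guide_id[pairs$j],
                         sep = "__"),
    guide_pos1 = guides$guide_id[pairs$i],
    guide_pos2 = guides$guide_id[pairs$j],
    gene_pos1 = guides$gene_id[pairs$i],
    gene_pos2 = guides$gene_id[pairs$j],
    role_pos1 = guides$role[pairs$i],
    role_pos2 = guides$role[pairs$j])
  gi_design(constructs)
}

# active-epsilon lookup per (canonical pair, condition)
.interaction_table <- function(config) {
  if (is.null(config$interactions) || nrow(config$interactions) == 0) {
    return(tibble::tibble(gene_a = character(), gene_b = character(),
                          condition = character(), epsilon = numeric()))
  }
  config$interactions |>
    dplyr::mutate(gene_a0 = pmin(.data$gene_a, .data$gene_b),
                  gene_b0 = pmax(.data$gene_a, .data$gene_b)) |>
    dplyr::rowwise() |>
    dplyr::mutate(condition = list(
      if (!"conditions" %in% names(config$interactions) ||
          is.na(.data$conditions)) config$conditions
      else strsplit(.data$conditions, ",")[[1]])) |>
    dplyr::ungroup() |>
    tidyr::unnest("condition") |>
    dplyr::select(gene_a = "gene_a0", gene_b = "gene_b0", "condition",
                  "epsilon")
}

#' Simulate counts for a guide-pair screen with known ground truth
#'
#' @param design A [gi_design], typically from [generate_design()].
#' @param config A [sim_config()].
#' @param seed Integer seed; identical design + config + seed give
#'   bit-identical output.
#' @return A list of class `gi_sim`: `counts` (long tibble incl. the plasmid
#'   input sample), `meta`, `design`, and `truth` — a list with `genes`
#'   (gene_id, s), `guides` (guide_id, efficiency), `pairs` (planted
#'   interactions per condition), and `construct_lfc` (closed-form expected
#'   LFC per construct x condition x timepoint).
#' @export
simulate_counts <- function(design, config, seed = 1) {
  withr::local_seed(seed)
  guides <- design$guides
  cons <- design$constructs
  n_cons <- nrow(cons)
  genes <- unique(guides$gene_id)

  # --- ground truth draws -------------------------------------------------
  s <- setNames(rep(0, length(genes)), genes)
  target_genes <- unique(guides$gene_id[guides$role == .role_target])
  if (!is.null(config$gene_fitness)) {
    s[names(config$gene_fitness)] <- config$gene_fitness
  } else {
    cls <- sample(c("neutral", "mild", "essential"), length(target_genes),
                  replace = TRUE, prob = c(0.85, 0.10, 0.05))
    s[target_genes] <- ifelse(cls == "neutral",
                              rnorm(length(target_genes), 0, 0.05),
                       ifelse(cls == "mild",
                              rnorm(length(target_genes), -0.5, 0.2),
                              rnorm(length(target_genes), -2.5, 0.3)))
  }

  if (!config$noise) {
    eff <- setNames(rep(1, nrow(guides)), guides$guide_id)
  } else if (!is.null(config$guide_efficiency)) {
    ge <- config$guide_efficiency
    eff <- setNames(rep(1, nrow(guides)), guides$guide_id)
    if (is.null(names(ge))) {
      eff[] <- ge  # scalar (or recycled) shared efficiency
    } else {
      eff[names(ge)] <- ge
    }
  } else {
    eff <- setNames(rbeta(nrow(guides), 8, 2), guides$guide_id)
  }
  eff[guides$guide_id[guides$role == .role_or]] <- 1  # neutral anyway

  itab <- .interaction_table(config)
  mods <- config$condition_modifiers
  if (is.null(mods)) {
    mods <- tibble::tibble(gene_id = character(), condition = character(),
                           delta = numeric())
  }

  w0 <- if (config$noise) rlnorm(n_cons, 0, config$plasmid_sigma)
        else rep(1, n_cons)
  tau <- if (config$noise && config$transduction_sd > 0) {
    rnorm(n_cons, 0, config$transduction_sd)
  } else rep(0, n_cons)

  depth <- config$depth %||% (500 * n_cons)

  # per-construct ingredients
  base <- cons |>
    dplyr::mutate(s1 = unname(s[.data$gene_pos1]),
                  s2 = unname(s[.data$gene_pos2]),
                  e1 = unname(eff[.data$guide_pos1]),
                  e2 = unname(eff[.data$guide_pos2]),
                  gene_a = pmin(.data$gene_pos1, .data$gene_pos2),
                  gene_b = pmax(.data$gene_pos1, .data$gene_pos2),
                  w0 = w0, tau = tau)

  clamp <- function(x) pmax(x, config$fitness_floor)

  # expected relative abundance multiplier at time t for one condition
  cond_growth <- function(base_c, t) {
    p11 <- base_c$e1 * base_c$e2
    p10 <- base_c$e1 * (1 - base_c$e2)
    p01 <- (1 - base_c$e1) * base_c$e2
    p00 <- (1 - base_c$e1) * (1 - base_c$e2)
    f11 <- clamp(base_c$s1c + base_c$s2c + base_c$epsc)
    f10 <- clamp(base_c$s1c)
    f01 <- clamp(base_c$s2c)
    f00 <- clamp(0)
    p11 * 2^(f11 * t) + p10 * 2^(f10 * t) + p01 * 2^(f01 * t) +
      p00 * 2^(f00 * t)
  }

  # condition-specific fitness and epsilon columns
  per_cond <- lapply(config$conditions, function(cond) {
    m <- mods[mods$condition == cond, ]
    d1 <- setNames(m$delta, m$gene_id)
    it <- itab[itab$condition == cond, ]
    b <- base
    b$s1c <- b$s1 + dplyr::coalesce(unname(d1[b$gene_pos1]), 0)
    b$s2c <- b$s2 + dplyr::coalesce(unname(d1[b$gene_pos2]), 0)
    key <- paste(b$gene_a, b$gene_b)
    epsmap <- setNames(it$epsilon, paste(it$gene_a, it$gene_b))
    # a guide pair within one gene is not a pairwise interaction
    epsc <- dplyr::coalesce(unname(epsmap[key]), 0)
    epsc[b$gene_pos1 == b$gene_pos2] <- 0
    b$epsc <- epsc
    b$condition <- cond
    b
  })
  names(per_cond) <- config$conditions

  tt <- cons$role_pos1 == .role_target & cons$role_pos2 == .role_target
  if (any(tt) && all(vapply(per_cond, function(b)
    all((b$s1c + b$s2c + b$epsc)[tt] <= config$fitness_floor),
    logical(1)))) {
    warn("degenerate configuration: every double-KO fitness sits at the floor")
  }

  # --- sample table -------------------------------------------------------
  meta <- tidyr::expand_grid(condition = config$conditions,
                             timepoint_weeks = config$timepoints_weeks,
                             replicate = seq_len(config$replicates)) |>
    dplyr::mutate(sample_id = sprintf("%s_w%g_r%d", .data$condition,
                                      .data$timepoint_weeks, .data$replicate),
                  sample_kind = .kind_gdna, screen_id = "sim") |>
    dplyr::bind_rows(tibble::tibble(
      sample_id = "plasmid", sample_kind = .kind_input, replicate = 1L,
      timepoint_weeks = 0, condition = config$conditions[1],
      screen_id = "sim")) |>
    dplyr::select("sample_id", "sample_kind", "replicate", "timepoint_weeks",
                  "condition", "screen_id")
  meta <- validate_sample_meta(meta)

  draw_counts <- function(abund) {
    if (!config$noise) return(abund / sum(abund) * depth)
    x <- abund
    if (config$overdispersion > 0) {
      shape <- 1 / config$overdispersion
      x <- x * rgamma(length(x), shape = shape, rate = shape)
    }
    as.numeric(rmultinom(1, size = depth, prob = x))
  }

  count_cols <- vector("list", nrow(meta))
  for (i in seq_len(nrow(meta))) {
    mi <- meta[i, ]
    if (mi$sample_kind == .kind_input) {
      abund <- w0
    } else {
      b <- per_cond[[mi$condition]]
      abund <- b$w0 * cond_growth(b, mi$timepoint_weeks) * 2^b$tau
    }
    count_cols[[i]] <- tibble::tibble(construct_id = cons$construct_id,
                                      sample_id = mi$sample_id,
                                      count = draw_counts(abund))
  }
  counts <- dplyr::bind_rows(count_cols)

  # --- closed-form expected LFC truth ------------------------------------
  construct_lfc <- purrr::map_dfr(config$conditions, function(cond) {
    b <- per_cond[[cond]]
    purrr::map_dfr(config$timepoints_weeks, function(t) {
      tibble::tibble(construct_id = b$construct_id, condition = cond,
                     timepoint_weeks = t,
                     lfc_true = log2(cond_growth(b, t)) + b$tau)
    })
  })

  truth <- list(
    genes = tibble::tibble(gene_id = genes, s = unname(s[genes])),
    guides = tibble::tibble(guide_id = guides$guide_id,
                            efficiency = unname(eff[guides$guide_id])),
    pairs = itab,
    constructs = dplyr::select(base, "construct_id", "s1", "s2", "e1", "e2",
                               "w0", "tau"),
    construct_lfc = construct_lfc)

  structure(list(counts = counts, meta = meta, design = design,
                 truth = truth, config = config, seed = seed),
            class = "gi_sim")
}

#' @export
print.gi_sim <- function(x, ...) {
  cat("<gi_sim> ", nrow(x$design$constructs), " constructs x ",
      nrow(x$meta), " samples; ", nrow(x$truth$pairs),
      " planted interaction terms; seed ", x$seed, "\n", sep = "")
  invisible(x)
}

#' Benchmark interaction calls against simulator ground truth
#'
#' @param truth The `truth` element of a [simulate_counts()] result.
#' @param calls An interaction-call tibble (from [call_interactions()] /
#'   [apply_filters()]).
#' @param call_col Which call column to evaluate; default `"call_filtered"`
#'   if present, else `"call"`.
#' @return Per condition x planted epsilon: `n_planted`, `n_recovered`
#'   (called with the matching sign), `recall`; plus per-condition
#'   `n_called`, `n_true_positive`, `precision`, `fdr` (NA when no calls).
#' @export
benchmark_report <- function(truth, calls,
                             call_col = NULL) {
  call_col <- call_col %||%
    (if ("call_filtered" %in% names(calls)) "call_filtered" else "call")
  calls <- calls |>
    dplyr::mutate(call_eval = .data[[call_col]]) |>
    dplyr::filter(.data$call_eval != .call_none)
  planted <- truth$pairs

  conds <- unique(c(planted$condition, calls$condition))
  purrr::map_dfr(conds, function(cond) {
    pl <- planted[planted$condition == cond, ]
    cl <- calls[calls$condition == cond, ]
    key_cl <- paste(cl$gene_a, cl$gene_b)
    hit <- function(ga, gb, eps) {
      j <- match(paste(ga, gb), key_cl)
      !is.na(j) & ((eps < 0 & cl$call_eval[j] == .call_lethal) |
                     (eps > 0 & cl$call_eval[j] == .call_viable))
    }
    pl$recovered <- if (nrow(pl)) hit(pl$gene_a, pl$gene_b, pl$epsilon)
                    else logical(0)
    n_tp <- sum(pl$recovered)
    per_eps <- pl |>
      dplyr::group_by(epsilon = .data$epsilon) |>
      dplyr::summarise(n_planted = dplyr::n(),
                       n_recovered = sum(.data$recovered),
                       recall = mean(.data$recovered), .groups = "drop")
    if (nrow(per_eps) == 0) {
      per_eps <- tibble::tibble(epsilon = NA_real_, n_planted = 0L,
                                n_recovered = 0L, recall = NA_real_)
    }
    per_eps |>
      dplyr::mutate(condition = cond, n_called = nrow(cl),
                    n_true_positive = n_tp,
                    precision = if (nrow(cl) == 0) NA_real_
                                else n_tp / nrow(cl),
                    fdr = 1 - .data$precision) |>
      dplyr::relocate("condition")
  })
}
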