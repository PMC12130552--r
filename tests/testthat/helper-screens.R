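# Fixture builders shared across test files. Everything is generated in code;
# no stored data.

# Minimal hand-built design: genes A and B (one guide each) plus one OR
# control, all four orientation/anchor constructs spelled out.
toy_design <- function() {
  cons <- tibble::tibble(
    construct_id = c("A__B", "A__OR", "OR__B", "OR__OR"),
    guide_pos1 = c("gA", "gA", "gOR", "gOR"),
    guide_pos2 = c("gB", "gOR", "gB", "gOR"),
    gene_pos1 = c("A", "A", "OR1", "OR1"),
    gene_pos2 = c("B", "OR1", "B", "OR1"),
    role_pos1 = c("TARGET", "TARGET", "OR_CONTROL", "OR_CONTROL"),
    role_pos2 = c("TARGET", "OR_CONTROL", "TARGET", "OR_CONTROL"))
  gi_design(cons)
}

# LFC tibble for toy_design() with chosen observed LFCs in one sample.
toy_lfc <- function(lfc_ab, lfc_a_or, lfc_or_b, lfc_or_or = 0,
                    sample_id = "s1") {
  tibble::tibble(construct_id = c("A__B", "A__OR", "OR__B", "OR__OR"),
                 sample_id = sample_id,
                 lfc_obs = c(lfc_ab, lfc_a_or, lfc_or_b, lfc_or_or))
}

toy_meta <- function(sample_ids = "s1", timepoint = 3) {
  tibble::tibble(
    sample_id = c("input", sample_ids),
    sample_kind = c("PLASMID_INPUT", rep("GDNA", length(sample_ids))),
    replicate = c(1L, seq_along(sample_ids)),
    timepoint_weeks = c(0, rep(timepoint, length(sample_ids))),
    condition = "standard", screen_id = "toy")
}

# Small simulated screen used by several files: n genes, weeks 1 and 3,
# 3 replicates, optional planted interactions and fixed gene fitness.
quick_sim <- function(n_genes = 6, interactions = NULL, gene_fitness = NULL,
                      seed = 1, replicates = 3, conditions = "standard",
                      noise = TRUE, ...) {
  cfg <- sim_config(n_target_genes = n_genes, timepoints_weeks = c(1, 3),
                    replicates = replicates, conditions = conditions,
                    interactions = interactions, gene_fitness = gene_fitness,
                    noise = noise, ...)
  design <- generate_design(cfg)
  sim <- simulate_counts(design, cfg, seed = seed)
  sim
}

# neutral background: every target gene exactly fitness 0
neutral_fitness <- function(n_genes) {
  setNames(rep(0, n_genes), sprintf("GENE%03d", seq_len(n_genes)))
}

# Independent brute-force two-stage step-up rejection set (indices), used as
# the oracle for bky_adjust().
bky_oracle_reject <- function(p, q) {
  m <- length(p)
  q1 <- q / (1 + q)
  step_up <- function(mult) {
    o <- order(p)
    k <- which(p[o] <= seq_len(m) * q1 / mult)
    if (length(k) == 0) integer(0) else sort(o[seq_len(max(k))])
  }
  r1 <- length(step_up(m))
  m0 <- m - r1
  if (m0 == 0) return(seq_len(m))
  step_up(m0)
}
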