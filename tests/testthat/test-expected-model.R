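test_that("single-KO effect is the average over OR pairings, per orientation", {
  # one target guide paired with three OR guides at position 2
  cons <- tibble::tibble(
    construct_id = c("T__OR1", "T__OR2", "T__OR3", "OR1__OR1"),
    guide_pos1 = c("gT", "gT", "gT", "gOR1"),
    guide_pos2 = c("gOR1", "gOR2", "gOR3", "gOR1"),
    gene_pos1 = c("T", "T", "T", "OR1"),
    gene_pos2 = c("OR1", "OR2", "OR3", "OR1"),
    role_pos1 = c("TARGET", "TARGET", "TARGET", "OR_CONTROL"),
    role_pos2 = rep("OR_CONTROL", 4))
  suppressWarnings(des <- gi_design(cons))
  lfc <- tibble::tibble(construct_id = cons$construct_id, sample_id = "s1",
                        lfc_obs = c(-1.0, -1.2, -0.8, 0))
  eff <- estimate_guide_effects(lfc, des)
  gt <- eff[eff$guide_id == "gT" & eff$position == "pos1", ]
  expect_equal(gt$lfc_single, -1.0)
  expect_equal(gt$n_or_pairs, 3L)
  # median option
  effm <- estimate_guide_effects(lfc, des, stat = "median")
  expect_equal(effm$lfc_single[effm$guide_id == "gT"], -1.0)
})

test_that("additive expectation and dLFC reproduce the worked two-gene arithmetic", {
  des <- toy_design()
  # Cas12a-style: singles +0.60 and +0.56, observed double +0.65
  lfc <- toy_lfc(lfc_ab = 0.65, lfc_a_or = 0.60, lfc_or_b = 0.56)
  dl <- compute_expected(lfc, estimate_guide_effects(lfc, des), des)
  ab <- dl[dl$construct_id == "A__B", ]
  expect_equal(ab$lfc_exp, 1.16)
  expect_equal(ab$dlfc, -0.51)  # candidate synthetic lethal

  # Cas9-style: singles -0.44 and -0.56, observed double -0.40
  lfc2 <- toy_lfc(lfc_ab = -0.40, lfc_a_or = -0.44, lfc_or_b = -0.56)
  dl2 <- compute_expected(lfc2, estimate_guide_effects(lfc2, des), des)
  ab2 <- dl2[dl2$construct_id == "A__B", ]
  expect_equal(ab2$lfc_exp, -1.00)
  expect_equal(ab2$dlfc, 0.60)  # candidate synthetic viable
  expect_true(sign(ab$dlfc) != sign(ab2$dlfc))

  # OR-containing constructs have dLFC exactly 0 here (their own estimate
  # enters the expectation), so the centering offset is 0
  expect_equal(dl$dlfc[dl$construct_id == "A__OR"], 0)
  expect_equal(attr(dl, "dlfc_offsets")$offset, 0)
})

test_that("gene-level single KO is the unweighted mean over guides and positions", {
  eff <- tibble::tibble(
    guide_id = rep(c("gA1", "gA2", "gA3"), each = 2),
    position = rep(c("pos1", "pos2"), 3),
    sample_id = "s1",
    lfc_single = c(-2.5, -2.1, -1.9, -2.6, -2.2, -2.0),
    n_or_pairs = 3L)
  des <- list(guides = tibble::tibble(guide_id = c("gA1", "gA2", "gA3"),
                                      gene_id = "A", role = "TARGET"))
  ko <- gene_level_single_ko(eff, des)
  expect_equal(ko$lfc_single_gene, -2.2166667, tolerance = 1e-7)
  expect_equal(ko$n_guide_effects, 6L)

  zero <- dplyr::mutate(eff, lfc_single = 0)
  expect_equal(gene_level_single_ko(zero, des)$lfc_single_gene, 0)
})

test_that("on null screens OR guides and OR-containing constructs stay near zero", {
  sim <- quick_sim(5, gene_fitness = neutral_fitness(5), seed = 21)
  des <- sim$design
  lfc <- compute_lfc_obs(normalize_depth(sim$counts), des, sim$meta)
  eff <- estimate_guide_effects(lfc, des)
  or_ids <- des$guides$guide_id[des$guides$role == "OR_CONTROL"]
  or_eff <- eff$lfc_single[eff$guide_id %in% or_ids]
  expect_lt(abs(mean(or_eff)), 0.1)

  dl <- compute_expected(lfc, eff, des)
  with_or <- des$constructs$construct_id[
    des$constructs$role_pos1 == "OR_CONTROL" |
      des$constructs$role_pos2 == "OR_CONTROL"]
  expect_lt(abs(mean(dl$dlfc[dl$construct_id %in% with_or], na.rm = TRUE)),
            0.05)
})

test_that("dLFC matches an independent straight-line recomputation from raw counts", {
  sim <- quick_sim(2, guides_per_gene = 1, n_or_guides = 1, seed = 13,
                   replicates = 1)  # 9 constructs
  des <- sim$design

  # pipeline route
  lfc <- compute_lfc_obs(normalize_depth(sim$counts), des, sim$meta)
  dl <- compute_expected(lfc, estimate_guide_effects(lfc, des), des)

  # oracle route: plain base-R matrix arithmetic, no package internals
  wide <- tidyr::pivot_wider(sim$counts, names_from = "sample_id",
                             values_from = "count")
  m <- as.matrix(wide[-1])
  rownames(m) <- wide$construct_id
  cpm <- sweep(m, 2, colSums(m), "/") * 1e6
  cons <- des$constructs
  oror <- cons$construct_id[cons$role_pos1 == "OR_CONTROL" &
                              cons$role_pos2 == "OR_CONTROL"]
  for (s in setdiff(colnames(m), "plasmid")) {
    raw <- log2((cpm[, s] + 1) / (cpm[, "plasmid"] + 1))
    raw <- raw - median(raw[oror])
    # per-guide effects from OR pairings
    eff1 <- sapply(unique(cons$guide_pos1), function(g) {
      sel <- cons$guide_pos1 == g & cons$role_pos2 == "OR_CONTROL"
      mean(raw[cons$construct_id[sel]])
    })
    eff2 <- sapply(unique(cons$guide_pos2), function(g) {
      sel <- cons$guide_pos2 == g & cons$role_pos1 == "OR_CONTROL"
      mean(raw[cons$construct_id[sel]])
    })
    exp_lfc <- eff1[cons$guide_pos1] + eff2[cons$guide_pos2]
    dlfc <- raw[cons$construct_id] - exp_lfc
    has_or <- cons$role_pos1 == "OR_CONTROL" | cons$role_pos2 == "OR_CONTROL"
    dlfc <- dlfc - median(dlfc[has_or])
    got <- dl[dl$sample_id == s, ]
    expect_equal(got$dlfc[match(cons$construct_id, got$construct_id)],
                 unname(dlfc), tolerance = 1e-12)
  }
})

test_that("orientation halves agree on symmetric simulations", {
  sim <- quick_sim(6, seed = 31, overdispersion = 0.01,
                   gene_fitness = setNames(seq(-1.5, 0, length.out = 6),
                                           sprintf("GENE%03d", 1:6)))
  lfc <- compute_lfc_obs(normalize_depth(sim$counts), sim$design, sim$meta)
  dl <- compute_expected(lfc, estimate_guide_effects(lfc, sim$design),
                         sim$design)
  w3 <- sim$meta$sample_id[sim$meta$timepoint_weeks == 3]
  cc <- orientation_concordance(dl, sim$design, value = "lfc_obs",
                                samples = w3)
  expect_gt(cc$pcc, 0.9)
})
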