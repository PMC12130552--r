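test_that("saturation filter removes clamped pseudo-rescues, keeps genuine ones", {
  cfg <- filter_config()
  # singles -2 and -1 (expectation -3), observed -2.5: below both singles,
  # expectation saturated -> filtered
  expect_true(saturation_filter("SYNTHETIC_VIABLE", lfc_obs = -2.5,
                                lfc_exp = -3, single_ko_a = -2,
                                single_ko_b = -1, config = cfg))
  # observed -0.8 rises above the milder single (-1): genuine rescue, kept
  expect_false(saturation_filter("SYNTHETIC_VIABLE", lfc_obs = -0.8,
                                 lfc_exp = -3, single_ko_a = -2,
                                 single_ko_b = -1, config = cfg))
  # expectation above the threshold: never filtered
  expect_false(saturation_filter("SYNTHETIC_VIABLE", lfc_obs = -0.5,
                                 lfc_exp = -0.2, single_ko_a = -0.1,
                                 single_ko_b = -0.1, config = cfg))
  # lethal calls and non-calls are never touched
  expect_false(saturation_filter("SYNTHETIC_LETHAL", -2.5, -3, -2, -1, cfg))
  expect_false(saturation_filter("NONE", -2.5, -3, -2, -1, cfg))
  # undefined singles retain the call
  expect_false(saturation_filter("SYNTHETIC_VIABLE", -2.5, -3, NA, -1, cfg))
})

test_that("time-course filter drops changes smaller than 0.1 log2", {
  cfg <- filter_config()
  expect_true(timecourse_filter(-0.50, -0.45, config = cfg))   # |d| = 0.05
  expect_false(timecourse_filter(-0.5, 0, config = cfg))       # grew in
  expect_true(timecourse_filter(-0.5, -0.5, config = cfg))     # zero change
  expect_false(timecourse_filter(-0.5, NA, config = cfg))      # skipped
  # directional variant: a lethal call whose dLFC moved toward zero is dropped
  dcfg <- filter_config(timecourse_directional = TRUE)
  expect_true(timecourse_filter(-0.5, -0.9, call = "SYNTHETIC_LETHAL",
                                config = dcfg))
  expect_false(timecourse_filter(-0.9, -0.5, call = "SYNTHETIC_LETHAL",
                                 config = dcfg))
})

test_that("essential flag requires the threshold in every screen", {
  ko <- tibble::tibble(
    screen_id = rep(c("cas12a", "cas9"), each = 3),
    gene_id = rep(c("G1", "G2", "G3"), 2),
    lfc_single_gene = c(-2.5, -2.5, -0.5, -2.5, -1.0, -0.6))
  expect_identical(essential_genes(ko), "G1")  # G2 misses in cas9
  calls <- tibble::tibble(gene_a = c("G1", "G2"), gene_b = c("G3", "G3"),
                          essential_flag = FALSE)
  flagged <- flag_essential(calls, ko)
  expect_identical(flagged$essential_flag, c(TRUE, FALSE))
})

test_that("the clamped essential x essential pair is viable-called then filtered", {
  # both genes strongly deleterious; the additive expectation overshoots the
  # fitness floor, so the double KO looks 'viable' -- the saturation filter's
  # target case. Analytic mode keeps the arithmetic exact.
  suppressWarnings(  # legitimately degenerate: the one pair is clamped
    sim <- quick_sim(2, guides_per_gene = 2, n_or_guides = 2,
                     gene_fitness = c(GENE001 = -2.5, GENE002 = -2.5),
                     noise = FALSE, seed = 1))
  res <- score_screen(sim$counts, sim$design, sim$meta, pseudocount = 0)
  pair <- dplyr::filter(res$calls, gene_a == "GENE001", gene_b == "GENE002")
  expect_gt(pair$dlfc, 0.3)                     # apparent viability
  expect_identical(pair$call, "SYNTHETIC_VIABLE")
  expect_true(pair$saturation_filtered)
  expect_identical(pair$call_filtered, "NONE")
  expect_true(pair$essential_flag)

  # genuine rescue: a strong positive interaction lifts the double KO above
  # the milder single-KO effect -> kept
  sim2 <- quick_sim(2, guides_per_gene = 2, n_or_guides = 2,
                    gene_fitness = c(GENE001 = -2, GENE002 = -1),
                    interactions = data.frame(gene_a = "GENE001",
                                              gene_b = "GENE002",
                                              epsilon = 2.2),
                    noise = FALSE, seed = 1)
  res2 <- score_screen(sim2$counts, sim2$design, sim2$meta, pseudocount = 0)
  pair2 <- dplyr::filter(res2$calls, gene_a == "GENE001", gene_b == "GENE002")
  expect_identical(pair2$call, "SYNTHETIC_VIABLE")
  expect_false(pair2$saturation_filtered)
  expect_identical(pair2$call_filtered, "SYNTHETIC_VIABLE")
})

test_that("saturation filtering measurably cuts false viables among essentials", {
  fit <- c(setNames(rep(-2.5, 4), sprintf("GENE%03d", 1:4)),
           setNames(rep(0, 4), sprintf("GENE%03d", 5:8)))
  # near-complete editing and deep sequencing: the regime where clamped
  # essential pairs masquerade as synthetic viable
  sim <- quick_sim(8, gene_fitness = fit, seed = 61,
                   guide_efficiency = 0.95, depth = 2e6)
  res <- score_screen(sim$counts, sim$design, sim$meta)
  ess_pairs <- res$calls |>
    dplyr::filter(gene_a %in% names(fit)[1:4], gene_b %in% names(fit)[1:4])
  before <- sum(ess_pairs$call == "SYNTHETIC_VIABLE")
  after <- sum(ess_pairs$call_filtered == "SYNTHETIC_VIABLE")
  expect_gt(before, 0)
  expect_lt(after, before)
})

test_that("filters are pure per-row predicates and only touch their own sign", {
  sim <- quick_sim(4, seed = 67,
                   interactions = data.frame(gene_a = "GENE001",
                                             gene_b = "GENE002",
                                             epsilon = -1))
  res <- score_screen(sim$counts, sim$design, sim$meta)
  calls <- res$calls
  # recompute flags standalone; must equal what the pipeline stored
  expect_identical(
    saturation_filter(calls$call, calls$lfc_obs, calls$lfc_exp,
                      calls$single_ko_a, calls$single_ko_b, res$filters),
    calls$saturation_filtered)
  # saturation never removes lethal calls
  expect_false(any(calls$saturation_filtered &
                     calls$call == "SYNTHETIC_LETHAL"))
  # flagged table is a superset view: filtered calls still carry their raw call
  expect_true(all(calls$call[calls$call_filtered != "NONE"] ==
                    calls$call_filtered[calls$call_filtered != "NONE"]))
})
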