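test_that("paired test matches the textbook statistic and its conventions", {
  # oracle-computed frozen values for fixed differences
  obs <- c(-0.5, -0.6, -0.4, -0.5, -0.55, -0.45)
  res <- paired_test(obs, rep(0, 6))
  expect_equal(res$t, -17.3205081, tolerance = 1e-6)
  expect_equal(res$p, 1.175206e-05, tolerance = 1e-5)
  expect_equal(res$df, 5)

  # obs == exp elementwise: no interaction, p = 1 by convention
  same <- paired_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$p, 1)
  expect_true(same$degenerate)

  # constant nonzero differences: p = 0 with the degenerate flag
  const <- paired_test(c(1, 2, 3), c(0, 1, 2))
  expect_equal(const$p, 0)
  expect_true(const$degenerate)
  expect_identical(const$t, Inf)

  # antisymmetry: negating differences negates t, keeps p
  a <- paired_test(c(0.1, 0.4, 0.2, 0.5), c(0, 0, 0, 0))
  b <- paired_test(-c(0.1, 0.4, 0.2, 0.5), c(0, 0, 0, 0))
  expect_equal(a$t, -b$t)
  expect_equal(a$p, b$p)

  # a single pair is untestable
  expect_true(is.na(paired_test(1, 2)$p))
})

test_that("BKY adjustment reproduces the brute-force two-stage rejection set", {
  expect_equal(as.numeric(bky_adjust(rep(1, 5), q = 0.1)), rep(1, 5))
  expect_error(bky_adjust(c(0.5, 1.2)), class = "gipairs_data_error")
  expect_error(bky_adjust(c(0.5, NA)), class = "gipairs_data_error")

  # m = 1: rejection iff p <= q/(1+q), across a q grid
  for (q in seq(0.01, 0.5, by = 0.01)) {
    padj <- bky_adjust(0.03, q = q)
    expect_identical(padj <= q, 0.03 <= q / (1 + q))
  }

  # random vectors of length <= 12 against the independent oracle
  set.seed(99)
  for (i in 1:300) {
    m <- sample(1:12, 1)
    p <- switch(sample(3, 1), runif(m), rbeta(m, 0.3, 1), round(runif(m), 2))
    for (q in c(0.005, 0.01, 0.05, 0.1)) {
      padj <- bky_adjust(p, q = q)
      expect_identical(which(padj <= q), bky_oracle_reject(p, q))
    }
    # monotone in p-rank
    padj <- as.numeric(bky_adjust(p, q = 0.1))
    expect_true(all(diff(padj[order(p)]) >= -1e-15))
  }
})

test_that("per-replicate scoring yields one tested row per pair per replicate", {
  sim <- quick_sim(3, seed = 41)
  res <- score_screen(sim$counts, sim$design, sim$meta)
  w3 <- dplyr::filter(res$scores, timepoint_weeks == 3)
  counts <- dplyr::count(w3, gene_a, gene_b)
  expect_true(all(counts$n == 3))          # 3 replicates
  expect_true(all(w3$n_constructs == 18))  # 3x3 guides, both orientations
  expect_true(all(!is.na(w3$p) & !is.na(w3$padj)))
  expect_true(all(w3$p >= 0 & w3$p <= 1))
  # pair dLFC equals mean(obs) - mean(exp) over the same set
  expect_equal(w3$dlfc, w3$lfc_obs - w3$lfc_exp, tolerance = 1e-12)
})

test_that("merged mode equals a single test on the replicate-concatenated set", {
  sim <- quick_sim(3, seed = 43, replicates = 2,
                   interactions = data.frame(gene_a = "GENE001",
                                             gene_b = "GENE002",
                                             epsilon = -0.8))
  des <- sim$design
  lfc <- compute_lfc_obs(normalize_depth(sim$counts), des, sim$meta)
  dl <- compute_expected(lfc, estimate_guide_effects(lfc, des), des)
  merged <- score_gene_pairs(dl, des, sim$meta,
                             scoring_config(mode = "merged"))
  m12 <- dplyr::filter(merged, gene_a == "GENE001", gene_b == "GENE002",
                       timepoint_weeks == 3)
  expect_identical(m12$n_constructs, 36L)  # 18 constructs x 2 replicates

  # direct t.test on the stacked per-replicate vectors
  w3 <- sim$meta$sample_id[sim$meta$timepoint_weeks == 3]
  stacked <- dl |>
    dplyr::inner_join(des$constructs, by = "construct_id") |>
    dplyr::filter(sample_id %in% w3, role_pos1 == "TARGET",
                  role_pos2 == "TARGET",
                  pmin(gene_pos1, gene_pos2) == "GENE001",
                  pmax(gene_pos1, gene_pos2) == "GENE002")
  tt <- t.test(stacked$lfc_obs, stacked$lfc_exp, paired = TRUE)
  expect_equal(m12$p, tt$p.value, tolerance = 1e-12)
  expect_equal(m12$dlfc, mean(stacked$lfc_obs - stacked$lfc_exp),
               tolerance = 1e-12)
})

test_that("interaction calls respect thresholds and replicate unanimity", {
  mk_scores <- function(dlfc, padj) {
    tibble::tibble(screen_id = "s", condition = "standard",
                   replicate = seq_along(dlfc), timepoint_weeks = 3,
                   gene_a = "A", gene_b = "B", n_constructs = 18,
                   lfc_obs = 0, lfc_exp = 0, dlfc = dlfc, t = 0, df = 17,
                   p = padj, degenerate = FALSE, padj = padj)
  }
  cfg <- scoring_config()
  lethal <- call_interactions(mk_scores(c(-0.51, -0.5, -0.52),
                                        c(0.01, 0.02, 0.05)), cfg)
  expect_identical(lethal$call, "SYNTHETIC_LETHAL")

  # magnitude below threshold: no call however significant
  weak <- call_interactions(mk_scores(c(0.25, 0.25, 0.25), rep(1e-6, 3)), cfg)
  expect_identical(weak$call, "NONE")

  # unanimity: one replicate above alpha kills the call
  split <- call_interactions(mk_scores(c(-0.8, -0.8, -0.8),
                                       c(0.01, 0.2, 0.01)), cfg)
  expect_identical(split$call, "NONE")

  # an untestable replicate can never support a call
  nat <- call_interactions(mk_scores(c(-0.8, -0.8, -0.8),
                                     c(0.01, NA, 0.01)), cfg)
  expect_identical(nat$call, "NONE")
})

test_that("per-replicate unanimity is at least as conservative as any replicate", {
  sim <- quick_sim(6, seed = 47,
                   interactions = data.frame(
                     gene_a = c("GENE001", "GENE003"),
                     gene_b = c("GENE002", "GENE004"),
                     epsilon = c(-1, -0.4)))
  res <- score_screen(sim$counts, sim$design, sim$meta)
  cfg <- res$config
  called <- res$calls |>
    dplyr::filter(call != "NONE") |>
    dplyr::mutate(key = paste(gene_a, gene_b))
  w3 <- dplyr::filter(res$scores, timepoint_weeks == 3)
  for (r in unique(w3$replicate)) {
    solo <- w3 |>
      dplyr::filter(replicate == r, !is.na(padj), padj < cfg$alpha,
                    abs(dlfc) > cfg$dlfc_threshold) |>
      dplyr::mutate(key = paste(gene_a, gene_b))
    expect_true(all(called$key %in% solo$key))
  }
})

test_that("a null screen produces essentially no calls", {
  sim <- quick_sim(6, gene_fitness = neutral_fitness(6), seed = 53)
  res <- score_screen(sim$counts, sim$design, sim$meta)
  expect_lte(sum(res$calls$call != "NONE"), 1)  # 15 pairs, < 1 expected
})
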