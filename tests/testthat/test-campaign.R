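test_that("greedy selection returns the best-predicted ids", {
  lib <- fixture_library(1000, 7)
  sub <- lib[1:10, ]
  pred <- stats::setNames(seq(-10, -1, length.out = 10), sub$id)
  sel <- select_batch(round_spec(3, selection = "greedy"), sub,
                      predictions = pred)
  expect_identical(sel, sub$id[1:3])
  # deterministic tie-break on equal predictions: lexicographic id
  tied <- stats::setNames(rep(-5, 10), sub$id)
  sel_t <- select_batch(round_spec(3, selection = "greedy"), sub,
                        predictions = tied)
  expect_identical(sel_t, sort(sub$id)[1:3])
})

test_that("diverse selection degenerates to one pick for identical molecules", {
  lib <- fixture_library(1000, 7)
  same <- lib[rep(3, 8), ]
  same$id <- paste0("d", 1:8)
  pred <- stats::setNames(rep(-5, 8), same$id)
  expect_warning(
    sel <- select_batch(round_spec(5, selection = "diverse",
                                   sim_threshold = 0.4),
                        same, predictions = pred),
    "shortfall")
  expect_length(sel, 1)
})

test_that("diverse selection equals brute-force leader over the pool", {
  lib <- fixture_library(1000, 7)
  pool <- lib[1:50, ]
  pred <- score_tier1(pool)
  names(pred) <- pool$id
  expect_warning(
    sel <- select_batch(round_spec(50, selection = "diverse",
                                   sim_threshold = 0.4),
                        pool, predictions = pred),
    "shortfall")
  ord <- order(pred[pool$id], pool$id)
  fps <- fingerprints(pool[ord, ])
  expect_identical(sel, pool$id[ord][bf_leader(fps, 0.4)])
})

test_that("an exhaustive screen recovers every hit", {
  lib <- fixture_library(2000, 21)
  cs <- run_screening_campaign(
    lib, schedule = list(round_spec(2000, selection = "random")), seed = 1)
  expect_equal(nrow(cs$ledger), 2000)
  truth <- score_tier1(lib)
  thr <- unname(quantile(truth, 0.01, type = 7))
  expect_equal(sum(cs$ledger$score < thr), sum(truth < thr))
  # recall CI at full budget contains 1.0
  est <- estimate_recall_bootstrap(cs$ledger$score, 2000, thr,
                                   found = sum(cs$ledger$score < thr),
                                   seed = 4)
  expect_lte(est$ci_recall[1], 1.0)
  expect_gte(est$ci_recall[2], 1.0)
  expect_equal(est$recall, 1.0, tolerance = 1e-12)
})

test_that("campaign ledger accounting and hit monotonicity hold", {
  lib <- fixture_library(2000, 21)
  sched <- list(round_spec(120, selection = "random"),
                round_spec(60, pool = 0.2, selection = "diverse",
                           sim_threshold = 0.5),
                round_spec(60, pool = 0.2, selection = "greedy"))
  cs <- suppressWarnings(run_screening_campaign(lib, schedule = sched, seed = 2,
                                                hit_threshold = -8))
  expect_lte(nrow(cs$ledger), 240)
  expect_equal(anyDuplicated(cs$ledger$id), 0)
  expect_true(all(cs$ledger$id %in% lib$id))
  expect_equal(nrow(cs$ledger),
               sum(vapply(cs$rounds, `[[`, numeric(1), "acquired")))
  cum <- vapply(cs$rounds, `[[`, numeric(1), "cumulative_hits")
  expect_true(all(diff(cum) >= 0))
  # over-budget schedules are rejected before any scoring
  expect_error(run_screening_campaign(
    lib, schedule = list(round_spec(3000, selection = "random"))),
    "over budget")
})

test_that("campaigns are reproducible under a fixed seed", {
  lib <- fixture_library(2000, 21)
  sched <- list(round_spec(120, selection = "random"),
                round_spec(60, pool = 0.2, selection = "greedy"))
  c1 <- run_screening_campaign(lib, schedule = sched, seed = 9)
  c2 <- run_screening_campaign(lib, schedule = sched, seed = 9)
  expect_identical(c1$ledger, c2$ledger)
})

test_that("campaign configurations round-trip through YAML", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c(
    "library: {n_molecules: 5000, seed: 3}",
    "seed: 2",
    "hit_threshold: -8.5",
    "schedule:",
    "  - {acquire_size: 500, pool: whole_library, selection: random}",
    "  - {acquire_size: 100, pool: 0.05, selection: diverse, sim_threshold: 0.5}",
    "  - {acquire_size: 100, pool: 0.05, selection: greedy}"), path)
  cfg <- read_campaign_config(path)
  expect_s3_class(cfg$library, "library_config")
  expect_equal(cfg$library$n_molecules, 5000L)
  expect_length(cfg$schedule, 3)
  expect_s3_class(cfg$schedule[[2]], "round_spec")
  expect_equal(cfg$schedule[[2]]$sim_threshold, 0.5)
  expect_equal(cfg$hit_threshold, -8.5)
  # omitted schedule falls back to the default shape
  minimal <- withr::local_tempfile(fileext = ".yaml")
  writeLines("library: {n_molecules: 200000}", minimal)
  cfg2 <- read_campaign_config(minimal)
  expect_length(cfg2$schedule, 4)
  expect_equal(cfg2$schedule[[1]]$acquire_size, 75L)
})

test_that("bootstrap recall estimation matches known ground truth", {
  # synthetic calibration: 10,000 scores with exactly 100 below threshold
  scores <- c(seq(-12, -9.01, length.out = 100),
              seq(-8.9, -2, length.out = 9900))
  thr <- -9
  samp <- alscreen:::.with_seed(5, sample(scores, 1000))
  k <- sum(samp < thr)
  est <- estimate_recall_bootstrap(samp, 10000, thr, found = 50, B = 1000,
                                   seed = 2)
  expect_equal(est$estimated_total, k / 1000 * 10000)
  expect_equal(est$recall, min(1, 50 / est$estimated_total))
  expect_lte(est$ci_recall[1], 0.5)
  expect_gte(est$ci_recall[2], 0.5)
  # deterministic under a fixed seed
  est2 <- estimate_recall_bootstrap(samp, 10000, thr, found = 50, B = 1000,
                                    seed = 2)
  expect_identical(est$ci_recall, est2$ci_recall)
  # degenerate all-hits sample
  all_hits <- rep(-10, 200)
  e <- estimate_recall_bootstrap(all_hits, 200, -9, found = 200, seed = 1)
  expect_equal(e$recall, 1.0)
  expect_equal(unname(e$ci_recall), c(1, 1))
  expect_error(estimate_recall_bootstrap(rep(-2, 100), 1000, -9, found = 0),
               "no hits in calibration sample")
})

test_that("rescoring stages honour their contracts", {
  lib <- fixture_library(20000, 31)
  cs <- suppressWarnings(run_screening_campaign(
    lib,
    schedule = list(round_spec(400, selection = "random"),
                    round_spec(400, pool = 0.1, selection = "greedy")),
    seed = 3, hit_threshold = -7))
  cfg <- rescoring_config(eligibility_threshold = -7, scale = 1 / 20)
  l2 <- suppressWarnings(run_rescoring_campaign(cs, lib, config = cfg, seed = 4))
  expect_gt(nrow(l2), 0)
  expect_equal(anyDuplicated(l2$id), 0)
  expect_true(all(l2$stage %in% c("seed", "loop", "refine", "final")))
  expect_true(all(l2$id %in% lib$id))
  # stage C excludes molecules with two or more carboxylic acids
  refine_ids <- l2$id[l2$stage == "refine"]
  if (length(refine_ids) > 0) {
    expect_true(all(lib$n_acid[match(refine_ids, lib$id)] < 2))
  }
  # stage counts respect the rescaled configuration
  n_final <- sum(l2$stage == "final")
  expect_lte(n_final, ceiling(522 / 20))
  expect_lte(sum(l2$stage %in% c("seed", "loop")), ceiling(1700 / 20))
  # every rescored id is tier-1 eligible (stages A-C) or in the relaxed pool
  t1 <- cs$ledger
  eligible <- t1$id[t1$score < -7]
  relaxed <- t1$id[t1$score < -4]
  expect_true(all(l2$id[l2$stage != "final"] %in% eligible))
  expect_true(all(l2$id[l2$stage == "final"] %in% relaxed))
})

test_that("rescoring warns and skips on an empty eligible pool", {
  lib <- fixture_library(2000, 21)
  cs <- run_screening_campaign(
    lib, schedule = list(round_spec(100, selection = "random")), seed = 1)
  cfg <- rescoring_config(eligibility_threshold = -99)
  expect_warning(l2 <- run_rescoring_campaign(cs, lib, config = cfg),
                 "empty eligible pool")
  expect_equal(nrow(l2), 0)
})
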