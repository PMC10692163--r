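test_that("CSV round trip preserves ids, structures and numeric columns", {
  lib <- fixture_library(1000, 7)
  recs <- lib[1:10, ]
  recs$tier1 <- score_tier1(lib[1:10, ])
  path <- withr::local_tempfile(fileext = ".csv")
  write_molecules(recs, path)
  back <- read_molecules(path)
  expect_identical(back$id, recs$id)
  expect_identical(back$smiles, recs$smiles)
  expect_equal(back$tier1, recs$tier1, tolerance = 1e-12)
  # descriptors recomputed from structure agree with the generator's
  expect_equal(back$mw, recs$mw, tolerance = 1e-6)
  expect_equal(back$n_rotatable, recs$n_rotatable)
})

test_that("invalid entries are reported, not dropped silently", {
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(id = paste0("m", 1:5),
                       smiles = c("CCO", "C1CC1", "xx((", "c1ccccc1", "CC(=O)O")),
            path, row.names = FALSE)
  recs <- read_molecules(path)
  expect_equal(nrow(recs), 4)
  expect_identical(attr(recs, "failures"), "m3")

  empty <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(id = "m1", smiles = "not_a_smiles(("), empty,
            row.names = FALSE)
  expect_error(read_molecules(empty), "no valid structures")
  expect_error(read_molecules(withr::local_tempfile(fileext = ".xyz")),
               "no such file")
})

test_that("SDF input yields records with the 3D flag set", {
  recs <- molecule_records(c("CC(=O)NCC(=O)O", "OC(=O)c1ccc(F)cc1", "CCO"),
                           c("S1", "S2", "S3"))
  path <- withr::local_tempfile(fileext = ".sdf")
  generate_poses(recs, path, seed = 1)
  back <- read_molecules(path)
  expect_equal(nrow(back), 3)
  expect_true(all(back$is_3d))
})

test_that("lead-like filter applies the strict bounds", {
  mk <- function(mw, clogp, rings, rot) {
    data.frame(id = "x", mw = mw, clogp = clogp, n_rings = rings,
               n_rotatable = rot)
  }
  # interior point passes
  expect_true(leadlike_filter(mk(300, 2, 2, 5))$pass)
  # single violated criterion is named
  r <- leadlike_filter(mk(470, 2, 2, 5))
  expect_false(r$pass)
  expect_identical(r$failed_criteria, "mw")
  # boundaries: all "less than" bounds strict, logP interval inclusive
  expect_false(leadlike_filter(mk(460, 2, 2, 5))$pass)
  expect_false(leadlike_filter(mk(300, 2, 4, 5))$pass)
  expect_false(leadlike_filter(mk(300, 2, 2, 10))$pass)
  expect_true(leadlike_filter(mk(300, 4, 2, 5))$pass)
  expect_true(leadlike_filter(mk(300, -4, 2, 5))$pass)
  expect_false(leadlike_filter(mk(300, 4.01, 2, 5))$pass)
  # multiple violations enumerate every rule
  r2 <- leadlike_filter(mk(500, 5, 6, 12))
  expect_identical(r2$failed_criteria, "mw,clogp,rings,rotatable")
})

test_that("tanimoto matches hand counts and is symmetric", {
  expect_equal(tanimoto(c(1L, 2L, 3L), c(2L, 3L, 4L)), 0.5)
  expect_equal(tanimoto(c(5L, 9L), c(5L, 9L)), 1.0)
  expect_equal(tanimoto(c(1L, 2L), c(7L, 8L)), 0.0)
  expect_equal(tanimoto(integer(0), integer(0)), 0.0)

  lib <- fixture_library(1000, 7)
  fps <- fingerprints(lib[1:20, ])
  for (i in 1:5) {
    a <- fps[[2 * i - 1]]; b <- fps[[2 * i]]
    expect_equal(tanimoto(a, b), tanimoto(b, a))
    expect_equal(tanimoto(a, b), bf_tanimoto(a, b), tolerance = 1e-12)
    expect_equal(tanimoto(a, a), 1.0)
  }
})

test_that("fingerprints are invariant to input atom renumbering", {
  pairs <- rbind(
    c("CC(=O)NC(Cc1ccccc1)C(=O)O", "OC(=O)C(Cc1ccccc1)NC(C)=O"),
    c("Fc1ccc(CNC(=O)CO)cc1", "OCC(=O)NCc1ccc(F)cc1"),
    c("CCS(=O)(=O)NC", "CNS(=O)(=O)CC"))
  for (i in seq_len(nrow(pairs))) {
    recs <- molecule_records(pairs[i, ], c("a", "b"))
    fps <- fingerprints(recs)
    expect_identical(fps$a, fps$b)
  }
})

test_that("diverse_subset equals the brute-force leader algorithm", {
  lib <- fixture_library(1000, 7)
  recs <- lib[sample.int(1000, 50), ]
  fps <- fingerprints(recs)
  kept <- diverse_subset(recs, threshold = 0.4)
  expect_identical(kept$id, recs$id[bf_leader(fps, 0.4)])
  # output order is a subsequence of input order; rerun is identical
  expect_true(all(diff(match(kept$id, recs$id)) > 0))
  expect_identical(kept, diverse_subset(recs, threshold = 0.4))
  # every kept pair is below the threshold
  kfps <- fingerprints(kept)
  for (i in seq_along(kfps)) {
    for (j in seq_len(i - 1)) {
      expect_lt(tanimoto(kfps[[i]], kfps[[j]]), 0.4)
    }
  }
})

test_that("diverse_subset handles degenerate inputs", {
  lib <- fixture_library(1000, 7)
  same <- lib[rep(3, 5), ]
  same$id <- paste0("dup", 1:5)
  expect_equal(nrow(diverse_subset(same, threshold = 0.4)), 1)
  expect_equal(nrow(diverse_subset(lib[0, ], threshold = 0.4)), 0)
  # threshold 1 keeps everything but exact duplicates
  expect_equal(nrow(diverse_subset(same, threshold = 1)), 1)
})

test_that("count_substructure counts unique SMARTS matches", {
  recs <- molecule_records(
    c("CC(=O)O", "c1ccccc1", "NC(CC(=O)O)C(=O)O", "CS(=O)(=O)NC", "CC(=O)NC"),
    c("acetic", "benzene", "asp", "sulfonamide", "amide"))
  acid <- count_substructure(recs, "carboxylic_acid")
  expect_equal(unname(acid), c(1L, 0L, 2L, 0L, 0L))
  expect_equal(unname(count_substructure(recs, "sulfonamide")),
               c(0L, 0L, 0L, 1L, 0L))
  expect_equal(unname(count_substructure(recs, "amide")),
               c(0L, 0L, 0L, 0L, 1L))
  expect_equal(unname(count_substructure(recs, "a")),
               c(0L, 6L, 0L, 0L, 0L))
})

test_that("graph feature selections agree with substructure counts", {
  lib <- fixture_library(1000, 7)
  idx <- seq(1, 1000, by = 97)
  recs <- lib[idx, ]
  counts <- count_substructure(recs, "carboxylic_acid")
  parsed <- alscreen:::mol_graphs_from_smiles(
    stats::setNames(recs$smiles, recs$id))
  rule <- vapply(parsed$graphs[recs$id],
                 function(g) length(feature_atoms(g, "carboxylic_acid")),
                 integer(1))
  expect_equal(unname(rule), unname(counts))
  expect_equal(unname(rule), recs$n_acid)
})
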