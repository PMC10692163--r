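test_that("library generation is deterministic, unique and valid", {
  one <- generate_library(library_config(n_molecules = 1, seed = 1))
  expect_equal(nrow(one), 1)
  expect_identical(one, generate_library(library_config(n_molecules = 1, seed = 1)))

  lib <- fixture_library(1000, 7)
  expect_equal(nrow(lib), 1000)
  expect_equal(length(unique(lib$id)), 1000)
  expect_identical(lib, generate_library(library_config(n_molecules = 1000, seed = 7)))

  parsed <- alscreen:::mol_graphs_from_smiles(stats::setNames(lib$smiles, lib$id))
  expect_length(parsed$failures, 0)
})

test_that("a documented majority of generated molecules is lead-like", {
  lib <- fixture_library(1000, 7)
  lf <- leadlike_filter(lib)
  expect_gte(sum(lf$pass), 800)
})

test_that("generator requests beyond the enumeration space are rejected", {
  sets <- list(acids = c("CC(=O)O", "CCC(=O)O"),
               centrals = "NCC(=O)O",
               amines = c("NC", "NCC"))
  cfg <- library_config(n_molecules = 4, seed = 1, synthon_sets = sets,
                        coupling_rules = "AC")
  expect_equal(nrow(generate_library(cfg)), 4)
  expect_error(generate_library(library_config(n_molecules = 5, seed = 1,
                                               synthon_sets = sets,
                                               coupling_rules = "AC")),
               "exceeds the enumeration space")
  expect_error(alscreen:::.parse_fragments("C1CC1[[", "acid"), "unparseable")
})

test_that("additive library descriptors equal direct per-molecule computation", {
  lib <- fixture_library(1000, 7)
  idx <- seq(1, 1000, by = 37)
  direct <- molecule_records(lib$smiles[idx], lib$id[idx])
  expect_equal(direct$mw, lib$mw[idx], tolerance = 1e-9)
  expect_equal(direct$clogp, lib$clogp[idx], tolerance = 1e-9)
  expect_equal(direct$n_rings, lib$n_rings[idx])
  expect_equal(direct$n_rotatable, lib$n_rotatable[idx])
  expect_equal(direct$n_acid, lib$n_acid[idx])
})

test_that("tier-1 oracle is deterministic and respects the noise limit", {
  lib <- fixture_library(1000, 7)
  s1 <- score_tier1(lib)
  expect_identical(s1, score_tier1(lib))
  expect_true(all(is.finite(s1)))

  # pure-noise limit: no correlation with the descriptor signal
  lib10k <- fixture_library(10000, 11)
  s0 <- score_tier1(lib10k, oracle_params(signal_fraction = 0))
  g <- alscreen:::.g_signal(lib10k)
  expect_lt(abs(cor(s0, g)), 0.05)
})

test_that("tier-2 correlation matches rho across its range", {
  lib <- fixture_library(10000, 11)
  s1 <- score_tier1(lib)

  r1 <- cor(s1, score_tier2(lib, oracle_params(rho = 1)))
  expect_equal(r1, 1.0, tolerance = 1e-12)

  r0 <- cor(score_tier1(lib, oracle_params(rho = 0)),
            score_tier2(lib, oracle_params(rho = 0)))
  expect_lt(abs(r0), 0.03)

  r <- cor(s1, score_tier2(lib))
  expect_equal(r, 0.42, tolerance = 0.03)
})

test_that("pose generation places fixture features at the hotspot", {
  recs <- molecule_records(
    c("CC(=O)NCC(=O)O", "OC(=O)c1ccc(F)cc1", "OC(=O)Cc1ccsc1",
      "NC(CC(=O)O)C(=O)O"),
    c("P1", "P2", "P3", "P4"))
  path <- withr::local_tempfile(fileext = ".sdf")
  res <- generate_poses(recs, path, seed = 3, fixture_mode = TRUE,
                        hotspot = c(0, 0, 0))
  expect_gte(res$n_written, 3)
  sdfset <- ChemmineR::read.SDFset(path)
  for (i in seq_along(sdfset)) {
    g <- alscreen:::mol_graph_from_sdf(sdfset[[i]])
    coords <- ChemmineR::atomblock(sdfset[[i]])[, 1:3, drop = FALSE]
    fa <- feature_atoms(g, "carboxylic_acid")
    expect_gte(length(fa), 1)
    expect_lt(sqrt(sum(coords[fa[1], ]^2)), 0.5)
    expect_true(all(is.finite(coords)))
  }
})

test_that("pose coordinates vary with seed while topology is preserved", {
  recs <- molecule_records(c("CC(=O)NCC(=O)O", "OC(=O)c1ccc(F)cc1"),
                           c("Q1", "Q2"))
  p1 <- withr::local_tempfile(fileext = ".sdf")
  p2 <- withr::local_tempfile(fileext = ".sdf")
  generate_poses(recs, p1, seed = 1)
  generate_poses(recs, p2, seed = 2)
  s1 <- ChemmineR::read.SDFset(p1)
  s2 <- ChemmineR::read.SDFset(p2)
  for (i in seq_along(s1)) {
    c1 <- ChemmineR::atomblock(s1[[i]])[, 1:3]
    c2 <- ChemmineR::atomblock(s2[[i]])[, 1:3]
    expect_gt(max(abs(c1 - c2)), 0.1)
    expect_identical(ChemmineR::bondblock(s1[[i]]), ChemmineR::bondblock(s2[[i]]))
  }
})

test_that("assay fixtures are deterministic and honour their ground truth", {
  fx <- generate_assay_fixtures()
  expect_identical(fx, generate_assay_fixtures())

  # noiseless dose-response equals the closed-form curve
  truth <- attr(fx, "truth")$dose_response
  expected <- dose_response_curve(fx$dose_response$concentration_uM,
                                  truth$Top, truth$Bottom, truth$LogIC50)
  expect_equal(fx$dose_response$response, expected, tolerance = 1e-12)

  # constructed slope pair flows through the efflux normalization
  sl <- vapply(split(fx$fluorescence, fx$fluorescence$condition),
               function(d) fluorescence_slope(d$time, d$signal,
                                              attr(fx, "truth")$background)$slope,
               numeric(1))
  expect_equal(unname(sl[c("control", "compound")]), c(100, 50), tolerance = 1e-9)

  expect_error(generate_assay_fixtures(concentrations_uM = c(-1, 1, 10, 100)),
               "positive")
  expect_error(generate_assay_fixtures(
    true_params = list(slopes = c(control = 1), background = 0,
                       dose_response = list(Top = 0, Bottom = 1, LogIC50 = 0),
                       atpase = list(activity = 1, vanadate_rate = 0,
                                     time_min = 1, protein_mg = 1,
                                     standard_slope = 1))),
    "Top > Bottom")
})
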