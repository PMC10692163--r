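# a minimal hand-built SDF with one carboxylate at known coordinates
.write_tiny_sdf <- function(path, shift = c(0, 0, 0)) {
  # acetic acid: C, C(=O), O(double), O(H); carboxyl carbon at atom 2
  coords <- rbind(c(-1.2, 0.3, 0.2), c(0.1, 0.1, 0.1),
                  c(0.6, 1.0, 0.9), c(0.8, -0.9, -0.6))
  coords <- sweep(coords, 2, shift, `+`)
  lines <- c("tiny", " test 3D", "",
             "  4  3  0  0  0  0  0  0  0  0999 V2000",
             sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                     coords[, 1], coords[, 2], coords[, 3],
                     c("C", "C", "O", "O")),
             "  1  2  1  0  0  0  0",
             "  2  3  2  0  0  0  0",
             "  2  4  1  0  0  0  0",
             "M  END", "$$$$")
  writeLines(lines, path)
  path
}

test_that("a single feature atom lands in its voxel", {
  path <- withr::local_tempfile(fileext = ".sdf")
  .write_tiny_sdf(path)
  g <- accumulate_density(path, "carboxylic_acid", spacing = 0.5,
                          origin = c(-2, -2, -2), dims = c(8, 8, 8))
  # carboxyl carbon at (0.1, 0.1, 0.1) -> voxel floor((0.1+2)/0.5) = 4 (1-based 5)
  expect_equal(sum(g$values), 1)
  expect_equal(g$values[5, 5, 5], 1)
  expect_equal(g$overflow, 0)
})

test_that("an empty feature selection yields an all-zero grid", {
  path <- withr::local_tempfile(fileext = ".sdf")
  .write_tiny_sdf(path)
  g <- accumulate_density(path, "sulphone", spacing = 0.5,
                          origin = c(-2, -2, -2), dims = c(8, 8, 8))
  expect_true(all(g$values == 0))
})

test_that("2D input is rejected", {
  path <- withr::local_tempfile(fileext = ".sdf")
  sdf <- ChemmineR::smiles2sdf(c(flat = "CC(=O)NCC(=O)O"))
  ChemmineR::write.SDF(sdf, path)
  expect_error(accumulate_density(path, "carboxylic_acid"), "2D-only")
})

test_that("fixture poses concentrate density at the hotspot", {
  recs <- molecule_records(
    c("CC(=O)NCC(=O)O", "OC(=O)c1ccc(F)cc1", "OC(=O)Cc1ccsc1",
      "NC(C)C(=O)O", "OC(=O)CCC(=O)O"),
    paste0("H", 1:5))
  path <- withr::local_tempfile(fileext = ".sdf")
  res <- generate_poses(recs, path, seed = 11, fixture_mode = TRUE,
                        hotspot = c(2, -1, 4))
  g <- accumulate_density(path, "carboxylic_acid", spacing = 0.5)
  # every carboxyl carbon of every written pose is binned (or overflows)
  expected <- sum(recs$n_acid[!(recs$id %in% res$skipped)])
  expect_equal(sum(g$values) + g$overflow, expected)
  am <- which(g$values == max(g$values), arr.ind = TRUE)[1, ]
  centre <- g$origin + (am - 0.5) * g$spacing
  expect_lt(sqrt(sum((centre - c(2, -1, 4))^2)), sqrt(3) * g$spacing)
})

test_that("mass is conserved exactly, including the overflow tally", {
  path <- withr::local_tempfile(fileext = ".sdf")
  .write_tiny_sdf(path)
  # grid too small to contain the atom -> overflow
  g <- accumulate_density(path, "carboxylic_acid", spacing = 0.5,
                          origin = c(10, 10, 10), dims = c(2, 2, 2))
  expect_equal(sum(g$values), 0)
  expect_equal(g$overflow, 1)
  # hba: both oxygens counted, inside a covering grid
  g2 <- accumulate_density(path, "hba", spacing = 0.5,
                           origin = c(-3, -3, -3), dims = c(12, 12, 12))
  expect_equal(sum(g2$values) + g2$overflow, 2)
  # smoothing preserves total mass
  g3 <- accumulate_density(path, "hba", spacing = 0.5,
                           origin = c(-3, -3, -3), dims = c(12, 12, 12),
                           smooth_sd = 0.75)
  expect_equal(sum(g3$values), sum(g2$values), tolerance = 1e-9)
})

test_that("densities are translation-equivariant", {
  p1 <- withr::local_tempfile(fileext = ".sdf")
  p2 <- withr::local_tempfile(fileext = ".sdf")
  .write_tiny_sdf(p1)
  shift <- c(3.25, -1.5, 0.75)
  .write_tiny_sdf(p2, shift = shift)
  g1 <- accumulate_density(p1, "hba", spacing = 0.5,
                           origin = c(-3, -3, -3), dims = c(10, 10, 10))
  g2 <- accumulate_density(p2, "hba", spacing = 0.5,
                           origin = c(-3, -3, -3) + shift, dims = c(10, 10, 10))
  expect_identical(g1$values, g2$values)
})

test_that("OpenDX export writes the documented layout and round-trips", {
  vals <- array(seq_len(8), dim = c(2, 2, 2))
  grid <- structure(list(origin = c(0, 0, 0), spacing = 0.5,
                         dims = c(2L, 2L, 2L), values = vals,
                         feature_name = "hba", total_binned = sum(vals),
                         overflow = 0L),
                    class = "feature_density_grid")
  path <- withr::local_tempfile(fileext = ".dx")
  write_grid(grid, path)
  lines <- readLines(path)
  start <- grep("data follows", lines) + 1
  nums <- as.numeric(unlist(strsplit(trimws(lines[start:(start + 2)]), " ")))
  # z varies fastest: (1,1,1),(1,1,2),(1,2,1),(1,2,2),(2,1,1)...
  expect_equal(nums, c(vals[1, 1, 1], vals[1, 1, 2], vals[1, 2, 1],
                       vals[1, 2, 2], vals[2, 1, 1], vals[2, 1, 2],
                       vals[2, 2, 1], vals[2, 2, 2]))
  back <- read_grid(path)
  expect_identical(back$dims, grid$dims)
  expect_equal(back$origin, grid$origin)
  expect_equal(back$spacing, grid$spacing)
  expect_equal(back$values, grid$values, tolerance = 1e-12)
  expect_equal(sum(back$values), sum(grid$values))
})
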