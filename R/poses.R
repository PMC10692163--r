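# Synthetic 3D pose generation (SDF) for the density-grid analysis.
#
# Conformers are generated with OpenBabel's 3D builder (deterministic per
# structure); pose-to-pose variability across seeds is emulated by a seeded
# rigid-body rotation/translation of each conformer. In fixture mode the
# designated feature atom of every molecule is placed within 0.5 angstrom of
# a declared hotspot, giving grid tests a known density maximum.

# random 3x3 rotation matrix from the current RNG stream (QR of a Gaussian
# matrix, sign-corrected to a proper rotation)
.random_rotation <- function() {
  qr_ <- qr(matrix(rnorm(9), 3, 3))
  q <- qr.Q(qr_)
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

#' Generate 3D poses for molecules
#'
#' @param records a `molecule_records` data frame
#' @param path output SDF file
#' @param seed integer seed controlling the rigid-body placement
#' @param fixture_mode if `TRUE`, translate each molecule so its first
#'   `feature` atom lies within 0.5 angstrom of `hotspot`
#' @param hotspot numeric xyz of the fixture hotspot (angstrom)
#' @param feature feature selection for fixture placement (see
#'   [feature_atoms()])
#' @param box half-width (angstrom) of the cubic region poses are scattered
#'   in when not in fixture mode
#' @return invisibly, a list with `path`, `n_written`, and `skipped`
#'   (ids that failed 3D embedding or lack the feature, with a warning)
#' @export
generate_poses <- function(records, path, seed = 1L, fixture_mode = FALSE,
                           hotspot = c(0, 0, 0), feature = "carboxylic_acid",
                           box = 8) {
  stopifnot(nrow(records) >= 1)
  skipped <- character(0)
  sdf_list <- list()
  .with_seed(seed, {
    for (i in seq_len(nrow(records))) {
      id <- records$id[i]
      sdf_txt <- tryCatch(
        ChemmineOB::convertFormat(
          "SMI", "SDF", paste0(records$smiles[i], "\t", id, "\n"),
          options = data.frame(names = "gen3d", args = "")),
        error = function(e) NULL)
      sdfset <- if (!is.null(sdf_txt)) {
        tryCatch(ChemmineR::read.SDFset(ChemmineR::read.SDFstr(
          strsplit(sdf_txt, "\n", fixed = TRUE)[[1]])),
          error = function(e) NULL)
      }
      if (is.null(sdfset) || length(sdfset) == 0) {
        skipped <- c(skipped, id)
        next
      }
      sdf <- sdfset[[1]]
      ab <- ChemmineR::atomblock(sdf)
      coords <- ab[, 1:3, drop = FALSE]
      if (all(coords[, 3] == 0) && nrow(coords) > 3) {
        skipped <- c(skipped, id)  # 3D embedding failed (planar output)
        next
      }
      rot <- .random_rotation()
      center <- colMeans(coords)
      coords <- sweep(coords, 2, center) %*% t(rot)
      if (fixture_mode) {
        g <- tryCatch(mol_graph_from_sdf(sdf), error = function(e) NULL)
        fa <- if (!is.null(g)) feature_atoms(g, feature) else integer(0)
        if (length(fa) == 0) {
          skipped <- c(skipped, id)
          next
        }
        jitter <- runif(3, -1, 1)
        jitter <- jitter / sqrt(sum(jitter^2)) * runif(1, 0, 0.3)
        shift <- hotspot + jitter - coords[fa[1], ]
      } else {
        shift <- runif(3, -box, box)
      }
      # V2000 atom lines carry fixed-width %10.4f coordinate fields
      coords <- round(sweep(coords, 2, shift, `+`), 4)
      ab[, 1:3] <- coords
      sdf@atomblock <- ab
      sdf@header["Molecule_Name"] <- id
      sdf_list[[length(sdf_list) + 1]] <- sdf
    }
  })
  if (length(skipped) > 0) {
    warning(length(skipped), " molecule(s) skipped: ",
            paste(skipped, collapse = ", "))
  }
  if (length(sdf_list) == 0) stop("no poses could be generated")
  out <- methods::as(new("SDFset",
                         SDF = sdf_list,
                         ID = vapply(sdf_list, function(s)
                           unname(ChemmineR::header(s)["Molecule_Name"]),
                           character(1))),
                     "SDFset")
  ChemmineR::write.SDF(out, path)
  invisible(list(path = path, n_written = length(sdf_list), skipped = skipped))
}
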