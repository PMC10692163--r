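# 3D voxel densities of SMARTS-defined feature atoms over pose ensembles,
# with OpenDX import/export.
#
# Binning uses half-open voxel intervals: an atom at x falls in voxel
# floor((x - origin) / spacing). With smoothing off the grid conserves mass
# exactly: binned counts + overflow = matched feature atoms.

#' Accumulate a feature density grid over 3D poses
#'
#' @param poses path to an SDF file with 3D coordinates, or a
#'   `ChemmineR::SDFset`
#' @param feature feature selection (see [feature_atoms()]): a packaged name
#'   such as `"carboxylic_acid"`, `"aromatic"`, `"hba"`, `"hbd"`,
#'   `"sulphone"`, or a function(graph) returning atom indices
#' @param spacing voxel edge length in angstrom (default 0.5)
#' @param origin grid origin (xyz, angstrom); default: pose bounding box
#'   minus `padding`
#' @param dims integer voxel counts per axis; default: cover the bounding
#'   box plus `padding`
#' @param padding bounding-box padding in angstrom (default 2)
#' @param smooth_sd isotropic Gaussian smoothing bandwidth in angstrom
#'   (0 = off); smoothing uses reflecting boundaries so total mass is
#'   preserved
#' @return an object of class `feature_density_grid`: `origin`, `spacing`,
#'   `dims`, `values` (3D array), `feature_name`, `total_binned`, `overflow`
#' @export
accumulate_density <- function(poses, feature = "carboxylic_acid",
                               spacing = 0.5, origin = NULL, dims = NULL,
                               padding = 2, smooth_sd = 0) {
  sdfset <- if (is.character(poses)) ChemmineR::read.SDFset(poses) else poses
  stopifnot(spacing > 0)
  pts <- NULL
  for (i in seq_along(sdfset)) {
    sdf <- sdfset[[i]]
    g <- mol_graph_from_sdf(sdf)
    coords <- ChemmineR::atomblock(sdf)[, 1:3, drop = FALSE]
    if (all(coords[, 3] == 0) && nrow(coords) > 3) {
      stop("pose ", i, " has no 3D coordinates (2D-only input)")
    }
    fa <- feature_atoms(g, feature)
    if (length(fa) > 0) pts <- rbind(pts, coords[fa, , drop = FALSE])
  }
  n_pts <- if (is.null(pts)) 0L else nrow(pts)
  if (is.null(origin) || is.null(dims)) {
    if (n_pts == 0) {
      if (is.null(origin)) origin <- c(0, 0, 0)
      if (is.null(dims)) dims <- c(1L, 1L, 1L)
    } else {
      lo <- apply(pts, 2, min) - padding
      hi <- apply(pts, 2, max) + padding
      if (is.null(origin)) origin <- lo
      if (is.null(dims)) dims <- pmax(1L, as.integer(ceiling((hi - origin) / spacing)))
    }
  }
  dims <- as.integer(dims)
  stopifnot(length(dims) == 3, all(dims >= 1))
  values <- array(0, dim = dims)
  overflow <- 0L
  if (n_pts > 0) {
    idx <- floor(sweep(pts, 2, origin) / spacing)
    inside <- idx[, 1] >= 0 & idx[, 1] < dims[1] &
      idx[, 2] >= 0 & idx[, 2] < dims[2] &
      idx[, 3] >= 0 & idx[, 3] < dims[3]
    overflow <- sum(!inside)
    if (any(inside)) {
      ii <- idx[inside, , drop = FALSE] + 1
      for (k in seq_len(nrow(ii))) {
        values[ii[k, 1], ii[k, 2], ii[k, 3]] <-
          values[ii[k, 1], ii[k, 2], ii[k, 3]] + 1
      }
    }
  }
  total_binned <- sum(values)
  if (smooth_sd > 0) values <- .smooth_grid(values, smooth_sd / spacing)
  structure(list(origin = as.numeric(origin), spacing = spacing, dims = dims,
                 values = values,
                 feature_name = if (is.character(feature)) feature else "custom",
                 total_binned = total_binned, overflow = overflow),
            class = "feature_density_grid")
}

# separable Gaussian smoothing with reflecting boundaries (mass-preserving)
.smooth_grid <- function(values, sd_vox) {
  half <- max(1L, ceiling(4 * sd_vox))
  kern <- exp(-(seq(-half, half))^2 / (2 * sd_vox^2))
  kern <- kern / sum(kern)
  conv_axis <- function(v, axis) {
    d <- dim(v)
    n <- d[axis]
    # half-sample reflection (0 -> 1, -1 -> 2, n+1 -> n): the fold is
    # measure-preserving, so a normalized kernel conserves total mass
    reflect <- function(i) {
      p <- (i - 1) %% (2 * n)
      ifelse(p < n, p + 1, 2 * n - p)
    }
    out <- array(0, dim = d)
    for (o in seq(-half, half)) {
      w <- kern[o + half + 1]
      src <- reflect(seq_len(n) + o)
      idx_src <- switch(axis,
                        `1` = v[src, , , drop = FALSE],
                        `2` = v[, src, , drop = FALSE],
                        `3` = v[, , src, drop = FALSE])
      out <- out + w * idx_src
    }
    out
  }
  for (ax in 1:3) values <- conv_axis(values, ax)
  values
}

#' @export
print.feature_density_grid <- function(x, ...) {
  cat("feature_density_grid [", x$feature_name, "]: ",
      paste(x$dims, collapse = " x "), " voxels at ", x$spacing,
      " A; total counts ", sum(x$values), " (overflow ", x$overflow, ")\n",
      sep = "")
  invisible(x)
}

#' Write a density grid as an OpenDX scalar field
#'
#' The emitted file is readable by common molecular viewers; values are
#' written with the z index varying fastest.
#'
#' @param grid a `feature_density_grid`
#' @param path output file
#' @export
write_grid <- function(grid, path) {
  stopifnot(inherits(grid, "feature_density_grid"))
  d <- grid$dims
  con <- try(file(path, "w"), silent = TRUE)
  if (inherits(con, "try-error")) stop("cannot write to ", path)
  on.exit(close(con))
  writeLines(c(
    sprintf("# feature density grid: %s", grid$feature_name),
    sprintf("object 1 class gridpositions counts %d %d %d", d[1], d[2], d[3]),
    sprintf("origin %.6f %.6f %.6f", grid$origin[1], grid$origin[2], grid$origin[3]),
    sprintf("delta %.6f 0.000000 0.000000", grid$spacing),
    sprintf("delta 0.000000 %.6f 0.000000", grid$spacing),
    sprintf("delta 0.000000 0.000000 %.6f", grid$spacing),
    sprintf("object 2 class gridconnections counts %d %d %d", d[1], d[2], d[3]),
    sprintf("object 3 class array type double rank 0 items %d data follows",
            prod(d))), con)
  vals <- as.vector(aperm(grid$values, c(3, 2, 1)))  # z fastest
  lines <- tapply(vals, (seq_along(vals) - 1) %/% 3,
                  function(v) paste(sprintf("%.10g", v), collapse = " "))
  writeLines(unname(lines), con)
  writeLines(c("attribute \"dep\" string \"positions\"",
               "object \"density\" class field",
               "component \"positions\" value 1",
               "component \"connections\" value 2",
               "component \"data\" value 3"), con)
  invisible(path)
}

#' Read an OpenDX scalar field written by [write_grid()]
#'
#' @param path OpenDX file
#' @return a `feature_density_grid`
#' @export
read_grid <- function(path) {
  lines <- readLines(path, warn = FALSE)
  gp <- grep("class gridpositions counts", lines, value = TRUE)[1]
  d <- as.integer(strsplit(sub(".*counts ", "", gp), " ")[[1]])
  or <- as.numeric(strsplit(sub("^origin ", "", grep("^origin", lines, value = TRUE)[1]), " ")[[1]])
  deltas <- grep("^delta", lines, value = TRUE)
  sp <- as.numeric(strsplit(sub("^delta ", "", deltas[1]), " ")[[1]])[1]
  start <- grep("data follows", lines)[1] + 1
  n <- prod(d)
  vals <- numeric(0)
  i <- start
  while (length(vals) < n && i <= length(lines)) {
    row <- suppressWarnings(as.numeric(strsplit(trimws(lines[i]), "[[:space:]]+")[[1]]))
    if (anyNA(row)) break
    vals <- c(vals, row)
    i <- i + 1
  }
  if (length(vals) != n) stop("malformed grid file: expected ", n, " values")
  values <- aperm(array(vals, dim = rev(d)), c(3, 2, 1))
  structure(list(origin = or, spacing = sp, dims = d, values = values,
                 feature_name = sub("^# feature density grid: ", "",
                                    grep("^# feature density grid",
                                         lines, value = TRUE)[1]),
                 total_binned = sum(values), overflow = 0L),
            class = "feature_density_grid")
}
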