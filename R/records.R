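# Molecule records: the tabular container used throughout the pipeline.
# One row per molecule; descriptor columns are computed once at construction.

#' Build molecule records from SMILES
#'
#' Parses structures with OpenBabel (via ChemmineR), computes the descriptors
#' used by the lead-like filter and the scoring oracles, and reports (rather
#' than drops) entries that fail to parse.
#'
#' @param smiles character vector of SMILES strings
#' @param ids optional identifiers (defaults to `M1`, `M2`, ...); must be
#'   unique
#' @return a `molecule_records` data frame; parse failures are attached as
#'   attribute `"failures"` (character vector of ids)
#' @export
molecule_records <- function(smiles, ids = NULL) {
  if (length(smiles) == 0) stop("no input structures")
  if (is.null(ids)) ids <- names(smiles)
  if (is.null(ids)) ids <- paste0("M", seq_along(smiles))
  if (anyDuplicated(ids)) stop("ids must be unique")
  parsed <- mol_graphs_from_smiles(stats::setNames(unname(smiles), ids))
  graphs <- parsed$graphs
  if (length(graphs) == 0) stop("no valid structures among ", length(smiles), " inputs")
  ok <- names(graphs)
  sdf <- ChemmineR::smiles2sdf(stats::setNames(unname(smiles)[match(ok, ids)], ok))
  props <- ChemmineR::propOB(sdf)
  recs <- data.frame(
    id = ok,
    smiles = unname(smiles)[match(ok, ids)],
    mw = props$MW,
    clogp = props$logP,
    n_rings = vapply(graphs, .n_rings_graph, integer(1)),
    n_rotatable = vapply(graphs, function(g) {
      cpp_rotatable_count(g$z, g$charge, g$nh, g$inring, g$bfrom, g$bto, g$border)
    }, integer(1)),
    n_hba = vapply(graphs, function(g) sum(g$z %in% c(7L, 8L)), integer(1)),
    n_aromatic_rings = vapply(graphs, .n_aromatic_rings, integer(1)),
    n_acid = vapply(graphs, function(g) length(.acid_carbons(g)), integer(1)),
    formal_charge = vapply(graphs, function(g) sum(g$charge), integer(1)),
    stringsAsFactors = FALSE, row.names = NULL
  )
  class(recs) <- c("molecule_records", "data.frame")
  attr(recs, "failures") <- parsed$failures
  recs
}

#' Lead-like filter
#'
#' Passes molecules with molecular weight below 460 g/mol, logP within
#' \[-4, 4\], fewer than 4 rings and fewer than 10 rotatable bonds. All
#' "less than" bounds are strict; the logP interval is inclusive.
#'
#' @param records a `molecule_records` data frame (or any data frame with
#'   columns `mw`, `clogp`, `n_rings`, `n_rotatable`)
#' @return a data frame with logical column `pass` and one logical column per
#'   criterion (`fail_mw`, `fail_clogp`, `fail_rings`, `fail_rotatable`);
#'   `failed_criteria` lists the violated rules per molecule
#' @export
leadlike_filter <- function(records) {
  need <- c("mw", "clogp", "n_rings", "n_rotatable")
  if (!all(need %in% names(records))) {
    stop("records lack descriptor columns: ",
         paste(setdiff(need, names(records)), collapse = ", "))
  }
  fail_mw <- !(records$mw < 460)
  fail_clogp <- !(records$clogp >= -4 & records$clogp <= 4)
  fail_rings <- !(records$n_rings < 4)
  fail_rot <- !(records$n_rotatable < 10)
  fails <- cbind(mw = fail_mw, clogp = fail_clogp, rings = fail_rings,
                 rotatable = fail_rot)
  out <- data.frame(
    id = if ("id" %in% names(records)) records$id else seq_len(nrow(records)),
    pass = !(fail_mw | fail_clogp | fail_rings | fail_rot),
    fail_mw = fail_mw, fail_clogp = fail_clogp,
    fail_rings = fail_rings, fail_rotatable = fail_rot,
    stringsAsFactors = FALSE
  )
  out$failed_criteria <- apply(fails, 1, function(f) {
    paste(colnames(fails)[f], collapse = ",")
  })
  out
}
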