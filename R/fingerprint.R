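# Circular (Morgan-style) fingerprints, Tanimoto similarity and
# leader-algorithm diversity selection.
#
# Fingerprints are hashed circular environments of radius 2 folded into 2048
# bits (the conventional lead-optimization setting). Hashing combines
# neighbour environments in sorted order, so bits are invariant to the input
# atom numbering; aromatic ring bonds are order-normalized at parse time so
# the emitted kekule form does not matter either.

#' Compute fingerprints for molecule records
#'
#' Library records carrying fragment provenance are fingerprinted via direct
#' graph assembly (no re-parsing); other records are parsed from their SMILES.
#'
#' @param records a `molecule_records` data frame
#' @param n_bits fingerprint length (default 2048)
#' @param radius circular environment radius in bonds (default 2)
#' @return a named list of sorted integer vectors of on-bit indices
#'   (0-based), one per molecule
#' @export
fingerprints <- function(records, n_bits = 2048L, radius = 2L) {
  if (!is.null(records$frag_a) && !is.null(attr(records, "synthon_sets"))) {
    data <- .synthon_data(attr(records, "synthon_sets"))
    fps <- lapply(seq_len(nrow(records)), function(i) {
      ga <- cpp_assemble_graph(data$frags, records$frag_a[i], records$frag_b[i],
                               records$frag_c[i])
      ri <- cpp_ring_info(ga$z, ga$charge, ga$nh, ga$inring, ga$bfrom, ga$bto,
                          ga$border)
      cpp_fp_bits(ga$z, ga$charge, ga$nh, as.integer(ri$atom_ring),
                  ga$bfrom, ga$bto, ga$border, radius, n_bits)
    })
  } else {
    parsed <- mol_graphs_from_smiles(stats::setNames(records$smiles, records$id))
    if (length(parsed$failures) > 0) {
      stop("unparseable structures: ", paste(parsed$failures, collapse = ", "))
    }
    fps <- lapply(parsed$graphs[records$id], fingerprint_graph,
                  n_bits = n_bits, radius = radius)
  }
  names(fps) <- records$id
  attr(fps, "n_bits") <- as.integer(n_bits)
  attr(fps, "radius") <- as.integer(radius)
  fps
}

#' @rdname fingerprints
#' @param g a molecular graph (see [feature_atoms()])
#' @export
fingerprint_graph <- function(g, n_bits = 2048L, radius = 2L) {
  cpp_fp_bits(g$z, g$charge, g$nh, g$inring, g$bfrom, g$bto, g$border,
              radius, n_bits)
}

#' Sparse fingerprint matrix
#'
#' @inheritParams fingerprints
#' @return a `dgCMatrix` (molecules x bits) of 0/1 values
#' @export
fingerprint_matrix <- function(records, n_bits = 2048L, radius = 2L) {
  cache <- attr(records, "fp_cache")
  if (!is.null(cache) && ncol(cache) == n_bits &&
      all(records$id %in% rownames(cache))) {
    return(cache[records$id, , drop = FALSE])
  }
  if (!is.null(records$frag_a) && !is.null(attr(records, "synthon_sets"))) {
    return(.library_fp_matrix(records, n_bits = n_bits, radius = radius))
  }
  fps <- fingerprints(records, n_bits = n_bits, radius = radius)
  i <- rep(seq_along(fps), lengths(fps))
  j <- unlist(fps, use.names = FALSE) + 1L
  out <- Matrix::sparseMatrix(i = i, j = j, x = 1,
                              dims = c(length(fps), n_bits))
  rownames(out) <- names(fps)
  out
}

#' Tanimoto similarity of two fingerprints
#'
#' Intersection over union of on-bits; the empty/empty case is defined as 0
#' so that diversity selection is total.
#'
#' @param a,b integer vectors of on-bit indices (as returned by
#'   [fingerprints()]); both must come from the same bit length
#' @param n_bits bit length consistency check (optional; if both inputs carry
#'   a `n_bits` attribute they must agree)
#' @return similarity in `[0, 1]`
#' @export
tanimoto <- function(a, b, n_bits = NULL) {
  na <- attr(a, "n_bits"); nb <- attr(b, "n_bits")
  if (!is.null(na) && !is.null(nb) && na != nb) {
    stop("fingerprints have mismatched bit lengths (", na, " vs ", nb, ")")
  }
  cpp_tanimoto(as.integer(a), as.integer(b))
}

#' Diversity selection by the leader algorithm
#'
#' Scans records in their given order (callers pass score-sorted lists, best
#' first) and keeps a record iff its maximum Tanimoto similarity to all
#' previously kept records is strictly below `threshold`. Every kept pair is
#' therefore less similar than the threshold.
#'
#' @param records a `molecule_records` data frame, or a list of fingerprints
#' @param threshold similarity ceiling in (0, 1]
#' @param max_keep stop after this many kept records (default: no cap)
#' @param fps optional precomputed fingerprints aligned with `records`
#' @return the kept subset (same type as the input), in input order
#' @export
diverse_subset <- function(records, threshold = 0.4, max_keep = 0L, fps = NULL) {
  stopifnot(threshold > 0, threshold <= 1)
  if (is.data.frame(records)) {
    if (nrow(records) == 0) return(records)
    if (is.null(fps)) fps <- fingerprints(records)
    keep <- cpp_leader_select(unname(fps), threshold, as.integer(max_keep))
    records[keep, , drop = FALSE]
  } else {
    if (length(records) == 0) return(records)
    keep <- cpp_leader_select(unname(records), threshold, as.integer(max_keep))
    records[keep]
  }
}
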