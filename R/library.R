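# Synthetic combinatorial library generation.

#' Configure a synthetic combinatorial library
#'
#' Defines an enumerable amide-coupled synthon library. Products are drawn
#' without replacement from the mixed-radix enumeration of two-component
#' (acid + amine) and three-component (acid + central + amine) couplings.
#'
#' @param n_molecules number of molecules to emit (>= 1)
#' @param seed integer seed controlling the subsample
#' @param synthon_sets list with character vectors `acids`, `centrals`,
#'   `amines`; defaults to the packaged sets
#' @param coupling_rules which couplings to enumerate: `"AC"` two-component
#'   amides, `"ABC"` three-component bis-amides
#' @return an object of class `library_config`
#' @export
library_config <- function(n_molecules = 200000L, seed = 1L,
                           synthon_sets = default_synthon_sets(),
                           coupling_rules = c("AC", "ABC")) {
  stopifnot(n_molecules >= 1, length(seed) == 1, is.finite(seed))
  if (!all(coupling_rules %in% c("AC", "ABC")) || length(coupling_rules) == 0) {
    stop("coupling_rules must be a subset of c(\"AC\", \"ABC\")")
  }
  if (!is.list(synthon_sets) ||
      !all(c("acids", "centrals", "amines") %in% names(synthon_sets)) ||
      any(vapply(synthon_sets[c("acids", "centrals", "amines")], length, integer(1)) == 0)) {
    stop("synthon_sets must contain non-empty 'acids', 'centrals' and 'amines'")
  }
  structure(list(n_molecules = as.integer(n_molecules), seed = as.integer(seed),
                 synthon_sets = synthon_sets, coupling_rules = coupling_rules),
            class = "library_config")
}

# run code under a fixed RNG state without touching the caller's stream
.with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  force(code)
}

#' Generate a synthetic compound library
#'
#' Deterministically enumerates the coupling space of the configured synthon
#' sets in mixed-radix order, subsamples `n_molecules` without replacement
#' under the configured seed, and emits molecule records with additively
#' computed descriptors (exact for the amide coupling chemistry used).
#'
#' @param config a [library_config()]
#' @return a `molecule_records` data frame with columns `id`, `smiles`,
#'   descriptor columns (`mw`, `clogp`, `n_rings`, `n_rotatable`, `n_hba`,
#'   `n_aromatic_rings`, `n_acid`, `formal_charge`) and fragment provenance
#'   (`frag_a`, `frag_b`, `frag_c`)
#' @export
generate_library <- function(config) {
  stopifnot(inherits(config, "library_config"))
  data <- .synthon_data(config$synthon_sets)
  total <- .space_size(data, config$coupling_rules)
  if (config$n_molecules > total) {
    stop("n_molecules (", config$n_molecules, ") exceeds the enumeration space (",
         total, ")")
  }
  k0 <- if (config$n_molecules == total) {
    seq_len(total) - 1L
  } else {
    sort(.with_seed(config$seed, sample.int(total, config$n_molecules))) - 1L
  }
  comp <- .decode_index(k0, data, config$coupling_rules)
  gcomp <- .global_comp(comp, data)
  tab <- data$table
  n_j <- 1L + (gcomp[, 2] > 0L)  # amide junctions formed
  sum3 <- function(col) {
    tab[[col]][gcomp[, 1]] +
      ifelse(gcomp[, 2] > 0L, tab[[col]][pmax(gcomp[, 2], 1L)], 0) +
      tab[[col]][gcomp[, 3]]
  }
  mw <- sum3("mw") - .water_mw * n_j
  clogp <- sum3("logp") + data$logp_delta * n_j
  n_rings <- sum3("n_rings")
  n_arom <- sum3("n_arom")
  n_hba <- sum3("n_no") - n_j  # one carboxyl O leaves per junction
  n_acid <- sum3("n_acid") - n_j  # each junction consumes one carboxyl
  alpha_b <- ifelse(gcomp[, 2] > 0L, tab$alpha_corr[pmax(gcomp[, 2], 1L)], 0)
  n_rot <- sum3("rot") + alpha_b + tab$alpha_corr[gcomp[, 3]]
  records <- data.frame(
    id = sprintf("SYN-%09d", k0),
    smiles = .product_smiles(gcomp, data),
    mw = mw, clogp = clogp,
    n_rings = as.integer(n_rings),
    n_rotatable = as.integer(n_rot),
    n_hba = as.integer(n_hba),
    n_aromatic_rings = as.integer(n_arom),
    n_acid = as.integer(n_acid),
    formal_charge = 0L,
    frag_a = gcomp[, 1], frag_b = gcomp[, 2], frag_c = gcomp[, 3],
    stringsAsFactors = FALSE
  )
  class(records) <- c("molecule_records", "data.frame")
  attr(records, "synthon_sets") <- config$synthon_sets
  attr(records, "coupling_rules") <- config$coupling_rules
  records
}

# fingerprint matrix (sparse, molecules x bits) for library records carrying
# fragment provenance; assembled in C++ without re-parsing SMILES
.library_fp_matrix <- function(records, data = NULL, n_bits = 2048L, radius = 2L,
                               chunk = 20000L) {
  if (is.null(data)) data <- .synthon_data(attr(records, "synthon_sets"))
  n <- nrow(records)
  parts <- split(seq_len(n), ceiling(seq_len(n) / chunk))
  mats <- lapply(parts, function(idx) {
    comp <- cbind(records$frag_a[idx], records$frag_b[idx], records$frag_c[idx])
    tri <- cpp_library_fp(data$frags, comp, radius, n_bits)
    Matrix::sparseMatrix(i = tri$i, j = tri$j, x = 1,
                         dims = c(length(idx), n_bits))
  })
  out <- do.call(rbind, mats)
  rownames(out) <- records$id
  out
}
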