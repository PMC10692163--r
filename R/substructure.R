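# Substructure counting via SMARTS (OpenBabel backend).

.packaged_patterns <- c(
  carboxylic_acid = "[CX3](=O)[OX2H1,OX1-]",
  sulfonamide = "S(=O)(=O)N",
  sulphone = "S(=O)(=O)",
  amide = "C(=O)N",
  aromatic = "a"
)

#' Packaged SMARTS patterns
#'
#' @return named character vector of the SMARTS patterns used by the pipeline
#' @export
packaged_patterns <- function() .packaged_patterns

#' Count substructure matches
#'
#' @param records a `molecule_records` data frame
#' @param pattern a SMARTS string, or the name of a packaged pattern
#'   (see [packaged_patterns()])
#' @return integer vector of unique match counts, one per record
#' @export
count_substructure <- function(records, pattern) {
  if (pattern %in% names(.packaged_patterns)) {
    pattern <- .packaged_patterns[[pattern]]
  }
  sdf <- ChemmineR::smiles2sdf(stats::setNames(records$smiles, records$id))
  counts <- tryCatch(
    ChemmineR::smartsSearchOB(sdf, pattern, uniqueMatches = TRUE),
    error = function(e) stop("invalid SMARTS pattern '", pattern, "': ",
                             conditionMessage(e))
  )
  out <- as.integer(counts)
  if (length(out) != nrow(records)) {
    stop("invalid SMARTS pattern: ", pattern)
  }
  names(out) <- records$id
  out
}
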