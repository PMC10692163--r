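# Shared fixtures (built in code, cached per test run) and independent
# brute-force oracles used to cross-check the fast implementations.

.fixture_env <- new.env(parent = emptyenv())

fixture_library <- function(n = 2000, seed = 101) {
  key <- paste0("lib_", n, "_", seed)
  if (is.null(.fixture_env[[key]])) {
    .fixture_env[[key]] <- generate_library(
      library_config(n_molecules = n, seed = seed))
  }
  .fixture_env[[key]]
}

# Tanimoto on sorted on-bit sets, written independently of the C++ path
bf_tanimoto <- function(a, b) {
  if (length(a) == 0 && length(b) == 0) return(0)
  length(intersect(a, b)) / length(union(a, b))
}

# leader selection by direct similarity-matrix scan
bf_leader <- function(fps, threshold) {
  kept <- integer(0)
  for (i in seq_along(fps)) {
    ok <- TRUE
    for (j in kept) {
      if (bf_tanimoto(fps[[i]], fps[[j]]) >= threshold) { ok <- FALSE; break }
    }
    if (ok) kept <- c(kept, i)
  }
  kept
}

# ROC AUC by explicit pair enumeration (ties count one half)
bf_auc <- function(scores, labels) {
  act <- scores[labels == "active"]
  dec <- scores[labels == "decoy"]
  s <- 0
  for (a in act) for (d in dec) s <- s + (a < d) + 0.5 * (a == d)
  s / (length(act) * length(dec))
}
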