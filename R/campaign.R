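# Active-learning screening campaign: batch selection, round orchestration,
# and bootstrap hit-recall estimation.

#' Specify one acquisition round
#'
#' @param acquire_size number of molecules to score this round (>= 1)
#' @param pool `"whole_library"`, or a fraction in (0, 1] of the library
#'   ranked by current surrogate predictions (best first)
#' @param selection `"random"`, `"greedy"` (best predicted) or `"diverse"`
#'   (leader filter over the prediction-sorted pool)
#' @param sim_threshold Tanimoto ceiling for `"diverse"` selection
#' @param exclude_scored drop already-scored molecules from the pool first
#' @return an object of class `round_spec`
#' @export
round_spec <- function(acquire_size, pool = "whole_library",
                       selection = c("random", "diverse", "greedy"),
                       sim_threshold = 0.4, exclude_scored = TRUE) {
  selection <- match.arg(selection)
  stopifnot(acquire_size >= 1)
  if (is.numeric(pool)) {
    stopifnot(pool > 0, pool <= 1)
  } else if (!identical(pool, "whole_library")) {
    stop("pool must be \"whole_library\" or a fraction in (0, 1]")
  }
  if (selection == "diverse" && (is.null(sim_threshold) || !is.finite(sim_threshold))) {
    stop("diverse selection requires a similarity threshold")
  }
  structure(list(acquire_size = as.integer(acquire_size), pool = pool,
                 selection = selection, sim_threshold = sim_threshold,
                 exclude_scored = isTRUE(exclude_scored)),
            class = "round_spec")
}

#' Default two-tier screening schedule
#'
#' The reference campaign docks 6 million of 2.654 billion compounds: a random
#' million, two similarity-filtered millions drawn from the predicted
#' top-100-million pool, and a greedy final 3 million. Here every count is
#' expressed as a library fraction so desk-scale campaigns keep the same
#' shape: round sizes 1/2654 (three times) and 3/2654 of the library, pool
#' fraction 100/2654 = 0.0377 for the model-guided rounds.
#'
#' @param library_size number of molecules in the screened library
#' @param sim_threshold Tanimoto ceiling of the exploration filter in rounds
#'   2-3 (default 0.5: in a synthon-combinatorial pool the 0.4 ceiling used
#'   for tier-2 diversity keeps fewer unique leaders than the round budget)
#' @return list of [round_spec()] objects
#' @export
default_screening_schedule <- function(library_size, sim_threshold = 0.5) {
  unit <- max(1L, round(library_size / 2654))
  pool_frac <- 100 / 2654
  list(
    round_spec(unit, pool = "whole_library", selection = "random"),
    round_spec(unit, pool = pool_frac, selection = "diverse",
               sim_threshold = sim_threshold),
    round_spec(unit, pool = pool_frac, selection = "diverse",
               sim_threshold = sim_threshold),
    round_spec(3L * unit, pool = pool_frac, selection = "greedy")
  )
}

# fingerprints of records as a list of on-bit vectors (fast path via the
# sparse matrix so the library assembly code is reused)
.fp_list <- function(records, n_bits = 2048L, radius = 2L) {
  x <- fingerprint_matrix(records, n_bits = n_bits, radius = radius)
  xt <- methods::as(x, "TsparseMatrix")
  split(xt@j, factor(xt@i + 1L, levels = seq_len(nrow(x))))
}

#' Select an acquisition batch
#'
#' @param spec a [round_spec()]
#' @param library `molecule_records` of the full library
#' @param predictions named numeric surrogate predictions over the library
#'   (required unless `selection = "random"` on the whole library)
#' @param scored_ids ids already scored (removed first when
#'   `exclude_scored`)
#' @param seed integer seed (used by random selection)
#' @return character vector of selected ids; if the pool is smaller than
#'   `acquire_size` the whole pool is returned with a shortfall warning
#' @export
select_batch <- function(spec, library, predictions = NULL,
                         scored_ids = character(0), seed = 1L) {
  stopifnot(inherits(spec, "round_spec"))
  ids <- library$id
  needs_model <- !(spec$selection == "random" &&
                     identical(spec$pool, "whole_library"))
  if (needs_model && is.null(predictions)) {
    stop("this round needs surrogate predictions (pool ranking or greedy/diverse selection)")
  }
  if (!is.null(predictions)) {
    predictions <- predictions[ids]
  }
  keep <- if (spec$exclude_scored) !(ids %in% scored_ids) else rep(TRUE, length(ids))
  pool_idx <- which(keep)
  if (is.numeric(spec$pool)) {
    n_pool <- max(1L, floor(spec$pool * length(ids)))
    # rank by prediction (best = most negative), id as deterministic tie-break
    ord <- order(predictions[pool_idx], ids[pool_idx])
    pool_idx <- pool_idx[ord][seq_len(min(n_pool, length(pool_idx)))]
  }
  if (length(pool_idx) == 0) stop("empty pool after exclusions")
  k <- spec$acquire_size
  if (spec$selection == "random") {
    if (length(pool_idx) <= k) {
      if (length(pool_idx) < k) {
        warning("pool shortfall: ", length(pool_idx), " < ", k,
                "; returning the whole pool")
      }
      return(ids[pool_idx])
    }
    sel <- .with_seed(seed, sample(pool_idx, k))
    return(ids[sel])
  }
  ord <- order(predictions[pool_idx], ids[pool_idx])
  pool_idx <- pool_idx[ord]
  if (spec$selection == "greedy") {
    if (length(pool_idx) < k) {
      warning("pool shortfall: ", length(pool_idx), " < ", k,
              "; returning the whole pool")
      return(ids[pool_idx])
    }
    return(ids[pool_idx[seq_len(k)]])
  }
  # diverse: leader filter over the prediction-sorted pool until k kept
  pool_recs <- library[pool_idx, , drop = FALSE]
  attr(pool_recs, "synthon_sets") <- attr(library, "synthon_sets")
  fps <- .fp_list(pool_recs)
  kept <- cpp_leader_select(unname(fps), spec$sim_threshold, as.integer(k))
  if (length(kept) < k) {
    warning("diverse selection shortfall: kept ", length(kept), " of ", k,
            " requested at threshold ", spec$sim_threshold)
  }
  ids[pool_idx[kept]]
}

#' Run a tier-1 active-learning screening campaign
#'
#' Executes the schedule round by round: select a batch, score it with the
#' tier-1 oracle, retrain the surrogate on everything scored so far, and form
#' the next round's pool from fresh whole-library predictions.
#'
#' @param library `molecule_records` of the library to screen
#' @param oracle function mapping a records subset to tier-1 scores
#'   (default: [score_tier1()] at default parameters)
#' @param schedule list of [round_spec()]; default
#'   [default_screening_schedule()]
#' @param seed integer campaign seed (drives batch sampling and surrogate
#'   splits)
#' @param hit_threshold hit definition in kcal/mol (strictly below; default
#'   -9)
#' @param surrogate_cfg a [surrogate_config()]
#' @param fp_matrix optional precomputed [fingerprint_matrix()] of the
#'   library (computed once here otherwise)
#' @return an object of class `campaign_state`: `ledger` (id, score, round),
#'   `rounds` (per-round log), `model` (final surrogate), `hit_threshold`
#' @export
run_screening_campaign <- function(library, oracle = score_tier1,
                                   schedule = NULL, seed = 1L,
                                   hit_threshold = -9,
                                   surrogate_cfg = surrogate_config(),
                                   fp_matrix = NULL) {
  if (is.null(schedule)) schedule <- default_screening_schedule(nrow(library))
  total <- sum(vapply(schedule, `[[`, integer(1), "acquire_size"))
  if (total > nrow(library)) {
    stop("schedule over budget: total acquisition ", total,
         " exceeds library size ", nrow(library))
  }
  if (is.null(fp_matrix)) {
    fp_matrix <- fingerprint_matrix(library, n_bits = surrogate_cfg$n_bits,
                                    radius = surrogate_cfg$radius)
  }
  attr(library, "fp_cache") <- fp_matrix
  ledger <- data.frame(id = character(0), score = numeric(0),
                       round = integer(0), stringsAsFactors = FALSE)
  rounds <- list()
  model <- NULL
  predictions <- NULL
  for (r in seq_along(schedule)) {
    spec <- schedule[[r]]
    batch_ids <- select_batch(spec, library, predictions = predictions,
                              scored_ids = ledger$id, seed = seed + 1000L * r)
    batch <- library[match(batch_ids, library$id), , drop = FALSE]
    scores <- oracle(batch)
    ledger <- rbind(ledger, data.frame(id = batch_ids, score = scores,
                                       round = r, stringsAsFactors = FALSE))
    rounds[[r]] <- list(
      round = r, selection = spec$selection,
      pool = spec$pool, acquired = length(batch_ids),
      round_hits = sum(scores < hit_threshold),
      cumulative_hits = sum(ledger$score < hit_threshold)
    )
    if (r < length(schedule)) {
      scored <- library[match(ledger$id, library$id), , drop = FALSE]
      attr(scored, "fp_cache") <- fp_matrix
      cfg <- surrogate_cfg
      cfg$seed <- seed + 17L * r
      model <- train_surrogate(scored, ledger$score, cfg)
      rounds[[r]]$val_r2 <- model$training_meta$val_r2
      predictions <- predict_scores(model, library)
    }
  }
  structure(list(ledger = ledger, rounds = rounds, model = model,
                 hit_threshold = hit_threshold, seed = seed,
                 library_size = nrow(library)),
            class = "campaign_state")
}

#' @export
print.campaign_state <- function(x, ...) {
  cat("campaign_state:", nrow(x$ledger), "molecules scored in",
      length(x$rounds), "rounds;",
      sum(x$ledger$score < x$hit_threshold), "hits below",
      x$hit_threshold, "kcal/mol\n")
  invisible(x)
}

#' Read a campaign configuration from YAML
#'
#' Expected layout:
#' ```yaml
#' library: {n_molecules: 20000, seed: 1}
#' seed: 1
#' hit_threshold: -9
#' schedule:
#'   - {acquire_size: 1000, pool: whole_library, selection: random}
#'   - {acquire_size: 200, pool: 0.05, selection: diverse, sim_threshold: 0.5}
#' ```
#' Omitted fields fall back to the package defaults; an omitted `schedule`
#' means [default_screening_schedule()] for the configured library size.
#'
#' @param path YAML file
#' @return list with `library` (a [library_config()]), `schedule`, `seed`,
#'   `hit_threshold`
#' @export
read_campaign_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  libcfg <- do.call(library_config, as.list(cfg$library %||% list()))
  schedule <- if (is.null(cfg$schedule)) {
    default_screening_schedule(libcfg$n_molecules)
  } else {
    lapply(cfg$schedule, function(r) do.call(round_spec, as.list(r)))
  }
  list(library = libcfg, schedule = schedule,
       seed = as.integer(cfg$seed %||% 1L),
       hit_threshold = as.numeric(cfg$hit_threshold %||% -9))
}

#' Bootstrap estimate of screening hit recall
#'
#' Extrapolates the hit prevalence of the initial uniform random sample to
#' the whole library, with a percentile bootstrap CI, and reports the
#' campaign recall as found / estimated-total.
#'
#' @param initial_sample_scores tier-1 scores of the initial uniform random
#'   sample
#' @param library_size total library size the sample was drawn from
#' @param threshold hit definition (strictly below, kcal/mol)
#' @param found total number of hits found by the whole campaign
#' @param B number of bootstrap resamples (>= 100; default 1000)
#' @param seed integer seed
#' @return an object of class `recall_estimate`: point estimate and 95
#'   percent CI of the library-wide hit total and of recall (recall CI
#'   clamped to `[0, 1]`)
#' @export
estimate_recall_bootstrap <- function(initial_sample_scores, library_size,
                                      threshold = -9, found, B = 1000L,
                                      seed = 1L) {
  stopifnot(B >= 100, found >= 0, library_size >= length(initial_sample_scores))
  n <- length(initial_sample_scores)
  k <- sum(initial_sample_scores < threshold)
  if (k == 0) {
    stop("no hits in calibration sample; recall unidentifiable")
  }
  hit <- initial_sample_scores < threshold
  boot_k <- .with_seed(seed, {
    vapply(seq_len(B), function(b) sum(hit[sample.int(n, n, replace = TRUE)]),
           numeric(1))
  })
  total_hat <- k / n * library_size
  boot_total <- boot_k / n * library_size
  ci_total <- unname(quantile(boot_total, c(0.025, 0.975), type = 7))
  recall <- found / total_hat
  ci_recall <- c(found / ci_total[2], found / ci_total[1])
  ci_recall <- pmin(pmax(ci_recall, 0), 1)
  structure(list(threshold = threshold, found = found,
                 sample_size = n, sample_hits = k,
                 estimated_total = total_hat, ci_total = ci_total,
                 recall = min(max(recall, 0), 1), ci_recall = ci_recall,
                 B = B, seed = seed),
            class = "recall_estimate")
}

#' @export
print.recall_estimate <- function(x, ...) {
  cat(sprintf(
    "recall_estimate: %d hits found below %g kcal/mol; estimated total %.1f (95%% CI %.1f-%.1f);\n  recall %.2f (95%% CI %.2f-%.2f)\n",
    x$found, x$threshold, x$estimated_total, x$ci_total[1], x$ci_total[2],
    x$recall, x$ci_recall[1], x$ci_recall[2]))
  invisible(x)
}
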