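# Tier-2 rescoring campaign: iterative surrogate-guided selection of tier-1
# hits for the slow scoring tier, following the reference protocol's stages:
#   A (seed)   diverse seed set among tier-1 hits (Tanimoto < 0.4)
#   B (loop)   repeat: retrain on tier-2 scores -> predict over the eligible
#              pool -> take the predicted top -> select a batch with minimal
#              similarity to everything scored or selected -> score, until
#              the target tier-2 count is reached
#   C (refine) predicted top slice -> keep molecules with fewer than two
#              acidic groups -> diversity-select -> score
#   D (final)  predict over the relaxed pool (tier-1 below the relaxed
#              threshold) -> diversity-select against everything scored ->
#              score

#' Configuration of the tier-2 rescoring campaign
#'
#' Stage counts follow the reference protocol (1500/200 loop slices up to a
#' 1700 total, a 4000/800 refinement slice, a 522-compound final round) and
#' are rescaled by `scale`, which defaults to the screening campaign's
#' library fraction (library size / 2.654e9). Rescaled counts are rounded up
#' and floored at 1, so very small campaigns degenerate gracefully.
#'
#' @param eligibility_threshold tier-1 ceiling (strict, kcal/mol) for stages
#'   A-C (default -9)
#' @param relaxed_threshold tier-1 ceiling for the stage-D pool (default -4)
#' @param sim_threshold Tanimoto ceiling used by every diversity step
#'   (default 0.4)
#' @param loop_top,loop_batch,loop_total,refine_top,refine_keep,final_keep
#'   stage counts before rescaling
#' @param max_acid stage C keeps molecules with strictly fewer carboxylic
#'   acid groups than this (default 2)
#' @param scale count rescaling factor; `NULL` means the campaign's library
#'   fraction
#' @param surrogate_cfg a [surrogate_config()] for the tier-2 surrogate
#' @return an object of class `rescoring_config`
#' @export
rescoring_config <- function(eligibility_threshold = -9, relaxed_threshold = -4,
                             sim_threshold = 0.4,
                             loop_top = 1500L, loop_batch = 200L,
                             loop_total = 1700L, refine_top = 4000L,
                             refine_keep = 800L, final_keep = 522L,
                             max_acid = 2L, scale = NULL,
                             surrogate_cfg = surrogate_config()) {
  stopifnot(sim_threshold > 0, sim_threshold <= 1, max_acid >= 1)
  structure(list(eligibility_threshold = eligibility_threshold,
                 relaxed_threshold = relaxed_threshold,
                 sim_threshold = sim_threshold,
                 loop_top = loop_top, loop_batch = loop_batch,
                 loop_total = loop_total, refine_top = refine_top,
                 refine_keep = refine_keep, final_keep = final_keep,
                 max_acid = as.integer(max_acid), scale = scale,
                 surrogate_cfg = surrogate_cfg),
            class = "rescoring_config")
}

.rescale_count <- function(count, scale) max(1L, as.integer(ceiling(count * scale)))

# tier-2 predictions over a candidate subset; falls back to tier-1 ranking
# while too few tier-2 scores exist to train the surrogate
.tier2_predictions <- function(scored_recs, scores2, candidates, cfg, seed,
                               fp_cache) {
  if (nrow(scored_recs) >= 50) {
    scfg <- cfg$surrogate_cfg
    scfg$seed <- seed
    attr(scored_recs, "fp_cache") <- fp_cache
    model <- train_surrogate(scored_recs, scores2, scfg)
    attr(candidates, "fp_cache") <- fp_cache
    predict_scores(model, candidates)
  } else {
    stats::setNames(candidates$tier1, candidates$id)
  }
}

#' Run a tier-2 rescoring campaign over a screened library
#'
#' @param state a `campaign_state` from [run_screening_campaign()] (its
#'   ledger supplies the tier-1 scores)
#' @param library the `molecule_records` the campaign screened
#' @param oracle function mapping a records subset to tier-2 scores
#'   (default: [score_tier2()] at default parameters)
#' @param config a [rescoring_config()]
#' @param seed integer seed
#' @return a data frame ledger with columns `id`, `score` (tier-2),
#'   `stage` (`"seed"`, `"loop"`, `"refine"`, `"final"`), `iteration`
#' @export
run_rescoring_campaign <- function(state, library, oracle = score_tier2,
                                   config = rescoring_config(), seed = 1L) {
  stopifnot(inherits(state, "campaign_state"), inherits(config, "rescoring_config"))
  scale <- if (is.null(config$scale)) state$library_size / 2.654e9 else config$scale
  n_loop_top <- .rescale_count(config$loop_top, scale)
  n_loop_batch <- .rescale_count(config$loop_batch, scale)
  n_loop_total <- .rescale_count(config$loop_total, scale)
  n_refine_top <- .rescale_count(config$refine_top, scale)
  n_refine_keep <- .rescale_count(config$refine_keep, scale)
  n_final_keep <- .rescale_count(config$final_keep, scale)

  t1 <- state$ledger
  pool_ids <- t1$id[t1$score < config$eligibility_threshold]
  # records of the eligible pool, ordered by tier-1 score (best first)
  sub <- library[match(pool_ids, library$id), , drop = FALSE]
  sub$tier1 <- t1$score[match(pool_ids, t1$id)]
  sub <- sub[order(sub$tier1, sub$id), , drop = FALSE]
  attr(sub, "synthon_sets") <- attr(library, "synthon_sets")
  ledger2 <- data.frame(id = character(0), score = numeric(0),
                        stage = character(0), iteration = integer(0),
                        stringsAsFactors = FALSE)
  if (nrow(sub) == 0) {
    warning("empty eligible pool (no tier-1 scores below ",
            config$eligibility_threshold, "); rescoring skipped")
    return(ledger2)
  }
  fp_cache <- fingerprint_matrix(sub, n_bits = config$surrogate_cfg$n_bits,
                                 radius = config$surrogate_cfg$radius)
  fps_all <- .fp_list(sub)
  names(fps_all) <- sub$id
  score_batch <- function(ids, stage, it) {
    batch <- sub[match(ids, sub$id), , drop = FALSE]
    data.frame(id = ids, score = oracle(batch), stage = stage, iteration = it,
               stringsAsFactors = FALSE)
  }

  # stage A: diverse seed set among tier-1 hits (size set by the diversity
  # filter itself, as in the reference protocol)
  kept <- cpp_leader_select(unname(fps_all), config$sim_threshold, 0L)
  ledger2 <- rbind(ledger2, score_batch(sub$id[kept], "seed", 0L))

  # stage B: surrogate-guided loop until the rescaled tier-2 target count
  it <- 0L
  while (nrow(ledger2) < n_loop_total) {
    it <- it + 1L
    cand <- sub[!(sub$id %in% ledger2$id), , drop = FALSE]
    if (nrow(cand) == 0) {
      warning("tier-2 loop stopped early: eligible pool exhausted at ",
              nrow(ledger2), " scores")
      break
    }
    scored_recs <- sub[match(ledger2$id, sub$id), , drop = FALSE]
    pred <- .tier2_predictions(scored_recs, ledger2$score, cand, config,
                               seed + 31L * it, fp_cache)
    cand <- cand[order(pred[cand$id], cand$id), , drop = FALSE]
    cand <- cand[seq_len(min(n_loop_top, nrow(cand))), , drop = FALSE]
    sel <- cpp_leader_select_ref(unname(fps_all[cand$id]),
                                 unname(fps_all[ledger2$id]),
                                 config$sim_threshold,
                                 as.integer(min(n_loop_batch,
                                                n_loop_total - nrow(ledger2))))
    if (length(sel) == 0) {
      # nothing passes the similarity filter; take the single best predicted
      sel <- 1L
    }
    ledger2 <- rbind(ledger2, score_batch(cand$id[sel], "loop", it))
  }

  # stage C: predicted top slice, acid-count filter, diversity selection
  cand <- sub[!(sub$id %in% ledger2$id), , drop = FALSE]
  if (nrow(cand) == 0) {
    warning("stage C skipped: eligible pool exhausted")
  } else {
    scored_recs <- sub[match(ledger2$id, sub$id), , drop = FALSE]
    pred <- .tier2_predictions(scored_recs, ledger2$score, cand, config,
                               seed + 7001L, fp_cache)
    cand <- cand[order(pred[cand$id], cand$id), , drop = FALSE]
    cand <- cand[seq_len(min(n_refine_top, nrow(cand))), , drop = FALSE]
    ok <- cand$n_acid < config$max_acid
    if (!any(ok)) {
      stop("acid-group filter eliminated every stage-C candidate (all have >= ",
           config$max_acid, " carboxylic acids)")
    }
    cand <- cand[ok, , drop = FALSE]
    kept <- cpp_leader_select(unname(fps_all[cand$id]), config$sim_threshold,
                              as.integer(n_refine_keep))
    ledger2 <- rbind(ledger2, score_batch(cand$id[kept], "refine", 0L))
  }

  # stage D: relaxed pool (tier-1 below the relaxed threshold), diversity
  # selection against everything already scored
  relaxed_ids <- t1$id[t1$score < config$relaxed_threshold]
  relaxed_ids <- setdiff(relaxed_ids, ledger2$id)
  if (length(relaxed_ids) == 0) {
    warning("stage D skipped: relaxed pool empty")
    return(ledger2)
  }
  rel <- library[match(relaxed_ids, library$id), , drop = FALSE]
  rel$tier1 <- t1$score[match(relaxed_ids, t1$id)]
  attr(rel, "synthon_sets") <- attr(library, "synthon_sets")
  rel_fp_cache <- fingerprint_matrix(rel, n_bits = config$surrogate_cfg$n_bits,
                                     radius = config$surrogate_cfg$radius)
  full_cache <- rbind(fp_cache, rel_fp_cache[setdiff(rownames(rel_fp_cache),
                                                     rownames(fp_cache)), ,
                                             drop = FALSE])
  scored_recs <- sub[match(ledger2$id, sub$id), , drop = FALSE]
  pred <- .tier2_predictions(scored_recs, ledger2$score, rel, config,
                             seed + 9001L, full_cache)
  rel <- rel[order(pred[rel$id], rel$id), , drop = FALSE]
  rel_fps <- .fp_list(rel)
  names(rel_fps) <- rel$id
  sel <- cpp_leader_select_ref(unname(rel_fps),
                               unname(fps_all[intersect(ledger2$id, names(fps_all))]),
                               config$sim_threshold, as.integer(n_final_keep))
  if (length(sel) > 0) {
    batch <- rel[sel, , drop = FALSE]
    ledger2 <- rbind(ledger2,
                     data.frame(id = batch$id, score = oracle(batch),
                                stage = "final", iteration = 0L,
                                stringsAsFactors = FALSE))
  }
  ledger2
}
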