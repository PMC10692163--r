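# Surrogate model: regression from molecular structure to oracle score, plus
# atom-removal attribution.
#
# The default backend is a ridge-regularized linear model on 2048-bit
# circular fingerprints (glmnet), with the regularization strength chosen on
# a held-out validation split — the linear-model analogue of early stopping.
# Any regressor honouring the fit/predict contract can be plugged in behind
# the same interface.

#' Surrogate training configuration
#'
#' @param n_bits,radius fingerprint featurization (defaults 2048 / 2)
#' @param val_fraction held-out fraction used for model selection and the
#'   reported validation Pearson R-squared (default 0.1)
#' @param batch_size minibatch size handed to pluggable iterative backends
#'   (default 128); the ridge default fits in closed form and records it for
#'   provenance only
#' @param seed integer seed for the train/validation split
#' @param backend `"ridge"` or a function
#'   `function(x_train, y_train, x_val, y_val, config)` returning a list with
#'   elements `predict` (function of a sparse matrix) and optional `info`
#' @return an object of class `surrogate_config`
#' @export
surrogate_config <- function(n_bits = 2048L, radius = 2L, val_fraction = 0.1,
                             batch_size = 128L, seed = 1L, backend = "ridge") {
  stopifnot(n_bits >= 8, radius >= 0, val_fraction > 0, val_fraction < 1)
  structure(list(n_bits = as.integer(n_bits), radius = as.integer(radius),
                 val_fraction = val_fraction, batch_size = as.integer(batch_size),
                 seed = as.integer(seed), backend = backend),
            class = "surrogate_config")
}

.ridge_backend <- function(x_train, y_train, x_val, y_val, config) {
  fit <- glmnet::glmnet(x_train, y_train, alpha = 0, nlambda = 50,
                        standardize = FALSE)
  pred_val <- predict(fit, x_val)
  mse <- colMeans((pred_val - y_val)^2)
  best <- which.min(mse)
  lambda <- fit$lambda[best]
  list(predict = function(x) as.vector(predict(fit, x, s = lambda)),
       info = list(lambda = lambda, n_lambda_path = length(fit$lambda)))
}

#' Train a surrogate score predictor
#'
#' @param records a `molecule_records` data frame (>= 50 rows)
#' @param scores finite numeric oracle scores aligned with `records`
#' @param config a [surrogate_config()]
#' @return an object of class `surrogate_model` with a `training_meta` list
#'   (`n_train`, `n_val`, `val_r2` — held-out Pearson R-squared —,
#'   `batch_size`, `backend`)
#' @export
train_surrogate <- function(records, scores, config = surrogate_config()) {
  stopifnot(inherits(config, "surrogate_config"))
  if (nrow(records) < 50) {
    stop("insufficient data: surrogate training needs at least 50 scored records")
  }
  if (!all(is.finite(scores)) || length(scores) != nrow(records)) {
    stop("scores must be finite and aligned with records")
  }
  x <- fingerprint_matrix(records, n_bits = config$n_bits, radius = config$radius)
  if (sd(scores) == 0) {
    warning("degenerate targets: all scores identical; model predicts the constant")
    model <- structure(list(config = config, constant = scores[1],
                            training_meta = list(n_train = nrow(records), n_val = 0L,
                                                 val_r2 = NA_real_,
                                                 batch_size = config$batch_size,
                                                 backend = "constant")),
                       class = "surrogate_model")
    return(model)
  }
  n <- nrow(records)
  n_val <- max(1L, round(config$val_fraction * n))
  val_idx <- .with_seed(config$seed, sample.int(n, n_val))
  tr_idx <- setdiff(seq_len(n), val_idx)
  backend_fn <- if (is.function(config$backend)) config$backend else .ridge_backend
  fitted <- backend_fn(x[tr_idx, , drop = FALSE], scores[tr_idx],
                       x[val_idx, , drop = FALSE], scores[val_idx], config)
  pred_val <- fitted$predict(x[val_idx, , drop = FALSE])
  val_r2 <- suppressWarnings(cor(pred_val, scores[val_idx]))^2
  if (is.na(val_r2)) val_r2 <- 0
  structure(list(config = config, predict_fn = fitted$predict,
                 backend_info = fitted$info,
                 training_meta = list(
                   n_train = length(tr_idx), n_val = n_val, val_r2 = val_r2,
                   batch_size = config$batch_size,
                   backend = if (is.function(config$backend)) "custom" else config$backend)),
            class = "surrogate_model")
}

#' @export
print.surrogate_model <- function(x, ...) {
  m <- x$training_meta
  cat("surrogate_model (", m$backend, "): n_train =", m$n_train,
      ", validation Pearson R^2 =", round(m$val_r2, 3), "\n")
  invisible(x)
}

#' Predict oracle scores with a trained surrogate
#'
#' Predictions are deterministic and independent of batching. Records that
#' cannot be featurized receive `NA` and are listed in the `"failures"`
#' attribute; other records are unaffected.
#'
#' @param model a `surrogate_model`
#' @param records a `molecule_records` data frame
#' @param chunk number of molecules featurized per block
#' @return named numeric vector of predicted scores (kcal/mol)
#' @export
predict_scores <- function(model, records, chunk = 20000L) {
  stopifnot(inherits(model, "surrogate_model"))
  n <- nrow(records)
  out <- rep(NA_real_, n)
  names(out) <- records$id
  if (!is.null(model$constant)) {
    out[] <- model$constant
    return(out)
  }
  failures <- character(0)
  parts <- split(seq_len(n), ceiling(seq_len(n) / chunk))
  for (idx in parts) {
    block <- records[idx, , drop = FALSE]
    x <- tryCatch(fingerprint_matrix(block, n_bits = model$config$n_bits,
                                     radius = model$config$radius),
                  error = function(e) NULL)
    if (!is.null(x) && nrow(x) == length(idx)) {
      out[idx] <- model$predict_fn(x)
    } else {
      # fall back to per-record featurization to isolate failures
      for (i in idx) {
        xi <- tryCatch(fingerprint_matrix(records[i, , drop = FALSE],
                                          n_bits = model$config$n_bits,
                                          radius = model$config$radius),
                       error = function(e) NULL)
        if (is.null(xi)) failures <- c(failures, records$id[i])
        else out[i] <- model$predict_fn(xi)
      }
    }
  }
  if (length(failures) > 0) attr(out, "failures") <- failures
  out
}

# fingerprint of a graph with one heavy atom removed (bonds dropped, no
# valence repair; remaining fragments featurized together)
.ablated_fp <- function(g, atom, n_bits, radius) {
  keep <- setdiff(seq_along(g$z), atom)
  remap <- match(seq_along(g$z), keep)
  bkeep <- g$bfrom != atom & g$bto != atom
  cpp_fp_bits(g$z[keep], g$charge[keep], g$nh[keep], g$inring[keep],
              remap[g$bfrom[bkeep]], remap[g$bto[bkeep]], g$border[bkeep],
              radius, n_bits)
}

#' Atom-removal attribution of surrogate predictions
#'
#' For each heavy atom, the contribution is the predicted score of the full
#' molecule minus the prediction for the molecule with that atom (and its
#' bonds) deleted. No valence repair is applied and hydrogens are not
#' attributed; all remaining fragments stay in the featurization.
#'
#' @param model a trained `surrogate_model`
#' @param record one-row `molecule_records` data frame (or id + smiles list)
#' @return a data frame with `id`, `atom_index`, `symbol`, `contribution`
#'   (kcal/mol), one row per heavy atom
#' @export
atom_attribution <- function(model, record) {
  stopifnot(inherits(model, "surrogate_model"), nrow(record) == 1)
  if (grepl("^\\[?[A-Za-z][a-z]?([+-][0-9]?)?\\]?$", record$smiles)) {
    # single-heavy-atom molecules cannot be ablated
    stop("attribution needs at least 2 heavy atoms (ablation would empty the graph)")
  }
  parsed <- mol_graphs_from_smiles(stats::setNames(record$smiles, record$id))
  if (length(parsed$graphs) == 0) stop("unparseable structure: ", record$smiles)
  g <- parsed$graphs[[1]]
  n <- length(g$z)
  if (n < 2) {
    stop("attribution needs at least 2 heavy atoms (ablation would empty the graph)")
  }
  nb <- model$config$n_bits
  rad <- model$config$radius
  to_x <- function(bits) {
    Matrix::sparseMatrix(i = rep(1L, length(bits)), j = bits + 1L, x = 1,
                         dims = c(1L, nb))
  }
  pred1 <- function(bits) {
    if (!is.null(model$constant)) model$constant else model$predict_fn(to_x(bits))
  }
  full <- pred1(fingerprint_graph(g, n_bits = nb, radius = rad))
  contrib <- vapply(seq_len(n), function(i) {
    full - pred1(.ablated_fp(g, i, nb, rad))
  }, numeric(1))
  data.frame(id = record$id, atom_index = seq_len(n), symbol = g$sym,
             contribution = contrib, stringsAsFactors = FALSE)
}
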