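# User-facing model fitting: vanilla topological regression (tr_fit) and
# the adaptive variant with ridge, k-means response anchors, adaptive
# structure-anchor selection and optimization-based reconstruction
# (adaptor_fit).

anchor_rows <- function(data, ids) {
  data[match(ids, data$id), , drop = FALSE]
}

new_tr_model <- function(dmodel, structure_anchors, response_anchors,
                         reconstruction, fp_kind, seed, n_train,
                         class = "tr_model") {
  structure(
    list(
      model = dmodel,
      structure_anchors = structure_anchors,
      response_anchors = response_anchors[, c("id", "response")],
      reconstruction = reconstruction,
      fp_kind = fp_kind,
      seed = seed,
      n_train = n_train
    ),
    class = unique(c(class, "tr_model"))
  )
}

fit_on_anchors <- function(rows, structure_anchors, response_anchors,
                           lambda) {
  Ds <- build_distance_matrix(rows, structure_anchors, "structure")
  Dr <- build_distance_matrix(rows, response_anchors, "response")
  fit_distance_regression(Ds, Dr, lambda = lambda,
                          response_anchor_values = response_anchors$response)
}

#' Fit a vanilla topological regression model
#'
#' The parent method: `round(anchor_fraction * N)` training molecules are
#' drawn at random and used as both structure and response anchors, the
#' distance regression is fitted on all training rows by least squares
#' (`lambda = 0`) and responses are reconstructed with the RBF weighted
#' average.
#'
#' @param data Molecule table with a `fingerprint` list-column.
#' @param anchor_fraction Fraction of training samples used as anchors;
#'   default 0.6.
#' @param lambda Ridge penalty; default 0 (ordinary least squares).
#' @param reconstruction `"rbf"` (default for vanilla TR) or
#'   `"optimization"`.
#' @param gamma RBF bandwidth.
#' @param solver Solver for the optimization reconstruction.
#' @param seed Seed controlling the anchor draw.
#' @return A `tr_model`; predict with [predict.tr_model()].
#' @export
tr_fit <- function(data, anchor_fraction = 0.6, lambda = 0,
                   reconstruction = c("rbf", "optimization"), gamma = 1,
                   solver = c("exact", "nelder_mead"), seed = 1) {
  reconstruction <- match.arg(reconstruction)
  solver <- match.arg(solver)
  check_molecule_table(data, need_fingerprints = TRUE)
  anchor_ids <- select_tr_anchors(data$id, anchor_fraction, seed)
  anchors <- anchor_rows(data, anchor_ids)
  dmodel <- fit_on_anchors(data, anchors, anchors, lambda)
  new_tr_model(dmodel, anchors, anchors,
               list(method = reconstruction, gamma = gamma, solver = solver),
               fp_kind_of(data), seed, nrow(data))
}

#' Fit an adaptive topological regression model
#'
#' The full adaptive method: ridge distance regression (`lambda`), `kr`
#' response anchors chosen by k-means in response space, and `steps` rounds
#' of adaptive structure-anchor selection. Step 1 fits on a random
#' `round(anchor_fraction * N)`-sized anchor set S1; each later step adds
#' the held-out training molecules with the highest absolute prediction
#' error (`Sp = Sp-1 U S*p-1`) and refits. With the defaults
#' (fraction 0.15, 4 steps) the final anchor set holds 60% of the training
#' samples — the same budget as vanilla TR, but concentrated where the
#' model was wrong. Responses are reconstructed by minimizing the
#' distance-mismatch objective (default) or by RBF weighting.
#'
#' @param data Molecule table with a `fingerprint` list-column.
#' @param lambda Ridge penalty; default 0.05.
#' @param kr Number of response anchors; default 10.
#' @param anchor_fraction Fraction of training samples added to the
#'   structure-anchor set at each step; default 0.15.
#' @param steps Number of adaptive steps P; default 4.
#' @param reconstruction `"optimization"` (default) or `"rbf"`.
#' @param gamma RBF bandwidth.
#' @param solver Solver for the optimization reconstruction.
#' @param early_stopping If `TRUE`, 10% of the training data is split off
#'   as a validation set (by seed) and the loop stops once validation NRMSE
#'   improves by less than `min_delta` for `patience` consecutive steps.
#' @param min_delta,patience Early-stopping hyperparameters; defaults 0.006
#'   and 2.
#' @param val_fraction Validation fraction used when `early_stopping` is on.
#' @param seed Master seed (fans out to split/anchor/k-means streams).
#' @return An `adaptor_model` (also a `tr_model`), with the per-step models
#'   available via [step_models()].
#' @export
adaptor_fit <- function(data, lambda = 0.05, kr = 10, anchor_fraction = 0.15,
                        steps = 4,
                        reconstruction = c("optimization", "rbf"),
                        gamma = 1, solver = c("exact", "nelder_mead"),
                        early_stopping = FALSE, min_delta = 0.006,
                        patience = 2, val_fraction = 0.1, seed = 1) {
  reconstruction <- match.arg(reconstruction)
  solver <- match.arg(solver)
  check_molecule_table(data, need_fingerprints = TRUE)
  check_scalar_number(anchor_fraction, "anchor_fraction", lower = 1e-9,
                      upper = 1)
  stopifnot(steps >= 1, kr >= 1)

  validation <- NULL
  pool <- data
  if (early_stopping) {
    n_val <- round(val_fraction * nrow(data))
    if (n_val < 2) {
      rlang::abort("early stopping needs a validation split of at least 2 samples.")
    }
    val_ids <- with_seed(sub_seed(seed, "val_split"), sample(data$id, n_val))
    validation <- anchor_rows(data, val_ids)
    pool <- data[!(data$id %in% val_ids), , drop = FALSE]
  }

  n <- nrow(pool)
  ka <- round(anchor_fraction * n)
  if (ka < 1) rlang::abort("anchor_fraction too small: no anchors per step.")
  if (steps * ka > n) {
    rlang::abort(sprintf(
      "infeasible configuration: steps * Ka = %d exceeds N = %d.",
      steps * ka, n))
  }

  response_anchors <- anchor_rows(pool,
                                  select_response_anchors(pool, kr, seed))
  recon <- list(method = reconstruction, gamma = gamma, solver = solver)

  s_p <- sort(select_initial_structure_anchors(pool$id, ka, seed))
  anchor_sets <- list()
  anchor_star_sets <- list()
  step_fits <- list()
  val_history <- numeric(0)
  early_stopped <- FALSE

  for (p in seq_len(steps)) {
    anchors <- anchor_rows(pool, s_p)
    dmodel <- fit_on_anchors(anchors, anchors, response_anchors, lambda)
    step_model <- new_tr_model(dmodel, anchors, response_anchors, recon,
                               fp_kind_of(data), seed, nrow(data))
    anchor_sets[[p]] <- s_p
    step_fits[[p]] <- step_model

    if (early_stopping) {
      val_pred <- predict(step_model, validation)$.pred
      val_history <- c(val_history,
                       compute_metrics(validation$response, val_pred)$nrmse)
      if (early_stop_check(val_history, min_delta, patience)) {
        early_stopped <- TRUE
        break
      }
    }
    if (p == steps) break

    heldout <- pool[!(pool$id %in% s_p), , drop = FALSE]
    err <- abs(heldout$response - predict(step_model, heldout)$.pred)
    pick <- heldout$id[order(-err, heldout$id)][seq_len(ka)]
    anchor_star_sets[[p]] <- sort(pick)
    s_p <- sort(c(s_p, pick))
  }

  final <- step_fits[[length(step_fits)]]
  structure(
    c(unclass(final),
      list(
        steps = step_fits,
        anchor_sets = anchor_sets,
        anchor_star_sets = anchor_star_sets,
        validation_ids = validation$id,
        val_history = val_history,
        early_stopped = early_stopped,
        config = list(lambda = lambda, kr = kr,
                      anchor_fraction = anchor_fraction, steps = steps,
                      min_delta = min_delta, patience = patience,
                      early_stopping = early_stopping)
      )),
    class = c("adaptor_model", "tr_model")
  )
}

#' Step models from adaptive anchor selection
#'
#' @param model An `adaptor_model`.
#' @return List of per-step `tr_model`s (intermediate and final).
#' @export
step_models <- function(model) {
  stopifnot(inherits(model, "adaptor_model"))
  model$steps
}

#' Predict responses for new molecules
#'
#' Computes structure distances from `newdata` to the model's structure
#' anchors, maps them to estimated response distances through the fitted
#' weights, and reconstructs a scalar response per molecule.
#'
#' @param object A fitted `tr_model` or `adaptor_model`.
#' @param newdata Molecule table with a `fingerprint` list-column.
#' @param ... Unused.
#' @return A tibble with columns `id` and `.pred`.
#' @export
predict.tr_model <- function(object, newdata, ...) {
  check_molecule_table(newdata, need_fingerprints = TRUE)
  Ds_new <- build_distance_matrix(newdata, object$structure_anchors,
                                  "structure")
  d_hat <- predict_response_distances(object$model, Ds_new, clip = "raw")
  preds <- reconstruct_responses(
    d_hat, object$response_anchors$response,
    method = object$reconstruction$method,
    gamma = object$reconstruction$gamma,
    solver = object$reconstruction$solver
  )
  tibble::tibble(id = newdata$id, .pred = as.numeric(preds))
}

#' @export
print.tr_model <- function(x, ...) {
  cat(sprintf(
    "<%s> %d structure anchors, %d response anchors, lambda = %g, reconstruction = %s\n",
    class(x)[1], nrow(x$structure_anchors), nrow(x$response_anchors),
    x$model$lambda, x$reconstruction$method))
  if (inherits(x, "adaptor_model")) {
    sizes <- vapply(x$anchor_sets, length, integer(1))
    cat(sprintf("  adaptive steps: %d (anchor set sizes: %s)%s\n",
                length(x$steps), paste(sizes, collapse = " -> "),
                if (x$early_stopped) ", early-stopped" else ""))
  }
  invisible(x)
}

#' @describeIn predict.tr_model Tidied distance-regression weights.
#' @param x A fitted model.
#' @export
tidy.tr_model <- function(x, ...) tidy(x$model)

#' @describeIn predict.tr_model One-row fit summary.
#' @export
glance.tr_model <- function(x, ...) {
  dplyr::mutate(glance(x$model),
                reconstruction = x$reconstruction$method,
                n_train = x$n_train,
                steps = if (inherits(x, "adaptor_model")) length(x$steps) else 1L)
}
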