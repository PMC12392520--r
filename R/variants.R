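# Ensemble and stacking variants of topological regression.

#' Fit an ensemble of enhanced TR models with random anchor fractions
#'
#' Draws `n_models` anchor fractions from `Normal(frac_mean, frac_sd)`
#' clipped to `frac_bounds` and fits one enhanced TR member per fraction
#' (random structure anchors of that fraction, k-means response anchors,
#' ridge regression, the chosen reconstruction — i.e. all the adaptive
#' method's features except adaptive selection). The ensemble prediction is
#' the arithmetic mean of the member predictions.
#'
#' @param data Molecule table with fingerprints.
#' @param n_models Number of members; default 15.
#' @param frac_mean,frac_sd Gaussian the fractions are drawn from;
#'   defaults 0.6 and 0.3.
#' @param frac_bounds Clipping bounds for the fractions; default
#'   `c(0.3, 0.9)`.
#' @param lambda,kr,reconstruction,gamma,solver Member model settings (see
#'   [adaptor_fit()]).
#' @param seed Master seed.
#' @return An `ensemble_model`.
#' @export
ensemble_fit <- function(data, n_models = 15, frac_mean = 0.6,
                         frac_sd = 0.3, frac_bounds = c(0.3, 0.9),
                         lambda = 0.05, kr = 10,
                         reconstruction = c("rbf", "optimization"),
                         gamma = 1, solver = c("exact", "nelder_mead"),
                         seed = 1) {
  reconstruction <- match.arg(reconstruction)
  solver <- match.arg(solver)
  check_molecule_table(data, need_fingerprints = TRUE)
  if (n_models < 1) rlang::abort("`n_models` must be at least 1.")
  fractions <- with_seed(sub_seed(seed, "fractions"),
                         stats::rnorm(n_models, frac_mean, frac_sd))
  fractions <- pmin(pmax(fractions, frac_bounds[1]), frac_bounds[2])
  members <- lapply(seq_len(n_models), function(m) {
    adaptor_fit(data, lambda = lambda, kr = kr,
                anchor_fraction = fractions[m], steps = 1,
                reconstruction = reconstruction, gamma = gamma,
                solver = solver, seed = sub_seed(seed, paste0("member", m)))
  })
  structure(list(members = members, fractions = fractions, seed = seed),
            class = "ensemble_model")
}

#' @export
print.ensemble_model <- function(x, ...) {
  cat(sprintf("<ensemble_model> %d members, anchor fractions %s\n",
              length(x$members),
              paste(sprintf("%.2f", x$fractions), collapse = ", ")))
  invisible(x)
}

# Members may be fitted models (anything whose predict() returns a `.pred`
# column) or plain functions newdata -> numeric predictions.
member_prediction_matrix <- function(members, newdata) {
  vapply(members, function(m) {
    if (is.function(m)) m(newdata) else predict(m, newdata)$.pred
  }, numeric(nrow(newdata)))
}

#' @describeIn ensemble_fit Mean of the member predictions.
#' @param object An `ensemble_model`.
#' @param newdata Molecule table with fingerprints.
#' @param ... Unused.
#' @export
predict.ensemble_model <- function(object, newdata, ...) {
  P <- member_prediction_matrix(object$members, newdata)
  tibble::tibble(id = newdata$id, .pred = rowMeans(as.matrix(P)))
}

#' Stack fitted models with a linear combination
#'
#' Holds out `val_fraction` of the training molecules (by seed), predicts
#' them with every member and fits an ordinary least-squares combination
#' (with intercept) of the member predictions against the observed
#' responses. Members should have been fitted without the holdout molecules
#' to keep the weight estimate honest.
#'
#' @param data The training molecule table the holdout is drawn from.
#' @param members List of at least two fitted models (any model with a
#'   `predict` method returning `.pred`, or a plain function
#'   `newdata -> numeric`).
#' @param val_fraction Holdout fraction; default 0.1.
#' @param seed Seed for the holdout draw.
#' @return A `stack_model` with `weights` (intercept first).
#' @export
stack_fit <- function(data, members, val_fraction = 0.1, seed = 1) {
  check_molecule_table(data, need_fingerprints = TRUE)
  if (length(members) < 2) rlang::abort("stacking needs at least 2 members.")
  n_val <- round(val_fraction * nrow(data))
  if (n_val < length(members) + 1) {
    rlang::abort(sprintf(
      "holdout of %d samples cannot identify %d stacking weights + intercept.",
      n_val, length(members)))
  }
  val_ids <- with_seed(sub_seed(seed, "stack_val"), sample(data$id, n_val))
  val <- data[data$id %in% val_ids, , drop = FALSE]
  P <- as.matrix(member_prediction_matrix(members, val))
  fit <- stats::lm.fit(cbind(1, P), val$response)
  w <- fit$coefficients
  w[is.na(w)] <- 0   # collinear members (e.g. identical) get zero extra weight
  structure(list(members = members, weights = unname(w),
                 validation_ids = sort(val_ids), seed = seed),
            class = "stack_model")
}

#' @describeIn stack_fit Weighted combination of member predictions.
#' @param object A `stack_model`.
#' @param newdata Molecule table with fingerprints.
#' @param ... Unused.
#' @export
predict.stack_model <- function(object, newdata, ...) {
  P <- as.matrix(member_prediction_matrix(object$members, newdata))
  tibble::tibble(id = newdata$id,
                 .pred = as.numeric(cbind(1, P) %*% object$weights))
}

#' Ensemble or stack the step models of adaptive anchor selection
#'
#' Combines the predictions of the intermediate and final models produced
#' during adaptive anchor selection: `mode = "ensemble"` averages them,
#' `mode = "stack"` fits stacking weights on a supplied validation table
#' first.
#'
#' @param model An `adaptor_model` with at least 2 retained step models.
#' @param newdata Molecule table with fingerprints.
#' @param mode `"ensemble"` or `"stack"`.
#' @param validation Molecule table used to estimate stacking weights
#'   (required for `mode = "stack"`).
#' @param seed Seed for the stacking holdout.
#' @return A tibble with columns `id` and `.pred`.
#' @export
adaptive_ensemble_predict <- function(model, newdata,
                                      mode = c("ensemble", "stack"),
                                      validation = NULL, seed = 1) {
  mode <- match.arg(mode)
  stopifnot(inherits(model, "adaptor_model"))
  members <- step_models(model)
  if (length(members) < 1) rlang::abort("no step history retained.")
  if (length(members) == 1) return(predict(members[[1]], newdata))
  if (mode == "ensemble") {
    P <- as.matrix(member_prediction_matrix(members, newdata))
    return(tibble::tibble(id = newdata$id, .pred = rowMeans(P)))
  }
  if (is.null(validation)) {
    rlang::abort("`mode = \"stack\"` needs a `validation` table to estimate weights.")
  }
  stack <- stack_fit(validation, members, val_fraction = 1, seed = seed)
  predict(stack, newdata)
}
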