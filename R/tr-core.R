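# Core distance-space regression: Dr = Ds W + 1 beta + eps, fitted by
# ordinary least squares (lambda = 0) or ridge regression.

#' Fit the linear map from structure distances to response distances
#'
#' Builds the augmented design `Ds* = [1, Ds]` and solves the ridge normal
#' equations `(Ds*' Ds* + lambda I) W* = Ds*' Dr` with a symmetric
#' positive-definite solve; `lambda = 0` gives the ordinary least-squares
#' solution. By default the penalty applies to the whole coefficient matrix
#' `W* = [beta', W']'`, i.e. the intercept row is penalized too.
#'
#' @param Ds N x Ks structure distance matrix (column names are the
#'   structure-anchor ids).
#' @param Dr N x Kr response distance matrix (column names are the
#'   response-anchor ids).
#' @param lambda Ridge penalty, `>= 0`; default 0.05.
#' @param response_anchor_values Length-Kr responses `t_k` of the response
#'   anchors (needed later for reconstruction; optional at fit time).
#' @param penalize_intercept Penalize the intercept row of `W*` (default
#'   `TRUE`, the exact Frobenius-norm objective); set `FALSE` to exempt it.
#' @return A `distance_model`: list with `W` (Ks x Kr), `beta` (length Kr),
#'   `lambda`, anchor id vectors and `response_anchor_values`.
#' @export
fit_distance_regression <- function(Ds, Dr, lambda = 0.05,
                                    response_anchor_values = NULL,
                                    penalize_intercept = TRUE) {
  Ds <- as.matrix(Ds); Dr <- as.matrix(Dr)
  if (nrow(Ds) != nrow(Dr)) {
    rlang::abort("`Ds` and `Dr` must have the same rows (samples).")
  }
  check_scalar_number(lambda, "lambda", lower = 0)
  X <- cbind(`(intercept)` = 1, Ds)
  A <- crossprod(X)
  pen <- diag(ncol(X)) * lambda
  if (!penalize_intercept) pen[1, 1] <- 0
  A <- A + pen
  Wstar <- tryCatch(
    solve(A, crossprod(X, Dr)),
    error = function(e) {
      if (lambda == 0) {
        rlang::abort(paste0(
          "normal equations are singular (collinear structure distances); ",
          "refit with lambda > 0."))
      }
      stop(e)
    }
  )
  structure(
    list(
      W = Wstar[-1, , drop = FALSE],
      beta = Wstar[1, ],
      lambda = lambda,
      penalize_intercept = penalize_intercept,
      structure_anchor_ids = colnames(Ds),
      response_anchor_ids = colnames(Dr),
      response_anchor_values = response_anchor_values
    ),
    class = "distance_model"
  )
}

#' Predict response distances from structure distances
#'
#' Computes `Ds* W*` for new samples and optionally maps the raw estimates
#' through `|.|` (used in weight interpretation) or `max(0, .)` (used in
#' response reconstruction, where a distance must be nonnegative).
#'
#' @param model A `distance_model`.
#' @param Ds_new n x Ks structure distance matrix; columns must align with
#'   `model$structure_anchor_ids`.
#' @param clip `"raw"`, `"abs"` or `"nonneg"`.
#' @return An n x Kr matrix of estimated response distances.
#' @export
predict_response_distances <- function(model, Ds_new,
                                       clip = c("raw", "abs", "nonneg")) {
  clip <- match.arg(clip)
  stopifnot(inherits(model, "distance_model"))
  Ds_new <- as.matrix(Ds_new)
  if (ncol(Ds_new) != nrow(model$W)) {
    rlang::abort("`Ds_new` has the wrong number of anchor columns.")
  }
  if (!is.null(colnames(Ds_new)) && !is.null(model$structure_anchor_ids) &&
      !identical(colnames(Ds_new), model$structure_anchor_ids)) {
    rlang::abort("`Ds_new` columns do not match the model's structure anchors.")
  }
  D <- Ds_new %*% model$W +
    matrix(model$beta, nrow(Ds_new), length(model$beta), byrow = TRUE)
  switch(clip, raw = D, abs = abs(D), nonneg = pmax(D, 0))
}

#' @export
print.distance_model <- function(x, ...) {
  cat(sprintf(
    "<distance_model> %d structure anchors -> %d response anchors, lambda = %g\n",
    nrow(x$W), ncol(x$W), x$lambda))
  invisible(x)
}

#' @describeIn fit_distance_regression Tidy the fitted weights into one row
#'   per (structure anchor, response anchor) pair, with the intercept as
#'   structure anchor `"(intercept)"`.
#' @param x A `distance_model`.
#' @param ... Unused.
#' @export
tidy.distance_model <- function(x, ...) {
  Wstar <- rbind(`(intercept)` = x$beta, x$W)
  sa <- c("(intercept)", x$structure_anchor_ids %||%
            as.character(seq_len(nrow(x$W))))
  ra <- x$response_anchor_ids %||% as.character(seq_len(ncol(x$W)))
  tidyr::expand_grid(structure_anchor = sa, response_anchor = ra) |>
    dplyr::arrange(match(.data$structure_anchor, sa)) |>
    dplyr::mutate(weight = as.vector(t(Wstar)))
}

#' @describeIn fit_distance_regression One-row model summary.
#' @export
glance.distance_model <- function(x, ...) {
  tibble::tibble(
    n_structure_anchors = nrow(x$W),
    n_response_anchors = ncol(x$W),
    lambda = x$lambda,
    frobenius_norm = sqrt(sum(rbind(x$beta, x$W)^2))
  )
}

#' Save or load a fitted model archive
#'
#' Model archives hold everything needed to predict (weights, anchor ids,
#' anchor responses and fingerprints, reconstruction settings) and
#' round-trip exactly.
#'
#' @param model Any fitted topreg model.
#' @param path Archive path (`.rds`).
#' @return `save_model()` returns `path` invisibly; `load_model()` returns
#'   the model.
#' @export
save_model <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) readRDS(path)
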