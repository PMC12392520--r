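# Evaluation metrics and the drug-blind cross-validation harness.

#' Prediction performance metrics
#'
#' Computes the four standard QSAR evaluation metrics:
#' * `nrmse` — root-mean-square error divided by the standard deviation of
#'   the observed responses (equivalently `sqrt(SS_res / SS_tot)`); the
#'   mean-predictor null model scores exactly 1;
#' * `spearman_rho` — Spearman rank correlation (mid-ranks under ties; with
#'   distinct ranks this equals `1 - 6 sum(v_i^2) / (n (n^2 - 1))` for rank
#'   differences `v_i`);
#' * `pcc` — Pearson correlation;
#' * `bias` — slope of the best-fit line of the residuals against the
#'   observed responses, `sum((y - ybar) (y - yhat)) / sum((y - ybar)^2)`;
#'   0 for unbiased predictions, 1 for the null model.
#'
#' @param y Observed responses.
#' @param y_hat Predicted responses.
#' @return A one-row tibble: `nrmse`, `spearman_rho`, `pcc`, `bias`, `n`.
#' @export
compute_metrics <- function(y, y_hat) {
  stopifnot(length(y) == length(y_hat), length(y) >= 2,
            all(is.finite(y)), all(is.finite(y_hat)))
  ss_tot <- sum((y - mean(y))^2)
  if (ss_tot == 0) {
    rlang::abort("observed responses are constant; metrics are undefined.")
  }
  nrmse <- sqrt(sum((y - y_hat)^2) / ss_tot)
  rho <- if (stats::sd(y_hat) == 0) 0 else
    stats::cor(rank(y), rank(y_hat))
  pcc <- if (stats::sd(y_hat) == 0) 0 else stats::cor(y, y_hat)
  bias <- sum((y - mean(y)) * (y - y_hat)) / ss_tot
  tibble::tibble(nrmse = nrmse, spearman_rho = rho, pcc = pcc, bias = bias,
                 n = length(y))
}

#' Prediction bias via the residual-angle formulation
#'
#' The bias metric admits a geometric reading: with centred observation
#' vector `u = y - mean(y)` and centred residual vector `r`, the slope of
#' residuals on observations equals `(|r| / |u|) * cos(angle(u, r))`. This
#' function computes the bias through that angle explicitly; it agrees with
#' the ratio form in [compute_metrics()] to numerical precision.
#'
#' @inheritParams compute_metrics
#' @return The bias as a single number.
#' @export
bias_angle_check <- function(y, y_hat) {
  stopifnot(length(y) == length(y_hat), length(y) >= 2)
  u <- y - mean(y)
  if (sum(u^2) == 0) {
    rlang::abort("observed responses are constant; bias is undefined.")
  }
  r <- y - y_hat
  rc <- r - mean(r)
  nr <- sqrt(sum(rc^2))
  if (nr == 0) return(0)
  cosang <- sum(u * rc) / (sqrt(sum(u^2)) * nr)
  theta <- acos(min(1, max(-1, cosang)))
  (nr / sqrt(sum(u^2))) * cos(theta)
}

#' Model specifications for cross-validation
#'
#' A model specification bundles a label, a `fit(data, seed)` function and
#' a `predict(model, newdata)` function returning a numeric prediction per
#' row, so that [cross_validate()] can treat every model uniformly.
#' `null_spec()` predicts the training mean (the NRMSE = 1 reference);
#' `tr_spec()` and `adaptor_spec()` wrap [tr_fit()] and [adaptor_fit()];
#' `ensemble_spec()` wraps [ensemble_fit()].
#'
#' @param ... Arguments forwarded to the underlying fit function.
#' @return A `model_spec` list.
#' @export
null_spec <- function() {
  structure(list(
    label = "null",
    fit = function(data, seed) list(mean = mean(data$response)),
    predict = function(model, newdata) rep(model$mean, nrow(newdata))
  ), class = "model_spec")
}

#' @rdname null_spec
#' @export
tr_spec <- function(...) {
  args <- list(...)
  structure(list(
    label = "tr",
    fit = function(data, seed) do.call(tr_fit, c(list(data), args,
                                                 list(seed = seed))),
    predict = function(model, newdata) predict(model, newdata)$.pred
  ), class = "model_spec")
}

#' @rdname null_spec
#' @export
adaptor_spec <- function(...) {
  args <- list(...)
  structure(list(
    label = "adaptor",
    fit = function(data, seed) do.call(adaptor_fit, c(list(data), args,
                                                      list(seed = seed))),
    predict = function(model, newdata) predict(model, newdata)$.pred
  ), class = "model_spec")
}

#' @rdname null_spec
#' @export
ensemble_spec <- function(...) {
  args <- list(...)
  structure(list(
    label = "ensemble",
    fit = function(data, seed) do.call(ensemble_fit, c(list(data), args,
                                                       list(seed = seed))),
    predict = function(model, newdata) predict(model, newdata)$.pred
  ), class = "model_spec")
}

#' Drug-blind k-fold cross-validation
#'
#' Shuffles the molecules by seed into `folds` disjoint test folds (each
#' molecule appears in exactly one test fold — a drug-blind split), fits
#' the model specification on each training portion and scores its
#' predictions on the held-out fold.
#'
#' @param data Molecule table (unique ids required).
#' @param spec A `model_spec` (see [null_spec()]).
#' @param folds Number of folds; default 5 (80/20 splits).
#' @param seed Seed controlling the fold assignment and each fold's fit.
#' @return A tibble of class `topreg_cv` with one row per fold: fold index,
#'   sizes, the four metrics and wall-clock fit/predict times (seconds,
#'   informational).
#' @export
cross_validate <- function(data, spec, folds = 5, seed = 1) {
  check_molecule_table(data)
  stopifnot(inherits(spec, "model_spec"), folds >= 2)
  if (nrow(data) < 2 * folds) {
    rlang::abort("not enough samples for the requested number of folds.")
  }
  # contiguous blocks of the shuffled ids form the disjoint test folds
  shuffled <- with_seed(sub_seed(seed, "cv_split"), sample(data$id))
  sizes <- rep(floor(length(shuffled) / folds), folds)
  sizes[seq_len(length(shuffled) - sum(sizes))] <-
    sizes[seq_len(length(shuffled) - sum(sizes))] + 1
  stops <- cumsum(sizes)
  starts <- c(1, utils::head(stops, -1) + 1)

  purrr::map_dfr(seq_len(folds), function(f) {
    test_ids <- shuffled[starts[f]:stops[f]]
    test <- data[data$id %in% test_ids, , drop = FALSE]
    train <- data[!(data$id %in% test_ids), , drop = FALSE]
    t0 <- proc.time()[["elapsed"]]
    model <- spec$fit(train, sub_seed(seed, paste0("fold", f)))
    t1 <- proc.time()[["elapsed"]]
    preds <- spec$predict(model, test)
    t2 <- proc.time()[["elapsed"]]
    dplyr::mutate(
      compute_metrics(test$response, preds),
      fold = f, model = spec$label,
      n_train = nrow(train), n_test = nrow(test),
      train_time_s = t1 - t0, test_time_s = t2 - t1,
      .before = 1
    )
  }) |>
    (\(x) {class(x) <- c("topreg_cv", class(x)); x})()
}

#' @describeIn cross_validate Mean and standard deviation of each metric
#'   across folds.
#' @param x A `topreg_cv` tibble.
#' @param ... Unused.
#' @export
glance.topreg_cv <- function(x, ...) {
  dplyr::summarise(
    tibble::as_tibble(x),
    dplyr::across(c("nrmse", "spearman_rho", "pcc", "bias",
                    "train_time_s", "test_time_s"),
                  list(mean = mean, sd = stats::sd)),
    folds = dplyr::n(), .by = "model")
}

#' Paired Wilcoxon signed-rank comparison of two cross-validation reports
#'
#' Convenience wrapper around [stats::wilcox.test()] comparing two models'
#' per-fold metrics (paired by fold).
#'
#' @param a,b `topreg_cv` tibbles over the same folds.
#' @param metrics Metric columns to compare.
#' @return A tibble with one row per metric: estimate difference of means
#'   (a - b) and the paired Wilcoxon p-value.
#' @export
compare_models <- function(a, b, metrics = c("nrmse", "spearman_rho",
                                             "pcc", "bias")) {
  stopifnot(nrow(a) == nrow(b))
  purrr::map_dfr(metrics, function(m) {
    tibble::tibble(
      metric = m,
      mean_diff = mean(a[[m]]) - mean(b[[m]]),
      p_value = suppressWarnings(
        stats::wilcox.test(a[[m]], b[[m]], paired = TRUE)$p.value)
    )
  })
}

#' Write a cross-validation report as CSV
#'
#' @param report A `topreg_cv` tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cv_report <- function(report, path) {
  utils::write.csv(tibble::as_tibble(report), path, row.names = FALSE)
  invisible(path)
}
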