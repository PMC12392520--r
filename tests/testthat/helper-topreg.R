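# Shared fixtures, all built in code at test time.

# Small synthetic dataset cache (per test file run).
small_qsar <- local({
  cache <- new.env(parent = emptyenv())
  function(n = 120, seed = 7) {
    key <- paste0("d", n, "_", seed)
    if (is.null(cache[[key]])) cache[[key]] <- make_synthetic_qsar(n, seed = seed)
    cache[[key]]
  }
})

# Write a molecule CSV and return its path.
write_molecule_csv <- function(rows, path = tempfile(fileext = ".csv")) {
  write.csv(rows, path, row.names = FALSE, quote = FALSE)
  path
}

# A hand-built distance model with arbitrary weights, for interpretation
# and prediction-contract tests.
fake_tr_model <- function(W, beta = rep(0, ncol(W)),
                          structure_responses = seq_len(nrow(W)),
                          response_anchor_values = seq_len(ncol(W))) {
  dm <- structure(list(
    W = W, beta = beta, lambda = 0, penalize_intercept = TRUE,
    structure_anchor_ids = sprintf("S%02d", seq_len(nrow(W))),
    response_anchor_ids = sprintf("R%02d", seq_len(ncol(W))),
    response_anchor_values = response_anchor_values
  ), class = "distance_model")
  structure(list(
    model = dm,
    structure_anchors = tibble::tibble(
      id = dm$structure_anchor_ids, response = structure_responses),
    response_anchors = tibble::tibble(
      id = dm$response_anchor_ids, response = response_anchor_values),
    reconstruction = list(method = "rbf", gamma = 1, solver = "exact"),
    fp_kind = "binary", seed = 1, n_train = nrow(W)
  ), class = "tr_model")
}

# Brute-force minimizer of the reconstruction objective on a fine grid —
# independent oracle for the piecewise-quadratic solver.
grid_reconstruct <- function(d_hat, anchors, n = 200001) {
  width <- max(pmax(0, d_hat)) + 1
  grid <- seq(min(anchors) - width, max(anchors) + width, length.out = n)
  A <- abs(outer(grid, anchors, "-"))            # n x Kr
  obj <- rowSums(sweep(-A, 2, pmax(0, d_hat), "+")^2)
  grid[which.min(obj)]
}
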