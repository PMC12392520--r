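# Synthetic data: the four-anchor toy reconstruction geometry and full
# synthetic QSAR datasets with a smooth latent structure-response surface.

#' Toy reconstruction example with Gaussian distance noise
#'
#' Four anchors with responses 4, 5, 6 and 8 and a test sample with
#' response 7: the true response distances are `|7 - t_k| = (3, 2, 1, 1)`,
#' and zero-mean Gaussian noise (sd 0.5 by default) is added to them to
#' emulate response-distance estimation error. This geometry isolates the
#' difference between RBF and optimization-based reconstruction: the RBF
#' weights of the two far anchors vanish, while the optimization objective
#' uses all four distances.
#'
#' @param anchor_responses Anchor responses; default `c(4, 5, 6, 8)`.
#' @param test_response True response of the test sample; default 7.
#' @param noise_sd Standard deviation of the Gaussian distance noise;
#'   default 0.5.
#' @param seed Seed.
#' @return A list: `d_hat` (noisy distances), `true_distances`,
#'   `anchor_responses`, `true_response`, `noise_sd`.
#' @export
make_toy_example <- function(anchor_responses = c(4, 5, 6, 8),
                             test_response = 7, noise_sd = 0.5, seed = 1) {
  check_scalar_number(noise_sd, "noise_sd", lower = 0)
  true_d <- abs(test_response - anchor_responses)
  noise <- if (noise_sd == 0) rep(0, length(true_d)) else
    with_seed(sub_seed(seed, "toy_noise"),
              stats::rnorm(length(true_d), 0, noise_sd))
  list(
    d_hat = true_d + noise,
    true_distances = true_d,
    anchor_responses = anchor_responses,
    true_response = test_response,
    noise_sd = noise_sd
  )
}

#' Generate a synthetic QSAR dataset
#'
#' Molecules live on a latent 2-D coordinate plane; the response is a
#' smooth multi-modal surface of the coordinates plus Gaussian noise,
#' rescaled into `response_range` (default (4, 8), the span of NLOGGI50
#' potencies). Binary fingerprints are built from random-hyperplane
#' indicators of the latent coordinates, so the Jaccard distance between
#' two molecules increases, on average, with their latent distance — the
#' smooth structure-to-response relationship the distance-regression model
#' assumes. Everything is deterministic given the seed.
#'
#' @param n Number of molecules (`>= 20`); default 500.
#' @param n_features Number of fingerprint bits; default 512.
#' @param response_range Range the responses are rescaled into; default
#'   `c(4, 8)`.
#' @param noise_sd Response noise sd (on the surface's natural scale,
#'   which spans roughly `[-1.5, 1.5]` before rescaling); default 0.2.
#' @param seed Seed.
#' @return A molecule table: `id`, `response`, `fingerprint` list-column
#'   (binary), with the latent coordinates as the `latent` attribute
#'   (n x 2 matrix).
#' @export
make_synthetic_qsar <- function(n = 500, n_features = 512,
                                response_range = c(4, 8), noise_sd = 0.2,
                                seed = 1) {
  if (n < 20) rlang::abort("`n` must be at least 20.")
  if (n_features < 8) rlang::abort("`n_features` must be at least 8.")
  if (response_range[2] <= response_range[1]) {
    rlang::abort("`response_range` must be increasing.")
  }
  check_scalar_number(noise_sd, "noise_sd", lower = 0)
  with_seed(sub_seed(seed, "synthetic_qsar"), {
    z <- cbind(stats::runif(n, -1, 1), stats::runif(n, -1, 1))
    surface <- sin(3 * z[, 1]) * cos(2 * z[, 2]) +
      1.2 * exp(-((z[, 1] - 0.5)^2 + (z[, 2] - 0.5)^2) / 0.08) -
      1.0 * exp(-((z[, 1] + 0.6)^2 + (z[, 2] + 0.4)^2) / 0.10)
    y <- surface + stats::rnorm(n, 0, noise_sd)
    y <- response_range[1] +
      (y - min(y)) / (max(y) - min(y)) * diff(response_range)
    w <- matrix(stats::rnorm(2 * n_features), 2)
    w <- sweep(w, 2, sqrt(colSums(w^2)), "/")
    offs <- stats::runif(n_features, -1, 1)
    bits <- (z %*% w > matrix(offs, n, n_features, byrow = TRUE)) * 1L
    ids <- sprintf("M%04d", seq_len(n))
    fps <- lapply(seq_len(n), function(i) {
      fp <- as.integer(bits[i, ])
      attr(fp, "kind") <- "binary"
      fp
    })
    out <- tibble::tibble(id = ids, response = y, fingerprint = fps)
    attr(out, "fp_kind") <- "binary"
    attr(out, "latent") <- z
    out
  })
}

#' Write a synthetic dataset as CSV plus a fingerprint sidecar
#'
#' The main CSV holds `id,response`; the sidecar holds one row per molecule
#' with the id followed by the fingerprint values.
#'
#' @param data A molecule table with fingerprints.
#' @param path Main CSV path; the sidecar is `<path base>_fp.csv`.
#' @return Character vector of the two paths, invisibly.
#' @export
write_synthetic_dataset <- function(data, path) {
  check_molecule_table(data, need_fingerprints = TRUE)
  utils::write.csv(data[, c("id", "response")], path, row.names = FALSE)
  fp_path <- paste0(sub("\\.csv$", "", path), "_fp.csv")
  m <- fp_matrix(data)
  utils::write.csv(data.frame(id = data$id, m, check.names = FALSE), fp_path,
                   row.names = FALSE)
  invisible(c(path, fp_path))
}

#' Read a dataset written by [write_synthetic_dataset()]
#'
#' @param path Main CSV path (the sidecar `<path base>_fp.csv` must exist).
#' @param fp_kind Fingerprint kind recorded on the loaded vectors; default
#'   `"binary"`.
#' @return A molecule table with fingerprints.
#' @export
read_synthetic_dataset <- function(path, fp_kind = "binary") {
  main <- utils::read.csv(path, stringsAsFactors = FALSE)
  fp <- utils::read.csv(paste0(sub("\\.csv$", "", path), "_fp.csv"),
                        stringsAsFactors = FALSE)
  stopifnot(identical(as.character(main$id), as.character(fp$id)))
  m <- as.matrix(fp[, -1, drop = FALSE])
  fps <- lapply(seq_len(nrow(m)), function(i) {
    v <- as.integer(m[i, ])
    attr(v, "kind") <- fp_kind
    v
  })
  out <- tibble::tibble(id = as.character(main$id),
                        response = as.numeric(main$response),
                        fingerprint = fps)
  attr(out, "fp_kind") <- fp_kind
  out
}
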