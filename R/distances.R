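# Structure- and response-space distance matrices (the model inputs Ds, Dr).

#' Distance between two fingerprints
#'
#' Jaccard (Tanimoto) distance `1 - |a & b| / |a | b|` for bit fingerprints
#' (`ecfp4` and synthetic `binary` fingerprints); fraction of differing
#' positions for min-hash fingerprints (`mhfp6`), which is the standard
#' min-hash estimator of the Jaccard distance of the underlying shingle
#' sets. Both lie in [0, 1].
#'
#' @param a,b Integer fingerprint vectors of equal length and kind.
#' @return A distance in [0, 1].
#' @export
structure_distance <- function(a, b) {
  ka <- attr(a, "kind", exact = TRUE) %||% "binary"
  kb <- attr(b, "kind", exact = TRUE) %||% "binary"
  if (!identical(ka, kb)) {
    rlang::abort(sprintf("fingerprint kinds differ: %s vs %s", ka, kb))
  }
  if (length(a) != length(b)) {
    rlang::abort("fingerprint lengths differ.")
  }
  if (ka == "mhfp6") {
    mean(a != b)
  } else {
    inter <- sum(a & b)
    uni <- sum(a | b)
    if (uni == 0) 0 else 1 - inter / uni
  }
}

# Pairwise structure distances between the rows of two fingerprint matrices.
structure_distance_matrix <- function(X, A, kind) {
  if (kind == "mhfp6") {
    out <- matrix(0, nrow(X), nrow(A))
    for (k in seq_len(nrow(A))) {
      out[, k] <- rowMeans(X != matrix(A[k, ], nrow(X), ncol(A), byrow = TRUE))
    }
    out
  } else {
    inter <- X %*% t(A)
    nx <- rowSums(X != 0)
    na <- rowSums(A != 0)
    uni <- outer(nx, na, "+") - inter
    d <- 1 - inter / uni
    d[uni == 0] <- 0   # two empty fingerprints are identical
    d
  }
}

#' Build a structure or response distance matrix
#'
#' Computes the N x K matrix of distances between the molecules in `rows`
#' and the anchor molecules in `cols`: fingerprint distances for
#' `space = "structure"`, absolute response differences `|t_i - t_k|` for
#' `space = "response"`.
#'
#' @param rows A molecule table (the samples, one per matrix row).
#' @param cols A molecule table (the anchors, one per matrix column).
#' @param space `"structure"` or `"response"`.
#' @return A numeric matrix with row/column names set to molecule ids and a
#'   `space` attribute. Entries are 0 whenever a row and a column refer to
#'   the same molecule.
#' @export
build_distance_matrix <- function(rows, cols,
                                  space = c("structure", "response")) {
  space <- match.arg(space)
  if (nrow(cols) == 0) rlang::abort("anchor set is empty.")
  if (space == "structure") {
    kind <- fp_kind_of(rows)
    if (!identical(kind, fp_kind_of(cols))) {
      rlang::abort("fingerprint kinds of rows and cols differ.")
    }
    d <- structure_distance_matrix(fp_matrix(rows), fp_matrix(cols), kind)
  } else {
    check_molecule_table(rows); check_molecule_table(cols)
    d <- abs(outer(rows$response, cols$response, "-"))
  }
  same <- outer(rows$id, cols$id, "==")
  d[same] <- 0
  dimnames(d) <- list(rows$id, cols$id)
  attr(d, "space") <- space
  d
}

#' Write a distance matrix as delimited text
#'
#' @param d A matrix from [build_distance_matrix()].
#' @param path Output CSV path (row ids in the first column, anchor ids as
#'   header).
#' @return `path`, invisibly.
#' @export
write_distance_matrix <- function(d, path) {
  utils::write.csv(as.data.frame(d), path, row.names = TRUE)
  invisible(path)
}
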