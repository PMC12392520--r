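# Weight-based model interpretation: which structure anchors drive the
# estimated distances to each response anchor, and which are critical
# overall once low-response columns are sign-flipped.

as_distance_model <- function(model) {
  if (inherits(model, "tr_model")) return(model)
  rlang::abort("`model` must be a fitted tr_model/adaptor_model.")
}

#' Top structure anchors for one response anchor
#'
#' The i-th column of the fitted weight matrix W holds the weights with
#' which each structure anchor's distance contributes to the estimated
#' response distance to the i-th response anchor. A large positive weight
#' means structural closeness to that anchor pulls the sample's response
#' towards the response anchor's value; a large negative weight pushes it
#' away.
#'
#' @param model A fitted `tr_model` or `adaptor_model`.
#' @param response_anchor Column index (1..Kr) of the response anchor.
#' @param k Number of anchors per direction; default 5.
#' @return A tibble with columns `direction` (`"positive"`/`"negative"`),
#'   `rank`, `anchor_id`, `weight`, `anchor_response`.
#' @export
top_anchor_weights <- function(model, response_anchor, k = 5) {
  model <- as_distance_model(model)
  W <- model$model$W
  if (response_anchor < 1 || response_anchor > ncol(W)) {
    rlang::abort(sprintf("`response_anchor` must be in 1..%d.", ncol(W)))
  }
  k <- min(k, nrow(W))
  w <- W[, response_anchor]
  ids <- model$structure_anchors$id
  resp <- model$structure_anchors$response
  if (all(w == 0)) {
    rlang::warn("all weights for this response anchor are zero.")
    return(tibble::tibble(direction = character(), rank = integer(),
                          anchor_id = character(), weight = numeric(),
                          anchor_response = numeric()))
  }
  pick <- function(ord, direction, keep) {
    idx <- ord[keep]
    tibble::tibble(direction = direction, rank = seq_along(idx),
                   anchor_id = ids[idx], weight = w[idx],
                   anchor_response = resp[idx])
  }
  pos_ord <- order(-w, ids)
  neg_ord <- order(w, ids)
  dplyr::bind_rows(
    pick(pos_ord, "positive", which(w[pos_ord] > 0)[seq_len(min(k, sum(w > 0)))]),
    pick(neg_ord, "negative", which(w[neg_ord] < 0)[seq_len(min(k, sum(w < 0)))])
  )
}

#' Critical structure anchors by adjusted weight sums
#'
#' Flips the sign of the weight-matrix columns whose response-anchor value
#' is below `low_response_threshold` (so that "pulls towards a low
#' response" and "pushes away from a high response" count alike), then sums
#' each structure anchor's adjusted weights across the response anchors.
#' Anchors with large positive (negative) scores are those whose structural
#' proximity (remoteness) is associated with high responses.
#'
#' @param model A fitted `tr_model` or `adaptor_model`.
#' @param low_response_threshold Response value below which a response
#'   anchor counts as "low"; default 5 (an NLOGGI50 convention, tunable).
#' @return A tibble with columns `anchor_id`, `anchor_response`, `score`,
#'   `rank` (1 = most positive score).
#' @export
adjusted_weight_sums <- function(model, low_response_threshold = 5.0) {
  model <- as_distance_model(model)
  W <- model$model$W
  t_k <- model$model$response_anchor_values %||%
    model$response_anchors$response
  flip <- ifelse(t_k < low_response_threshold, -1, 1)
  scores <- as.numeric(W %*% flip)
  out <- tibble::tibble(
    anchor_id = model$structure_anchors$id,
    anchor_response = model$structure_anchors$response,
    score = scores
  )
  out <- dplyr::arrange(out, dplyr::desc(.data$score), .data$anchor_id)
  out$rank <- seq_len(nrow(out))
  out
}

#' Write interpretation reports as CSV
#'
#' Writes the adjusted-weight-sum ranking and, optionally, one per-response-
#' anchor top-weight table per file.
#'
#' @param model A fitted model.
#' @param prefix Output path prefix; files are named
#'   `<prefix>_adjusted_weights.csv` and
#'   `<prefix>_response_anchor_<i>.csv`.
#' @param k Anchors per direction in the per-response-anchor tables.
#' @param low_response_threshold Passed to [adjusted_weight_sums()].
#' @param per_anchor Also write the per-response-anchor tables.
#' @return Character vector of the files written, invisibly.
#' @export
write_interpretation <- function(model, prefix, k = 5,
                                 low_response_threshold = 5.0,
                                 per_anchor = TRUE) {
  files <- character(0)
  f <- paste0(prefix, "_adjusted_weights.csv")
  utils::write.csv(adjusted_weight_sums(model, low_response_threshold), f,
                   row.names = FALSE)
  files <- c(files, f)
  if (per_anchor) {
    for (i in seq_len(ncol(model$model$W))) {
      fi <- paste0(prefix, "_response_anchor_", i, ".csv")
      utils::write.csv(top_anchor_weights(model, i, k), fi,
                       row.names = FALSE)
      files <- c(files, fi)
    }
  }
  invisible(files)
}
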