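# Anchor selection: response anchors by k-means in response space,
# structure anchors by random draw (vanilla TR) or adaptive accumulation.

#' Select response anchors by k-means clustering in response space
#'
#' Runs k-means (10 restarts) on the responses with `kr` clusters and picks,
#' for each cluster, the molecule closest to the cluster center; ties go to
#' the lexicographically smaller id. The selected anchors cover the response
#' range far better than a random draw of the same size.
#'
#' @param data A molecule table.
#' @param kr Number of response anchors; default 10.
#' @param seed Seed controlling the k-means restarts.
#' @return Character vector of `kr` molecule ids.
#' @export
select_response_anchors <- function(data, kr = 10, seed = 1) {
  check_molecule_table(data)
  n_distinct <- length(unique(data$response))
  if (kr > nrow(data) || kr > n_distinct) {
    rlang::abort(sprintf(
      "kr = %d exceeds the number of distinct samples (%d).", kr, n_distinct))
  }
  if (kr == nrow(data)) return(data$id[order(data$response, data$id)])
  km <- with_seed(sub_seed(seed, "kmeans"),
                  stats::kmeans(data$response, centers = kr, nstart = 10))
  ids <- character(kr)
  for (cl in seq_len(kr)) {
    members <- which(km$cluster == cl)
    d <- abs(data$response[members] - km$centers[cl])
    pick <- members[order(d, data$id[members])][1]
    ids[cl] <- data$id[pick]
  }
  ids[order(data$response[match(ids, data$id)])]
}

#' Randomly select initial structure anchors
#'
#' Uniform random subset of `ka` molecule ids, reproducible by seed. This is
#' the step-1 anchor set of adaptive selection.
#'
#' @param ids Candidate molecule ids.
#' @param ka Number of anchors to draw.
#' @param seed Seed.
#' @return Character vector of `ka` ids.
#' @export
select_initial_structure_anchors <- function(ids, ka, seed = 1) {
  if (ka > length(ids)) {
    rlang::abort(sprintf("ka = %d exceeds the number of samples (%d).",
                         ka, length(ids)))
  }
  with_seed(sub_seed(seed, "anchors"), sample(ids, ka))
}

#' Random anchor set for vanilla topological regression
#'
#' Vanilla TR uses one random draw of `round(fraction * N)` training
#' molecules as both structure and response anchors; the conventional
#' budget is 60% of the training samples.
#'
#' @param ids Training molecule ids.
#' @param fraction Anchor fraction of the training set; default 0.6.
#' @param seed Seed.
#' @return Character vector of anchor ids.
#' @export
select_tr_anchors <- function(ids, fraction = 0.6, seed = 1) {
  check_scalar_number(fraction, "fraction", lower = 0, upper = 1)
  select_initial_structure_anchors(ids, round(fraction * length(ids)), seed)
}

#' Early-stopping decision from a validation history
#'
#' Returns `TRUE` when the improvement (decrease) in validation NRMSE has
#' been below `min_delta` for `patience` consecutive steps.
#'
#' @param history Numeric vector of validation scores, one per step (lower
#'   is better).
#' @param min_delta Minimum improvement that counts as progress;
#'   default 0.006.
#' @param patience Number of consecutive stalled steps that triggers the
#'   stop; default 2.
#' @return Logical.
#' @export
early_stop_check <- function(history, min_delta = 0.006, patience = 2) {
  stopifnot(length(history) >= 1, patience >= 1)
  if (length(history) <= patience) return(FALSE)
  improvements <- -diff(history)
  recent <- utils::tail(improvements, patience)
  all(recent < min_delta)
}
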