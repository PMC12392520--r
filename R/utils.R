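# Internal helpers shared across modules.

# Derive a reproducible 32-bit sub-seed from a master seed and a label, so
# that independent components (splits, anchors, k-means, noise) consume
# independent random streams but remain fully determined by one user seed.
sub_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- 0
  for (ch in utf8ToInt(label)) h <- (h * 31 + ch) %% 2147483647
  as.integer((abs(seed) * 2654435 + h) %% 2147483647)
}

# Evaluate `expr` under a local RNG state seeded by `seed`; the caller's RNG
# state is untouched.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

check_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) ||
      x < lower || x > upper) {
    rlang::abort(sprintf("`%s` must be a single finite number in [%s, %s].",
                         name, format(lower), format(upper)))
  }
  invisible(x)
}

check_molecule_table <- function(data, need_fingerprints = FALSE) {
  if (!is.data.frame(data)) {
    rlang::abort("`data` must be a data frame (see `read_molecule_table()`).")
  }
  miss <- setdiff(c("id", "response"), names(data))
  if (length(miss) > 0) {
    rlang::abort(paste0("`data` is missing required column(s): ",
                        paste(miss, collapse = ", "), "."))
  }
  if (anyDuplicated(data$id)) {
    rlang::abort("molecule ids must be unique (duplicates would leak drugs across folds).")
  }
  if (!all(is.finite(data$response))) {
    rlang::abort("all responses must be finite.")
  }
  if (need_fingerprints && !("fingerprint" %in% names(data))) {
    rlang::abort("`data` needs a `fingerprint` list-column; see `add_fingerprints()` or `make_synthetic_qsar()`.")
  }
  invisible(data)
}

# Stack a fingerprint list-column into an integer matrix with id rownames.
fp_matrix <- function(data) {
  check_molecule_table(data, need_fingerprints = TRUE)
  m <- do.call(rbind, lapply(data$fingerprint, as.integer))
  rownames(m) <- data$id
  m
}

fp_kind_of <- function(data) {
  k <- attr(data, "fp_kind", exact = TRUE)
  if (is.null(k) && "fingerprint" %in% names(data) && nrow(data) > 0) {
    k <- attr(data$fingerprint[[1]], "kind", exact = TRUE)
  }
  k %||% "binary"
}
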