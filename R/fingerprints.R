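# Molecular fingerprints.
#
# Both encodings are computed from the OpenBabel *canonical* SMILES so that
# equivalent notations of the same molecule are bit-identical:
#   * "ecfp4"  — circular (Morgan-style) substructure fingerprint, radius 2,
#                hashed into a fixed-length 0/1 bit vector;
#   * "mhfp6"  — min-hash fingerprint over the radius-3 circular substructure
#                shingle set; each position holds the minimum of a distinct
#                universal hash over the shingles, so the fraction of
#                positions at which two fingerprints differ estimates the
#                Jaccard distance of the underlying shingle sets.

MOD_PRIME <- 2147483647   # 2^31 - 1; all hash arithmetic stays exact in doubles
SHINGLE_MOD <- 67108859   # prime < 2^26 so a*s + b < 2^53

# Deterministic string hash into [0, MOD_PRIME).
str_hash <- function(s) {
  h <- 0
  for (ch in utf8ToInt(s)) h <- (h * 131 + ch) %% MOD_PRIME
  h
}

.fp_env <- new.env(parent = emptyenv())

# Fixed universal-hash coefficients for min-hashing (internal constant seed:
# the permutations are part of the fingerprint definition, not user RNG).
minhash_coefs <- function(n_perm) {
  key <- paste0("mh", n_perm)
  if (is.null(.fp_env[[key]])) {
    .fp_env[[key]] <- with_seed(1299709, list(
      a = sample.int(2^25 - 1, n_perm, replace = TRUE),
      b = sample.int(MOD_PRIME, n_perm, replace = TRUE) - 1
    ))
  }
  .fp_env[[key]]
}

# Scramble a shingle hash across the full modulus before the per-position
# affine hash; without this, affine maps on small shingle values are far
# from min-wise independent and the mismatch fraction is biased.
mix_hash <- function(s) {
  x <- (s * 2654435761) %% MOD_PRIME
  ((x * 40503 + 1013904223) %% MOD_PRIME) %% SHINGLE_MOD
}

# Min-hash a set of integer shingle hashes into an n_perm-long signature.
minhash_signature <- function(shingles, n_perm) {
  co <- minhash_coefs(n_perm)
  s <- mix_hash(unique(as.numeric(shingles)))
  sig <- integer(n_perm)
  for (j in seq_len(n_perm)) {
    sig[j] <- as.integer(min((co$a[j] * s + co$b[j]) %% MOD_PRIME))
  }
  sig
}

# Parse a canonical SMILES into a simple molecular graph:
# elements, bond list (i, j, order).
smiles_graph <- function(canonical_smiles) {
  sdf <- suppressWarnings(ChemmineR::smiles2sdf(canonical_smiles))[[1]]
  ab <- ChemmineR::atomblock(sdf)
  bb <- ChemmineR::bondblock(sdf)
  elements <- sub("_.*$", "", rownames(ab))
  n <- length(elements)
  bonds <- if (is.null(dim(bb)) || nrow(bb) == 0) {
    matrix(numeric(0), ncol = 3)
  } else {
    cbind(bb[, 1], bb[, 2], bb[, 3])
  }
  list(elements = elements, n = n, bonds = bonds)
}

# Iterated circular atom invariants (Morgan algorithm): a list with one
# integer vector of per-atom identifiers per radius 0..radius.
circular_invariants <- function(graph, radius) {
  n <- graph$n
  nbr <- vector("list", n)
  if (nrow(graph$bonds) > 0) {
    for (b in seq_len(nrow(graph$bonds))) {
      i <- graph$bonds[b, 1]; j <- graph$bonds[b, 2]; o <- graph$bonds[b, 3]
      nbr[[i]] <- rbind(nbr[[i]], c(j, o))
      nbr[[j]] <- rbind(nbr[[j]], c(i, o))
    }
  }
  degree <- vapply(nbr, function(x) if (is.null(x)) 0L else nrow(x), integer(1))
  ordsum <- vapply(nbr, function(x) if (is.null(x)) 0 else sum(x[, 2]), numeric(1))
  inv <- vapply(seq_len(n), function(i) {
    str_hash(paste("A", graph$elements[i], degree[i], ordsum[i], sep = "|"))
  }, numeric(1))
  out <- list(inv)
  if (radius >= 1) {
    for (r in seq_len(radius)) {
      inv <- vapply(seq_len(n), function(i) {
        if (is.null(nbr[[i]])) return((inv[i] * 7 + r) %% MOD_PRIME)
        parts <- paste(nbr[[i]][, 2], inv[nbr[[i]][, 1]], sep = ":")
        str_hash(paste("R", r, inv[i], paste(sort(parts), collapse = ","),
                       sep = "|"))
      }, numeric(1))
      out[[r + 1]] <- inv
    }
  }
  out
}

#' Compute a molecular fingerprint from a SMILES string
#'
#' Deterministic structure encodings for distance-based QSAR modeling:
#' `"ecfp4"` is a circular substructure bit vector (radius 2), `"mhfp6"` a
#' min-hash signature over radius-3 circular substructure shingles. Both are
#' computed from the canonical SMILES, so any valid notation of the same
#' molecule yields an identical fingerprint.
#'
#' @param smiles A single SMILES string.
#' @param kind `"ecfp4"` or `"mhfp6"`.
#' @param length Fingerprint length (number of bits / permutations);
#'   default 2048.
#' @return An integer vector of the requested length with attribute `kind`;
#'   values are 0/1 for `"ecfp4"` and hash values for `"mhfp6"`.
#' @examples
#' \donttest{
#' fp <- compute_fingerprint("CCO", "ecfp4")
#' sum(fp)   # number of set bits
#' }
#' @export
compute_fingerprint <- function(smiles, kind = c("ecfp4", "mhfp6"),
                                length = 2048L) {
  kind <- match.arg(kind)
  check_scalar_number(length, "length", lower = 1)
  can <- canonicalize_smiles(smiles)
  if (!nzchar(can)) {
    rlang::abort(sprintf("cannot parse SMILES string: \"%s\"", smiles))
  }
  graph <- smiles_graph(can)
  radius <- if (kind == "ecfp4") 2L else 3L
  invs <- circular_invariants(graph, radius)
  features <- unique(unlist(invs))
  fp <- if (kind == "ecfp4") {
    bits <- integer(length)
    bits[(features %% length) + 1] <- 1L
    bits
  } else {
    minhash_signature(features, length)
  }
  attr(fp, "kind") <- kind
  fp
}

#' Attach fingerprints to a molecule table
#'
#' Adds a `fingerprint` list-column (one integer vector per molecule) to a
#' table read with [read_molecule_table()].
#'
#' @param data A molecule table with a `smiles` column.
#' @param kind,length Passed to [compute_fingerprint()].
#' @return `data` with a `fingerprint` list-column and an `fp_kind`
#'   attribute.
#' @export
add_fingerprints <- function(data, kind = c("ecfp4", "mhfp6"),
                             length = 2048L) {
  kind <- match.arg(kind)
  check_molecule_table(data)
  if (!("smiles" %in% names(data))) {
    rlang::abort("`data` needs a `smiles` column to compute fingerprints.")
  }
  data$fingerprint <- lapply(data$smiles, compute_fingerprint,
                             kind = kind, length = length)
  attr(data, "fp_kind") <- kind
  data
}
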