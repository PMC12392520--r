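#' Read a molecule table from delimited text
#'
#' Reads a CSV/TSV file with molecule identifiers, SMILES strings and a
#' scalar response (e.g. a GI50 concentration or an NLOGGI50 potency).
#' Rows whose SMILES cannot be parsed are dropped, not fatal: the number of
#' exclusions is reported via a message and the excluded ids are attached as
#' the `"excluded"` attribute of the result.
#'
#' @param path Path to a delimited text file with a header.
#' @param response_transform Either `"none"` (use responses as given) or
#'   `"nloggi50"` (responses are GI50 concentrations in molar units and are
#'   transformed with [nloggi50()]).
#' @param id_col,smiles_col,response_col Column names in the file.
#' @param sep Field separator; `","` by default, use `"\t"` for TSV.
#'
#' @return A tibble with columns `id`, `smiles`, `response` (one row per
#'   molecule with a valid SMILES). Attributes: `excluded` (character vector
#'   of dropped ids).
#' @seealso [add_fingerprints()] to attach fingerprints for modeling.
#' @export
read_molecule_table <- function(path,
                                response_transform = c("none", "nloggi50"),
                                id_col = "id", smiles_col = "smiles",
                                response_col = "response", sep = ",") {
  response_transform <- match.arg(response_transform)
  raw <- utils::read.csv(path, sep = sep, stringsAsFactors = FALSE,
                         check.names = FALSE)
  miss <- setdiff(c(id_col, smiles_col, response_col), names(raw))
  if (length(miss) > 0) {
    rlang::abort(sprintf("input file %s is missing column(s): %s",
                         path, paste(miss, collapse = ", ")))
  }
  tbl <- tibble::tibble(
    id = as.character(raw[[id_col]]),
    smiles = as.character(raw[[smiles_col]]),
    response = as.numeric(raw[[response_col]])
  )
  canon <- vapply(tbl$smiles, canonicalize_smiles, character(1))
  bad <- !nzchar(canon) | !is.finite(tbl$response)
  if (all(bad)) {
    rlang::abort(sprintf("no valid molecules in %s (all %d rows excluded).",
                         path, nrow(tbl)))
  }
  excluded <- tbl$id[bad]
  if (length(excluded) > 0) {
    rlang::inform(sprintf(
      "read_molecule_table: excluded %d molecule(s) without a valid SMILES or finite response: %s",
      length(excluded), paste(excluded, collapse = ", ")))
  }
  tbl <- tbl[!bad, , drop = FALSE]
  tbl$smiles <- unname(canon[!bad])
  if (response_transform == "nloggi50") {
    tbl$response <- nloggi50(tbl$response)
  }
  if (anyDuplicated(tbl$id)) {
    rlang::abort("molecule ids must be unique.")
  }
  attr(tbl, "excluded") <- excluded
  tbl
}

#' Negative log10 transform of GI50 concentrations
#'
#' `NLOGGI50 = -log10(GI50)` with GI50 in molar units; higher values mean
#' stronger growth inhibition.
#'
#' @param gi50 Numeric vector of positive concentrations (molar).
#' @return `-log10(gi50)`.
#' @examples
#' nloggi50(1e-6) # 6
#' @export
nloggi50 <- function(gi50) {
  if (!is.numeric(gi50) || any(!is.finite(gi50)) || any(gi50 <= 0)) {
    rlang::abort("`gi50` must be positive and finite (molar concentration).")
  }
  -log10(gi50)
}

#' Canonicalize a SMILES string
#'
#' Returns the OpenBabel canonical SMILES, or `""` if the string cannot be
#' parsed. Fingerprints are always computed from the canonical form so that
#' equivalent notations (e.g. aromatic vs Kekule benzene) encode identically.
#'
#' @param smiles A single SMILES string.
#' @return The canonical SMILES, or `""` for unparseable input.
#' @export
canonicalize_smiles <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) == 1L)
  if (!nzchar(trimws(smiles))) return("")
  out <- tryCatch(
    ChemmineOB::convertFormat("SMI", "CAN", source = smiles),
    error = function(e) ""
  )
  # OpenBabel appends a tab/newline; the canonical string is the first token.
  out <- strsplit(trimws(out), "[ \t\n]")[[1]]
  if (length(out) == 0) "" else out[[1]]
}
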