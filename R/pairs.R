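#' Canonically ordered protein pairs
#'
#' Builds a tibble of unordered protein pairs in canonical (lexicographic)
#' order, so that `pair_keys(x, y)` and `pair_keys(y, x)` yield identical
#' rows. All pair-valued tables in the package use this representation.
#'
#' @param protein_a,protein_b Character vectors of protein identifiers
#'   (recycled to a common length).
#' @return A tibble with columns `protein_a` and `protein_b`,
#'   `protein_a < protein_b` in every row.
#' @examples
#' pair_keys(c("DVU1951", "DVU0001"), c("DVU1950", "DVU0002"))
#' @export
pair_keys <- function(protein_a, protein_b) {
  n <- max(length(protein_a), length(protein_b))
  protein_a <- rep_len(as.character(protein_a), n)
  protein_b <- rep_len(as.character(protein_b), n)
  if (any(protein_a == protein_b)) {
    stop("self-pairs are not allowed: ",
         paste(unique(protein_a[protein_a == protein_b]), collapse = ", "))
  }
  lo <- pmin(protein_a, protein_b)
  hi <- pmax(protein_a, protein_b)
  tibble(protein_a = lo, protein_b = hi)
}

#' Coerce a data frame to a canonical pair set
#'
#' Keeps the `protein_a`/`protein_b` columns, canonicalizes the ordering
#' within each pair and drops duplicates. Used to ingest interactome and
#' gold-standard pair lists before any set algebra.
#'
#' @param x A data frame with `protein_a` and `protein_b` columns (extra
#'   columns are dropped).
#' @param name Optional set label, stored as the `"pair_set_name"` attribute.
#' @return A deduplicated tibble of canonical pairs.
#' @export
as_pair_set <- function(x, name = NULL) {
  stopifnot(all(c("protein_a", "protein_b") %in% names(x)))
  out <- distinct(pair_keys(x$protein_a, x$protein_b))
  if (!is.null(name)) attr(out, "pair_set_name") <- name
  out
}

.pair_set_name <- function(x, default = "pairs") {
  attr(x, "pair_set_name") %||% default
}

`%||%` <- function(a, b) if (is.null(a)) b else a
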