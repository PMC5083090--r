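#' Assemble and validate an elution dataset
#'
#' An elution dataset bundles everything the downstream feature and
#' classification steps need: per-multiplex relative iTRAQ abundances of each
#' protein across chromatographic fractions, the multiplex design (which
#' fractions belong to which multiplex, in which separation dimension), the
#' per-protein per-multiplex unique-peptide counts, and protein annotations
#' (operon membership, functional role, exclusion flag).
#'
#' @param abundance Tibble with columns `protein_id`, `multiplex_id`,
#'   `fraction_id`, `abundance` and optionally `peptides` (constant within a
#'   protein x multiplex; split out into the `peptides` table).
#' @param design Tibble with columns `multiplex_id`, `dimension`
#'   (`"SEC"` or `"HIC"`), `fraction_id`, `is_joint` (0/1), one row per
#'   fraction of each multiplex, ordered by elution position.
#' @param proteins Optional annotation tibble with columns `protein_id`,
#'   `operon_id`, `tigr_role`, `excluded`. Missing proteins observed in
#'   `abundance` are added with empty annotations.
#' @param peptides Optional tibble `protein_id`, `multiplex_id`, `peptides`;
#'   required (here or as an `abundance` column) for every detection.
#' @return An object of class `elution_dataset`: a list of the four validated
#'   tibbles plus a `normalized` flag.
#' @seealso [read_elution_tables()], [normalize_apex()], [filter_exclusions()]
#' @export
elution_dataset <- function(abundance, design, proteins = NULL, peptides = NULL) {
  abundance <- as_tibble(abundance)
  design <- as_tibble(design)

  need_ab <- c("protein_id", "multiplex_id", "fraction_id", "abundance")
  if (!all(need_ab %in% names(abundance))) {
    stop("abundance table must have columns: ", paste(need_ab, collapse = ", "))
  }
  need_de <- c("multiplex_id", "dimension", "fraction_id", "is_joint")
  if (!all(need_de %in% names(design))) {
    stop("design table must have columns: ", paste(need_de, collapse = ", "))
  }
  if (!all(design$dimension %in% c("SEC", "HIC"))) {
    stop("design dimension must be 'SEC' or 'HIC'")
  }

  if (is.null(peptides) && "peptides" %in% names(abundance)) {
    peptides <- distinct(abundance, .data$protein_id, .data$multiplex_id,
                         .data$peptides)
  }
  abundance <- abundance[intersect(names(abundance),
                                   c(need_ab, "raw"))]

  bad <- which(is.na(abundance$abundance) | abundance$abundance < 0)
  if (length(bad) > 0) {
    stop("abundance must be a non-negative number; offending row(s): ",
         paste(head(bad, 5), collapse = ", "))
  }

  # every abundance row must reference a declared (multiplex, fraction)
  key_ab <- paste(abundance$multiplex_id, abundance$fraction_id)
  key_de <- paste(design$multiplex_id, design$fraction_id)
  dangling <- which(!key_ab %in% key_de)
  if (length(dangling) > 0) {
    stop("abundance row(s) reference undeclared multiplex/fraction: row ",
         paste(head(dangling, 5), collapse = ", "),
         " (e.g. ", key_ab[dangling[1]], ")")
  }
  dup <- duplicated(paste(abundance$protein_id, key_ab))
  if (any(dup)) {
    stop("duplicated abundance record(s), e.g. row ", which(dup)[1])
  }

  sizes <- count(distinct(design, .data$multiplex_id, .data$fraction_id),
                 .data$multiplex_id)
  if (any(sizes$n < 2 | sizes$n > 8)) {
    stop("each multiplex must pool 2-8 fractions (isobaric label limit); ",
         "offending: ",
         paste(sizes$multiplex_id[sizes$n < 2 | sizes$n > 8], collapse = ", "))
  }
  ndim <- count(distinct(design, .data$multiplex_id, .data$dimension),
                .data$multiplex_id)
  if (any(ndim$n != 1)) {
    stop("a multiplex must belong to exactly one dimension: ",
         paste(ndim$multiplex_id[ndim$n != 1], collapse = ", "))
  }

  obs <- distinct(abundance, .data$protein_id, .data$multiplex_id)
  if (is.null(peptides)) {
    stop("peptide counts are required for every (protein, multiplex) detection")
  }
  peptides <- as_tibble(peptides)[c("protein_id", "multiplex_id", "peptides")]
  missing_pep <- anti_join(obs, peptides, by = c("protein_id", "multiplex_id"))
  if (nrow(missing_pep) > 0) {
    stop("missing peptide count for ", nrow(missing_pep),
         " detection(s), e.g. ", missing_pep$protein_id[1], " in ",
         missing_pep$multiplex_id[1])
  }
  if (any(is.na(peptides$peptides) | peptides$peptides < 1)) {
    stop("peptide counts must be >= 1 for every detection")
  }
  peptides <- semi_join(peptides, obs, by = c("protein_id", "multiplex_id")) |>
    arrange(.data$protein_id, .data$multiplex_id)

  if (is.null(proteins)) {
    proteins <- tibble(protein_id = sort(unique(abundance$protein_id)))
  }
  proteins <- as_tibble(proteins)
  if (!"protein_id" %in% names(proteins)) stop("proteins table needs protein_id")
  if (anyDuplicated(proteins$protein_id)) {
    stop("protein_id must be unique in the annotation table")
  }
  for (col in c("operon_id", "tigr_role")) {
    if (!col %in% names(proteins)) proteins[[col]] <- NA_character_
    proteins[[col]] <- as.character(proteins[[col]])
  }
  if (!"excluded" %in% names(proteins)) proteins$excluded <- FALSE
  proteins$excluded <- as.logical(proteins$excluded)
  unknown <- setdiff(abundance$protein_id, proteins$protein_id)
  if (length(unknown) > 0) {
    proteins <- bind_rows(proteins,
                          tibble(protein_id = sort(unknown), excluded = FALSE))
  }

  structure(
    list(
      proteins = proteins,
      design = design,
      abundance = abundance,
      peptides = peptides,
      normalized = FALSE
    ),
    class = "elution_dataset"
  )
}

#' @export
print.elution_dataset <- function(x, ...) {
  ndim <- count(distinct(x$design, .data$multiplex_id, .data$dimension),
                .data$dimension)
  cat("<elution_dataset>\n")
  cat("  proteins:   ", nrow(x$proteins),
      " (", sum(x$proteins$excluded), " flagged for exclusion)\n", sep = "")
  cat("  multiplexes: ", sum(ndim$n), " (",
      paste0(ndim$dimension, "=", ndim$n, collapse = ", "), ")\n", sep = "")
  cat("  detections: ", nrow(x$peptides), "\n", sep = "")
  cat("  normalized: ", x$normalized, "\n", sep = "")
  invisible(x)
}

#' Read an elution dataset from TSV tables
#'
#' Ingests the three tab-separated tables of the exchange format: a long
#' abundance table (`protein_id`, `multiplex_id`, `fraction_id`, `abundance`,
#' `peptides`), a multiplex design table (`multiplex_id`, `dimension`,
#' `fraction_id`, `is_joint`) and an optional protein annotation table
#' (`protein_id`, `operon_id`, `tigr_role`, `excluded`). Rows referencing
#' undeclared multiplexes or fractions are rejected with an error naming the
#' offending row.
#'
#' @param abundance_path,design_path,annotation_path File paths; the
#'   annotation path may be `NULL`.
#' @return A validated [elution_dataset()].
#' @export
read_elution_tables <- function(abundance_path, design_path,
                                annotation_path = NULL) {
  abundance <- .read_tsv_checked(
    abundance_path,
    c("protein_id", "multiplex_id", "fraction_id", "abundance"))
  design <- .read_tsv_checked(
    design_path, c("multiplex_id", "dimension", "fraction_id", "is_joint"))
  proteins <- NULL
  if (!is.null(annotation_path)) {
    proteins <- .read_tsv_checked(annotation_path, "protein_id")
  }
  elution_dataset(abundance, design, proteins)
}

.read_tsv_checked <- function(path, required) {
  if (!file.exists(path)) stop("file not found: ", path)
  out <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  probs <- readr::problems(out)
  if (nrow(probs) > 0) {
    stop("malformed row in ", path, ": line ", probs$row[1] + 1L,
         " (", probs$expected[1], ")")
  }
  missing <- setdiff(required, names(out))
  if (length(missing) > 0) {
    stop(path, " is missing required column(s): ",
         paste(missing, collapse = ", "))
  }
  out
}

#' Write an elution dataset as TSV tables
#'
#' Inverse of [read_elution_tables()]; numeric columns round-trip exactly.
#'
#' @param dataset An [elution_dataset()].
#' @param dir Output directory (created if needed).
#' @param prefix Filename prefix.
#' @return Invisibly, the named vector of file paths written.
#' @export
write_elution_tables <- function(dataset, dir, prefix = "elution") {
  stopifnot(inherits(dataset, "elution_dataset"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(
    abundance = file.path(dir, paste0(prefix, "-abundance.tsv")),
    design = file.path(dir, paste0(prefix, "-design.tsv")),
    annotation = file.path(dir, paste0(prefix, "-annotation.tsv"))
  )
  ab <- left_join(dataset$abundance, dataset$peptides,
                  by = c("protein_id", "multiplex_id"))
  readr::write_tsv(ab, paths["abundance"], progress = FALSE)
  readr::write_tsv(dataset$design, paths["design"], progress = FALSE)
  readr::write_tsv(dataset$proteins, paths["annotation"], progress = FALSE)
  invisible(paths)
}

#' Read or write a pair list
#'
#' Pair lists (gold standards, interactomes, benchmark sets) are TSV files
#' with columns `protein_a`, `protein_b` and optionally `label`. Pairs are
#' canonicalized on input.
#'
#' @param path File path.
#' @return `read_pair_list()` returns a tibble of canonical pairs (plus
#'   `label` when present).
#' @export
read_pair_list <- function(path) {
  raw <- .read_tsv_checked(path, c("protein_a", "protein_b"))
  out <- pair_keys(raw$protein_a, raw$protein_b)
  if ("label" %in% names(raw)) out$label <- raw$label
  distinct(out)
}

#' @rdname read_pair_list
#' @param pairs A pair tibble.
#' @export
write_pair_list <- function(pairs, path) {
  readr::write_tsv(as_tibble(pairs), path, progress = FALSE)
  invisible(path)
}

#' Read a genome-context score table
#'
#' STRING-style per-pair genome-context subscores (gene neighborhood, gene
#' co-occurrence across genomes, gene fusion), rescaled to `[0, 1]`. Pairs
#' absent from the table default to 0 everywhere downstream.
#'
#' @param path TSV with columns `protein_a`, `protein_b`, `neighborhood`,
#'   `cooccurrence`, `fusion`.
#' @return A canonical-pair tibble with the three score columns.
#' @export
read_context_table <- function(path) {
  raw <- .read_tsv_checked(
    path, c("protein_a", "protein_b", "neighborhood", "cooccurrence", "fusion"))
  scores <- raw[c("neighborhood", "cooccurrence", "fusion")]
  if (any(vapply(scores, function(x) any(x < 0 | x > 1), logical(1)))) {
    stop("genome-context scores must lie in [0, 1]")
  }
  bind_cols(pair_keys(raw$protein_a, raw$protein_b), scores)
}

#' Apex-normalize iTRAQ relative abundances
#'
#' Within each (protein, multiplex) profile the fraction with the highest
#' relative abundance (the apex) is assigned the value 1 and all other
#' fractions are rescaled against it, making elution shapes comparable across
#' multiplexes with different loadings. Ties at the maximum all become 1.
#' The pre-normalization values are retained in a `raw` column; eligibility
#' screens for correlation scoring are applied to these raw intensities.
#' Profiles that are zero everywhere cannot be normalized and are dropped
#' with a warning.
#'
#' @param dataset An [elution_dataset()].
#' @return The dataset with normalized abundances (`normalized = TRUE`).
#'   The operation is idempotent.
#' @export
normalize_apex <- function(dataset) {
  stopifnot(inherits(dataset, "elution_dataset"))
  ab <- dataset$abundance
  if (!"raw" %in% names(ab)) ab$raw <- ab$abundance

  mx <- ab |>
    group_by(.data$protein_id, .data$multiplex_id) |>
    summarise(.apex = max(.data$abundance), .groups = "drop")
  zero <- filter(mx, .data$.apex <= 0)
  if (nrow(zero) > 0) {
    warning("dropping ", nrow(zero),
            " all-zero (protein, multiplex) profile(s), e.g. ",
            zero$protein_id[1], " in ", zero$multiplex_id[1])
    ab <- anti_join(ab, zero, by = c("protein_id", "multiplex_id"))
  }
  ab <- ab |>
    inner_join(filter(mx, .data$.apex > 0),
               by = c("protein_id", "multiplex_id")) |>
    mutate(abundance = .data$abundance / .data$.apex) |>
    select(-".apex")

  dataset$abundance <- ab
  dataset$peptides <- semi_join(
    dataset$peptides, distinct(ab, .data$protein_id, .data$multiplex_id),
    by = c("protein_id", "multiplex_id"))
  dataset$normalized <- TRUE
  dataset
}

#' Default exclusion rules
#'
#' The copurification analysis removes ribosomal proteins (the ribosome's RNA
#' scaffold makes it atypical) and the four most abundant chaperonins, all of
#' which co-elute promiscuously and inflate false positives. The defaults
#' target the Desulfovibrio vulgaris annotations; other organisms can supply
#' their own list.
#'
#' @return A list with `role_pattern` (regex matched case-insensitively
#'   against `tigr_role`) and `protein_ids` (explicit identifiers).
#' @export
default_exclusions <- function() {
  list(
    role_pattern = "ribosom",
    protein_ids = c("DVU0811", "DVU0812", "DVU1976", "DVU1977")
  )
}

#' Resolve an exclusion list against a dataset
#'
#' @param dataset An [elution_dataset()].
#' @param rules A list like [default_exclusions()].
#' @return Character vector of protein ids present in the dataset that match
#'   the rules or carry the `excluded` annotation flag.
#' @export
exclusion_list <- function(dataset, rules = default_exclusions()) {
  pr <- dataset$proteins
  hit <- pr$excluded |
    pr$protein_id %in% rules$protein_ids |
    (!is.na(pr$tigr_role) &
       grepl(rules$role_pattern, pr$tigr_role, ignore.case = TRUE))
  pr$protein_id[hit]
}

#' Remove excluded proteins from a dataset
#'
#' Drops the listed proteins from every table so they contribute to no
#' downstream pair, feature or count. Listed proteins absent from the dataset
#' are ignored.
#'
#' @param dataset An [elution_dataset()].
#' @param exclusions Character vector of protein ids; defaults to the
#'   dataset's `excluded` annotation flag combined with
#'   [default_exclusions()].
#' @return The filtered dataset.
#' @export
filter_exclusions <- function(dataset, exclusions = NULL) {
  stopifnot(inherits(dataset, "elution_dataset"))
  if (is.null(exclusions)) exclusions <- exclusion_list(dataset)
  dataset$proteins <- filter(dataset$proteins,
                             !.data$protein_id %in% exclusions)
  dataset$abundance <- filter(dataset$abundance,
                              !.data$protein_id %in% exclusions)
  dataset$peptides <- filter(dataset$peptides,
                             !.data$protein_id %in% exclusions)
  dataset
}

#' Detections: which proteins appear in which multiplexes
#'
#' A protein counts as detected in a multiplex if it has at least one
#' abundance record there (confidence filtering is assumed applied upstream
#' by the search engine).
#'
#' @param dataset An [elution_dataset()].
#' @return Tibble `protein_id`, `multiplex_id`, one row per detection.
#' @export
detections <- function(dataset) {
  distinct(dataset$abundance, .data$protein_id, .data$multiplex_id)
}

#' Co-occurring protein pairs
#'
#' Every unordered pair of proteins detected together in at least one iTRAQ
#' multiplex (either dimension). Only co-occurring pairs can be scored by the
#' elution-profile features, so this set is the candidate universe for PPI
#' prediction.
#'
#' @param dataset An [elution_dataset()].
#' @return Canonical pair tibble.
#' @export
cooccurring_pairs <- function(dataset) {
  det <- detections(dataset)
  out <- inner_join(det, det, by = "multiplex_id",
                    relationship = "many-to-many") |>
    filter(.data$protein_id.x < .data$protein_id.y) |>
    distinct(protein_a = .data$protein_id.x, protein_b = .data$protein_id.y) |>
    arrange(.data$protein_a, .data$protein_b)
  out
}
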