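#' Per-multiplex Pearson co-elution correlation
#'
#' Computes the Pearson correlation (CC value) between the apex-normalized
#' elution profiles of two proteins over the fractions of one multiplex.
#' Fractions in which a protein was not detected contribute a relative
#' abundance of 0. A multiplex is only eligible for a pair if at least one of
#' the two proteins has raw iTRAQ intensity at or above `min_intensity` in at
#' least `min_fractions` of its fractions; ineligible multiplexes, pairs not
#' co-detected there, and constant profiles (Pearson undefined) return `NA`.
#'
#' @param dataset A normalized [elution_dataset()].
#' @param protein_a,protein_b Protein identifiers (vectorized).
#' @param multiplex_id Multiplex identifier (vectorized).
#' @param min_intensity,min_fractions Raw-intensity eligibility screen.
#' @return Numeric vector of CC values (or `NA` where undefined).
#' @export
multiplex_cc <- function(dataset, protein_a, protein_b, multiplex_id,
                         min_intensity = 0.01, min_fractions = 3) {
  tab <- pair_cc_table(dataset, min_intensity = min_intensity,
                       min_fractions = min_fractions, keep_na = TRUE)
  key <- pair_keys(protein_a, protein_b)
  req <- tibble(protein_a = key$protein_a, protein_b = key$protein_b,
                multiplex_id = rep_len(multiplex_id, nrow(key)))
  left_join(req, tab,
            by = c("protein_a", "protein_b", "multiplex_id"))$cc
}

#' All per-multiplex CC values of co-detected pairs
#'
#' Work-horse behind [multiplex_cc()], [max_cc()], [min_proteins()] and
#' [assemble_features()]: for every multiplex, the Pearson correlations
#' between normalized profiles of all pairs of proteins detected there.
#'
#' @inheritParams multiplex_cc
#' @param keep_na Keep rows whose CC is `NA` (ineligible multiplex or
#'   zero-variance profile)? Default drops them.
#' @return Tibble `protein_a`, `protein_b`, `multiplex_id`, `dimension`, `cc`.
#' @export
pair_cc_table <- function(dataset, min_intensity = 0.01, min_fractions = 3,
                          keep_na = FALSE) {
  stopifnot(inherits(dataset, "elution_dataset"))
  if (!dataset$normalized) {
    stop("dataset must be apex-normalized first (see normalize_apex())")
  }
  des <- distinct(dataset$design, .data$multiplex_id, .data$dimension)
  ab_by_m <- split(dataset$abundance, dataset$abundance$multiplex_id)
  frac_by_m <- split(dataset$design$fraction_id, dataset$design$multiplex_id)

  res <- purrr::map(names(ab_by_m), function(m) {
    ab <- ab_by_m[[m]]
    prot <- sort(unique(ab$protein_id))
    if (length(prot) < 2) return(NULL)
    frs <- unique(frac_by_m[[m]])
    i <- match(ab$fraction_id, frs)
    j <- match(ab$protein_id, prot)
    M <- matrix(0, nrow = length(frs), ncol = length(prot))
    M[cbind(i, j)] <- ab$abundance
    R <- matrix(0, nrow = length(frs), ncol = length(prot))
    R[cbind(i, j)] <- if ("raw" %in% names(ab)) ab$raw else ab$abundance

    elig <- colSums(R >= min_intensity) >= min_fractions
    C <- suppressWarnings(cor(M))
    idx <- which(upper.tri(C), arr.ind = TRUE)
    cc <- C[idx]
    # eligibility: at least one protein of the pair passes the raw screen
    cc[!(elig[idx[, 1]] | elig[idx[, 2]])] <- NA_real_
    tibble(
      protein_a = prot[idx[, 1]],
      protein_b = prot[idx[, 2]],
      multiplex_id = m,
      cc = cc
    )
  })
  out <- bind_rows(res)
  if (nrow(out) == 0) {
    out <- tibble(protein_a = character(), protein_b = character(),
                  multiplex_id = character(), cc = numeric())
  }
  out <- left_join(out, des, by = "multiplex_id") |>
    relocate("dimension", .after = "multiplex_id")
  if (!keep_na) out <- filter(out, !is.na(.data$cc))
  out
}

#' Maximal CC over one dimension (features 1 and 2)
#'
#' For each pair, the maximum per-multiplex CC value over all eligible
#' multiplexes of the given separation dimension. Pairs never co-detected in
#' an eligible multiplex of that dimension are assigned the sentinel -1,
#' the most unfavorable value on the correlation scale.
#'
#' @inheritParams multiplex_cc
#' @param pairs Pair tibble to score; defaults to all co-occurring pairs.
#' @param dimension `"SEC"` or `"HIC"`.
#' @return `pairs` with a `max_cc` column.
#' @export
max_cc <- function(dataset, dimension, pairs = NULL,
                   min_intensity = 0.01, min_fractions = 3) {
  dimension <- match.arg(dimension, c("SEC", "HIC"))
  if (is.null(pairs)) pairs <- cooccurring_pairs(dataset)
  tab <- pair_cc_table(dataset, min_intensity, min_fractions) |>
    filter(.data$dimension == .env$dimension)
  tab <- if (nrow(tab) == 0) {
    tibble(protein_a = character(), protein_b = character(),
           max_cc = numeric())
  } else {
    tab |>
      group_by(.data$protein_a, .data$protein_b) |>
      summarise(max_cc = max(.data$cc), .groups = "drop")
  }
  pairs |>
    left_join(tab, by = c("protein_a", "protein_b")) |>
    mutate(max_cc = ifelse(is.na(.data$max_cc), -1, .data$max_cc))
}

# observance count: number of multiplexes (both dimensions) a protein
# was detected in; joint fractions do not double-count because the
# multiplex, not the fraction, is the unit of observation
.observances <- function(dataset) {
  count(detections(dataset), .data$protein_id, name = "observances")
}

# grouped min of multiplex protein counts, safe on zero rows
.min_proteins_of <- function(df) {
  if (nrow(df) == 0) {
    return(tibble(protein_a = character(), protein_b = character(),
                  min_proteins = numeric()))
  }
  df |>
    group_by(.data$protein_a, .data$protein_b) |>
    summarise(min_proteins = min(.data$n_proteins), .groups = "drop")
}

#' Co-migration coefficient (feature 3)
#'
#' The number of multiplexes in which the two proteins were observed
#' together, divided by the sum of each protein's individual observances over
#' all multiplexes of both dimensions. The value lies in `[0, 0.5]` (half the
#' classic Dice coefficient; set `classic = TRUE` for the conventional
#' `2*together / (count_a + count_b)` scaling). Promiscuous "frequent
#' fliers" detected in many multiplexes score near 0 even when they happen
#' to correlate with something.
#'
#' @inheritParams max_cc
#' @param classic Multiply by 2 to obtain the classic Dice coefficient.
#' @return `pairs` with a `dice` column.
#' @export
dice_coefficient <- function(dataset, pairs = NULL, classic = FALSE) {
  if (is.null(pairs)) pairs <- cooccurring_pairs(dataset)
  det <- detections(dataset)
  obs <- .observances(dataset)
  together <- inner_join(det, det, by = "multiplex_id",
                         relationship = "many-to-many") |>
    filter(.data$protein_id.x < .data$protein_id.y) |>
    count(protein_a = .data$protein_id.x, protein_b = .data$protein_id.y,
          name = "together")
  out <- pairs |>
    left_join(together, by = c("protein_a", "protein_b")) |>
    left_join(obs, by = c(protein_a = "protein_id")) |>
    left_join(obs, by = c(protein_b = "protein_id"),
              suffix = c("_a", "_b"))
  if (any(is.na(out$observances_a) | is.na(out$observances_b))) {
    miss <- unique(c(out$protein_a[is.na(out$observances_a)],
                     out$protein_b[is.na(out$observances_b)]))
    stop("protein(s) with zero observances: ",
         paste(head(miss, 5), collapse = ", "))
  }
  out |>
    mutate(
      together = tidyr::replace_na(.data$together, 0L),
      dice = (if (classic) 2 else 1) * .data$together /
        (.data$observances_a + .data$observances_b)
    ) |>
    select(-"together", -"observances_a", -"observances_b")
}

#' Peptide-count ratio (feature 4)
#'
#' The unique-peptide count approximates protein abundance; members of a
#' stable complex should be near their maximal abundance where they co-elute
#' with their partners. For each protein and multiplex, the ratio of its
#' unique-peptide count there to its maximal count in any multiplex is
#' computed; a co-detected pair in a multiplex scores the smaller of the two
#' ratios, and the pair's feature is the maximum of that score over all
#' shared multiplexes. Pairs sharing no multiplex take the sentinel 0.
#'
#' @inheritParams max_cc
#' @return `pairs` with a `peptide_ratio` column.
#' @export
peptide_ratio <- function(dataset, pairs = NULL) {
  if (is.null(pairs)) pairs <- cooccurring_pairs(dataset)
  pep <- dataset$peptides |>
    group_by(.data$protein_id) |>
    mutate(ratio = .data$peptides / max(.data$peptides)) |>
    ungroup() |>
    select("protein_id", "multiplex_id", "ratio")
  shared <- inner_join(pep, pep, by = "multiplex_id",
                       relationship = "many-to-many") |>
    filter(.data$protein_id.x < .data$protein_id.y) |>
    group_by(protein_a = .data$protein_id.x,
             protein_b = .data$protein_id.y) |>
    summarise(peptide_ratio = max(pmin(.data$ratio.x, .data$ratio.y)),
              .groups = "drop")
  pairs |>
    left_join(shared, by = c("protein_a", "protein_b")) |>
    mutate(peptide_ratio = tidyr::replace_na(.data$peptide_ratio, 0))
}

#' Fraction-density score (feature 5)
#'
#' Crowded regions of fractionation space produce chance correlations. For
#' each pair, over the multiplexes where the pair co-elutes with CC at or
#' above `cc_threshold`, the score is the protein count of the emptiest such
#' multiplex. Pairs that never co-elute that tightly take the sentinel
#' (largest multiplex protein count) + 1, i.e. the worst possible density.
#'
#' @inheritParams max_cc
#' @param cc_threshold Tight co-elution cutoff on the per-multiplex CC.
#' @return `pairs` with a `min_proteins` column.
#' @export
min_proteins <- function(dataset, pairs = NULL, cc_threshold = 0.85,
                         min_intensity = 0.01, min_fractions = 3) {
  if (is.null(pairs)) pairs <- cooccurring_pairs(dataset)
  sizes <- count(detections(dataset), .data$multiplex_id, name = "n_proteins")
  sentinel <- max(sizes$n_proteins) + 1L
  qual <- pair_cc_table(dataset, min_intensity, min_fractions) |>
    filter(.data$cc >= cc_threshold) |>
    inner_join(sizes, by = "multiplex_id")
  qual <- .min_proteins_of(qual)
  pairs |>
    left_join(qual, by = c("protein_a", "protein_b")) |>
    mutate(min_proteins = ifelse(is.na(.data$min_proteins),
                                 sentinel, .data$min_proteins))
}

#' Assemble the eight-feature table for all co-occurring pairs
#'
#' Computes the five MS-derived features (maximal SEC and HIC CC values,
#' co-migration coefficient, peptide-count ratio, fraction-density score) for
#' every co-occurring pair and joins the three genome-context scores
#' (neighborhood, co-occurrence, fusion), defaulting to 0 for pairs absent
#' from the context table.
#'
#' @inheritParams min_proteins
#' @param context Optional genome-context tibble as from
#'   [read_context_table()].
#' @return Tibble with one row per co-occurring pair and columns
#'   `protein_a`, `protein_b`, `cc_sec`, `cc_hic`, `dice`, `peptide_ratio`,
#'   `min_proteins`, `string_neighborhood`, `string_cooccurrence`,
#'   `string_fusion`.
#' @export
assemble_features <- function(dataset, context = NULL, cc_threshold = 0.85,
                              min_intensity = 0.01, min_fractions = 3) {
  stopifnot(inherits(dataset, "elution_dataset"))
  pairs <- cooccurring_pairs(dataset)
  cc_tab <- pair_cc_table(dataset, min_intensity, min_fractions)
  sizes <- count(detections(dataset), .data$multiplex_id, name = "n_proteins")
  sentinel <- max(sizes$n_proteins) + 1L

  by_dim <- if (nrow(cc_tab) == 0) {
    tibble(protein_a = character(), protein_b = character())
  } else {
    cc_tab |>
      group_by(.data$protein_a, .data$protein_b, .data$dimension) |>
      summarise(max_cc = max(.data$cc), .groups = "drop") |>
      tidyr::pivot_wider(names_from = "dimension", values_from = "max_cc",
                         names_prefix = "cc_")
  }
  for (col in c("cc_SEC", "cc_HIC")) {
    if (!col %in% names(by_dim)) by_dim[[col]] <- NA_real_
  }

  dense <- cc_tab |>
    filter(.data$cc >= cc_threshold) |>
    inner_join(sizes, by = "multiplex_id") |>
    .min_proteins_of()

  out <- pairs |>
    left_join(by_dim, by = c("protein_a", "protein_b")) |>
    mutate(
      cc_sec = ifelse(is.na(.data$cc_SEC), -1, .data$cc_SEC),
      cc_hic = ifelse(is.na(.data$cc_HIC), -1, .data$cc_HIC)
    ) |>
    select(-"cc_SEC", -"cc_HIC")
  out <- dice_coefficient(dataset, out)
  out <- peptide_ratio(dataset, out)
  out <- out |>
    left_join(dense, by = c("protein_a", "protein_b")) |>
    mutate(min_proteins = ifelse(is.na(.data$min_proteins),
                                 sentinel, .data$min_proteins))

  if (is.null(context)) {
    context <- tibble(protein_a = character(), protein_b = character(),
                      neighborhood = numeric(), cooccurrence = numeric(),
                      fusion = numeric())
  }
  out |>
    left_join(context, by = c("protein_a", "protein_b")) |>
    mutate(
      string_neighborhood = tidyr::replace_na(.data$neighborhood, 0),
      string_cooccurrence = tidyr::replace_na(.data$cooccurrence, 0),
      string_fusion = tidyr::replace_na(.data$fusion, 0)
    ) |>
    select(-"neighborhood", -"cooccurrence", -"fusion")
}

#' Write a feature table
#'
#' @param features Tibble from [assemble_features()].
#' @param path Output TSV path.
#' @export
write_feature_table <- function(features, path) {
  readr::write_tsv(features, path, progress = FALSE)
  invisible(path)
}
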