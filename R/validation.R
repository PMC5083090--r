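#' PPI fold enrichment of a pair set
#'
#' Measures how strongly a set of putative interactions co-purifies in the
#' co-fractionation data. The numerator is the fraction of the query set's
#' pairs, among those with both members detected, that co-occur with CC
#' values at or above `cc_threshold` in both the SEC and the HIC dimension.
#' That fraction is normalized by the same fraction computed over all pairs
#' of detected proteins, irrespective of any interaction evidence, which
#' removes differences in detection rates between sets. The full
#' detected-pair universe therefore has fold enrichment exactly 1; sets of
#' genuine complex members score well above it.
#'
#' @param query Pair tibble (the interactome or benchmark set to audit).
#' @param features Feature tibble from [assemble_features()] (supplies the
#'   per-pair maximal CC values).
#' @param detected Character vector of detected protein ids.
#' @param cc_threshold Tight co-elution cutoff (default 0.85).
#' @return One-row tibble: `set_name`, `n_detected_pairs`, `n_high_cc`,
#'   `frac_high_cc`, `reference_frac`, `fold_enrichment`. The fold
#'   enrichment is `NA` (not estimable) when the reference fraction is 0.
#' @export
ppi_fold_enrichment <- function(query, features, detected,
                                cc_threshold = 0.85) {
  query <- as_pair_set(query)
  name <- .pair_set_name(query, "query")
  in_univ <- query$protein_a %in% detected & query$protein_b %in% detected
  n_pairs <- sum(in_univ)

  hi <- features |>
    filter(.data$cc_sec >= cc_threshold, .data$cc_hic >= cc_threshold)
  n_hi_all <- nrow(hi)
  n_detected <- length(unique(detected))
  n_univ <- choose(n_detected, 2)
  reference_frac <- if (n_univ > 0) n_hi_all / n_univ else 0

  n_hi_query <- nrow(semi_join(hi, query[in_univ, ],
                               by = c("protein_a", "protein_b")))
  frac <- if (n_pairs > 0) n_hi_query / n_pairs else NA_real_
  tibble(
    set_name = name,
    n_detected_pairs = n_pairs,
    n_high_cc = n_hi_query,
    frac_high_cc = frac,
    reference_frac = reference_frac,
    fold_enrichment = if (reference_frac > 0) frac / reference_frac
                      else NA_real_
  )
}

#' False-negative rate from recovered gold positives
#'
#' The fraction of eligible known interactions (both members detected by the
#' assay) that the screen failed to recover: `100 * (1 - recovered /
#' eligible)` percent.
#'
#' @param recovered Number of eligible gold positives present in the
#'   screen's prediction set.
#' @param eligible Number of gold positives with both members detected.
#' @return FNR in percent.
#' @export
estimate_fnr <- function(recovered, eligible) {
  stopifnot(length(recovered) == 1, length(eligible) == 1)
  if (eligible <= 0) stop("eligible count must be positive")
  if (recovered < 0 || recovered > eligible) {
    stop("recovered must lie in [0, eligible]")
  }
  100 * (1 - recovered / eligible)
}

#' Overlap accounting between two interactomes
#'
#' Full union/intersection bookkeeping for two pair sets, plus the
#' conditional overlap fractions restricted to pairs whose both members were
#' detected by the other assay -- the quantity whose complement approximates
#' the other assay's false-negative rate.
#'
#' @param a,b Pair tibbles (order defines `only_a` / `only_b`).
#' @param detected_in_a,detected_in_b Optional character vectors of proteins
#'   detected by each assay; needed for the conditional fractions.
#' @return One-row tibble with `n_a`, `n_b`, `n_shared`, `union_size`,
#'   `only_a`, `only_b` and, when detection lists are given,
#'   `n_a_detectable_in_b`, `frac_a_found_in_b`, `pct_a_not_in_b` (and the
#'   symmetric columns).
#' @export
overlap_report <- function(a, b, detected_in_a = NULL, detected_in_b = NULL) {
  a <- as_pair_set(a)
  b <- as_pair_set(b)
  if (nrow(a) == 0 || nrow(b) == 0) stop("pair sets must be nonempty")
  shared <- inner_join(a, b, by = c("protein_a", "protein_b"))
  out <- tibble(
    n_a = nrow(a), n_b = nrow(b), n_shared = nrow(shared),
    union_size = nrow(a) + nrow(b) - nrow(shared),
    only_a = nrow(a) - nrow(shared),
    only_b = nrow(b) - nrow(shared)
  )
  cond <- function(x, other, detected_other) {
    detectable <- x$protein_a %in% detected_other &
      x$protein_b %in% detected_other
    found <- nrow(inner_join(x[detectable, ], other,
                             by = c("protein_a", "protein_b")))
    n <- sum(detectable)
    list(n = n, frac = if (n > 0) found / n else NA_real_)
  }
  if (!is.null(detected_in_b)) {
    ca <- cond(a, b, detected_in_b)
    out$n_a_detectable_in_b <- ca$n
    out$frac_a_found_in_b <- ca$frac
    out$pct_a_not_in_b <- 100 * (1 - ca$frac)
  }
  if (!is.null(detected_in_a)) {
    cb <- cond(b, a, detected_in_a)
    out$n_b_detectable_in_a <- cb$n
    out$frac_b_found_in_a <- cb$frac
    out$pct_b_not_in_a <- 100 * (1 - cb$frac)
  }
  out
}

#' Re-estimate an FDR on held-out gold standards
#'
#' Given a prediction set and gold positive/negative pairs that were held
#' out of its training, the FDR is re-estimated as the percentage of
#' predicted-and-gold pairs that are gold negatives:
#' `100 * |pred n neg| / (|pred n pos| + |pred n neg|)`.
#'
#' @param predicted Pair tibble.
#' @param heldout_positives,heldout_negatives Pair tibbles (disjoint).
#' @return FDR in percent, `NA` if no predicted pair intersects the gold
#'   sets.
#' @export
heldout_fdr <- function(predicted, heldout_positives, heldout_negatives) {
  predicted <- as_pair_set(predicted)
  pos <- as_pair_set(heldout_positives)
  neg <- as_pair_set(heldout_negatives)
  both <- inner_join(pos, neg, by = c("protein_a", "protein_b"))
  if (nrow(both) > 0) stop("held-out gold sets must be disjoint")
  n_pos <- nrow(inner_join(predicted, pos, by = c("protein_a", "protein_b")))
  n_neg <- nrow(inner_join(predicted, neg, by = c("protein_a", "protein_b")))
  fdr_from_counts(n_pos, n_neg)
}

#' @rdname heldout_fdr
#' @param n_pos,n_neg Counts of predicted pairs intersecting the held-out
#'   gold positive and negative sets; published contingency counts can be
#'   audited directly through this form.
#' @export
fdr_from_counts <- function(n_pos, n_neg) {
  stopifnot(n_pos >= 0, n_neg >= 0)
  if (n_pos + n_neg == 0) return(NA_real_)
  100 * n_neg / (n_pos + n_neg)
}

#' Accuracy bound from differential overlap enrichment
#'
#' If the pairs of a trusted (gold) subset of an interactome overlap an
#' independent reference collection at rate `gold_overlap_rate`, while its
#' novel pairs overlap at the lower `novel_overlap_rate`, then even granting
#' the gold subset 100% accuracy the novel pairs can be at most
#' `100 * novel_rate / gold_rate` percent accurate, implying a minimum FDR
#' of 100 minus that.
#'
#' @param gold_overlap_rate,novel_overlap_rate Overlap rates with the
#'   independent reference (same units; only their ratio matters).
#' @return One-row tibble: `enrichment`, `implied_accuracy_pct`,
#'   `implied_min_fdr_pct`.
#' @export
overlap_enrichment_bound <- function(gold_overlap_rate, novel_overlap_rate) {
  if (gold_overlap_rate <= 0) stop("gold overlap rate must be positive")
  if (novel_overlap_rate <= 0) stop("novel overlap rate must be positive")
  acc <- 100 * novel_overlap_rate / gold_overlap_rate
  tibble(
    enrichment = gold_overlap_rate / novel_overlap_rate,
    implied_accuracy_pct = acc,
    implied_min_fdr_pct = 100 - acc
  )
}

#' Quality metrics of a pair set
#'
#' The suite of orthogonal sanity checks applied to candidate interactomes:
#' the percentage of pairs encoded in the same operon, the enrichment of
#' pairs sharing a functional (TIGR role) annotation over the expectation
#' for random protein pairs, and the percentage overlap with each supplied
#' reference interactome.
#'
#' The role-sharing expectation is computed from the marginal role
#' frequencies over the annotated proteins (`detected` when given, else all
#' annotated proteins): the probability that two random distinct proteins
#' share a role.
#'
#' @param query Pair tibble.
#' @param annotations Tibble `protein_id`, `operon_id`, `tigr_role`.
#' @param references Named list of reference pair tibbles.
#' @param detected Optional universe of protein ids for the role null.
#' @return Tibble `metric`, `value` (long form, one row per metric).
#' @export
quality_metrics <- function(query, annotations, references = list(),
                            detected = NULL) {
  query <- as_pair_set(query)
  annotations <- as_tibble(annotations)
  stopifnot("protein_id" %in% names(annotations))
  ann <- annotations
  if (!is.null(detected)) ann <- filter(ann, .data$protein_id %in% detected)

  q <- query |>
    left_join(select(annotations, "protein_id",
                     op_a = "operon_id", role_a = "tigr_role"),
              by = c(protein_a = "protein_id")) |>
    left_join(select(annotations, "protein_id",
                     op_b = "operon_id", role_b = "tigr_role"),
              by = c(protein_b = "protein_id"))

  same_operon <- !is.na(q$op_a) & !is.na(q$op_b) & q$op_a == q$op_b
  same_operon_pct <- if (nrow(q) > 0) 100 * mean(same_operon) else NA_real_

  roled <- !is.na(q$role_a) & !is.na(q$role_b)
  obs_share <- if (any(roled)) mean(q$role_a[roled] == q$role_b[roled])
               else NA_real_
  role_freq <- ann |>
    filter(!is.na(.data$tigr_role)) |>
    count(.data$tigr_role) |>
    mutate(p = .data$n / sum(.data$n))
  exp_share <- sum(role_freq$p^2)
  role_enrichment <- if (!is.na(obs_share) && exp_share > 0)
    obs_share / exp_share else NA_real_

  out <- tibble(
    metric = c("same_operon_pct", "tigr_role_enrichment"),
    value = c(same_operon_pct, role_enrichment)
  )
  if (length(references) > 0) {
    ref_names <- names(references) %||% paste0("reference_", seq_along(references))
    overlaps <- purrr::map2_dfr(references, ref_names, function(ref, nm) {
      ref <- as_pair_set(ref)
      hit <- nrow(inner_join(query, ref, by = c("protein_a", "protein_b")))
      tibble(metric = paste0("overlap_pct_", nm),
             value = if (nrow(query) > 0) 100 * hit / nrow(query)
                     else NA_real_)
    })
    out <- bind_rows(out, overlaps)
  }
  out
}
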