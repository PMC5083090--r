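# Fixtures are built in code. The oracles below are deliberately naive
# (per-pair loops over the definitions) and independent of the vectorized
# implementations they check.

# a tiny deterministic dataset: 3 proteins, 2 multiplexes (one per dimension)
tiny_dataset <- function() {
  design <- tibble::tibble(
    multiplex_id = c(rep("M1", 4), rep("M2", 4)),
    dimension = c(rep("SEC", 4), rep("HIC", 4)),
    fraction_id = c(paste0("s", 1:4), paste0("h", 1:4)),
    is_joint = 0L
  )
  abundance <- tibble::tibble(
    protein_id = rep(c("A", "B", "C"), each = 8),
    multiplex_id = rep(rep(c("M1", "M2"), each = 4), 3),
    fraction_id = rep(c(paste0("s", 1:4), paste0("h", 1:4)), 3),
    abundance = c(
      2, 4, 8, 1,   0.5, 1, 2, 0.2,   # A
      1, 2, 4, 0.5, 0.4, 0.8, 1.6, 0.1, # B: proportional to A
      8, 1, 0.5, 0.2, 2, 0.1, 0.05, 0.02 # C: different shape
    ),
    peptides = rep(c(4L, 2L, 6L, 3L, 5L, 5L), each = 4)
  )
  proteins <- tibble::tibble(
    protein_id = c("A", "B", "C"),
    operon_id = c("op1", "op1", NA),
    tigr_role = c("r1", "r1", "r2"),
    excluded = FALSE
  )
  elution_dataset(abundance, design, proteins)
}

# random small dataset exercising dropout, sub-threshold raw intensities
# and both dimensions; independent of the package's simulator
random_tiny_dataset <- function(seed, n_proteins = 7, n_multiplex = 5) {
  set.seed(seed)
  prot <- paste0("p", seq_len(n_proteins))
  rows <- list()
  design_rows <- list()
  for (m in seq_len(n_multiplex)) {
    nf <- sample(3:6, 1)
    mid <- paste0("m", m)
    frs <- paste0(mid, "_f", seq_len(nf))
    design_rows[[m]] <- tibble::tibble(
      multiplex_id = mid,
      dimension = sample(c("SEC", "HIC"), 1),
      fraction_id = frs,
      is_joint = 0L
    )
    for (p in prot) {
      if (stats::runif(1) < 0.35) next  # dropout
      nin <- sample(seq_len(nf), 1)
      sel <- sort(sample(seq_len(nf), nin))
      rows[[length(rows) + 1L]] <- tibble::tibble(
        protein_id = p, multiplex_id = mid, fraction_id = frs[sel],
        abundance = stats::runif(nin, 0.002, 2),  # some below 0.01
        peptides = sample(1:9, 1)
      )
    }
  }
  ab <- dplyr::bind_rows(rows)
  # guarantee at least one co-detected pair somewhere
  if (length(unique(ab$protein_id)) < 2) {
    ab <- dplyr::bind_rows(ab, tibble::tibble(
      protein_id = prot[1:2], multiplex_id = "m1",
      fraction_id = design_rows[[1]]$fraction_id[1],
      abundance = c(1, 1), peptides = c(2L, 2L)
    ))
  }
  elution_dataset(ab, dplyr::bind_rows(design_rows))
}

# --- brute-force oracles -----------------------------------------------

# profile of `p` over the declared fractions of multiplex `m` (0-filled)
.oracle_vec <- function(dataset, p, m, col = "abundance") {
  frs <- dataset$design$fraction_id[dataset$design$multiplex_id == m]
  frs <- unique(frs)
  v <- numeric(length(frs))
  ab <- dataset$abundance
  sel <- ab$protein_id == p & ab$multiplex_id == m
  v[match(ab$fraction_id[sel], frs)] <- ab[[col]][sel]
  v
}

.oracle_detected <- function(dataset, p, m) {
  any(dataset$abundance$protein_id == p & dataset$abundance$multiplex_id == m)
}

oracle_cc <- function(dataset, a, b, m, min_intensity = 0.01,
                      min_fractions = 3) {
  if (!.oracle_detected(dataset, a, m) || !.oracle_detected(dataset, b, m)) {
    return(NA_real_)
  }
  raw_col <- if ("raw" %in% names(dataset$abundance)) "raw" else "abundance"
  ra <- .oracle_vec(dataset, a, m, raw_col)
  rb <- .oracle_vec(dataset, b, m, raw_col)
  if (sum(ra >= min_intensity) < min_fractions &&
      sum(rb >= min_intensity) < min_fractions) {
    return(NA_real_)
  }
  x <- .oracle_vec(dataset, a, m)
  y <- .oracle_vec(dataset, b, m)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  # direct sum-based Pearson formula
  n <- length(x)
  num <- n * sum(x * y) - sum(x) * sum(y)
  den <- sqrt(n * sum(x^2) - sum(x)^2) * sqrt(n * sum(y^2) - sum(y)^2)
  num / den
}

oracle_multiplexes <- function(dataset, dimension = NULL) {
  d <- unique(dataset$design[c("multiplex_id", "dimension")])
  if (!is.null(dimension)) d <- d[d$dimension == dimension, ]
  d$multiplex_id
}

oracle_max_cc <- function(dataset, a, b, dimension, ...) {
  ccs <- c()
  for (m in oracle_multiplexes(dataset, dimension)) {
    ccs <- c(ccs, oracle_cc(dataset, a, b, m, ...))
  }
  ccs <- ccs[!is.na(ccs)]
  if (length(ccs) == 0) -1 else max(ccs)
}

oracle_dice <- function(dataset, a, b) {
  ms <- oracle_multiplexes(dataset)
  in_a <- vapply(ms, function(m) .oracle_detected(dataset, a, m), logical(1))
  in_b <- vapply(ms, function(m) .oracle_detected(dataset, b, m), logical(1))
  sum(in_a & in_b) / (sum(in_a) + sum(in_b))
}

oracle_peptide_ratio <- function(dataset, a, b) {
  pep <- dataset$peptides
  best <- -Inf
  max_a <- max(pep$peptides[pep$protein_id == a])
  max_b <- max(pep$peptides[pep$protein_id == b])
  for (m in oracle_multiplexes(dataset)) {
    pa <- pep$peptides[pep$protein_id == a & pep$multiplex_id == m]
    pb <- pep$peptides[pep$protein_id == b & pep$multiplex_id == m]
    if (length(pa) == 0 || length(pb) == 0) next
    best <- max(best, min(pa / max_a, pb / max_b))
  }
  if (is.infinite(best)) 0 else best
}

oracle_min_proteins <- function(dataset, a, b, cc_threshold = 0.85, ...) {
  ms <- oracle_multiplexes(dataset)
  nprot <- vapply(ms, function(m) {
    length(unique(dataset$abundance$protein_id[
      dataset$abundance$multiplex_id == m]))
  }, numeric(1))
  best <- Inf
  for (i in seq_along(ms)) {
    cc <- oracle_cc(dataset, a, b, ms[i], ...)
    if (!is.na(cc) && cc >= cc_threshold) best <- min(best, nprot[i])
  }
  if (is.infinite(best)) max(nprot) + 1 else best
}

oracle_cooccurring <- function(dataset) {
  prot <- sort(unique(dataset$abundance$protein_id))
  out <- list()
  for (i in seq_along(prot)) {
    for (j in seq_along(prot)) {
      if (i >= j) next
      for (m in oracle_multiplexes(dataset)) {
        if (.oracle_detected(dataset, prot[i], m) &&
            .oracle_detected(dataset, prot[j], m)) {
          out[[length(out) + 1L]] <- c(prot[i], prot[j])
          break
        }
      }
    }
  }
  if (length(out) == 0) {
    return(tibble::tibble(protein_a = character(), protein_b = character()))
  }
  m <- do.call(rbind, out)
  tibble::tibble(protein_a = m[, 1], protein_b = m[, 2])
}

# rank-sum AUC of scores for a binary label
auc_of <- function(score, label) {
  r <- rank(score)
  n1 <- sum(label == 1)
  n0 <- sum(label == 0)
  (sum(r[label == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
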