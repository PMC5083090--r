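#' Configuration for a synthetic co-fractionation experiment
#'
#' Collects and validates the parameters of the generator, which emulates a
#' two-dimensional (HIC then SEC) fractionation assayed by iTRAQ multiplexes:
#' complexes co-elute as shared Gaussian peaks in both dimensions, monomers
#' elute independently, multiplexes tile each column with one joint fraction
#' shared between neighbors, detection suffers dropout, a few promiscuous
#' "frequent fliers" smear across many fractions, and genome-context scores
#' are elevated for co-operonic and co-complex pairs.
#'
#' @param n_proteins Total proteins in the simulated proteome subset.
#' @param n_complexes Number of multi-protein complexes.
#' @param complex_size_lambda Complex sizes are `2 + Poisson(lambda)`,
#'   capped at `max_complex_size`.
#' @param max_complex_size Largest complex allowed.
#' @param n_hic_columns Number of HIC columns; each protein (except frequent
#'   fliers) elutes on one of them.
#' @param hic_fractions,sec_fractions Fractions per HIC and per SEC column.
#' @param sec_columns_per_hic SEC columns run from evenly spaced fractions
#'   of each HIC column.
#' @param multiplex_width Fractions pooled per multiplex (8-plex default);
#'   adjacent multiplexes of a column share one joint fraction.
#' @param peak_width_sec,peak_width_hic Gaussian elution peak widths, in
#'   fraction units.
#' @param apex_jitter SD of each complex member's apex around the complex
#'   apex, in fraction units.
#' @param noise_cv Multiplicative log-normal measurement noise
#'   (coefficient-of-variation scale).
#' @param detection_floor Raw relative intensity below which a fraction is
#'   not detected.
#' @param dropout Probability that a (protein, multiplex) detection is lost
#'   to data-dependent acquisition.
#' @param frequent_flier_frac Fraction of monomer proteins with broad,
#'   multi-peak profiles present on every HIC column.
#' @param abundance_meanlog,abundance_sdlog Log-normal base abundance.
#' @param peptide_scale Expected extra unique peptides at full relative
#'   abundance (counts are `1 + Poisson(scale * relative abundance)`).
#' @param operon_concordance Probability that a complex's members are
#'   encoded in one operon.
#' @param gold_frac Common sampling fraction used to draw gold positives
#'   from co-occurring co-complex pairs and gold negatives from co-occurring
#'   non-interacting pairs. A common rate keeps the gold-count FDR estimator
#'   calibrated against the candidate universe.
#' @param context_noise_frac Fraction of random non-interacting pairs given
#'   small nonzero genome-context scores.
#' @param n_ribosomal Monomers tagged with a ribosomal role and the
#'   `excluded` flag, to exercise exclusion filtering.
#' @param seed Integer seed; the simulation is a pure function of the
#'   config.
#' @return A validated list of class `simulation_config`.
#' @export
simulation_config <- function(n_proteins = 500,
                              n_complexes = 60,
                              complex_size_lambda = 2,
                              max_complex_size = 8,
                              n_hic_columns = 4,
                              hic_fractions = 12,
                              sec_fractions = 19,
                              sec_columns_per_hic = 3,
                              multiplex_width = 8,
                              peak_width_sec = 1.2,
                              peak_width_hic = 0.9,
                              apex_jitter = 0.25,
                              noise_cv = 0.25,
                              detection_floor = 0.02,
                              dropout = 0.10,
                              frequent_flier_frac = 0.05,
                              abundance_meanlog = 0.3,
                              abundance_sdlog = 0.8,
                              peptide_scale = 7,
                              operon_concordance = 0.7,
                              gold_frac = 0.35,
                              context_noise_frac = 0.02,
                              n_ribosomal = 5,
                              seed = 1L) {
  cfg <- as.list(environment())
  probs <- c("dropout", "frequent_flier_frac", "operon_concordance",
             "gold_frac", "context_noise_frac")
  for (p in probs) {
    if (cfg[[p]] < 0 || cfg[[p]] > 1) stop(p, " must lie in [0, 1]")
  }
  for (p in c("n_proteins", "n_complexes", "n_hic_columns", "hic_fractions",
              "sec_fractions", "sec_columns_per_hic", "multiplex_width")) {
    if (cfg[[p]] < 1) stop(p, " must be positive")
  }
  if (cfg$multiplex_width < 2 || cfg$multiplex_width > 8) {
    stop("multiplex_width must be 2-8 (isobaric label limit)")
  }
  if (cfg$multiplex_width > cfg$sec_fractions ||
      cfg$multiplex_width > cfg$hic_fractions) {
    stop("infeasible geometry: multiplex_width exceeds the fractions of a ",
         "column")
  }
  if (cfg$n_complexes * 2 >= cfg$n_proteins) {
    stop("too many complexes for the proteome size")
  }
  structure(cfg, class = "simulation_config")
}

# tile 1..n into windows of `width` sharing one joint fraction:
# e.g. 19 -> [1-8], [8-15], [15-19]
.tile_column <- function(n, width) {
  starts <- 1L
  ends <- integer(0)
  s <- 1L
  repeat {
    e <- min(s + width - 1L, n)
    ends <- c(ends, e)
    if (e == n) break
    s <- e  # joint fraction: new multiplex starts on the previous end
    starts <- c(starts, s)
  }
  purrr::map2(starts, ends, seq)
}

.gauss_peak <- function(x, apex, width) {
  exp(-((x - apex)^2) / (2 * width^2))
}

# multi-apex profile (frequent fliers have >1 apex)
.profile <- function(x, apices, width) {
  rows <- lapply(apices, function(a) .gauss_peak(x, a, width))
  colSums(do.call(rbind, rows))
}

#' Simulate a complete tagless copurification experiment
#'
#' Generates an [elution_dataset()] with known ground truth: complex members
#' share Gaussian elution apices (with jitter) in both the HIC and SEC
#' dimensions, abundances carry multiplicative noise and detection dropout,
#' multiplexes tile each column with joint fractions, unique-peptide counts
#' grow with relative abundance, gold standards are sampled from the truth,
#' and genome-context scores are elevated for co-operonic/co-complex pairs.
#'
#' @param config A [simulation_config()].
#' @return A list of class `coelution_simulation` with elements `dataset`
#'   (validated, unnormalized [elution_dataset()]), `truth` (complex map,
#'   true co-complex pair set, per-protein apices), `gold`
#'   ([gold_standard()] tibble), `context` (genome-context tibble) and
#'   `config`.
#' @export
simulate_experiment <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  cfg <- config
  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  })
  set.seed(cfg$seed)

  ## ---- proteome and complexes ----
  sizes <- pmin(2 + rpois(cfg$n_complexes, cfg$complex_size_lambda),
                cfg$max_complex_size)
  if (sum(sizes) > 0.8 * cfg$n_proteins) {
    stop("complexes would consume >80% of the proteome; reduce n_complexes")
  }
  ids <- sprintf("P%04d", seq_len(cfg$n_proteins))
  complex_id <- rep(NA_character_, cfg$n_proteins)
  complex_id[seq_len(sum(sizes))] <-
    rep(sprintf("cpx%03d", seq_len(cfg$n_complexes)), sizes)

  is_member <- !is.na(complex_id)
  monomers <- which(!is_member)
  n_ff <- round(cfg$frequent_flier_frac * length(monomers))
  ff_idx <- if (n_ff > 0) sample(monomers, n_ff) else integer(0)
  is_ff <- seq_len(cfg$n_proteins) %in% ff_idx

  ## ---- elution geometry ----
  cpx_home <- sample.int(cfg$n_hic_columns, cfg$n_complexes, replace = TRUE)
  cpx_apex_h <- runif(cfg$n_complexes, 2, cfg$hic_fractions - 1)
  cpx_apex_s <- runif(cfg$n_complexes, 2, cfg$sec_fractions - 1)
  cpx_of <- match(complex_id, sprintf("cpx%03d", seq_len(cfg$n_complexes)))

  home <- ifelse(is_member, cpx_home[cpx_of],
                 sample.int(cfg$n_hic_columns, cfg$n_proteins, replace = TRUE))
  apex_h <- ifelse(is_member,
                   cpx_apex_h[cpx_of] + rnorm(cfg$n_proteins, 0, cfg$apex_jitter),
                   runif(cfg$n_proteins, 2, cfg$hic_fractions - 1))
  apex_s <- ifelse(is_member,
                   cpx_apex_s[cpx_of] + rnorm(cfg$n_proteins, 0, cfg$apex_jitter),
                   runif(cfg$n_proteins, 2, cfg$sec_fractions - 1))
  base <- stats::rlnorm(cfg$n_proteins, cfg$abundance_meanlog,
                        cfg$abundance_sdlog)
  base[is_ff] <- base[is_ff] * 3

  # frequent fliers: broad profiles with a second apex, on every HIC column
  extra_apex_h <- runif(cfg$n_proteins, 2, cfg$hic_fractions - 1)
  extra_apex_s <- runif(cfg$n_proteins, 2, cfg$sec_fractions - 1)
  width_h <- ifelse(is_ff, 2.5 * cfg$peak_width_hic, cfg$peak_width_hic)
  width_s <- ifelse(is_ff, 2.5 * cfg$peak_width_sec, cfg$peak_width_sec)

  noise_sd <- sqrt(log(1 + cfg$noise_cv^2))
  hic_profile <- function(i, noisefree = FALSE) {
    apices <- if (is_ff[i]) c(apex_h[i], extra_apex_h[i]) else apex_h[i]
    v <- .profile(seq_len(cfg$hic_fractions), apices, width_h[i])
    if (!noisefree) {
      v <- v * exp(rnorm(cfg$hic_fractions, 0, noise_sd))
    }
    v
  }

  ## ---- HIC dimension: one profile series per column ----
  hic_tiles <- .tile_column(cfg$hic_fractions, cfg$multiplex_width)
  ab_rows <- list()
  for (col in seq_len(cfg$n_hic_columns)) {
    members <- which(home == col | is_ff)
    for (i in members) {
      v <- base[i] * hic_profile(i)
      det <- which(v >= cfg$detection_floor)
      if (length(det) == 0) next
      ab_rows[[length(ab_rows) + 1L]] <- tibble(
        protein_id = ids[i],
        column = paste0("H", col),
        fraction = det,
        value = v[det]
      )
    }
  }
  hic_values <- bind_rows(ab_rows)

  ## ---- SEC dimension: columns run from selected HIC fractions ----
  sec_positions <- unique(round(seq(2, cfg$hic_fractions - 1,
                                    length.out = cfg$sec_columns_per_hic)))
  sec_tiles <- .tile_column(cfg$sec_fractions, cfg$multiplex_width)
  sec_rows <- list()
  for (col in seq_len(cfg$n_hic_columns)) {
    members <- which(home == col | is_ff)
    for (f in sec_positions) {
      for (i in members) {
        # loading of this SEC column is the protein's (noise-free) HIC level
        apices <- if (is_ff[i]) c(apex_h[i], extra_apex_h[i]) else apex_h[i]
        w <- .profile(f, apices, width_h[i])
        if (base[i] * w < cfg$detection_floor) next
        s_apices <- if (is_ff[i]) c(apex_s[i], extra_apex_s[i]) else apex_s[i]
        v <- base[i] * w *
          .profile(seq_len(cfg$sec_fractions), s_apices, width_s[i]) *
          exp(rnorm(cfg$sec_fractions, 0, noise_sd))
        det <- which(v >= cfg$detection_floor)
        if (length(det) == 0) next
        sec_rows[[length(sec_rows) + 1L]] <- tibble(
          protein_id = ids[i],
          column = paste0("H", col, "S", f),
          fraction = det,
          value = v[det]
        )
      }
    }
  }
  sec_values <- bind_rows(sec_rows)

  ## ---- tile columns into multiplexes ----
  expand_column <- function(values, tiles, dim_label) {
    if (nrow(values) == 0) return(NULL)
    tile_tab <- purrr::imap_dfr(tiles, function(frs, k) {
      tibble(fraction = frs, mplex = k)
    })
    values |>
      inner_join(tile_tab, by = "fraction",
                 relationship = "many-to-many") |>
      mutate(
        multiplex_id = paste0(.data$column, "_m", .data$mplex),
        fraction_id = paste0(.data$column, "_f", .data$fraction),
        dimension = dim_label
      )
  }
  long <- bind_rows(
    expand_column(hic_values, hic_tiles, "HIC"),
    expand_column(sec_values, sec_tiles, "SEC")
  )

  ## ---- design table ----
  design_of <- function(columns, tiles, dim_label) {
    purrr::map_dfr(columns, function(col) {
      purrr::imap_dfr(tiles, function(frs, k) {
        joint <- frs %in% unlist(tiles[-k])
        tibble(
          multiplex_id = paste0(col, "_m", k),
          dimension = dim_label,
          fraction_id = paste0(col, "_f", frs),
          is_joint = as.integer(joint)
        )
      })
    })
  }
  hic_cols <- paste0("H", seq_len(cfg$n_hic_columns))
  sec_cols <- as.vector(outer(hic_cols, paste0("S", sec_positions), paste0))
  design <- bind_rows(
    design_of(hic_cols, hic_tiles, "HIC"),
    design_of(sec_cols, sec_tiles, "SEC")
  )
  design <- semi_join(design, long, by = "multiplex_id")

  ## ---- per-multiplex dropout ----
  dets <- distinct(long, .data$protein_id, .data$multiplex_id)
  keep <- runif(nrow(dets)) >= cfg$dropout
  dets <- dets[keep, ]
  long <- semi_join(long, dets, by = c("protein_id", "multiplex_id"))

  abundance <- long |>
    transmute(.data$protein_id, .data$multiplex_id, .data$fraction_id,
              abundance = .data$value)

  ## ---- peptide counts: grow with relative abundance in the multiplex ----
  mmax <- abundance |>
    group_by(.data$protein_id, .data$multiplex_id) |>
    summarise(mx = max(.data$abundance), .groups = "drop") |>
    group_by(.data$protein_id) |>
    mutate(rel = .data$mx / max(.data$mx)) |>
    ungroup() |>
    arrange(.data$protein_id, .data$multiplex_id)
  peptides <- mmax |>
    mutate(peptides = 1L + rpois(n(), cfg$peptide_scale * .data$rel)) |>
    select("protein_id", "multiplex_id", "peptides")

  ## ---- operons and annotations ----
  concordant <- runif(cfg$n_complexes) < cfg$operon_concordance
  operon_id <- ifelse(
    is_member & concordant[cpx_of],
    sprintf("opn%03d", cpx_of),
    paste0("opn_s_", ids)
  )
  roles <- sprintf("role%02d", 1:15)
  cpx_role <- sample(roles, cfg$n_complexes, replace = TRUE)
  tigr_role <- ifelse(is_member & runif(cfg$n_proteins) < 0.8,
                      cpx_role[cpx_of],
                      sample(roles, cfg$n_proteins, replace = TRUE))
  excluded <- rep(FALSE, cfg$n_proteins)
  rib <- setdiff(monomers, ff_idx)
  rib <- head(rib, cfg$n_ribosomal)
  excluded[rib] <- TRUE
  tigr_role[rib] <- "Ribosomal proteins"
  proteins <- tibble(
    protein_id = ids, operon_id = operon_id,
    tigr_role = tigr_role, excluded = excluded
  )

  detected <- sort(unique(abundance$protein_id))
  dataset <- elution_dataset(abundance, design,
                             proteins = filter(proteins,
                                               .data$protein_id %in% detected),
                             peptides = peptides)

  ## ---- ground truth ----
  memb <- tibble(protein_id = ids, complex_id = complex_id) |>
    filter(!is.na(.data$complex_id))
  true_pairs <- memb |>
    inner_join(memb, by = "complex_id", relationship = "many-to-many") |>
    filter(.data$protein_id.x < .data$protein_id.y) |>
    distinct(protein_a = .data$protein_id.x, protein_b = .data$protein_id.y)
  truth <- list(
    membership = memb,
    true_pairs = true_pairs,
    apices = tibble(protein_id = ids, hic_column = hic_cols[home],
                    apex_hic = apex_h, apex_sec = apex_s,
                    frequent_flier = is_ff)
  )

  ## ---- gold standards: common sampling rate on the candidate universe ----
  clean <- filter_exclusions(dataset, ids[excluded])
  cooc <- cooccurring_pairs(clean)
  cooc_id <- .pair_id(cooc$protein_a, cooc$protein_b)
  true_id <- .pair_id(true_pairs$protein_a, true_pairs$protein_b)
  pos_univ <- cooc[cooc_id %in% true_id, ]
  neg_univ <- cooc[!cooc_id %in% true_id, ]
  n_pos <- max(2L, round(cfg$gold_frac * nrow(pos_univ)))
  n_neg <- max(2L, round(cfg$gold_frac * nrow(neg_univ)))
  gold <- gold_standard(
    pos_univ[sample.int(nrow(pos_univ), min(n_pos, nrow(pos_univ))), ],
    neg_univ[sample.int(nrow(neg_univ), min(n_neg, nrow(neg_univ))), ]
  )

  ## ---- genome-context scores ----
  op_of <- setNames(operon_id, ids)
  ctx_pairs <- true_pairs
  same_op <- op_of[ctx_pairs$protein_a] == op_of[ctx_pairs$protein_b]
  context <- ctx_pairs |>
    mutate(
      neighborhood = ifelse(same_op,
                            rbeta(n(), 6, 2), rbeta(n(), 1.5, 4)),
      cooccurrence = rbeta(n(), 4, 3),
      fusion = ifelse(runif(n()) < 0.15, rbeta(n(), 3, 3),
                      rbeta(n(), 1, 30))
    )
  n_noise <- round(cfg$context_noise_frac * nrow(neg_univ))
  if (n_noise > 0) {
    noise_pairs <- neg_univ[sample.int(nrow(neg_univ), n_noise), ]
    context <- bind_rows(
      context,
      mutate(noise_pairs,
             neighborhood = rbeta(n_noise, 1, 10),
             cooccurrence = rbeta(n_noise, 1, 10),
             fusion = rbeta(n_noise, 1, 30))
    )
  }

  structure(
    list(dataset = dataset, truth = truth, gold = gold,
         context = context, config = cfg),
    class = "coelution_simulation"
  )
}

#' @export
print.coelution_simulation <- function(x, ...) {
  cat("<coelution_simulation> seed ", x$config$seed, "\n", sep = "")
  print(x$dataset)
  cat("  true pairs: ", nrow(x$truth$true_pairs),
      "; gold: ", sum(x$gold$label == "positive"), " pos / ",
      sum(x$gold$label == "negative"), " neg\n", sep = "")
  invisible(x)
}

#' Score predictions against the simulation's ground truth
#'
#' @param predictions A `ppi_predictions` or a pair tibble.
#' @param truth The `truth` element of a [simulate_experiment()] result.
#' @param candidates Optional candidate-pair universe; when supplied, recall
#'   is computed against true pairs within it (the pairs the assay could in
#'   principle have scored).
#' @return One-row tibble: `n_predicted`, `n_true`, `tp`, `fp`,
#'   `empirical_fdr`, `precision`, `recall`.
#' @export
truth_metrics <- function(predictions, truth, candidates = NULL) {
  pairs <- if (inherits(predictions, "ppi_predictions"))
    predictions$predicted else predictions
  pairs <- as_pair_set(pairs)
  true_pairs <- as_pair_set(truth$true_pairs)
  if (!is.null(candidates)) {
    true_pairs <- semi_join(true_pairs, as_pair_set(candidates),
                            by = c("protein_a", "protein_b"))
  }
  tp <- nrow(inner_join(pairs, true_pairs, by = c("protein_a", "protein_b")))
  fp <- nrow(pairs) - tp
  tibble(
    n_predicted = nrow(pairs),
    n_true = nrow(true_pairs),
    tp = tp, fp = fp,
    empirical_fdr = if (nrow(pairs) > 0) fp / nrow(pairs) else NA_real_,
    precision = if (nrow(pairs) > 0) tp / nrow(pairs) else NA_real_,
    recall = if (nrow(true_pairs) > 0) tp / nrow(true_pairs) else NA_real_
  )
}

#' Write the simulated experiment's artifacts as TSV files
#'
#' @param sim A `coelution_simulation`.
#' @param dir Output directory.
#' @return Invisibly, the vector of files written.
#' @export
write_simulation <- function(sim, dir) {
  stopifnot(inherits(sim, "coelution_simulation"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- write_elution_tables(sim$dataset, dir, prefix = "synthetic")
  extra <- c(
    gold = file.path(dir, "synthetic-gold.tsv"),
    context = file.path(dir, "synthetic-context.tsv"),
    truth = file.path(dir, "synthetic-true-pairs.tsv")
  )
  readr::write_tsv(sim$gold, extra["gold"], progress = FALSE)
  readr::write_tsv(sim$context, extra["context"], progress = FALSE)
  readr::write_tsv(sim$truth$true_pairs, extra["truth"], progress = FALSE)
  invisible(c(paths, extra))
}
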