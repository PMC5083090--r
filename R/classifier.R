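#' Gold-standard pair table
#'
#' Validates and canonicalizes a gold standard: curated positive (known
#' interacting) and negative (believed non-interacting) protein pairs used to
#' train the classifier and to estimate false discovery rates. The two sets
#' must be disjoint.
#'
#' @param positives,negatives Pair tibbles (`protein_a`, `protein_b`).
#' @return Tibble `protein_a`, `protein_b`, `label` with
#'   `label` in `c("positive", "negative")`.
#' @export
gold_standard <- function(positives, negatives) {
  pos <- mutate(as_pair_set(positives), label = "positive")
  neg <- mutate(as_pair_set(negatives), label = "negative")
  both <- inner_join(pos, neg, by = c("protein_a", "protein_b"))
  if (nrow(both) > 0) {
    stop(nrow(both), " pair(s) are both gold positive and gold negative, ",
         "e.g. ", both$protein_a[1], "-", both$protein_b[1])
  }
  bind_rows(pos, neg)
}

# fill singleton operons for proteins missing from the map
.complete_operon_map <- function(operon_map, protein_ids) {
  operon_map <- as_tibble(operon_map)
  stopifnot(all(c("protein_id", "operon_id") %in% names(operon_map)))
  operon_map <- operon_map |>
    filter(!is.na(.data$operon_id)) |>
    distinct(.data$protein_id, .data$operon_id)
  missing <- setdiff(protein_ids, operon_map$protein_id)
  bind_rows(operon_map,
            tibble(protein_id = missing,
                   operon_id = paste0("singleton:", missing)))
}

#' One-operon-out cross-validation folds
#'
#' Interacting pairs are not independent observations: pairs sharing a
#' protein, and above all pairs from the same operon-encoded complex, are
#' strongly correlated. The cross-validation unit is therefore the operon.
#' For each operon, every candidate pair touching any of its proteins (inside
#' or outside the operon) is held out for validation, and the training set is
#' restricted to gold pairs touching none of them. Proteins without an
#' operon annotation form singleton operons.
#'
#' @param gold Gold-standard tibble from [gold_standard()].
#' @param candidate_pairs Pair tibble of all scoreable candidates.
#' @param operon_map Tibble `protein_id`, `operon_id`.
#' @return Nested tibble with one row per operon: `fold_id`, `proteins`,
#'   `train` and `validation` list-columns of pair tibbles.
#' @export
one_operon_out_folds <- function(gold, candidate_pairs, operon_map) {
  if (is.null(operon_map) || nrow(as_tibble(operon_map)) == 0) {
    stop("operon_map is empty; every gold protein needs an operon ",
         "(singletons count)")
  }
  prot <- unique(c(gold$protein_a, gold$protein_b,
                   candidate_pairs$protein_a, candidate_pairs$protein_b))
  omap <- .complete_operon_map(operon_map, prot)
  operons <- split(omap$protein_id, omap$operon_id)
  gold <- as_tibble(gold)
  candidate_pairs <- as_tibble(candidate_pairs)

  folds <- purrr::imap(operons, function(members, op) {
    held_train <- gold$protein_a %in% members | gold$protein_b %in% members
    held_val <- candidate_pairs$protein_a %in% members |
      candidate_pairs$protein_b %in% members
    tibble(
      fold_id = op,
      proteins = list(members),
      train = list(gold[!held_train, ]),
      validation = list(candidate_pairs[held_val, ])
    )
  })
  bind_rows(folds)
}

.MS_FEATURES <- c("cc_sec", "cc_hic", "dice", "peptide_ratio", "min_proteins")
.STRING_FEATURES <- c("string_neighborhood", "string_cooccurrence",
                      "string_fusion")

.model_features <- function(model_kind) {
  model_kind <- match.arg(model_kind, c("ms_string", "ms_only"))
  if (model_kind == "ms_only") .MS_FEATURES else
    c(.MS_FEATURES, .STRING_FEATURES)
}

.feature_matrix <- function(features, cols) {
  missing <- setdiff(cols, names(features))
  if (length(missing) > 0) {
    stop("feature table is missing column(s): ",
         paste(missing, collapse = ", "))
  }
  as.matrix(features[cols])
}

# ridge-penalized logistic fit on z-scaled features; the light fixed penalty
# keeps coefficients finite on separable training sets
.fit_core <- function(x, y, lambda) {
  if (length(unique(y)) < 2) {
    stop("training set contains a single class; need both gold positives ",
         "and negatives")
  }
  center <- colMeans(x)
  scale_ <- apply(x, 2, stats::sd)
  scale_[scale_ == 0] <- 1
  xs <- sweep(sweep(x, 2, center), 2, scale_, "/")
  # fit along a short decreasing path ending at the requested penalty;
  # warm starts keep the solver stable on strongly unbalanced folds
  path <- lambda * c(100, 20, 5, 1)
  fit <- glmnet::glmnet(xs, y, family = "binomial", alpha = 0,
                        lambda = path, standardize = FALSE,
                        thresh = 1e-10, maxit = 1e6)
  k <- length(path)
  beta <- as.numeric(fit$beta[, k])
  list(intercept = as.numeric(fit$a0[k]), beta = setNames(beta, colnames(x)),
       center = center, scale = scale_)
}

.predict_core <- function(core, x) {
  xs <- sweep(sweep(x, 2, core$center), 2, core$scale, "/")
  plogis(core$intercept + drop(xs %*% core$beta))
}

#' Fit a logistic PPI classifier
#'
#' Trains a logistic regression on the gold-standard pairs present in the
#' feature table, using either the five MS-derived features (`"ms_only"`) or
#' all eight including the genome-context scores (`"ms_string"`). Features
#' are z-scaled on the training data; a light fixed ridge penalty keeps the
#' fit defined on separable data. The fit is deterministic.
#'
#' @param features Feature tibble from [assemble_features()].
#' @param gold Gold-standard tibble from [gold_standard()].
#' @param model_kind `"ms_string"` (default) or `"ms_only"`.
#' @param lambda Ridge penalty.
#' @return An object of class `coelution_fit` with [tidy()] and [glance()]
#'   methods and a [predict][predict.coelution_fit] method returning
#'   interaction probabilities.
#' @export
fit_logistic <- function(features, gold, model_kind = c("ms_string", "ms_only"),
                         lambda = 0.01) {
  model_kind <- match.arg(model_kind)
  cols <- .model_features(model_kind)
  features <- select(as_tibble(features), "protein_a", "protein_b",
                     all_of(cols))
  gold <- select(as_tibble(gold), "protein_a", "protein_b", "label")
  train <- inner_join(features, gold, by = c("protein_a", "protein_b"))
  if (nrow(train) == 0) stop("no gold pairs among the scored candidates")
  x <- .feature_matrix(train, cols)
  y <- as.integer(train$label == "positive")
  core <- .fit_core(x, y, lambda)
  structure(
    list(core = core, model_kind = model_kind, lambda = lambda,
         n_pos = sum(y == 1), n_neg = sum(y == 0), feature_names = cols),
    class = "coelution_fit"
  )
}

#' Predict interaction probabilities
#'
#' @param object A `coelution_fit`.
#' @param newdata Feature tibble.
#' @param ... Unused.
#' @return Numeric vector of logistic scores in (0, 1).
#' @export
predict.coelution_fit <- function(object, newdata, ...) {
  x <- .feature_matrix(newdata, object$feature_names)
  .predict_core(object$core, x)
}

#' @export
print.coelution_fit <- function(x, ...) {
  cat("<coelution_fit> ", x$model_kind, " logistic classifier\n", sep = "")
  cat("  trained on ", x$n_pos, " gold positives / ", x$n_neg,
      " gold negatives (ridge lambda = ", x$lambda, ")\n", sep = "")
  print(round(x$core$beta, 3))
  invisible(x)
}

#' @export
tidy.coelution_fit <- function(x, ...) {
  tibble(
    term = c("(Intercept)", names(x$core$beta)),
    estimate = c(x$core$intercept, unname(x$core$beta)),
    center = c(NA, unname(x$core$center)),
    scale = c(NA, unname(x$core$scale))
  )
}

#' @export
glance.coelution_fit <- function(x, ...) {
  tibble(model_kind = x$model_kind, lambda = x$lambda,
         n_pos = x$n_pos, n_neg = x$n_neg)
}

#' Write / read a plain-text model file
#'
#' Serializes a fitted classifier as `key=value` lines (coefficients plus
#' the z-scaling parameters), so a fit can be audited or reused without R
#' serialization formats.
#'
#' @param fit A `coelution_fit`.
#' @param path Output path.
#' @export
write_model <- function(fit, path) {
  stopifnot(inherits(fit, "coelution_fit"))
  lines <- c(
    paste0("model_kind=", fit$model_kind),
    paste0("lambda=", format(fit$lambda, digits = 17)),
    paste0("n_pos=", fit$n_pos),
    paste0("n_neg=", fit$n_neg),
    paste0("intercept=", format(fit$core$intercept, digits = 17)),
    paste0("beta.", names(fit$core$beta), "=",
           format(unname(fit$core$beta), digits = 17)),
    paste0("center.", names(fit$core$center), "=",
           format(unname(fit$core$center), digits = 17)),
    paste0("scale.", names(fit$core$scale), "=",
           format(unname(fit$core$scale), digits = 17))
  )
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  kv <- strsplit(readLines(path), "=", fixed = TRUE)
  keys <- vapply(kv, `[`, "", 1)
  vals <- vapply(kv, `[`, "", 2)
  get1 <- function(k) vals[keys == k]
  pick <- function(prefix) {
    sel <- startsWith(keys, prefix)
    setNames(as.numeric(vals[sel]), sub(prefix, "", keys[sel], fixed = TRUE))
  }
  structure(
    list(
      core = list(intercept = as.numeric(get1("intercept")),
                  beta = pick("beta."), center = pick("center."),
                  scale = pick("scale.")),
      model_kind = get1("model_kind"),
      lambda = as.numeric(get1("lambda")),
      n_pos = as.integer(get1("n_pos")),
      n_neg = as.integer(get1("n_neg")),
      feature_names = names(pick("beta."))
    ),
    class = "coelution_fit"
  )
}

#' Held-out scores under one-operon-out cross-validation
#'
#' Scores every candidate pair with a classifier that never saw a gold pair
#' touching the held-out operon's proteins. Folds whose operon contains no
#' gold protein share the full-gold model (their training sets are
#' identical), which keeps the procedure fast without changing any score. A
#' pair spanning two operons is validated in both folds and receives the
#' mean of its two held-out scores.
#'
#' @inheritParams fit_logistic
#' @param operon_map Tibble `protein_id`, `operon_id`; proteins missing from
#'   it become singleton operons.
#' @return Tibble `protein_a`, `protein_b`, `score`, `n_folds`, `label`
#'   (`NA` for non-gold pairs), ordered by decreasing score.
#' @export
cv_score_pairs <- function(features, gold, operon_map,
                           model_kind = c("ms_string", "ms_only"),
                           lambda = 0.01) {
  model_kind <- match.arg(model_kind)
  cols <- .model_features(model_kind)
  features <- select(as_tibble(features), "protein_a", "protein_b",
                     all_of(cols))
  gold <- select(as_tibble(gold), "protein_a", "protein_b", "label")
  gold <- semi_join(gold, features, by = c("protein_a", "protein_b"))
  if (nrow(gold) == 0) stop("no gold pairs among the scored candidates")

  prot <- unique(c(features$protein_a, features$protein_b))
  omap <- .complete_operon_map(operon_map, prot)
  op_of <- setNames(omap$operon_id, omap$protein_id)

  gold_join <- inner_join(features, gold, by = c("protein_a", "protein_b"))
  x_gold <- .feature_matrix(gold_join, cols)
  y_gold <- as.integer(gold_join$label == "positive")
  gold_op_a <- op_of[gold_join$protein_a]
  gold_op_b <- op_of[gold_join$protein_b]

  x_all <- .feature_matrix(features, cols)
  cand_op_a <- op_of[features$protein_a]
  cand_op_b <- op_of[features$protein_b]

  gold_ops <- unique(c(gold_op_a, gold_op_b))
  all_ops <- unique(c(cand_op_a, cand_op_b))

  score_sum <- numeric(nrow(features))
  n_scored <- integer(nrow(features))

  # folds for operons absent from the gold standard share the full model
  full_core <- .fit_core(x_gold, y_gold, lambda)
  plain <- !(cand_op_a %in% gold_ops) & !(cand_op_b %in% gold_ops)
  if (any(plain)) {
    p <- .predict_core(full_core, x_all[plain, , drop = FALSE])
    # such a pair is validated once per distinct touched operon
    k <- 1L + as.integer(cand_op_a[plain] != cand_op_b[plain])
    score_sum[plain] <- score_sum[plain] + k * p
    n_scored[plain] <- n_scored[plain] + k
  }

  for (op in intersect(all_ops, gold_ops)) {
    train <- gold_op_a != op & gold_op_b != op
    val <- which(cand_op_a == op | cand_op_b == op)
    if (length(val) == 0) next
    core <- .fit_core(x_gold[train, , drop = FALSE], y_gold[train], lambda)
    p <- .predict_core(core, x_all[val, , drop = FALSE])
    score_sum[val] <- score_sum[val] + p
    n_scored[val] <- n_scored[val] + 1L
  }

  out <- features |>
    select("protein_a", "protein_b") |>
    mutate(score = score_sum / pmax(n_scored, 1L), n_folds = n_scored) |>
    left_join(gold, by = c("protein_a", "protein_b")) |>
    arrange(desc(.data$score))
  if (any(out$n_folds == 0)) {
    warning(sum(out$n_folds == 0), " pair(s) were never held out and ",
            "cannot be honestly scored; excluded")
    out <- filter(out, .data$n_folds > 0)
  }
  out
}

#' Gold-count FDR at a score threshold
#'
#' The false discovery rate at threshold `t` is estimated from the gold
#' standard as (gold negatives scoring >= t) / (gold pairs scoring >= t).
#'
#' @param scored Tibble with `score` and `label` columns (as from
#'   [cv_score_pairs()]); non-gold rows (`label` `NA`) are ignored.
#' @param threshold Score threshold (inclusive).
#' @return FDR estimate in `[0, 1]`, or `NA` when no gold pair reaches the
#'   threshold (not estimable).
#' @export
fdr_at_threshold <- function(scored, threshold) {
  g <- filter(scored, !is.na(.data$label), .data$score >= threshold)
  if (nrow(g) == 0) return(NA_real_)
  sum(g$label == "negative") / nrow(g)
}

#' Gold-count FDR staircase
#'
#' Recomputes the gold-count FDR at every distinct score in the list,
#' scanning from the highest down; thresholds above the first gold pair are
#' not estimable (`NA`).
#'
#' @inheritParams fdr_at_threshold
#' @return Tibble `threshold`, `n_pos`, `n_neg`, `fdr` in decreasing
#'   threshold order.
#' @export
fdr_curve <- function(scored) {
  if (!any(!is.na(scored$label))) {
    stop("no gold pairs among the scored candidates")
  }
  g <- arrange(scored, desc(.data$score))
  tibble(
    threshold = g$score,
    n_pos = cumsum(!is.na(g$label) & g$label == "positive"),
    n_neg = cumsum(!is.na(g$label) & g$label == "negative")
  ) |>
    group_by(.data$threshold) |>
    slice_tail(n = 1) |>
    ungroup() |>
    arrange(desc(.data$threshold)) |>
    mutate(fdr = ifelse(.data$n_pos + .data$n_neg > 0,
                        .data$n_neg / (.data$n_pos + .data$n_neg),
                        NA_real_))
}

#' Threshold the score list at a target FDR
#'
#' Chooses the lowest score threshold whose gold-count FDR estimate is at or
#' below `target` (ties at the threshold are included), and predicts every
#' candidate pair scoring at least that threshold.
#'
#' @inheritParams fdr_at_threshold
#' @param target Target FDR (default 0.20).
#' @param model_kind Optional label carried into the result.
#' @return An object of class `ppi_predictions`: the scored table, the
#'   chosen threshold, its FDR estimate and the predicted pairs in
#'   decreasing score order. If the target is unattainable an empty
#'   prediction set is returned with a warning.
#' @export
threshold_for_fdr <- function(scored, target = 0.20, model_kind = NULL) {
  stopifnot(target >= 0, target <= 1)
  curve <- fdr_curve(scored)
  ok <- !is.na(curve$fdr) & curve$fdr <= target
  if (!any(ok)) {
    warning("target FDR ", target, " is unreachable; returning an empty ",
            "prediction set")
    threshold <- Inf
    fdr_estimate <- NA_real_
  } else {
    threshold <- min(curve$threshold[ok])
    fdr_estimate <- curve$fdr[curve$threshold == threshold]
  }
  predicted <- scored |>
    filter(.data$score >= threshold) |>
    arrange(desc(.data$score))
  structure(
    list(scores = scored, threshold = threshold,
         fdr_estimate = fdr_estimate, target_fdr = target,
         predicted = predicted, model_kind = model_kind, curve = curve),
    class = "ppi_predictions"
  )
}

#' @export
print.ppi_predictions <- function(x, ...) {
  cat("<ppi_predictions>",
      if (!is.null(x$model_kind)) paste0(" (", x$model_kind, ")"), "\n",
      sep = "")
  cat("  ", nrow(x$predicted), " pairs predicted at threshold ",
      signif(x$threshold, 4), " (estimated FDR ",
      signif(100 * x$fdr_estimate, 3), "%, target ",
      100 * x$target_fdr, "%)\n", sep = "")
  invisible(x)
}

#' @export
tidy.ppi_predictions <- function(x, ...) {
  mutate(x$scores, predicted = as.integer(.data$score >= x$threshold))
}

#' @export
glance.ppi_predictions <- function(x, ...) {
  tibble(
    model_kind = x$model_kind %||% NA_character_,
    n_scored = nrow(x$scores),
    n_predicted = nrow(x$predicted),
    threshold = x$threshold,
    fdr_estimate = x$fdr_estimate,
    target_fdr = x$target_fdr
  )
}

#' Select a high-confidence subset of predictions
#'
#' Splits a prediction set at a score cut into a kept (high-confidence) and a
#' discarded portion and, when annotations are supplied, reports the quality
#' metrics of both sides so the cut can be judged against benchmark pair
#' sets.
#'
#' @param predictions A `ppi_predictions`.
#' @param score_cut Keep pairs with `score >= score_cut`.
#' @param annotations Optional protein annotation tibble (see
#'   [quality_metrics()]).
#' @param references Optional named list of reference pair sets.
#' @return List of class `high_confidence_set` with elements `kept`,
#'   `discarded` (pair tibbles) and `report` (metric tibble or `NULL`).
#' @export
select_high_confidence <- function(predictions, score_cut,
                                   annotations = NULL, references = list()) {
  stopifnot(inherits(predictions, "ppi_predictions"))
  kept <- filter(predictions$predicted, .data$score >= score_cut)
  discarded <- filter(predictions$predicted, .data$score < score_cut)
  report <- NULL
  if (!is.null(annotations)) {
    report <- bind_rows(
      mutate(quality_metrics(kept, annotations, references),
             portion = "kept", n_pairs = nrow(kept)),
      mutate(quality_metrics(discarded, annotations, references),
             portion = "discarded", n_pairs = nrow(discarded))
    )
  }
  structure(list(kept = kept, discarded = discarded, report = report,
                 score_cut = score_cut),
            class = "high_confidence_set")
}

#' @export
print.high_confidence_set <- function(x, ...) {
  cat("<high_confidence_set> ", nrow(x$kept), " kept / ",
      nrow(x$discarded), " discarded at score cut ",
      signif(x$score_cut, 4), "\n", sep = "")
  if (!is.null(x$report)) print(x$report)
  invisible(x)
}
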