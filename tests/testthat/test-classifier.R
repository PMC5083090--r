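# synthetic feature tables for classifier tests (no elution data needed)
make_feature_table <- function(n, seed = 1, signal = 2) {
  set.seed(seed)
  ids <- sprintf("q%03d", seq_len(2 * n))
  y <- rep(c(1, 0), length.out = n)
  tibble::tibble(
    protein_a = ids[seq_len(n)],
    protein_b = ids[n + seq_len(n)],
    cc_sec = stats::rnorm(n, signal * y, 1),
    cc_hic = stats::rnorm(n, signal * y, 1),
    dice = stats::runif(n),
    peptide_ratio = stats::runif(n),
    min_proteins = sample(5:50, n, replace = TRUE),
    string_neighborhood = stats::runif(n) * y,
    string_cooccurrence = stats::runif(n),
    string_fusion = 0,
    label = ifelse(y == 1, "positive", "negative")
  )
}

test_that("one-operon-out folds hold out every pair touching the operon", {
  gold <- gold_standard(
    tibble::tibble(protein_a = c("a1", "b1"), protein_b = c("a2", "b2")),
    tibble::tibble(protein_a = "c1", protein_b = "c2")
  )
  cand <- dplyr::bind_rows(gold[1:2],
                           tibble::tibble(protein_a = "a1", protein_b = "b2"))
  omap <- tibble::tibble(
    protein_id = c("a1", "a2", "b1", "b2", "c1", "c2"),
    operon_id = c("O1", "O1", "O2", "O2", "O3", "O3")
  )
  folds <- one_operon_out_folds(gold, cand, omap)
  expect_equal(nrow(folds), 3)
  # disjoint operons -> validation sets disjoint at the protein level is not
  # guaranteed for spanning pairs; the spanning pair a1-b2 must be validated
  # in both O1 and O2 and trained in neither
  for (i in seq_len(nrow(folds))) {
    val <- folds$validation[[i]]
    train <- folds$train[[i]]
    members <- folds$proteins[[i]]
    in_val <- any(val$protein_a == "a1" & val$protein_b == "b2")
    expect_equal(in_val, folds$fold_id[i] %in% c("O1", "O2"))
    expect_false(any(train$protein_a == "a1" & train$protein_b == "b2"))
    # CV hygiene: no training pair touches the held-out operon
    expect_false(any(train$protein_a %in% members |
                       train$protein_b %in% members))
  }
  expect_error(one_operon_out_folds(gold, cand, omap[0, ]), "empty")
})

test_that("fold hygiene holds on random operon structures", {
  set.seed(99)
  for (rep in 1:5) {
    prot <- sprintf("p%02d", 1:20)
    omap <- tibble::tibble(protein_id = prot,
                           operon_id = sample(paste0("O", 1:6), 20,
                                              replace = TRUE))
    pick <- function(k) {
      i <- replicate(k, sort(sample(20, 2)))
      tibble::tibble(protein_a = prot[i[1, ]], protein_b = prot[i[2, ]])
    }
    gold <- gold_standard(pick(8), dplyr::anti_join(
      pick(15), pick(8), by = c("protein_a", "protein_b")))
    cand <- dplyr::distinct(dplyr::bind_rows(
      gold[c("protein_a", "protein_b")], pick(20)))
    folds <- one_operon_out_folds(gold, cand, omap)
    for (i in seq_len(nrow(folds))) {
      members <- folds$proteins[[i]]
      train <- folds$train[[i]]
      val <- folds$validation[[i]]
      expect_false(any(train$protein_a %in% members |
                         train$protein_b %in% members))
      touches <- cand$protein_a %in% members | cand$protein_b %in% members
      expect_equal(nrow(val), sum(touches))
    }
  }
})

test_that("a separable gold standard is ranked perfectly on held-out pairs", {
  f <- make_feature_table(120, seed = 2, signal = 6)
  train_rows <- seq_len(80)
  gold_train <- gold_standard(
    f[train_rows, ][f$label[train_rows] == "positive", 1:2],
    f[train_rows, ][f$label[train_rows] == "negative", 1:2])
  fit <- fit_logistic(f[train_rows, ], gold_train)
  held <- f[-train_rows, ]
  p <- predict(fit, held)
  expect_gt(min(p[held$label == "positive"]),
            max(p[held$label == "negative"]))
  expect_error(
    fit_logistic(f[train_rows, ],
                 dplyr::mutate(gold_train, label = "positive")),
    "single class")
})

test_that("label permutation destroys held-out ranking (AUC near 1/2)", {
  f <- make_feature_table(200, seed = 3, signal = 4)
  aucs <- numeric(25)
  set.seed(7)
  for (k in 1:25) {
    perm <- f
    perm$label <- sample(perm$label)
    train <- perm[1:120, ]
    held <- perm[121:200, ]
    gold <- gold_standard(train[train$label == "positive", 1:2],
                          train[train$label == "negative", 1:2])
    fit <- fit_logistic(train, gold)
    aucs[k] <- auc_of(predict(fit, held),
                      as.integer(held$label == "positive"))
  }
  expect_lt(abs(mean(aucs) - 0.5), 0.05)
})

test_that("rescaling a feature by a positive constant leaves rankings intact", {
  f <- make_feature_table(150, seed = 4)
  gold <- gold_standard(f[f$label == "positive", 1:2],
                        f[f$label == "negative", 1:2])
  fit1 <- fit_logistic(f, gold)
  f2 <- dplyr::mutate(f, cc_sec = 37 * cc_sec, dice = 0.01 * dice)
  fit2 <- fit_logistic(f2, gold)
  expect_equal(order(predict(fit1, f)), order(predict(fit2, f2)))
})

test_that("model files round-trip through the plain-text format", {
  f <- make_feature_table(60, seed = 5)
  gold <- gold_standard(f[f$label == "positive", 1:2],
                        f[f$label == "negative", 1:2])
  fit <- fit_logistic(f, gold, model_kind = "ms_only")
  path <- withr::local_tempfile(fileext = ".txt")
  write_model(fit, path)
  back <- read_model(path)
  expect_equal(predict(back, f), predict(fit, f), tolerance = 1e-12)
  expect_equal(back$model_kind, "ms_only")
})

test_that("FDR counting matches an exhaustive threshold sweep", {
  set.seed(11)
  scored <- tibble::tibble(
    protein_a = sprintf("x%02d", 1:40), protein_b = sprintf("y%02d", 1:40),
    score = round(stats::runif(40), 2),  # force ties
    label = sample(c("positive", "negative", NA), 40, replace = TRUE)
  )
  for (t in sort(unique(scored$score))) {
    g <- scored[!is.na(scored$label) & scored$score >= t, ]
    want <- if (nrow(g) == 0) NA_real_ else
      sum(g$label == "negative") / nrow(g)
    expect_equal(fdr_at_threshold(scored, t), want)
  }
  # the staircase agrees with fdr_at_threshold at each distinct gold score
  cur <- fdr_curve(scored)
  for (i in seq_len(nrow(cur))) {
    expect_equal(cur$fdr[i], fdr_at_threshold(scored, cur$threshold[i]))
  }
  # the printed-count identity: 296 positives, 773 negatives above t -> 72%
  big <- tibble::tibble(
    protein_a = sprintf("a%04d", 1:1069), protein_b = sprintf("b%04d", 1:1069),
    score = 0.9,
    label = c(rep("positive", 296), rep("negative", 773))
  )
  expect_equal(round(100 * fdr_at_threshold(big, 0.5)), 72)
})

test_that("threshold selection attains the target on enumerable score sets", {
  toy <- tibble::tibble(
    protein_a = c("a", "b", "c"), protein_b = c("x", "y", "z"),
    score = c(0.9, 0.8, 0.1),
    label = c("positive", "positive", "negative")
  )
  pred <- threshold_for_fdr(toy, target = 0.2)
  expect_lte(pred$threshold, 0.8)
  expect_equal(nrow(pred$predicted), 2)
  expect_equal(pred$fdr_estimate, 0)
  # vacuous constraint predicts everything
  all_in <- threshold_for_fdr(toy, target = 1.0)
  expect_equal(nrow(all_in$predicted), 3)
  # unreachable target -> empty set with warning
  bad <- dplyr::mutate(toy, label = c("negative", "negative", "positive"))
  expect_warning(none <- threshold_for_fdr(bad, target = 0.2), "unreachable")
  expect_equal(nrow(none$predicted), 0)
  # staircase property: the chosen threshold attains the target and the
  # next-lower distinct gold score exceeds it
  set.seed(21)
  scored <- tibble::tibble(
    protein_a = sprintf("x%03d", 1:300), protein_b = sprintf("y%03d", 1:300),
    score = stats::runif(300),
    label = sample(c("positive", "negative"), 300, replace = TRUE,
                   prob = c(0.6, 0.4))
  )
  pred <- threshold_for_fdr(scored, target = 0.25)
  expect_lte(pred$fdr_estimate, 0.25)
  lower <- pred$curve$threshold[pred$curve$threshold < pred$threshold]
  if (length(lower) > 0) {
    expect_gt(fdr_at_threshold(scored, max(lower)), 0.25)
  }
  # ties at the threshold are all included
  expect_true(all(scored$score[scored$score >= pred$threshold] %in%
                    pred$predicted$score))
})

test_that("high-confidence selection splits at the score cut", {
  toy <- tibble::tibble(
    protein_a = c("a", "b", "c"), protein_b = c("x", "y", "z"),
    score = c(0.9, 0.8, 0.6),
    label = c("positive", NA, NA)
  )
  pred <- threshold_for_fdr(toy, target = 1)
  expect_equal(nrow(select_high_confidence(pred, 0)$kept), 3)
  expect_equal(nrow(select_high_confidence(pred, 0.99)$kept), 0)
  hc <- select_high_confidence(pred, 0.7)
  expect_equal(nrow(hc$kept), 2)
  expect_equal(nrow(hc$discarded), 1)
})

test_that("cross-validated scoring averages spanning pairs and flags gold", {
  f <- make_feature_table(100, seed = 6, signal = 3)
  gold <- gold_standard(f[f$label == "positive", 1:2][1:30, ],
                        f[f$label == "negative", 1:2][1:30, ])
  omap <- tibble::tibble(
    protein_id = unique(c(f$protein_a, f$protein_b)))
  omap$operon_id <- paste0("O", seq_len(nrow(omap)) %% 10)
  scored <- cv_score_pairs(f, gold, omap, model_kind = "ms_only")
  expect_equal(nrow(scored), nrow(f))
  expect_true(all(scored$n_folds %in% 1:2))
  # pairs spanning two operons are validated twice
  span <- omap$operon_id[match(scored$protein_a, omap$protein_id)] !=
    omap$operon_id[match(scored$protein_b, omap$protein_id)]
  expect_equal(scored$n_folds, ifelse(span, 2L, 1L))
  expect_equal(sum(!is.na(scored$label)), 60)
  expect_true(all(diff(scored$score) <= 0))
})
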