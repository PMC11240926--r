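test_that("stratified folds partition each class within one sample", {
  y <- rep(c("positive", "negative"), c(10, 20))
  plan <- stratified_kfold(y, k = 5, repeats = 3, seed = 1)
  for (r in 1:3) {
    assign <- plan$folds[[r]]
    expect_setequal(unique(assign), 1:5)
    for (f in 1:5) {
      expect_equal(sum(assign == f & y == "positive"), 2)
      expect_equal(sum(assign == f & y == "negative"), 4)
    }
  }
  # deterministic; distinct shuffles across repeats
  plan2 <- stratified_kfold(y, k = 5, repeats = 3, seed = 1)
  expect_identical(plan$folds, plan2$folds)
  expect_false(identical(plan$folds[[1]], plan$folds[[2]]))
  expect_error(stratified_kfold(rep(c("positive", "negative"), c(3, 20)),
                                k = 5), "smaller than k")
})

test_that("confusion counts match an elementwise tally oracle", {
  expect_equal(confusion(rep(c(TRUE, FALSE), c(10, 20)),
                         rep(c(TRUE, FALSE), c(10, 20))),
               c(TP = 10, FN = 0, TN = 20, FP = 0))
  expect_equal(confusion(rep(c(TRUE, FALSE), c(10, 20)),
                         rep(c(FALSE, TRUE), c(10, 20))),
               c(TP = 0, FN = 10, TN = 0, FP = 20))
  set.seed(31)
  for (i in 1:10) {
    t <- sample(c(TRUE, FALSE), 50, replace = TRUE)
    p <- sample(c(TRUE, FALSE), 50, replace = TRUE)
    tally <- c(TP = 0, FN = 0, TN = 0, FP = 0)
    for (j in 1:50) {
      slot <- if (t[j] && p[j]) "TP" else if (t[j]) "FN"
              else if (p[j]) "FP" else "TN"
      tally[slot] <- tally[slot] + 1
    }
    expect_equal(confusion(t, p), tally)
  }
  expect_error(confusion(c(TRUE, FALSE), TRUE), "length mismatch")
})

test_that("metric formulas reproduce hand-computed values and limits", {
  expect_equal(classification_metrics(c(TP = 10, FN = 0, TN = 20,
                                        FP = 0)),
               c(Sn = 1, Sp = 1, Acc = 1, MCC = 1))
  expect_equal(classification_metrics(c(TP = 0, FN = 10, TN = 0,
                                        FP = 20)),
               c(Sn = 0, Sp = 0, Acc = 0, MCC = -1))
  m <- classification_metrics(c(TP = 90, FN = 10, TN = 180, FP = 20))
  expect_equal(unname(m["Sn"]), 0.9)
  expect_equal(unname(m["Sp"]), 0.9)
  expect_equal(unname(m["Acc"]), 0.9)
  expect_equal(unname(m["MCC"]),
               (90 * 180 - 20 * 10) /
                 sqrt(110 * 100 * 200 * 190))
  expect_lt(abs(unname(m["MCC"]) - 0.783), 1e-3)
  # zero denominators are undefined, not zero
  und <- classification_metrics(c(TP = 0, FN = 0, TN = 5, FP = 5))
  expect_true(is.na(und[["Sn"]]))
  expect_true(is.na(und[["MCC"]]))
  expect_equal(und[["Sp"]], 0.5)
})

test_that("metrics are invariant under sample-order permutation", {
  set.seed(32)
  t <- sample(c(TRUE, FALSE), 40, replace = TRUE, prob = c(0.4, 0.6))
  p <- sample(c(TRUE, FALSE), 40, replace = TRUE)
  perm <- sample(40)
  expect_equal(classification_metrics(confusion(t, p)),
               classification_metrics(confusion(t[perm], p[perm])))
})

test_that("AUC equals the pairwise comparison probability", {
  expect_equal(roc_auc(c(1, 1, 0, 0), c(0.9, 0.8, 0.2, 0.1))$auc, 1)
  expect_equal(roc_auc(c(1, 0, 1, 0), rep(0.5, 4))$auc, 0.5)
  expect_equal(roc_auc(c(1, 0, 1, 0), c(0.9, 0.8, 0.7, 0.1))$auc, 0.75)
  expect_error(roc_auc(c(1, 1), c(0.4, 0.6)), "both classes")
})

test_that("rank AUC equals the ROC trapezoid on random suites", {
  trapezoid <- function(roc)
    sum(diff(roc$fpr) * (utils::head(roc$tpr, -1) +
                           utils::tail(roc$tpr, -1)) / 2)
  set.seed(33)
  for (i in 1:20) {
    n <- sample(10:60, 1)
    t <- c(TRUE, FALSE, sample(c(TRUE, FALSE), n - 2, replace = TRUE))
    s <- round(runif(n), 2)  # coarse scores force ties
    r <- roc_auc(t, s)
    expect_equal(r$auc, trapezoid(r$roc), tolerance = 1e-9)
    # exhaustive pairwise oracle with half-credit ties
    pairs <- outer(s[t], s[!t], function(a, b)
      (a > b) + 0.5 * (a == b))
    expect_equal(r$auc, mean(pairs), tolerance = 1e-12)
  }
})

test_that("repeated cross-validation reports one pooled row per repeat", {
  pep <- generate_peptides(synth_config(n_pos = 30, n_neg = 60, seed = 4))
  cv <- cross_validate(pep, spec = encoder_spec("AAC"),
                       params = model_params(C = 2, gamma = 0.25),
                       k = 5, repeats = 3, seed = 9)
  expect_equal(nrow(cv$per_repeat), 3)
  expect_equal(nrow(cv$per_fold), 15)
  expect_equal(names(cv$mean), c("Sn", "Sp", "Acc", "MCC", "AUC"))
  # pooled out-of-fold scores cover the dataset exactly once
  expect_equal(nrow(cv$scores), nrow(pep))
  # repeats = 1 equals a single k-fold pass at the same seed
  cv1 <- cross_validate(pep, spec = encoder_spec("AAC"),
                        params = model_params(C = 2, gamma = 0.25),
                        k = 5, repeats = 1, seed = 9)
  expect_equal(cv1$per_repeat[1, ], cv$per_repeat[1, ])
})

test_that("differential composition finds the constructed K contrast", {
  identical_sets <- random_peptides(15, seed = 41)
  d <- differential_composition(identical_sets, identical_sets)
  expect_true(all(d$diff == 0))

  profiles <- default_profiles()
  pos <- generate_peptides(synth_config(n_pos = 200, n_neg = 0,
                                        seed = 42))
  neg <- generate_peptides(synth_config(n_pos = 0, n_neg = 200,
                                        seed = 43))
  d <- differential_composition(pos, neg, mode = "AAC")
  k_row <- d[d$feature == "K", ]
  expect_gt(k_row$diff, 0)
  expect_lt(k_row$p, 0.01)
  expect_lt(d$diff[d$feature == "D"], 0)
})

test_that("CKSAAP differential output reshapes to the 20 x 20 matrix", {
  pos <- random_peptides(10, seed = 44, prefix = "pp")
  neg <- random_peptides(10, seed = 45, prefix = "nn")
  d <- differential_composition(pos, neg, mode = "CKSAAP", k = 1)
  expect_equal(nrow(d), 400)
  m <- composition_matrix(d)
  expect_equal(dim(m), c(20, 20))
  expect_equal(m["A", "K"], d$diff[d$feature == "AxK"])
  expect_error(composition_matrix(
    differential_composition(pos, neg, mode = "AAC")), "CKSAAP")
})

test_that("positional logo statistics flag a residue pinned at one end", {
  set.seed(46)
  base <- random_peptides(60, min_len = 12, max_len = 20, seed = 47)
  pos <- base
  # force K at the C-terminal position of every positive
  pos$sequence <- paste0(substr(pos$sequence, 1,
                                nchar(pos$sequence) - 1), "K")
  pos$id <- paste0("pos_", pos$id)
  neg <- random_peptides(60, min_len = 12, max_len = 20, seed = 48)
  stats <- positional_logo_stats(pos, neg, window = 5, end = "C")
  terminal_k <- stats[stats$position == 5 & stats$symbol == "K", ]
  expect_equal(terminal_k$freq_pos, 1)
  expect_equal(terminal_k$status, "enriched")
  # frequencies at each position sum to 1 per class
  sums <- tapply(stats$freq_pos, stats$position, sum)
  expect_true(all(abs(sums - 1) < 1e-12))
  # identical classes flag nothing
  none <- positional_logo_stats(base, base, window = 5, end = "N")
  expect_true(all(none$status == "none"))
})

test_that("short sequences are skipped from logo windows with a warning", {
  pos <- peptide_set(c("a", "b"), c("KKKKKKKKKKKK", "GGG"))
  neg <- random_peptides(10, seed = 49)
  expect_warning(positional_logo_stats(pos, neg, window = 5, end = "N"),
                 "skipped")
})
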