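# Model evaluation: repeated stratified k-fold cross-validation with
# sensitivity / specificity / accuracy / MCC and ROC/AUC. Per-repeat
# metrics are computed on the pooled out-of-fold predictions, which keeps
# MCC stable on small folds; the per-fold breakdown is also reported.

#' Repeated stratified k-fold assignment
#'
#' Within each repeat the folds partition the samples and every fold's
#' class ratio is within one sample of the global ratio (class members are
#' shuffled and dealt round-robin). Repeats use different shuffles;
#' everything is deterministic given the seed.
#'
#' @param labels Class labels (`"positive"`/`"negative"` or factor).
#' @param k Number of folds (default 5).
#' @param repeats Number of repeats (default 5).
#' @param seed Integer seed.
#' @return A `fold_plan` list: `folds` (list of `repeats` integer vectors
#'   of fold ids 1..k), `k`, `repeats`, `seed`.
#' @export
stratified_kfold <- function(labels, k = 5L, repeats = 5L, seed = 1L) {
  y <- as.factor(as.character(labels))
  k <- as.integer(k); repeats <- as.integer(repeats)
  stopifnot(k >= 2, repeats >= 1)
  small <- table(y) < k
  if (any(small))
    stop("class smaller than k: ",
         paste(names(which(small)), collapse = ", "))
  set.seed(as.integer(seed))
  folds <- lapply(seq_len(repeats), function(r) {
    assign <- integer(length(y))
    for (cls in levels(y)) {
      idx <- sample(which(y == cls))
      assign[idx] <- rep_len(seq_len(k), length(idx))
    }
    assign
  })
  structure(list(folds = folds, k = k, repeats = repeats,
                 seed = as.integer(seed)), class = "fold_plan")
}

#' Confusion counts
#'
#' @param truth True labels (`"positive"`/`"negative"`, factor, or
#'   logical where `TRUE` = positive).
#' @param calls Predicted calls, same conventions.
#' @return Named integer vector `c(TP, FN, TN, FP)`.
#' @export
#' @examples
#' confusion(c(TRUE, TRUE, FALSE), c(TRUE, FALSE, FALSE))
confusion <- function(truth, calls) {
  as_pos <- function(z) {
    if (is.logical(z)) return(z)
    z <- as.character(z)
    if (!all(z %in% c("positive", "negative")))
      stop("labels must be logical or 'positive'/'negative'")
    z == "positive"
  }
  t <- as_pos(truth); p <- as_pos(calls)
  if (length(t) != length(p)) stop("length mismatch")
  c(TP = sum(t & p), FN = sum(t & !p), TN = sum(!t & !p),
    FP = sum(!t & p))
}

#' Classification metrics from confusion counts
#'
#' Sn = TP/(TP+FN), Sp = TN/(TN+FP), Acc = (TP+TN)/n and the Matthews
#' correlation coefficient
#' MCC = (TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN)).
#' A metric whose denominator is zero is undefined and reported as `NA`
#' (never coerced to 0).
#'
#' @param counts Named vector with `TP`, `FN`, `TN`, `FP` (as from
#'   [confusion()]).
#' @return Named numeric vector `c(Sn, Sp, Acc, MCC)`.
#' @export
#' @examples
#' classification_metrics(c(TP = 90, FN = 10, TN = 180, FP = 20))
classification_metrics <- function(counts) {
  tp <- as.numeric(counts[["TP"]]); fn <- as.numeric(counts[["FN"]])
  tn <- as.numeric(counts[["TN"]]); fp <- as.numeric(counts[["FP"]])
  n <- tp + fn + tn + fp
  sn <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  sp <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  acc <- if (n > 0) (tp + tn) / n else NA_real_
  denom <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  mcc <- if (denom > 0) (tp * tn - fp * fn) / sqrt(denom) else NA_real_
  c(Sn = sn, Sp = sp, Acc = acc, MCC = mcc)
}

#' ROC curve and AUC
#'
#' AUC is computed by the rank (Mann-Whitney) statistic: the probability
#' that a random positive outscores a random negative, with ties counting
#' one half. The ROC point list sweeps every distinct score as a
#' threshold; the trapezoid area under those points equals the rank AUC.
#'
#' @param truth True labels (see [confusion()]); both classes required.
#' @param scores Numeric scores, higher = more positive.
#' @return A `roc_result` list: `auc` and `roc` (data frame `threshold`,
#'   `fpr`, `tpr`, including the (0,0) and (1,1) endpoints).
#' @export
#' @examples
#' roc_auc(c(1, 0, 1, 0), c(0.9, 0.8, 0.7, 0.1))$auc  # 0.75
roc_auc <- function(truth, scores) {
  pos <- if (is.logical(truth)) truth
         else if (is.numeric(truth)) truth != 0
         else as.character(truth) == "positive"
  if (length(pos) != length(scores)) stop("length mismatch")
  n_pos <- sum(pos); n_neg <- sum(!pos)
  if (n_pos == 0 || n_neg == 0)
    stop("both classes must be present to compute a ROC curve")
  r <- rank(scores, ties.method = "average")
  auc <- (sum(r[pos]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(thr, function(t) sum(pos & scores >= t) / n_pos,
                numeric(1))
  fpr <- vapply(thr, function(t) sum(!pos & scores >= t) / n_neg,
                numeric(1))
  roc <- data.frame(threshold = c(Inf, thr), fpr = c(0, fpr),
                    tpr = c(0, tpr))
  if (roc$fpr[nrow(roc)] < 1 || roc$tpr[nrow(roc)] < 1)
    roc <- rbind(roc, data.frame(threshold = -Inf, fpr = 1, tpr = 1))
  structure(list(auc = auc, roc = roc), class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat("ROC with", nrow(x$roc), "points; AUC =",
      format(x$auc, digits = 4), "\n")
  invisible(x)
}

#' Repeated cross-validation of the ACP classifier
#'
#' Runs `repeats` rounds of stratified `k`-fold cross-validation of an
#' RBF-SVM on the encoded dataset. Within each repeat the out-of-fold
#' predictions are pooled into one confusion matrix, from which Sn, Sp,
#' Acc, MCC and AUC are computed; the report carries per-repeat values and
#' their mean and standard deviation (and the per-fold breakdown).
#'
#' @param peptides A labeled [peptide_set].
#' @param spec An [encoder_spec()].
#' @param params A [model_params()].
#' @param k,repeats Folds and repeats (default 5 x 5).
#' @param seed Integer seed driving fold assignment and training.
#' @param ss Optional secondary-structure map (see [encode_peptides()]).
#' @param threshold Probability cutoff for calls (0.5).
#' @return An `acp_cv` object: `per_repeat` (one row per repeat:
#'   Sn/Sp/Acc/MCC/AUC), `mean`, `sd`, `per_fold`, `scores` (pooled
#'   out-of-fold probabilities from the first repeat, with the truth),
#'   plus the plan, spec and params.
#' @export
cross_validate <- function(peptides, spec = encoder_spec(),
                           params = model_params(), k = 5L, repeats = 5L,
                           seed = 1L, ss = NULL, threshold = 0.5) {
  y <- .as_label_factor(peptides$label)
  features <- encode_peptides(peptides, spec, ss = ss)
  plan <- stratified_kfold(y, k = k, repeats = repeats, seed = seed)
  per_fold <- NULL
  per_repeat <- NULL
  first_scores <- NULL
  for (r in seq_len(repeats)) {
    assign <- plan$folds[[r]]
    prob <- numeric(length(y))
    for (f in seq_len(k)) {
      test <- assign == f
      m <- acp_train(features[!test, , drop = FALSE], y[!test],
                     params = params,
                     seed = seed + 1000L * r + f)
      pred <- predict(m, features[test, , drop = FALSE],
                      threshold = threshold)
      prob[test] <- pred$probability
      cc <- confusion(y[test] == "positive", pred$call)
      per_fold <- rbind(per_fold,
                        data.frame(repeat_ = r, fold = f,
                                   t(classification_metrics(cc))))
    }
    calls <- prob >= threshold
    cc <- confusion(y == "positive", calls)
    met <- classification_metrics(cc)
    auc <- roc_auc(y == "positive", prob)$auc
    per_repeat <- rbind(per_repeat,
                        data.frame(repeat_ = r, t(met), AUC = auc))
    if (r == 1)
      first_scores <- data.frame(id = peptides$id,
                                 truth = y == "positive",
                                 probability = prob,
                                 stringsAsFactors = FALSE)
  }
  metric_cols <- c("Sn", "Sp", "Acc", "MCC", "AUC")
  out <- list(per_repeat = per_repeat,
              mean = colMeans(per_repeat[metric_cols]),
              sd = apply(per_repeat[metric_cols], 2, stats::sd),
              per_fold = per_fold,
              scores = first_scores,
              plan = plan, spec = spec, params = params,
              threshold = threshold)
  class(out) <- "acp_cv"
  out
}

#' @export
print.acp_cv <- function(x, digits = 4, ...) {
  cat("Repeated cross-validation: ", x$plan$repeats, " x ", x$plan$k,
      "-fold (pooled out-of-fold confusion per repeat)\n", sep = "")
  m <- x$mean; s <- x$sd
  for (nm in names(m))
    cat(sprintf("  %-4s %s +/- %s\n", nm,
                format(m[[nm]], digits = digits),
                format(s[[nm]], digits = 3)))
  invisible(x)
}

#' @export
summary.acp_cv <- function(object, ...) {
  print(object)
  cat("Per-repeat values:\n")
  print(object$per_repeat, row.names = FALSE)
  invisible(object)
}

#' @export
plot.acp_cv <- function(x, ...) {
  r <- roc_auc(x$scores$truth, x$scores$probability)
  graphics::plot(r$roc$fpr, r$roc$tpr, type = "l",
                 xlab = "False positive rate",
                 ylab = "True positive rate",
                 main = sprintf("Out-of-fold ROC (repeat 1), AUC = %.3f",
                                r$auc), ...)
  graphics::abline(0, 1, lty = 3)
  invisible(x)
}
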