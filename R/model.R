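# RBF-kernel SVM classifier (LIBSVM via e1071) with Platt-scaled
# probabilities. The fitting front door is acp_train(); it accepts either a
# ready feature matrix or a peptide set plus an encoder spec, and returns a
# classed model object with predict/print/summary methods.

#' SVM hyperparameters
#'
#' The default cell (C = 1, gamma = 0.125) was selected by the package's
#' own [grid_search()] refined with repeated cross-validation on the
#' default synthetic screening dataset under the hybrid
#' AAC + DPC + CKSAAP encoding; retune for other encodings or data.
#'
#' @param C Cost of constraint violation (> 0).
#' @param gamma RBF kernel width (> 0).
#' @param class_weighting `"none"` (the classifier sees the native class
#'   ratio, e.g. the 1:2 positive:negative training design) or
#'   `"balanced"` (inverse-frequency weights `n / (2 * n_class)`).
#' @param probability Fit the Platt probability model (default `TRUE`).
#' @return A `model_params` list.
#' @export
model_params <- function(C = 1, gamma = 0.125,
                         class_weighting = c("none", "balanced"),
                         probability = TRUE) {
  stopifnot(is.numeric(C), C > 0, is.numeric(gamma), gamma > 0)
  p <- list(C = C, gamma = gamma,
            class_weighting = match.arg(class_weighting),
            probability = isTRUE(probability))
  class(p) <- "model_params"
  p
}

#' @export
print.model_params <- function(x, ...) {
  cat("RBF-SVM parameters: C = ", format(x$C), ", gamma = ",
      format(x$gamma), ", class weighting = ", x$class_weighting,
      ", probability = ", x$probability, "\n", sep = "")
  invisible(x)
}

.as_label_factor <- function(labels) {
  labels <- as.character(labels)
  if (anyNA(labels) || !all(labels %in% c("positive", "negative")))
    stop("labels must be 'positive' or 'negative' with no NA")
  factor(labels, levels = c("negative", "positive"))
}

#' Fit the ACP classifier
#'
#' Trains an RBF-kernel support vector machine (LIBSVM through
#' \pkg{e1071}) on encoded peptides. Features are used unscaled: every
#' encoder block is already a composition on \[0, 1\]. With
#' `probability = TRUE` the model carries a Platt-scaled probability of the
#' positive (ACP) class.
#'
#' @param x A numeric feature matrix (rows = peptides, columns named as in
#'   [feature_names()]), or a labeled [peptide_set].
#' @param ... Passed between methods.
#' @return An object of class `acp_model`.
#' @export
acp_train <- function(x, ...) UseMethod("acp_train")

#' @rdname acp_train
#' @param labels Class labels (`"positive"`/`"negative"`), one per row.
#' @param params A [model_params()] object.
#' @param seed Integer seed (the Platt fit cross-validates internally).
#' @export
acp_train.matrix <- function(x, labels, params = model_params(),
                             seed = 1L, ...) {
  y <- .as_label_factor(labels)
  if (nrow(x) != length(y)) stop("nrow(x) != length(labels)")
  if (nlevels(droplevels(y)) < 2)
    stop("training data must contain both classes")
  if (any(table(y) < 2)) stop("need >= 2 samples per class")
  if (anyNA(x) || any(!is.finite(x))) stop("non-finite feature values")
  if (is.null(colnames(x))) stop("feature matrix must have column names")
  cw <- NULL
  if (params$class_weighting == "balanced") {
    tab <- table(y)
    cw <- as.numeric(length(y) / (2 * tab))
    names(cw) <- names(tab)
  }
  set.seed(as.integer(seed))
  fit <- e1071::svm(x, y, scale = FALSE, kernel = "radial",
                    cost = params$C, gamma = params$gamma,
                    probability = params$probability,
                    class.weights = cw)
  out <- list(fit = fit, feature_names = colnames(x), params = params,
              class_weights = cw, n_per_class = as.list(table(y)),
              seed = as.integer(seed), spec = NULL)
  class(out) <- "acp_model"
  out
}

#' @rdname acp_train
#' @param spec An [encoder_spec()] used to encode the peptides (stored in
#'   the model so that `predict()` can encode new peptides identically).
#' @param ss Optional named vector of secondary-structure strings (see
#'   [encode_peptides()]).
#' @export
acp_train.data.frame <- function(x, spec = encoder_spec(),
                                 params = model_params(), ss = NULL,
                                 seed = 1L, ...) {
  if (!"label" %in% names(x) || all(is.na(x$label)))
    stop("peptide set must carry labels to train on")
  feats <- encode_peptides(x, spec, ss = ss)
  m <- acp_train(feats, labels = x$label, params = params, seed = seed)
  m$spec <- spec
  m
}

#' @export
print.acp_model <- function(x, ...) {
  cat("ACP classifier (RBF-SVM, ", length(x$feature_names),
      " features)\n", sep = "")
  cat("  trained on ", x$n_per_class$positive, " positive / ",
      x$n_per_class$negative, " negative peptides\n", sep = "")
  print(x$params)
  if (!is.null(x$spec)) print(x$spec)
  invisible(x)
}

#' @export
summary.acp_model <- function(object, ...) {
  print(object)
  cat("  support vectors:", object$fit$tot.nSV, "\n")
  invisible(object)
}

#' Predict ACP probabilities
#'
#' @param object An `acp_model`.
#' @param newdata A feature matrix with the training feature names (any
#'   column order; columns are aligned by name), or a [peptide_set] (the
#'   model must have been trained from one, so that its encoder spec is
#'   stored).
#' @param threshold Probability cutoff for the positive call (0.5).
#' @param ss Optional secondary-structure map for peptide-set input.
#' @param ... Unused.
#' @return Data frame with columns `id`, `probability` (Platt-scaled
#'   positive-class probability) and `call` (logical).
#' @export
predict.acp_model <- function(object, newdata, threshold = 0.5,
                              ss = NULL, ...) {
  if (is.data.frame(newdata)) {
    if (is.null(object$spec))
      stop("model was trained on a bare matrix; encode the peptides ",
           "yourself or train from a peptide set")
    newdata <- encode_peptides(newdata, object$spec, ss = ss)
  }
  if (!is.matrix(newdata)) stop("newdata must be a matrix or peptide set")
  if (is.null(colnames(newdata)) ||
      !setequal(colnames(newdata), object$feature_names) ||
      ncol(newdata) != length(object$feature_names))
    stop("feature names do not match the trained model")
  newdata <- newdata[, object$feature_names, drop = FALSE]
  if (!object$params$probability)
    stop("model was fitted with probability = FALSE")
  pr <- stats::predict(object$fit, newdata, probability = TRUE)
  prob <- attr(pr, "probabilities")[, "positive"]
  ids <- rownames(newdata)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(newdata)))
  data.frame(id = ids, probability = unname(prob),
             call = unname(prob >= threshold), stringsAsFactors = FALSE)
}

#' Exhaustive (C, gamma) grid search by cross-validated accuracy
#'
#' Evaluates every grid cell with stratified k-fold cross-validation and
#' returns the cell with the best mean accuracy; ties are broken toward
#' smaller C, then smaller gamma (preferring the smoother model).
#'
#' @param features Numeric feature matrix.
#' @param labels Class labels.
#' @param C_grid,gamma_grid Numeric grids. Defaults follow common LIBSVM
#'   practice: C over `2^seq(-5, 15, 2)`, gamma over `2^seq(-15, 3, 2)`.
#' @param folds Cross-validation folds (5).
#' @param seed Integer seed for fold assignment and training.
#' @param class_weighting Passed to [model_params()].
#' @return A `grid_search` list: `best` ([model_params()]) and `table`
#'   (one row per cell with mean CV accuracy).
#' @export
grid_search <- function(features, labels, C_grid = 2^seq(-5, 15, 2),
                        gamma_grid = 2^seq(-15, 3, 2), folds = 5L,
                        seed = 1L, class_weighting = "none") {
  stopifnot(length(C_grid) > 0, length(gamma_grid) > 0)
  y <- .as_label_factor(labels)
  plan <- stratified_kfold(y, k = folds, repeats = 1L, seed = seed)
  assign <- plan$folds[[1]]
  cells <- expand.grid(C = C_grid, gamma = gamma_grid,
                       KEEP.OUT.ATTRS = FALSE)
  acc <- vapply(seq_len(nrow(cells)), function(i) {
    p <- model_params(C = cells$C[i], gamma = cells$gamma[i],
                      class_weighting = class_weighting)
    correct <- 0L
    for (f in seq_len(folds)) {
      test <- assign == f
      m <- acp_train(features[!test, , drop = FALSE], y[!test],
                     params = p, seed = seed)
      pred <- predict(m, features[test, , drop = FALSE])
      correct <- correct + sum(pred$call == (y[test] == "positive"))
    }
    correct / length(y)
  }, numeric(1))
  tab <- cbind(cells, accuracy = acc)
  ord <- order(-tab$accuracy, tab$C, tab$gamma)
  best <- tab[ord[1], ]
  out <- list(best = model_params(C = best$C, gamma = best$gamma,
                                  class_weighting = class_weighting),
              table = tab)
  class(out) <- "grid_search"
  out
}

#' @export
print.grid_search <- function(x, ...) {
  cat("Grid search over", nrow(x$table), "cells; best mean CV accuracy",
      format(max(x$table$accuracy), digits = 4), "\n")
  print(x$best)
  invisible(x)
}

#' Save / load a trained model
#'
#' Serialization wraps the fitted classifier together with its feature-name
#' list and parameters; `load_acp_model()` verifies the payload and
#' `predict()` re-checks feature names, so a reloaded model reproduces
#' predictions bit-identically.
#'
#' @param model An `acp_model`.
#' @param path File path.
#' @return `save_acp_model()` returns `path` invisibly;
#'   `load_acp_model()` returns the `acp_model`.
#' @export
save_acp_model <- function(model, path) {
  stopifnot(inherits(model, "acp_model"))
  payload <- list(format = "acpscreen-model", version = 1L, model = model)
  saveRDS(payload, path)
  invisible(path)
}

#' @rdname save_acp_model
#' @export
load_acp_model <- function(path) {
  payload <- tryCatch(readRDS(path), error = function(e)
    stop("cannot read model file '", path, "': ", conditionMessage(e),
         call. = FALSE))
  if (!is.list(payload) || !identical(payload$format, "acpscreen-model") ||
      !inherits(payload$model, "acp_model"))
    stop("'", path, "' is not an acpscreen model file")
  payload$model
}
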