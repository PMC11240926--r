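# Differential composition analytics: which residues, residue pairs or
# structure states distinguish ACPs from non-ACPs, and position-specific
# (two-sample-logo style) enrichment at the termini.

.per_sequence_features <- function(peptides, mode, k, ss, denominator) {
  switch(mode,
    "AAC" = t(vapply(peptides$sequence, aac, numeric(20))),
    "CKSAAP" = t(vapply(peptides$sequence, cksaap, numeric(400), k = k,
                        denominator = denominator)),
    "SSEC" = {
      if (is.null(ss)) ss <- predict_ss_propensity(peptides)
      miss <- setdiff(peptides$id, names(ss))
      if (length(miss))
        stop("no secondary structure for: ", paste(miss, collapse = ", "))
      comp <- ssec_composition(ss[peptides$id])
      if (is.null(dim(comp))) comp <- matrix(comp, nrow = 1,
                                             dimnames = list(NULL,
                                                             names(comp)))
      comp
    })
}

# Vectorized Welch two-sample t-test on per-sequence feature columns.
.welch_p <- function(a, b) {
  m1 <- colMeans(a); m2 <- colMeans(b)
  v1 <- apply(a, 2, stats::var); v2 <- apply(b, 2, stats::var)
  n1 <- nrow(a); n2 <- nrow(b)
  se2 <- v1 / n1 + v2 / n2
  t <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * stats::pt(-abs(t), df)
  # degenerate columns: zero variance in both classes
  flat <- se2 == 0
  p[flat] <- ifelse(m1[flat] == m2[flat], 1, 0)
  p
}

#' Differential composition between peptide classes
#'
#' Computes each feature's mean per-sequence frequency in the positive and
#' negative sets, their difference (positive minus negative), a two-sided
#' Welch t-test p-value on the per-sequence frequencies, and
#' Benjamini-Hochberg q-values across the features of the mode.
#'
#' @param positives,negatives Non-empty [peptide_set]s.
#' @param mode `"AAC"` (20 residues), `"CKSAAP"` (400 ordered pairs at gap
#'   `k`) or `"SSEC"` (H/E/C fractions).
#' @param k Gap for `mode = "CKSAAP"`.
#' @param ss Optional secondary-structure map for `mode = "SSEC"`
#'   (computed with [predict_ss_propensity()] when absent).
#' @param denominator CKSAAP normalization, see [cksaap()].
#' @return A `composition_diff` data frame (`feature`, `freq_pos`,
#'   `freq_neg`, `diff`, `p`, `q`) with attributes `mode` and `k`. For
#'   CKSAAP results, [composition_matrix()] reshapes a column into the
#'   20 x 20 pair matrix.
#' @export
differential_composition <- function(positives, negatives,
                                     mode = c("AAC", "CKSAAP", "SSEC"),
                                     k = 0L, ss = NULL,
                                     denominator = "paper") {
  mode <- match.arg(mode)
  if (nrow(positives) == 0 || nrow(negatives) == 0)
    stop("both classes must be non-empty")
  a <- .per_sequence_features(positives, mode, k, ss, denominator)
  b <- .per_sequence_features(negatives, mode, k, ss, denominator)
  p <- .welch_p(a, b)
  out <- data.frame(feature = colnames(a),
                    freq_pos = colMeans(a), freq_neg = colMeans(b),
                    diff = colMeans(a) - colMeans(b),
                    p = p, q = stats::p.adjust(p, method = "BH"),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "mode") <- mode
  attr(out, "k") <- if (mode == "CKSAAP") as.integer(k) else NA_integer_
  class(out) <- c("composition_diff", class(out))
  out
}

#' Reshape a CKSAAP differential result into a 20 x 20 matrix
#'
#' @param x A `composition_diff` with `mode = "CKSAAP"`.
#' @param value Which column to spread (default `"diff"`).
#' @return 20 x 20 numeric matrix, rows = first residue, columns = second.
#' @export
composition_matrix <- function(x, value = "diff") {
  if (!identical(attr(x, "mode"), "CKSAAP"))
    stop("composition_matrix() applies to CKSAAP results")
  aa <- amino_acids()
  m <- matrix(x[[value]], nrow = 20, ncol = 20, byrow = TRUE,
              dimnames = list(aa, aa))
  m
}

#' Position-specific two-sample enrichment (logo statistics)
#'
#' At each of `window` positions counted from the chosen terminus,
#' compares symbol frequencies between the two classes with a two-sided
#' two-proportion z-test (pooled variance), flagging symbols enriched or
#' depleted in the positives at the chosen p cutoff — the statistics
#' behind a two-sample sequence logo. Sequences shorter than the window
#' are skipped with a warning.
#'
#' @param positives,negatives [peptide_set]s.
#' @param window Number of terminal positions (default 5).
#' @param end `"N"` or `"C"`.
#' @param alphabet `"residue"` (amino acids) or `"ss"` (H/E/C states; `ss`
#'   must then cover both sets or is computed with the propensity
#'   stand-in).
#' @param ss Optional named secondary-structure map.
#' @param p_cutoff Raw-p flag threshold (0.05, the logo convention).
#' @param use_q Flag on BH q-values instead of raw p.
#' @return Data frame: `position` (1 = terminal-most when `end = "C"`
#'   counts backwards from the end inward as 1..window from the window
#'   start; positions are indexed within the extracted window from N to C),
#'   `symbol`, `freq_pos`, `freq_neg`, `diff`, `p`, `q`, `status`
#'   (`"enriched"`, `"depleted"`, `"none"`).
#' @export
positional_logo_stats <- function(positives, negatives, window = 5L,
                                  end = c("N", "C"),
                                  alphabet = c("residue", "ss"),
                                  ss = NULL, p_cutoff = 0.05,
                                  use_q = FALSE) {
  end <- match.arg(end)
  alphabet <- match.arg(alphabet)
  window <- as.integer(window)
  if (nrow(positives) == 0 || nrow(negatives) == 0)
    stop("both classes must be non-empty")
  get_strings <- function(pep) {
    if (alphabet == "residue") {
      stats::setNames(pep$sequence, pep$id)
    } else {
      local_ss <- ss
      if (is.null(local_ss)) local_ss <- predict_ss_propensity(pep)
      miss <- setdiff(pep$id, names(local_ss))
      if (length(miss))
        stop("no secondary structure for: ", paste(miss, collapse = ", "))
      local_ss[pep$id]
    }
  }
  symbols <- if (alphabet == "residue") amino_acids() else c("H", "E", "C")
  window_chars <- function(strings) {
    keep <- nchar(strings) >= window
    if (!all(keep))
      warning(sum(!keep), " sequence(s) shorter than the window skipped")
    strings <- strings[keep]
    if (length(strings) == 0) stop("no sequences long enough")
    w <- vapply(strings, terminal_window, character(1), end = end,
                n = window)
    t(vapply(w, function(s) strsplit(s, "", fixed = TRUE)[[1]],
             character(window)))
  }
  a <- window_chars(get_strings(positives))
  b <- window_chars(get_strings(negatives))
  n1 <- nrow(a); n2 <- nrow(b)
  rows <- lapply(seq_len(window), function(pos) {
    c1 <- table(factor(a[, pos], levels = symbols))
    c2 <- table(factor(b[, pos], levels = symbols))
    p1 <- as.vector(c1) / n1
    p2 <- as.vector(c2) / n2
    pooled <- (as.vector(c1) + as.vector(c2)) / (n1 + n2)
    se <- sqrt(pooled * (1 - pooled) * (1 / n1 + 1 / n2))
    z <- ifelse(se > 0, (p1 - p2) / se, 0)
    p <- ifelse(se > 0, 2 * stats::pnorm(-abs(z)), 1)
    data.frame(position = pos, symbol = symbols, freq_pos = p1,
               freq_neg = p2, diff = p1 - p2, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- stats::p.adjust(out$p, method = "BH")
  crit <- if (use_q) out$q else out$p
  out$status <- ifelse(crit < p_cutoff & out$diff > 0, "enriched",
                       ifelse(crit < p_cutoff & out$diff < 0,
                              "depleted", "none"))
  rownames(out) <- NULL
  out
}
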