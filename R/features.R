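# Feature encoders: amino acid composition (AAC), dipeptide composition
# (DPC), composition of k-spaced amino acid pairs (CKSAAP), secondary
# structure element composition (SSEC), and their N-/C-terminal variants.
# Feature name order is a pure function of the encoder spec; models
# serialize the name list and refuse mismatched vectors.

.pair_names <- function() {
  aa <- amino_acids()
  as.vector(t(outer(aa, aa, paste0)))  # row-major: AA, AC, ..., YY
}

#' Declare a feature encoding
#'
#' An encoder spec is an ordered list of feature blocks drawn from `AAC`
#' (20 features), `DPC` (400), `CKSAAP` (400 per gap k), `SSEC` (3),
#' `N-AAC`/`C-AAC` (20 each) and `N-SSEC`/`C-SSEC` (3 each). The encoded
#' vector is the concatenation of the blocks in the order given.
#'
#' @param components Character vector of block names, in encoding order.
#' @param K Integer gaps for the CKSAAP block, a subset of `0:3`. Default:
#'   `1:3` when `DPC` is also present (DPC already is the k = 0 block),
#'   otherwise `0:3`.
#' @param terminal_window Residues taken from each end for the terminal
#'   blocks (default 10).
#' @param cksaap_denominator `"paper"` normalizes pair counts by `L - k`
#'   (the printed CKSAAP formula); `"pair-count"` uses `L - k - 1`, the
#'   actual number of k-gapped pairs, under which each block sums to 1.
#' @return An `encoder_spec` object.
#' @export
#' @examples
#' encoder_spec()                        # AAC + DPC + CKSAAP(1:3), dim 1620
#' encoder_spec("CKSAAP", K = 1)         # the single-gap model, dim 400
encoder_spec <- function(components = c("AAC", "DPC", "CKSAAP"), K = NULL,
                         terminal_window = 10L,
                         cksaap_denominator = c("paper", "pair-count")) {
  valid <- c("AAC", "DPC", "CKSAAP", "SSEC", "N-AAC", "C-AAC",
             "N-SSEC", "C-SSEC")
  components <- as.character(components)
  if (length(components) == 0) stop("components must be non-empty")
  bad <- setdiff(components, valid)
  if (length(bad))
    stop("unknown component(s): ", paste(bad, collapse = ", "),
         " (valid: ", paste(valid, collapse = ", "), ")")
  if (anyDuplicated(components)) stop("duplicate components")
  if (is.null(K))
    K <- if ("DPC" %in% components) 1:3 else 0:3
  K <- sort(unique(as.integer(K)))
  if ("CKSAAP" %in% components && length(K) == 0)
    stop("CKSAAP requested with empty K")
  if (!all(K %in% 0:3)) stop("K must be a subset of 0:3")
  stopifnot(terminal_window >= 1, terminal_window <= 50)
  spec <- list(components = components, K = K,
               terminal_window = as.integer(terminal_window),
               cksaap_denominator = match.arg(cksaap_denominator))
  class(spec) <- "encoder_spec"
  spec
}

#' @export
print.encoder_spec <- function(x, ...) {
  blocks <- vapply(x$components, function(cp)
    if (cp == "CKSAAP") paste0("CKSAAP(k=", paste(x$K, collapse = ","), ")")
    else cp, character(1))
  cat("Encoder spec: ", paste(blocks, collapse = " + "),
      "  [", length(feature_names(x)), " features]\n", sep = "")
  if (any(grepl("^(N|C)-", x$components)))
    cat("  terminal window:", x$terminal_window, "residues\n")
  cat("  CKSAAP denominator:", x$cksaap_denominator, "\n")
  invisible(x)
}

#' Feature names for an encoder spec
#'
#' The fixed, documented feature ordering: blocks in spec order; within a
#' block, residues alphabetically (`ACDEFGHIKLMNPQRSTVWY`), pairs in
#' row-major alphabetical order, SSEC as H, E, C.
#'
#' @param spec An [encoder_spec()].
#' @return Character vector of feature names, e.g. `"AAC:A"`,
#'   `"CKSAAP1:AxK"`, `"SSEC:H"`.
#' @export
feature_names <- function(spec) {
  aa <- amino_acids()
  pairs <- .pair_names()
  sse <- c("H", "E", "C")
  out <- lapply(spec$components, function(cp) {
    switch(cp,
      "AAC" = paste0("AAC:", aa),
      "DPC" = paste0("DPC:", pairs),
      "CKSAAP" = unlist(lapply(spec$K, function(k)
        paste0("CKSAAP", k, ":", substr(pairs, 1, 1), "x",
               substr(pairs, 2, 2)))),
      "SSEC" = paste0("SSEC:", sse),
      "N-AAC" = paste0("N-AAC:", aa),
      "C-AAC" = paste0("C-AAC:", aa),
      "N-SSEC" = paste0("N-SSEC:", sse),
      "C-SSEC" = paste0("C-SSEC:", sse))
  })
  unlist(out)
}

.check_sequence <- function(sequence) {
  if (length(sequence) != 1 || is.na(sequence) || !nzchar(sequence))
    stop("sequence must be a single non-empty string")
  chars <- strsplit(toupper(sequence), "", fixed = TRUE)[[1]]
  if (!all(chars %in% amino_acids()))
    stop("invalid residue(s): ",
         paste(unique(setdiff(chars, amino_acids())), collapse = ", "))
  chars
}

#' Amino acid composition
#'
#' Frequency of each of the 20 standard residues: `f_i = x_i / L`, where
#' `x_i` counts residue `i` and `L` is the peptide length. Sums to 1.
#'
#' @param sequence A peptide sequence string.
#' @return Named numeric vector of 20 fractions in alphabetical residue
#'   order.
#' @export
#' @examples
#' aac("MEFVAKLFKFFKDLLGKFLGNN")
aac <- function(sequence) {
  chars <- .check_sequence(sequence)
  counts <- table(factor(chars, levels = amino_acids()))
  stats::setNames(as.vector(counts) / length(chars), amino_acids())
}

#' Composition of k-spaced amino acid pairs (CKSAAP)
#'
#' For gap `k`, counts occurrences `x_ij` of ordered residue pairs
#' `(i, j)` at positions `(p, p + k + 1)` and reports
#' `f_ij = x_ij / (L - k)` (the published formula; set
#' `denominator = "pair-count"` for the combinatorially exact `L - k - 1`,
#' under which the 400 values sum to 1 — with the `L - k` denominator they
#' sum to `(L - k - 1) / (L - k)`).
#'
#' @param sequence A peptide sequence string.
#' @param k Gap: number of residues between the pair (0 = adjacent).
#' @param denominator `"paper"` (`L - k`) or `"pair-count"` (`L - k - 1`).
#' @return Named numeric vector of 400 fractions, pairs in row-major
#'   alphabetical order.
#' @export
#' @examples
#' cksaap("ACAC", k = 1)[c("AxA", "CxC")]
cksaap <- function(sequence, k, denominator = c("paper", "pair-count")) {
  denominator <- match.arg(denominator)
  chars <- .check_sequence(sequence)
  k <- as.integer(k)
  stopifnot(k >= 0)
  L <- length(chars)
  if (L <= k + 1)
    stop("no k-spaced pairs: need L > k + 1 (L = ", L, ", k = ", k, ")")
  first <- chars[seq_len(L - k - 1)]
  second <- chars[seq_len(L - k - 1) + k + 1]
  counts <- table(factor(paste0(first, second), levels = .pair_names()))
  denom <- if (denominator == "paper") L - k else L - k - 1
  nm <- paste0(substr(.pair_names(), 1, 1), "x", substr(.pair_names(), 2, 2))
  stats::setNames(as.vector(counts) / denom, nm)
}

#' Dipeptide composition
#'
#' Frequencies of adjacent ordered residue pairs; identical to
#' [cksaap()] with `k = 0`.
#'
#' @inheritParams cksaap
#' @return Named numeric vector of 400 fractions.
#' @export
dpc <- function(sequence, denominator = c("paper", "pair-count")) {
  v <- cksaap(sequence, k = 0L, denominator = denominator)
  stats::setNames(v, gsub("x", "", names(v), fixed = TRUE))
}

#' Terminal subsequence
#'
#' The first (`N`) or last (`C`) `min(n, L)` residues of a sequence, order
#' preserved.
#'
#' @param sequence A sequence (or state) string.
#' @param end `"N"` or `"C"`.
#' @param n Window size in residues.
#' @return The subsequence string.
#' @export
#' @examples
#' terminal_window("GLPVCGETCVGGTCNTPGCTCSWPVCTRD", "C", 5)
terminal_window <- function(sequence, end = c("N", "C"), n) {
  end <- match.arg(end)
  stopifnot(n >= 1)
  L <- nchar(sequence)
  n <- min(n, L)
  if (end == "N") substr(sequence, 1L, n)
  else substr(sequence, L - n + 1L, L)
}

#' Encode a peptide as a feature vector
#'
#' Concatenates the feature blocks declared in the spec, in spec order.
#' SSEC-family blocks require the peptide's secondary-structure states.
#'
#' @param sequence A peptide sequence string.
#' @param spec An [encoder_spec()].
#' @param ss Optional H/E/C state string of the same length as `sequence`;
#'   required iff the spec contains an SSEC-family block.
#' @return Named numeric vector; names equal `feature_names(spec)`.
#' @export
#' @examples
#' length(encode("MEFVAKLFKFFKDLLGKFLGNN", encoder_spec()))  # 1620
encode <- function(sequence, spec = encoder_spec(), ss = NULL) {
  stopifnot(inherits(spec, "encoder_spec"))
  needs_ss <- any(grepl("SSEC", spec$components))
  if (needs_ss) {
    if (is.null(ss))
      stop("spec contains an SSEC-family block but no secondary ",
           "structure was supplied")
    if (nchar(ss) != nchar(sequence))
      stop("secondary-structure length != sequence length")
  }
  tw <- spec$terminal_window
  blocks <- lapply(spec$components, function(cp) {
    switch(cp,
      "AAC" = aac(sequence),
      "DPC" = dpc(sequence, denominator = spec$cksaap_denominator),
      "CKSAAP" = unlist(lapply(spec$K, function(k)
        cksaap(sequence, k, denominator = spec$cksaap_denominator))),
      "SSEC" = ssec_composition(ss),
      "N-AAC" = aac(terminal_window(sequence, "N", tw)),
      "C-AAC" = aac(terminal_window(sequence, "C", tw)),
      "N-SSEC" = ssec_composition(terminal_window(ss, "N", tw)),
      "C-SSEC" = ssec_composition(terminal_window(ss, "C", tw)))
  })
  stats::setNames(unlist(blocks), feature_names(spec))
}

#' Encode a peptide set as a feature matrix
#'
#' @param peptides A [peptide_set].
#' @param spec An [encoder_spec()].
#' @param ss Optional named character vector of H/E/C strings covering
#'   every peptide id; required iff the spec contains an SSEC-family block.
#'   When required but `NULL`, states are computed with
#'   [predict_ss_propensity()].
#' @param predict_ss If `TRUE` (default), fall back to the propensity
#'   stand-in for SSEC blocks when `ss` is `NULL`; set `FALSE` to require
#'   externally predicted states.
#' @return Numeric matrix, one row per peptide (rownames = ids), columns
#'   `feature_names(spec)`.
#' @export
encode_peptides <- function(peptides, spec = encoder_spec(), ss = NULL,
                            predict_ss = TRUE) {
  needs_ss <- any(grepl("SSEC", spec$components))
  if (needs_ss && is.null(ss)) {
    if (!predict_ss)
      stop("spec contains an SSEC-family block but no secondary ",
           "structure was supplied")
    ss <- predict_ss_propensity(peptides)
  }
  if (needs_ss) {
    missing_ss <- setdiff(peptides$id, names(ss))
    if (length(missing_ss))
      stop("no secondary structure for: ",
           paste(missing_ss, collapse = ", "))
  }
  rows <- lapply(seq_len(nrow(peptides)), function(i)
    encode(peptides$sequence[i], spec,
           ss = if (needs_ss) ss[[peptides$id[i]]] else NULL))
  out <- do.call(rbind, rows)
  rownames(out) <- peptides$id
  out
}
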