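# Independent brute-force oracles and small generators used across tests.
# Everything here is deliberately written without reference to the package
# implementation paths it checks.

random_peptides <- function(n, min_len = 10, max_len = 50, seed = NULL,
                            prefix = "pep") {
  if (!is.null(seed)) set.seed(seed)
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  L <- if (min_len == max_len) rep(min_len, n)
       else sample(min_len:max_len, n, replace = TRUE)
  seqs <- vapply(L, function(l)
    paste(sample(aa, l, replace = TRUE), collapse = ""), character(1))
  peptide_set(sprintf("%s_%03d", prefix, seq_len(n)), seqs)
}

# Needleman-Wunsch dynamic program maximizing matches (match = 1,
# mismatch = 0, zero gap penalty), normalized by the shorter length.
oracle_identity <- function(a, b) {
  x <- strsplit(a, "")[[1]]
  y <- strsplit(b, "")[[1]]
  n <- length(x); m <- length(y)
  dp <- matrix(0, n + 1, m + 1)
  for (i in seq_len(n))
    for (j in seq_len(m))
      dp[i + 1, j + 1] <- max(dp[i, j + 1], dp[i + 1, j],
                              dp[i, j] + (x[i] == y[j]))
  dp[n + 1, m + 1] / min(n, m)
}

# Exhaustive position scan for k-spaced pair counts.
oracle_cksaap <- function(sequence, k, denominator = c("paper",
                                                       "pair-count")) {
  denominator <- match.arg(denominator)
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  chars <- strsplit(sequence, "")[[1]]
  L <- length(chars)
  counts <- matrix(0, 20, 20, dimnames = list(aa, aa))
  for (p in seq_len(L)) {
    q <- p + k + 1
    if (q <= L) counts[chars[p], chars[q]] <- counts[chars[p], chars[q]] + 1
  }
  denom <- if (denominator == "paper") L - k else L - k - 1
  as.vector(t(counts)) / denom  # row-major pair order
}

oracle_aac <- function(sequence) {
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  chars <- strsplit(sequence, "")[[1]]
  vapply(aa, function(r) sum(chars == r), numeric(1)) / length(chars)
}

# Transitive greedy clustering over an explicit all-pairs identity matrix,
# longest-first with id tie-break: the contract reduce_redundancy promises.
oracle_greedy_clusters <- function(peptides, threshold,
                                   identity_fun = oracle_identity) {
  ord <- order(-nchar(peptides$sequence), peptides$id)
  x <- peptides[ord, ]
  reps <- integer(0)
  assignment <- character(nrow(x))
  for (i in seq_len(nrow(x))) {
    hit <- NA
    for (r in reps) {
      if (identity_fun(x$sequence[i], x$sequence[r]) >= threshold) {
        hit <- r; break
      }
    }
    if (is.na(hit)) {
      reps <- c(reps, i)
      assignment[i] <- x$id[i]
    } else assignment[i] <- x$id[hit]
  }
  list(representative_ids = x$id[reps],
       assignment = stats::setNames(assignment, x$id))
}

# Families of point-mutated copies around seed sequences, for clustering
# tests where identity thresholds actually bite.
make_mutated_family <- function(n_seeds = 10, copies = 3, seed = 5) {
  set.seed(seed)
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  seqs <- character(0); ids <- character(0)
  for (s in seq_len(n_seeds)) {
    L <- sample(20:40, 1)
    base <- paste(sample(aa, L, replace = TRUE), collapse = "")
    seqs <- c(seqs, base); ids <- c(ids, sprintf("seed%02d", s))
    for (cp in seq_len(copies - 1)) {
      mut <- strsplit(base, "")[[1]]
      k <- sample(seq_len(max(1, round(L * 0.1))), 1)
      at <- sample(L, k)
      mut[at] <- sample(aa, k, replace = TRUE)
      seqs <- c(seqs, paste(mut, collapse = ""))
      ids <- c(ids, sprintf("seed%02d_m%d", s, cp))
    }
  }
  peptide_set(ids, seqs)
}

# Toy linearly separable two-feature data for classifier tests.
toy_separable <- function(n_per_class = 10, seed = 42, gap = 4) {
  set.seed(seed)
  x <- rbind(matrix(rnorm(2 * n_per_class), ncol = 2),
             matrix(rnorm(2 * n_per_class) + gap, ncol = 2))
  colnames(x) <- c("f1", "f2")
  rownames(x) <- sprintf("s%02d", seq_len(2 * n_per_class))
  list(x = x, y = rep(c("negative", "positive"), each = n_per_class))
}
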