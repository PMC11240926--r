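# Dataset construction: length filter, alignment-identity redundancy
# reduction (CD-HIT-style greedy clustering), labeled-dataset assembly.

#' Keep peptides within a length window
#'
#' The screening pipeline considers peptides of 10-50 residues; everything
#' outside the window is discarded. Idempotent, order preserving.
#'
#' @param peptides A [peptide_set].
#' @param min_len,max_len Inclusive residue-count bounds.
#' @return The filtered `peptide_set`.
#' @export
filter_by_length <- function(peptides, min_len = 10L, max_len = 50L) {
  stopifnot(min_len >= 1, max_len >= min_len)
  L <- nchar(peptides$sequence)
  out <- peptides[L >= min_len & L <= max_len, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Pairwise sequence identity
#'
#' Identity between two peptides, defined as the maximum number of
#' identical aligned positions under global alignment with match = 1,
#' mismatch = 0 and zero gap penalty (equivalently, the length of the
#' longest common subsequence), divided by the length of the shorter
#' sequence. This is the short-sequence identity convention used by
#' CD-HIT-style clustering. Symmetric; `pairwise_identity(a, a)` is 1.
#'
#' Computed through the C-level generalized edit distance in
#' [utils::adist()]: with insertion = deletion = 1 and substitution = 2 the
#' edit distance `d` satisfies `LCS = (nchar(a) + nchar(b) - d) / 2`.
#'
#' @param a,b Character vectors of sequences (recycled to equal length).
#' @return Numeric vector of identity fractions in \[0, 1\].
#' @export
#' @examples
#' pairwise_identity("GLPVCGETCV", "GLPICGETCF")
pairwise_identity <- function(a, b) {
  a <- toupper(as.character(a))
  b <- toupper(as.character(b))
  n <- max(length(a), length(b))
  a <- rep_len(a, n)
  b <- rep_len(b, n)
  if (any(!nzchar(a)) || any(!nzchar(b)))
    stop("sequences must be non-empty")
  d <- mapply(function(x, y)
    utils::adist(x, y, costs = list(insertions = 1, deletions = 1,
                                    substitutions = 2))[1, 1],
    a, b, USE.NAMES = FALSE)
  lcs <- (nchar(a) + nchar(b) - d) / 2
  lcs / pmin(nchar(a), nchar(b))
}

#' Greedy redundancy reduction by identity threshold
#'
#' CD-HIT-style greedy clustering: peptides are visited longest-first (ties
#' broken by id for determinism); each peptide is absorbed by the first
#' retained representative to which its [pairwise_identity()] reaches the
#' threshold, otherwise it founds a new cluster. Every removed peptide has
#' identity >= threshold to its representative; representatives are not
#' guaranteed pairwise below threshold (the usual greedy contract). The
#' word-based screening heuristics of CD-HIT itself are not reproduced;
#' at peptide scale (<= 50 residues) exact alignment identity is cheap.
#'
#' @param peptides A [peptide_set].
#' @param threshold Identity fraction in (0, 1]; e.g. 0.8 for ACP training
#'   positives, 0.5 for the non-ACP background.
#' @return A `clustering_result` list with elements `representatives`
#'   (a `peptide_set`), `members` (data frame `removed_id`,
#'   `representative_id`, `identity`) and `threshold`.
#' @export
reduce_redundancy <- function(peptides, threshold) {
  stopifnot(is.numeric(threshold), threshold > 0, threshold <= 1)
  ord <- order(-nchar(peptides$sequence), peptides$id)
  x <- peptides[ord, , drop = FALSE]
  n <- nrow(x)
  rep_idx <- integer(0)          # indices into x, in creation order
  assigned_to <- character(0)
  removed <- character(0)
  identity <- numeric(0)
  for (i in seq_len(n)) {
    if (length(rep_idx)) {
      ident <- pairwise_identity(x$sequence[i], x$sequence[rep_idx])
      hit <- which(ident >= threshold)
    } else hit <- integer(0)
    if (length(hit)) {
      removed <- c(removed, x$id[i])
      assigned_to <- c(assigned_to, x$id[rep_idx[hit[1]]])
      identity <- c(identity, ident[hit[1]])
    } else {
      rep_idx <- c(rep_idx, i)
    }
  }
  reps <- x[rep_idx, , drop = FALSE]
  rownames(reps) <- NULL
  out <- list(representatives = reps,
              members = data.frame(removed_id = removed,
                                   representative_id = assigned_to,
                                   identity = identity,
                                   stringsAsFactors = FALSE),
              threshold = threshold)
  class(out) <- "clustering_result"
  out
}

#' @export
print.clustering_result <- function(x, ...) {
  cat("Greedy identity clustering at threshold ", x$threshold, ": ",
      nrow(x$representatives), " representative(s), ",
      nrow(x$members), " removed\n", sep = "")
  invisible(x)
}

#' Merge positive and negative peptides into a labeled dataset
#'
#' Labels the two collections, checks id disjointness, and shuffles the
#' merged set with a stated seed so that downstream fold assignment never
#' sees class-blocked input order.
#'
#' @param positives,negatives [peptide_set]s with disjoint ids.
#' @param seed Integer shuffle seed.
#' @return A labeled, shuffled `peptide_set` with attributes `n_pos`,
#'   `n_neg` and `seed`.
#' @export
assemble_dataset <- function(positives, negatives, seed = 17L) {
  clash <- intersect(positives$id, negatives$id)
  if (length(clash))
    stop("ids present in both classes: ", paste(clash, collapse = ", "))
  positives$label <- "positive"
  negatives$label <- "negative"
  x <- rbind(as.data.frame(positives), as.data.frame(negatives))
  set.seed(as.integer(seed))
  x <- x[sample.int(nrow(x)), , drop = FALSE]
  rownames(x) <- NULL
  class(x) <- unique(c("peptide_set", class(x)))
  attr(x, "n_pos") <- nrow(positives)
  attr(x, "n_neg") <- nrow(negatives)
  attr(x, "seed") <- as.integer(seed)
  x
}
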