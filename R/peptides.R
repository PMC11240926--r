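#' @keywords internal
"_PACKAGE"

#' The 20 standard amino acids, alphabetical one-letter codes
#'
#' Fixed residue ordering used by every encoder in the package.
#'
#' @return Character vector of length 20 (`A` through `Y`).
#' @export
#' @examples
#' amino_acids()
amino_acids <- function() {
  c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
}

#' Construct a peptide set
#'
#' A peptide set is a plain `data.frame` (class `peptide_set`) with columns
#' `id`, `sequence`, `label` and `source`. Sequences must use the 20
#' standard uppercase one-letter codes; ids must be unique within the set.
#' Labels, when present, are `"positive"` (ACP) or `"negative"` (non-ACP).
#'
#' @param id Character vector of unique identifiers.
#' @param sequence Character vector of uppercase amino-acid sequences.
#' @param label Optional class labels, `"positive"`/`"negative"` or `NA`.
#' @param source Optional free-text provenance tags.
#' @return A `peptide_set` data frame.
#' @export
#' @examples
#' peptide_set(c("p1", "p2"), c("GLFDIIKKIAESF", "KWKLFKKIEKVGQ"),
#'             label = c("positive", "negative"))
peptide_set <- function(id, sequence, label = NA_character_,
                        source = NA_character_) {
  id <- as.character(id)
  sequence <- toupper(as.character(sequence))
  if (length(id) != length(sequence))
    stop("'id' and 'sequence' must have the same length")
  label <- rep_len(as.character(label), length(id))
  source <- rep_len(as.character(source), length(id))
  x <- data.frame(id = id, sequence = sequence, label = label,
                  source = source, stringsAsFactors = FALSE)
  validate_peptides(x)
}

#' Validate a peptide set against the residue-alphabet contract
#'
#' @param x A `peptide_set` or data frame with `id` and `sequence` columns.
#' @param policy How to treat sequences with residues outside the 20-letter
#'   alphabet (X, B, Z, U, O, gaps, ...): `"strict"` raises an error,
#'   `"drop-sequence"` removes the offending records with a warning,
#'   `"strip-chars"` deletes the offending characters (records emptied by
#'   stripping are dropped with a warning).
#' @return The validated (possibly reduced) `peptide_set`.
#' @export
validate_peptides <- function(x, policy = c("strict", "drop-sequence",
                                            "strip-chars")) {
  policy <- match.arg(policy)
  stopifnot(is.data.frame(x), all(c("id", "sequence") %in% names(x)))
  if (!"label" %in% names(x)) x$label <- NA_character_
  if (!"source" %in% names(x)) x$source <- NA_character_
  x$id <- as.character(x$id)
  x$sequence <- toupper(as.character(x$sequence))
  if (anyDuplicated(x$id))
    stop("duplicate peptide ids: ",
         paste(unique(x$id[duplicated(x$id)]), collapse = ", "))
  bad_lab <- !is.na(x$label) & !x$label %in% c("positive", "negative")
  if (any(bad_lab))
    stop("labels must be 'positive', 'negative' or NA")

  ok <- grepl("^[ACDEFGHIKLMNPQRSTVWY]+$", x$sequence)
  if (!all(ok)) {
    offenders <- x$id[!ok]
    if (policy == "strict") {
      stop("sequences with non-standard residues or empty sequence: ",
           paste(offenders, collapse = ", "))
    } else if (policy == "drop-sequence") {
      warning("dropping ", sum(!ok), " sequence(s) with non-standard ",
              "residues: ", paste(offenders, collapse = ", "))
      x <- x[ok, , drop = FALSE]
    } else {
      x$sequence <- gsub("[^ACDEFGHIKLMNPQRSTVWY]", "", x$sequence)
      empty <- !nzchar(x$sequence)
      if (any(empty)) {
        warning("dropping ", sum(empty), " record(s) emptied by ",
                "stripping: ", paste(x$id[empty], collapse = ", "))
        x <- x[!empty, , drop = FALSE]
      }
    }
  }
  rownames(x) <- NULL
  class(x) <- unique(c("peptide_set", class(x)))
  x
}

#' @export
print.peptide_set <- function(x, ...) {
  n <- nrow(x)
  lab <- table(factor(x$label, levels = c("positive", "negative")))
  cat("Peptide set: ", n, " sequence(s)", sep = "")
  if (n > 0) {
    cat(", lengths ", min(nchar(x$sequence)), "-",
        max(nchar(x$sequence)), sep = "")
    if (any(!is.na(x$label)))
      cat("; ", lab[["positive"]], " positive / ",
          lab[["negative"]], " negative", sep = "")
  }
  cat("\n")
  if (n > 0) print.data.frame(utils::head(as.data.frame(x), 6))
  if (n > 6) cat("... and", n - 6, "more\n")
  invisible(x)
}

#' Peptide sequence lengths
#'
#' @param x A `peptide_set`.
#' @return Named integer vector of residue counts.
#' @export
peptide_lengths <- function(x) {
  stats::setNames(nchar(x$sequence), x$id)
}
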