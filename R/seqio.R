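# Sequence and table I/O. FASTA goes through Biostrings; prediction and
# annotation tables are plain TSV/CSV with a header.

#' Read peptides from a FASTA file
#'
#' Reads a (possibly multi-line) FASTA file into a [peptide_set]. Lowercase
#' residues are mapped to uppercase before validation. The first
#' whitespace-delimited token of each header is the peptide id.
#'
#' @param path Path to a FASTA file.
#' @param policy Residue policy applied to records containing characters
#'   outside the 20-letter alphabet; see [validate_peptides()]. The default
#'   drops offending records with a warning, which is the safe choice for
#'   natural peptides from UniProt (X/U/B are common there); use `"strict"`
#'   for curated training data.
#' @param source Optional provenance tag stored on every record.
#' @return A [peptide_set] in file order.
#' @export
#' @examples
#' fa <- system.file("extdata", "table5_peptides.fa", package = "acpscreen")
#' read_fasta(fa, policy = "strict")
read_fasta <- function(path, policy = c("drop-sequence", "strict",
                                        "strip-chars"),
                       source = NA_character_) {
  policy <- match.arg(policy)
  if (!file.exists(path)) stop("file not found: ", path)
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e)
                    stop("malformed FASTA in '", path, "': ",
                         conditionMessage(e), call. = FALSE))
  if (length(set) == 0)
    return(peptide_set(character(), character()))
  ids <- sub("\\s.*$", "", names(set))
  seqs <- as.character(set)
  empty <- !nzchar(seqs)
  if (any(empty))
    stop("malformed FASTA: empty sequence at record index ",
         paste(which(empty), collapse = ", "))
  x <- data.frame(id = ids, sequence = seqs, label = NA_character_,
                  source = rep_len(as.character(source), length(ids)),
                  stringsAsFactors = FALSE)
  validate_peptides(x, policy = policy)
}

#' Write peptides to a FASTA file
#'
#' Sequences are wrapped at 60 columns. `read_fasta(write_fasta(x))`
#' reproduces ids and sequences exactly.
#'
#' @param peptides A [peptide_set].
#' @param path Output path.
#' @param width Line-wrap width in residues.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(peptides, path, width = 60L) {
  peptides <- validate_peptides(peptides, policy = "strict")
  set <- Biostrings::AAStringSet(stats::setNames(peptides$sequence,
                                                 peptides$id))
  Biostrings::writeXStringSet(set, filepath = path, width = width)
  invisible(path)
}

#' Read a table of per-tool prediction scores
#'
#' Reads a delimited table with columns `id`, `tool` and `score` and/or
#' `call` into a normalized long-format prediction table. Scores are mapped
#' to \[0, 1\] according to the per-tool scale declared in `scales`; scales
#' are configuration, never inferred from the data, because different
#' predictors print scores under different conventions. A trailing `%` on a
#' score is stripped before parsing. Missing calls are derived by
#' thresholding the normalized score.
#'
#' @param path Path to a TSV (or CSV, by file extension) file with a header.
#' @param scales Named character vector mapping tool names to `"unit"`
#'   (scores already in \[0, 1\]) or `"percent"` (\[0, 100\], divided by 100).
#'   Tools not named fall back to `default_scale`.
#' @param default_scale Scale assumed for tools absent from `scales`.
#' @param thresholds Named numeric vector of per-tool call thresholds on the
#'   normalized scale; unnamed tools use `default_threshold`.
#' @param default_threshold Default call threshold (0.5).
#' @return A `prediction_table` data frame with columns `id`, `tool`,
#'   `score` (normalized, or `NA` when only calls are given) and `call`
#'   (logical).
#' @export
read_prediction_table <- function(path, scales = NULL,
                                  default_scale = c("unit", "percent"),
                                  thresholds = NULL,
                                  default_threshold = 0.5) {
  default_scale <- match.arg(default_scale)
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, comment.char = "#",
                           check.names = FALSE, quote = "\"")
  names(tab) <- tolower(names(tab))
  if (!all(c("id", "tool") %in% names(tab)))
    stop("prediction table needs 'id' and 'tool' columns")
  if (!any(c("score", "call") %in% names(tab)))
    stop("prediction table needs a 'score' and/or 'call' column")
  score <- if ("score" %in% names(tab)) tab$score else NA
  if (is.character(score)) score <- as.numeric(sub("%$", "", score))
  call <- if ("call" %in% names(tab)) as.logical(tab$call) else NA
  prediction_table(tab$id, tab$tool, score, call,
                   scales = scales, default_scale = default_scale,
                   thresholds = thresholds,
                   default_threshold = default_threshold)
}

#' Assemble a prediction table from vectors
#'
#' @param id,tool Character vectors (recycled to a common length).
#' @param score Numeric scores on each tool's declared scale, or `NA`.
#' @param call Logical calls, or `NA` to derive from the score threshold.
#' @inheritParams read_prediction_table
#' @return A `prediction_table` data frame.
#' @export
prediction_table <- function(id, tool, score = NA_real_, call = NA,
                             scales = NULL,
                             default_scale = c("unit", "percent"),
                             thresholds = NULL, default_threshold = 0.5) {
  default_scale <- match.arg(default_scale)
  n <- max(length(id), length(tool))
  x <- data.frame(id = rep_len(as.character(id), max(n, 0L)),
                  tool = rep_len(as.character(tool), max(n, 0L)),
                  score = rep_len(as.numeric(score), max(n, 0L)),
                  call = rep_len(as.logical(call), max(n, 0L)),
                  stringsAsFactors = FALSE)
  if (length(id) == 0) {
    x <- x[0, , drop = FALSE]
  }
  dup <- duplicated(x[c("id", "tool")])
  if (any(dup))
    stop("duplicate (id, tool) rows: ",
         paste(paste(x$id[dup], x$tool[dup], sep = "/"), collapse = ", "))

  tool_scale <- rep(default_scale, nrow(x))
  if (!is.null(scales)) {
    hit <- x$tool %in% names(scales)
    tool_scale[hit] <- unname(scales[x$tool[hit]])
  }
  if (!all(tool_scale %in% c("unit", "percent")))
    stop("scales must be 'unit' or 'percent'")
  hi <- ifelse(tool_scale == "percent", 100, 1)
  has_score <- !is.na(x$score)
  out_of_range <- has_score & (x$score < 0 | x$score > hi)
  if (any(out_of_range))
    stop("score outside declared scale for: ",
         paste(paste0(x$id[out_of_range], "/", x$tool[out_of_range],
                      "=", x$score[out_of_range]), collapse = ", "))
  x$score <- ifelse(tool_scale == "percent", x$score / 100, x$score)

  thr <- rep(default_threshold, nrow(x))
  if (!is.null(thresholds)) {
    hit <- x$tool %in% names(thresholds)
    thr[hit] <- unname(thresholds[x$tool[hit]])
  }
  derive <- is.na(x$call) & has_score
  x$call[derive] <- x$score[derive] >= thr[derive]
  if (anyNA(x$call))
    stop("rows with neither score nor call: ",
         paste(paste(x$id[is.na(x$call)], x$tool[is.na(x$call)],
                     sep = "/"), collapse = ", "))
  rownames(x) <- NULL
  class(x) <- unique(c("prediction_table", class(x)))
  x
}

#' Write a prediction table as TSV
#'
#' Writes normalized scores; `read_prediction_table()` on the result (unit
#' scale) reproduces the table.
#'
#' @param table A `prediction_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_prediction_table <- function(table, path) {
  utils::write.table(as.data.frame(table), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read peptide annotation terms
#'
#' Reads a two-column TSV (`id<TAB>term`) of annotation terms (for example
#' Gene Ontology identifiers) used by [term_enrichment()].
#'
#' @param path Path to the TSV file; a header line `id  term` is optional.
#' @return Data frame with character columns `id` and `term`.
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.table(path, header = FALSE, sep = "\t",
                           stringsAsFactors = FALSE, comment.char = "#",
                           col.names = c("id", "term"),
                           colClasses = "character")
  if (nrow(tab) > 0 && identical(tolower(unname(unlist(tab[1, ]))),
                                 c("id", "term")))
    tab <- tab[-1, , drop = FALSE]
  rownames(tab) <- NULL
  tab
}
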