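# End-to-end screen: preprocess -> encode -> train (or cross-validate) ->
# score query peptides -> merge external predictor calls -> vote -> rank
# -> optional term enrichment. Every output file carries a provenance
# header (# package version, seed, spec) so a run is reproducible from its
# own artifacts.

.provenance_header <- function(seed, spec, extra = character()) {
  c(paste0("# acpscreen ",
           as.character(utils::packageVersion("acpscreen"))),
    paste0("# seed=", seed),
    paste0("# spec=", paste(spec$components, collapse = "+"),
           "; K=", paste(spec$K, collapse = ","),
           "; denominator=", spec$cksaap_denominator),
    extra)
}

.write_tsv_with_header <- function(x, path, header) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  utils::write.table(x, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Run the full candidate screen
#'
#' Orchestrates the pipeline: length-filters and optionally
#' redundancy-reduces the training classes, assembles the labeled dataset,
#' trains the RBF-SVM on the encoded features, scores the query peptides,
#' merges the scores with any external predictor table under the
#' designated-model name `"Our Model"`, applies the vote rule, ranks the
#' nominated candidates, and (when annotations are given) tests term
#' enrichment of the candidates against the query background.
#'
#' @param positives,negatives Labeled training classes: [peptide_set]s or
#'   FASTA paths.
#' @param query Peptides to screen: a [peptide_set] or FASTA path.
#' @param external Optional external predictions: a `prediction_table` or
#'   a TSV path for [read_prediction_table()] (unit scale assumed unless a
#'   table object is given).
#' @param spec An [encoder_spec()].
#' @param params A [model_params()].
#' @param rule Vote rule, `"unanimous"` (default) or `"majority"`.
#' @param min_len,max_len Length filter bounds (10, 50).
#' @param pos_identity,neg_identity Optional redundancy-reduction identity
#'   thresholds applied within each training class (e.g. 0.8 and 0.5);
#'   `NULL` skips reduction.
#' @param annotations Optional annotation data frame (`id`, `term`) or TSV
#'   path covering the query peptides, for candidate term enrichment.
#' @param ss Optional secondary-structure map covering training and query
#'   peptides (only needed for SSEC-family specs).
#' @param seed Integer seed.
#' @param threshold Probability cutoff for the model's calls (0.5).
#' @param out_dir Optional directory: writes `predictions.tsv`,
#'   `candidates.tsv` and (if computed) `enrichment.tsv`, each with a
#'   provenance header.
#' @return An `acp_screen` list: `model`, `dataset`, `predictions` (the
#'   model's query scores), `records` (vote records), `candidates` (ranked
#'   candidates), `enrichment` (or `NULL`).
#' @export
run_screen <- function(positives, negatives, query, external = NULL,
                       spec = encoder_spec(), params = model_params(),
                       rule = c("unanimous", "majority"),
                       min_len = 10L, max_len = 50L,
                       pos_identity = NULL, neg_identity = NULL,
                       annotations = NULL, ss = NULL, seed = 17L,
                       threshold = 0.5, out_dir = NULL) {
  rule <- match.arg(rule)
  as_peptides <- function(x, src) {
    if (is.character(x) && length(x) == 1) read_fasta(x, source = src)
    else validate_peptides(x)
  }
  positives <- as_peptides(positives, "positives")
  negatives <- as_peptides(negatives, "negatives")
  query <- as_peptides(query, "query")

  positives <- filter_by_length(positives, min_len, max_len)
  negatives <- filter_by_length(negatives, min_len, max_len)
  if (!is.null(pos_identity))
    positives <- reduce_redundancy(positives, pos_identity)$representatives
  if (!is.null(neg_identity))
    negatives <- reduce_redundancy(negatives, neg_identity)$representatives
  dataset <- assemble_dataset(positives, negatives, seed = seed)

  model <- acp_train(dataset, spec = spec, params = params, ss = ss,
                     seed = seed)
  predictions <- predict(model, query, threshold = threshold, ss = ss)

  own <- prediction_table(predictions$id, "Our Model",
                          score = predictions$probability,
                          call = predictions$call)
  table <- own
  if (!is.null(external)) {
    if (is.character(external) && length(external) == 1)
      external <- read_prediction_table(external)
    if ("Our Model" %in% external$tool)
      stop("external table may not contain the designated model column")
    table <- rbind(as.data.frame(own), as.data.frame(external))
    class(table) <- unique(c("prediction_table", class(table)))
  }
  records <- integrate_votes(table, rule = rule, model = "Our Model")
  candidates <- rank_candidates(records)

  enrichment <- NULL
  if (!is.null(annotations)) {
    if (is.character(annotations) && length(annotations) == 1)
      annotations <- read_annotations(annotations)
    cand_ann <- annotations[annotations$id %in% candidates$id, ,
                            drop = FALSE]
    enrichment <- term_enrichment(cand_ann, annotations)
  }

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    hdr <- .provenance_header(seed, spec,
                              extra = paste0("# rule=", rule))
    .write_tsv_with_header(predictions,
                           file.path(out_dir, "predictions.tsv"), hdr)
    .write_tsv_with_header(candidates,
                           file.path(out_dir, "candidates.tsv"), hdr)
    if (!is.null(enrichment))
      .write_tsv_with_header(enrichment,
                             file.path(out_dir, "enrichment.tsv"), hdr)
  }
  out <- list(model = model, dataset = dataset, predictions = predictions,
              records = records, candidates = candidates,
              enrichment = enrichment, rule = rule, seed = seed)
  class(out) <- "acp_screen"
  out
}

#' @export
print.acp_screen <- function(x, ...) {
  cat("ACP screen (", x$rule, " vote, seed ", x$seed, ")\n", sep = "")
  cat("  training set: ", attr(x$dataset, "n_pos"), " positive / ",
      attr(x$dataset, "n_neg"), " negative\n", sep = "")
  cat("  query peptides scored: ", nrow(x$predictions), "\n", sep = "")
  cat("  candidates nominated:  ", nrow(x$candidates), "\n", sep = "")
  if (nrow(x$candidates) > 0) {
    cat("  top candidates:\n")
    print(utils::head(x$candidates, 5), row.names = FALSE)
  }
  invisible(x)
}
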