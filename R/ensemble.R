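# Consensus candidate nomination: integrate per-tool calls by unanimous or
# majority vote, rank candidates by the designated model's probability, and
# test annotation-term over-representation among the candidates.

#' Integrate per-tool predictions into vote records
#'
#' Pivots a long prediction table into one record per peptide and applies
#' the vote rule. Unanimity — a positive call from every declared tool —
#' is the default nomination rule; majority (positives > half the tools)
#' is available as a mode. Each record carries the designated model's
#' probability as its rank score.
#'
#' @param table A `prediction_table` (see [read_prediction_table()]).
#' @param rule `"unanimous"` or `"majority"`.
#' @param model Name of the designated ranking model; must appear in the
#'   table.
#' @param tools Tools that take part in the vote (default: every tool in
#'   the table).
#' @param missing What to do with peptides lacking a call from some tool:
#'   `"exclude"` them with a warning (default) or treat the missing call
#'   as `"negative"`.
#' @return A `prediction_records` data frame: `id`, `n_tools`, `votes`,
#'   `candidate`, `rank_score`.
#' @export
integrate_votes <- function(table, rule = c("unanimous", "majority"),
                            model, tools = NULL,
                            missing = c("exclude", "negative")) {
  rule <- match.arg(rule)
  missing <- match.arg(missing)
  if (is.null(tools)) tools <- sort(unique(table$tool))
  if (!model %in% table$tool)
    stop("designated model '", model, "' absent from the table")
  if (!model %in% tools) tools <- c(tools, model)
  tab <- table[table$tool %in% tools, , drop = FALSE]
  ids <- unique(tab$id)
  calls <- matrix(NA, nrow = length(ids), ncol = length(tools),
                  dimnames = list(ids, tools))
  calls[cbind(match(tab$id, ids), match(tab$tool, tools))] <- tab$call
  incomplete <- rowSums(is.na(calls)) > 0
  if (any(incomplete)) {
    if (missing == "exclude") {
      warning("excluding ", sum(incomplete), " peptide(s) lacking calls ",
              "from every tool: ",
              paste(utils::head(ids[incomplete], 5), collapse = ", "),
              if (sum(incomplete) > 5) ", ..." else "")
      calls <- calls[!incomplete, , drop = FALSE]
      ids <- ids[!incomplete]
    } else {
      calls[is.na(calls)] <- FALSE
    }
  }
  votes <- rowSums(calls)
  n_tools <- length(tools)
  candidate <- switch(rule,
                      unanimous = votes == n_tools,
                      majority = votes > n_tools / 2)
  model_rows <- tab[tab$tool == model, , drop = FALSE]
  rank_score <- stats::setNames(model_rows$score, model_rows$id)[ids]
  out <- data.frame(id = ids, n_tools = n_tools, votes = as.integer(votes),
                    candidate = unname(candidate),
                    rank_score = unname(rank_score),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "rule") <- rule
  attr(out, "model") <- model
  class(out) <- c("prediction_records", class(out))
  out
}

#' Rank nominated candidates
#'
#' Candidates are ordered by vote count (descending), then by the
#' designated model's probability (descending), with residual ties broken
#' by id so the ordering is deterministic.
#'
#' @param records A `prediction_records` data frame from
#'   [integrate_votes()].
#' @return The candidate rows, ordered, with a `rank` column prepended.
#' @export
rank_candidates <- function(records) {
  cand <- records[records$candidate, , drop = FALSE]
  ord <- order(-cand$votes, -cand$rank_score, cand$id)
  cand <- cand[ord, , drop = FALSE]
  rownames(cand) <- NULL
  cbind(rank = seq_len(nrow(cand)), cand)
}

#' Annotation-term over-representation among candidates
#'
#' One-sided hypergeometric test per term: the probability of drawing at
#' least the observed number of term-annotated peptides when sampling the
#' candidate set from the background, with Benjamini-Hochberg q-values
#' across all tested terms. Terms with no candidate hits are not tested.
#'
#' @param candidate_annotations Data frame (`id`, `term`) for the
#'   candidate peptides.
#' @param background_annotations Data frame (`id`, `term`) for the full
#'   background; candidate ids must be a subset of background ids.
#' @return An `enrichment_result` data frame: `term`, `candidate_hits`,
#'   `candidate_size`, `background_hits`, `background_size`, `p`, `q`,
#'   ordered by `p`.
#' @export
term_enrichment <- function(candidate_annotations,
                            background_annotations) {
  cand <- unique(candidate_annotations[c("id", "term")])
  bg <- unique(background_annotations[c("id", "term")])
  cand_ids <- unique(cand$id)
  bg_ids <- unique(bg$id)
  stray <- setdiff(cand_ids, bg_ids)
  if (length(stray))
    stop("candidate id(s) not in background: ",
         paste(stray, collapse = ", "))
  N <- length(bg_ids)
  n <- length(cand_ids)
  terms <- unique(cand$term)
  rows <- lapply(terms, function(tm) {
    K <- length(unique(bg$id[bg$term == tm]))
    hits <- length(unique(cand$id[cand$term == tm]))
    p <- stats::phyper(hits - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(term = tm, candidate_hits = hits, candidate_size = n,
               background_hits = K, background_size = N, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(term = character(), candidate_hits = integer(),
                      candidate_size = integer(),
                      background_hits = integer(),
                      background_size = integer(), p = numeric(),
                      stringsAsFactors = FALSE)
  out$q <- stats::p.adjust(out$p, method = "BH")
  out <- out[order(out$p, out$term), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("enrichment_result", class(out))
  out
}
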