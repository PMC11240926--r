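make_table <- function(calls, scores = NULL, tools = NULL) {
  # calls: matrix ids x tools of logicals
  if (is.null(tools)) tools <- colnames(calls)
  ids <- rownames(calls)
  long <- expand.grid(id = ids, tool = tools, stringsAsFactors = FALSE)
  long$call <- as.vector(calls)
  long$score <- if (is.null(scores)) ifelse(long$call, 0.9, 0.1)
                else as.vector(scores)
  prediction_table(long$id, long$tool, score = long$score,
                   call = long$call)
}

seven_tools <- c("ACPred", "ACPred-FL", "AntiCP", "AntiCP2", "iACP",
                 "mACPpred", "Our Model")

test_that("unanimity requires a positive call from every tool", {
  calls <- matrix(TRUE, nrow = 3, ncol = 7,
                  dimnames = list(c("all7", "six", "four"), seven_tools))
  calls["six", "AntiCP"] <- FALSE
  calls["four", c("AntiCP", "iACP", "ACPred")] <- FALSE
  tab <- make_table(calls)
  rec <- integrate_votes(tab, rule = "unanimous", model = "Our Model")
  expect_equal(rec$candidate, c(TRUE, FALSE, FALSE))
  expect_equal(rec$votes, c(7L, 6L, 4L))
  maj <- integrate_votes(tab, rule = "majority", model = "Our Model")
  expect_equal(maj$candidate, c(TRUE, TRUE, TRUE))   # 7, 6, 4 of 7
  expect_error(integrate_votes(tab, model = "Missing"), "absent")
})

test_that("missing calls are excluded with a warning or voted negative", {
  calls <- matrix(TRUE, nrow = 2, ncol = 2,
                  dimnames = list(c("complete", "partial"),
                                  c("toolA", "Our Model")))
  tab <- make_table(calls)
  tab <- tab[!(tab$id == "partial" & tab$tool == "toolA"), ]
  class(tab) <- c("prediction_table", "data.frame")
  expect_warning(rec <- integrate_votes(tab, model = "Our Model"),
                 "excluding")
  expect_equal(rec$id, "complete")
  rec2 <- suppressWarnings(
    integrate_votes(tab, model = "Our Model", missing = "negative"))
  expect_equal(rec2$candidate[rec2$id == "partial"], FALSE)
})

test_that("candidates rank by votes, then model score, then id", {
  calls <- matrix(TRUE, nrow = 4, ncol = 3,
                  dimnames = list(c("b", "a", "d", "c"),
                                  c("t1", "t2", "Our Model")))
  scores <- matrix(0.9, 4, 3, dimnames = dimnames(calls))
  scores[, "Our Model"] <- c(0.951, 0.996, 0.7, 0.7)
  tab <- make_table(calls, scores = scores)
  ranked <- rank_candidates(integrate_votes(tab, model = "Our Model"))
  expect_equal(ranked$id, c("a", "b", "c", "d"))
  expect_equal(ranked$rank, 1:4)
  # output is a permutation of the candidate set
  expect_setequal(ranked$id, rownames(calls))
})

test_that("unanimous candidates are a subset of majority candidates", {
  set.seed(61)
  for (i in 1:200) {
    n_tools <- sample(3:7, 1)
    n_pep <- sample(2:8, 1)
    calls <- matrix(runif(n_pep * n_tools) > 0.35, n_pep, n_tools,
                    dimnames = list(sprintf("p%02d", seq_len(n_pep)),
                                    c(head(seven_tools, n_tools - 1),
                                      "Our Model")))
    tab <- make_table(calls)
    u <- integrate_votes(tab, rule = "unanimous", model = "Our Model")
    m <- integrate_votes(tab, rule = "majority", model = "Our Model")
    expect_true(all(u$id[u$candidate] %in% m$id[m$candidate]))
  }
})

test_that("adding an all-positive tool keeps, an all-negative empties, the unanimous set", {
  set.seed(62)
  calls <- matrix(runif(30) > 0.3, 10, 3,
                  dimnames = list(sprintf("p%02d", 1:10),
                                  c("t1", "t2", "Our Model")))
  tab <- make_table(calls)
  base <- integrate_votes(tab, model = "Our Model")
  with_yes <- make_table(cbind(calls, yes = TRUE))
  expect_equal(integrate_votes(with_yes,
                               model = "Our Model")$candidate,
               base$candidate)
  with_no <- make_table(cbind(calls, no = FALSE))
  expect_false(any(integrate_votes(with_no,
                                   model = "Our Model")$candidate))
})

test_that("the packaged candidate table is unanimously positive", {
  tab <- acp_fixture_predictions()
  expect_equal(nrow(tab), 140)
  expect_equal(tab$score[tab$id == "KAB4_OLDAF" &
                           tab$tool == "Our Model"], 0.996)
  rec <- integrate_votes(tab, rule = "unanimous", model = "Our Model")
  expect_true(all(rec$candidate))
  ranked <- rank_candidates(rec)
  expect_equal(nrow(ranked), 20)
  # the two highest model probabilities top the ranking
  expect_setequal(ranked$id[1:2], c("CYO22_VIOOD", "CYPLE_PSYLE"))
})

test_that("term enrichment reproduces the exact hypergeometric tail", {
  bg <- data.frame(id = sprintf("p%03d", 1:100),
                   term = rep("other", 100))
  bg$term[1:10] <- "hit"
  extra <- data.frame(id = bg$id, term = "universal")
  bg <- rbind(bg, extra)
  cand_ids <- c(sprintf("p%03d", 1:5), sprintf("p%03d", 50:54))
  cand <- bg[bg$id %in% cand_ids, ]
  res <- term_enrichment(cand, bg)
  hit_row <- res[res$term == "hit", ]
  # oracle: explicit tail sum of the hypergeometric pmf
  oracle_p <- sum(vapply(5:10, function(x)
    choose(10, x) * choose(90, 10 - x) / choose(100, 10), numeric(1)))
  expect_equal(hit_row$p, oracle_p, tolerance = 1e-12)
  expect_equal(hit_row$candidate_hits, 5)
  expect_equal(hit_row$background_hits, 10)
  # the universal term is never significant
  expect_equal(res$p[res$term == "universal"], 1)
  # q-values are monotone in p-rank order
  expect_true(all(diff(res$q[order(res$p)]) >= -1e-12))
  expect_error(term_enrichment(data.frame(id = "zzz", term = "hit"), bg),
               "not in background")
})

test_that("uniformly drawn candidates show no enrichment in expectation", {
  set.seed(63)
  bg <- data.frame(id = rep(sprintf("p%03d", 1:200), each = 2),
                   term = sample(paste0("GO:", 1:20), 400,
                                 replace = TRUE))
  hits <- 0
  for (i in 1:20) {
    cand_ids <- sample(unique(bg$id), 20)
    res <- term_enrichment(bg[bg$id %in% cand_ids, ], bg)
    hits <- hits + sum(res$q < 0.05)
  }
  expect_lte(hits, 2)  # null draws should essentially never pass BH
})

test_that("enrichment p-values are invariant under id relabeling", {
  set.seed(64)
  bg <- data.frame(id = rep(sprintf("p%02d", 1:50), 2),
                   term = sample(c("a", "b", "c"), 100, replace = TRUE))
  cand_ids <- sprintf("p%02d", 1:10)
  res1 <- term_enrichment(bg[bg$id %in% cand_ids, ], bg)
  relabel <- stats::setNames(sprintf("q%02d", 50:1),
                             sprintf("p%02d", 1:50))
  bg2 <- bg; bg2$id <- relabel[bg$id]
  res2 <- term_enrichment(bg2[bg2$id %in% relabel[cand_ids], ], bg2)
  expect_equal(res1[order(res1$term), c("term", "p", "q")],
               res2[order(res2$term), c("term", "p", "q")])
})
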