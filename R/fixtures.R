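# Packaged fixture peptides: the natural ACP candidates nominated by the
# seven-tool consensus screen (top-20 table) and the putative ACPs taken
# into wet-lab validation (12 synthesized peptides), de-duplicated by
# UniProtKB entry name. Shipped so that every downstream module is
# exercisable without any download.

.fixture_data <- function() {
  tab <- rbind(
    c("KAB4_OLDAF",  "GLPVCGETCVGGTCNTPGCTCSWPVCTRD",                  "candidates+validated"),
    c("CYO22_VIOOD", "GLPICGETCVGGTCNTPGCTCSWPVCTRN",                  "candidates"),
    c("THN2_VISAL",  "KSCCPNTTGRNIYNTCRFGGGSREVCASLSGCKIISASTCPSYPDK", "candidates+validated"),
    c("CYH3_VIOHE",  "GLPVCGETCFGGTCNTPGCICDPWPVCTRN",                 "candidates"),
    c("MYX_CRODR",   "YKQCHKKGGHCFPKEKICIPPSSDFGKMDCRWRWKCCKKGSG",     "candidates+validated"),
    c("KAB10_OLDAF", "GLPTCGETCFGGTCNTPGCSCSSWPICTRD",                 "candidates"),
    c("PROTO_POLPI", "ILGTILGLLKSL",                                   "candidates"),
    c("CYO23_VIOOD", "GLPTCGETCFGGTCNTPGCTCDSSWPICTHN",                "candidates"),
    c("CYPLE_PSYLE", "SVTPIVCGETCFGGTCNTPGCSCSWPICTK",                 "candidates+validated"),
    c("CYPLD_PSYBR", "GLPVCGESCFGGTCNTPGCSCTWPVCTRD",                  "candidates"),
    c("ATOX_PHYTB",  "LTWKIPTRFCGVT",                                  "candidates"),
    c("CR12_RANCA",  "GLLGVLGSVAKHVLPHVVPVIAEHL",                      "candidates+validated"),
    c("KAB14_OLDAF", "GLPVCGESCFGGTCNTPGCACDPWPVCTRD",                 "candidates"),
    c("CYPLC_PSYLE", "GDLPVCGETCFGGTCNTPGCVCAWPVCTR",                  "candidates"),
    c("CYPLB_PSYLE", "GDLPICGETCFGGTCNTPGCVCAWPVCNR",                  "candidates"),
    c("GRAB_GRASX",  "IGGIISFFKRLF",                                   "candidates"),
    c("CIRF_CHAPA",  "AIPCGESCVWIPCISAAIGCSCKNKVCYR",                  "candidates+validated"),
    c("CYVNA_VIOIN", "GIPVCGETCTLGTCYTAGCSCSWPVCTRN",                  "candidates+validated"),
    c("PNG1_PANCL",  "LNWGAILKHIIK",                                   "candidates"),
    c("PSMA3_STAAN", "MEFVAKLFKFFKDLLGKFLGNN",                         "candidates+validated"),
    c("CYMEK_MELDN", "GSIPCGESCVWIPCISSVVGCACKNKVCYKN",                "validated"),
    c("CIRB_CHAPA",  "GVIPCGESCVFIPCISTLLGCSCKNKVCYRN",                "validated"),
    c("UT114_PEA",   "EQQQQQQPQNRRFRE",                                "validated"),
    c("TL11_SPIOL",  "FKGGGPYGQGVTRGQDLSGKDF",                         "validated"))
  data.frame(id = tab[, 1], sequence = tab[, 2], source = tab[, 3],
             stringsAsFactors = FALSE)
}

#' Packaged natural-ACP fixture peptides
#'
#' The consensus-screen candidate peptides and the wet-lab-validated
#' putative ACPs that ship with the package, de-duplicated by UniProtKB
#' entry name (24 unique sequences). Ids are entry names; `source` records
#' whether a peptide came from the candidate screen, the validation panel,
#' or both.
#'
#' @param source Optional filter: `"candidates"`, `"validated"`, or `NULL`
#'   (default) for all.
#' @return A [peptide_set].
#' @export
#' @examples
#' acp_fixtures()[1, ]
acp_fixtures <- function(source = NULL) {
  x <- .fixture_data()
  if (!is.null(source)) {
    source <- match.arg(source, c("candidates", "validated"))
    x <- x[grepl(source, x$source, fixed = TRUE), , drop = FALSE]
  }
  x$label <- NA_character_
  validate_peptides(x[c("id", "sequence", "label", "source")],
                    policy = "strict")
}

#' Packaged per-tool prediction scores for the candidate fixtures
#'
#' The seven-tool probability table for the 20 candidate fixture peptides
#' (six external ACP predictors plus the package's own model column), read
#' from the shipped TSV with all tools on the percent scale.
#'
#' @return A `prediction_table` (140 rows: 20 peptides x 7 tools) with
#'   scores normalized to \[0, 1\] and calls at the 0.5 threshold.
#' @export
acp_fixture_predictions <- function() {
  path <- system.file("extdata", "table4_predictions.tsv",
                      package = "acpscreen", mustWork = TRUE)
  tools <- c("ACPred", "ACPred-FL", "AntiCP", "AntiCP2", "iACP",
             "mACPpred", "Our Model")
  read_prediction_table(path,
                        scales = stats::setNames(rep("percent",
                                                     length(tools)),
                                                 tools))
}
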