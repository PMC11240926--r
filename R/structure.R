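# Three-state secondary structure (H = alpha-helix, E = beta-strand,
# C = coil). States come either from an external peptide-specific predictor
# (parsed from an SS3 file) or from the built-in propensity stand-in.

# Chou-Fasman conformational propensities (helix P_a, strand P_b).
.cf_helix <- c(A = 1.42, C = 0.70, D = 1.01, E = 1.51, F = 1.13, G = 0.57,
               H = 1.00, I = 1.08, K = 1.14, L = 1.21, M = 1.45, N = 0.67,
               P = 0.57, Q = 1.11, R = 0.98, S = 0.77, T = 0.83, V = 1.06,
               W = 1.08, Y = 0.69)
.cf_strand <- c(A = 0.83, C = 1.19, D = 0.54, E = 0.37, F = 1.38, G = 0.75,
                H = 0.87, I = 1.60, K = 0.74, L = 1.30, M = 1.05, N = 0.89,
                P = 0.55, Q = 1.10, R = 0.93, S = 0.75, T = 1.19, V = 1.70,
                W = 1.37, Y = 1.47)

#' Parse a three-state secondary-structure (SS3) file
#'
#' FASTA-like format: each header line carries a peptide id, the body lines
#' the H/E/C state string (the output convention of peptide secondary
#' structure web predictors). If `peptides` is supplied, every state string
#' must match its peptide's length.
#'
#' @param path Path to the SS3 file.
#' @param peptides Optional [peptide_set] to validate lengths against.
#' @return Named character vector of H/E/C strings, one per peptide id.
#' @export
parse_ss3 <- function(path, peptides = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e)
                    stop("malformed SS3 file '", path, "': ",
                         conditionMessage(e), call. = FALSE))
  ids <- sub("\\s.*$", "", names(set))
  states <- toupper(as.character(set))
  bad <- !grepl("^[HEC]+$", states)
  if (any(bad))
    stop("states outside {H,E,C} for: ", paste(ids[bad], collapse = ", "))
  if (anyDuplicated(ids))
    stop("duplicate ids in SS3 file: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  out <- stats::setNames(states, ids)
  if (!is.null(peptides)) {
    common <- intersect(peptides$id, ids)
    want <- stats::setNames(nchar(peptides$sequence), peptides$id)[common]
    got <- nchar(out[common])
    off <- common[want != got]
    if (length(off))
      stop("state length != sequence length for: ",
           paste(off, collapse = ", "))
  }
  out
}

#' Write secondary-structure states as an SS3 file
#'
#' @param states Named character vector of H/E/C strings.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ss3 <- function(states, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(states))
    writeLines(c(paste0(">", names(states)[i]), states[[i]]), con)
  invisible(path)
}

#' Propensity-based secondary-structure stand-in
#'
#' Deterministic per-residue H/E/C assignment from Chou-Fasman
#' conformational propensities: at each position the helix and strand
#' propensities are averaged over a sliding window (clipped at the
#' termini); the state is the argmax of the two averages when that maximum
#' exceeds the cutoff, otherwise coil; exact ties go to coil. This is a
#' self-contained first-order stand-in, not a reimplementation of any
#' neural peptide-structure predictor — parse genuine predictor output with
#' [parse_ss3()] whenever it is available.
#'
#' @param peptides A [peptide_set], or a single sequence string.
#' @param window Odd window width in residues (default 5).
#' @param cutoff Propensity threshold a state average must exceed (1.0).
#' @return Named character vector of H/E/C strings (unnamed for a bare
#'   sequence input).
#' @export
#' @examples
#' predict_ss_propensity("PPPPPPPPPP")  # proline breaks both -> all coil
predict_ss_propensity <- function(peptides, window = 5L, cutoff = 1.0) {
  stopifnot(window >= 1, window %% 2 == 1)
  seqs <- if (is.data.frame(peptides)) {
    stats::setNames(peptides$sequence, peptides$id)
  } else as.character(peptides)
  half <- (window - 1L) %/% 2L
  one <- function(s) {
    chars <- strsplit(s, "", fixed = TRUE)[[1]]
    if (!all(chars %in% names(.cf_helix)))
      stop("invalid residue in sequence")
    h <- .cf_helix[chars]
    e <- .cf_strand[chars]
    L <- length(chars)
    st <- character(L)
    for (p in seq_len(L)) {
      w <- max(1L, p - half):min(L, p + half)
      mh <- mean(h[w]); me <- mean(e[w])
      st[p] <- if (mh > cutoff && mh > me) "H"
               else if (me > cutoff && me > mh) "E"
               else "C"
    }
    paste(st, collapse = "")
  }
  out <- vapply(seqs, one, character(1))
  if (is.null(names(seqs))) unname(out) else out
}

#' Secondary-structure element composition (SSEC)
#'
#' Fractions of helix, strand and coil states in a state string; the three
#' fractions sum to 1.
#'
#' @param states A single H/E/C string, or a (named) character vector of
#'   them.
#' @return For one string, a named numeric vector `c(H=, E=, C=)`; for
#'   several, a matrix with one row per input.
#' @export
#' @examples
#' ssec_composition("HHHEEC")
ssec_composition <- function(states) {
  one <- function(s) {
    chars <- strsplit(s, "", fixed = TRUE)[[1]]
    if (length(chars) == 0 || !all(chars %in% c("H", "E", "C")))
      stop("states must be a non-empty string over {H,E,C}")
    as.vector(table(factor(chars, levels = c("H", "E", "C")))) /
      length(chars)
  }
  if (length(states) == 1)
    return(stats::setNames(one(states[[1]]), c("H", "E", "C")))
  out <- t(vapply(states, one, numeric(3)))
  colnames(out) <- c("H", "E", "C")
  out
}
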