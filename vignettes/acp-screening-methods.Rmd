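---
title: "Screening natural peptides for anticancer activity: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening natural peptides for anticancer activity: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(acpscreen)
```

## The problem

Anticancer peptides (ACPs) are short (10–50 residue) bioactive peptides
that lyse tumor cells, typically through electrostatic attraction between
their cationic residues and the anionic membrane surface of cancer cells.
Experimentally validated ACPs are scarce, so sequence-based classifiers
are used to triage large collections of natural peptides before any
wet-lab work. `acpscreen` implements such a screening pipeline end to
end: dataset construction, feature encoding, an RBF-kernel SVM
classifier, repeated cross-validated evaluation, differential composition
analytics, and consensus nomination of candidates across several
predictors.

## Dataset construction

Training data are labeled peptides (positive = ACP, negative = non-ACP)
over the 20 standard residues. Two preprocessing rules are applied:

* **Length filter.** Only peptides with 10–50 residues are retained —
  the length range within which ACPs are defined and within which the
  encoders are meaningful.
* **Redundancy reduction.** Homologous near-duplicates inflate
  cross-validation estimates. `reduce_redundancy()` performs greedy
  identity clustering in the CD-HIT style: peptides are visited
  longest-first (id as tie-break, so the procedure is deterministic), and
  each is absorbed by the first retained representative whose identity
  reaches the threshold. The convention is a 0.8 identity cutoff within
  the positive class and 0.5 within the negative class. Identity between
  two peptides is the maximum number of identical aligned positions under
  global alignment with zero gap/mismatch penalties — equivalently the
  longest-common-subsequence length — divided by the shorter sequence's
  length. At peptide scale this exact computation is cheap, so no word
  heuristics are needed. Note the greedy contract: removed peptides are
  guaranteed within-threshold of their representative, but representatives
  are not guaranteed pairwise below threshold. Cross-class near-duplicates
  are *not* removed; only within-class redundancy is addressed.

## Feature encodings

All encoders produce compositions on [0, 1] with a fixed, documented name
order (residues alphabetically, pairs row-major, structure states H, E,
C), which is what makes model serialization and feature-name checking at
prediction time safe.

* **AAC** — amino acid composition, $f_i = x_i / L$, 20 features.
* **DPC** — dipeptide composition, adjacent ordered pairs, 400 features.
* **CKSAAP** — composition of $k$-spaced amino acid pairs: ordered pairs
  of residues separated by $k$ intervening positions, with
  $f_{ij} = x_{ij} / (L - k)$ and $k \in \{0, 1, 2, 3\}$. Note that a
  sequence of length $L$ has $L - k - 1$ such pairs, so the conventional
  $L - k$ denominator leaves each 400-vector summing to
  $(L-k-1)/(L-k)$ rather than 1. The package follows the conventional
  formula by default and offers `cksaap_denominator = "pair-count"` for
  the combinatorially exact normalization; both block-sum identities are
  asserted in the test suite. In hybrid specs that contain both DPC and
  CKSAAP, the CKSAAP gaps default to $\{1, 2, 3\}$ so the dipeptide block
  is not duplicated.
* **SSEC** — secondary structure element composition: fractions of
  helix (H), strand (E) and coil (C) states. States come either from an
  external peptide-structure predictor via `parse_ss3()`, or from the
  built-in propensity stand-in (below).
* **N-/C-terminal variants** — AAC or SSEC restricted to the first or
  last 10 residues (the terminal window used for model features); the
  positional logo analytics use 5-residue windows instead, following the
  two-sample-logo convention.

`encoder_spec()` declares an ordered list of blocks; `encode()` is a pure
function of (sequence, states, spec), and the default hybrid spec
AAC + DPC + CKSAAP(1–3) has $20 + 400 + 3 \times 400 = 1620$ features.

### The secondary-structure stand-in

Peptide-specific structure predictors are web services and cannot be
embedded in a self-contained package. `predict_ss_propensity()` is a
deliberately simple, clearly-labeled stand-in: Chou–Fasman helix and
strand propensities averaged over a 5-residue window (clipped at the
termini); a position is assigned H or E when the larger average exceeds
1.0, otherwise C, with exact ties going to C. It is deterministic and
total, which is what the pipeline needs; it is *not* a reimplementation
of any neural predictor, and SSEC features are only method-faithful when
genuine predictor output is supplied through `parse_ss3()`. The window
width and cutoff are exposed as arguments.

## The classifier

The classifier is an RBF-kernel support vector machine fitted by LIBSVM
(through \pkg{e1071}), the engine conventional for this problem class.
Design choices that matter:

* **No feature scaling.** Every feature is already a composition on
  [0, 1], so the usual LIBSVM scaling step is skipped deliberately.
* **Probabilities.** Models are fitted with internal Platt scaling, and a
  peptide's score is the calibrated probability of the positive class;
  calls threshold that probability at 0.5 by default. Under the 1:2
  class imbalance of the screening design this matters: LIBSVM's native
  class decisions drift toward the majority class (measured
  cross-validated accuracy near 0.70 on the synthetic benchmark), while
  Platt-thresholded calls recover balanced operating points (near 0.90).
  The probability model's internal cross-validation is the one stochastic
  element of training, so fits are seeded.
* **Hyperparameters.** The paper trail for (C, γ) selection is
  `grid_search()`: exhaustive evaluation over
  $C \in 2^{-5..15}$, $\gamma \in 2^{-15..3}$ by stratified k-fold
  accuracy, ties broken toward smaller C then smaller γ (the smoother
  model). The package defaults (C = 1, γ = 0.125) are the optimum of that
  procedure, refined under repeated cross-validation, on the default
  synthetic dataset with the hybrid encoding; retune for other feature
  spaces.
* **Class weighting** defaults to none — the screening design trains on
  the native 1:2 ratio — with inverse-frequency (`"balanced"`) weighting
  available.

## Evaluation

`cross_validate()` runs five repeats of stratified five-fold
cross-validation by default. Within a repeat, the out-of-fold predictions
are pooled into a single confusion matrix from which sensitivity
(Sn = TP/(TP+FN)), specificity (Sp = TN/(TN+FP)), accuracy and the
Matthews correlation coefficient are computed, together with the rank
(Mann–Whitney) AUC of the pooled probabilities; the report is the
per-repeat table with mean ± standard deviation. Pooling per repeat
(rather than averaging fold-level metrics) keeps MCC well-defined on
small folds; the per-fold breakdown is also returned for readers who want
the other convention. Any metric whose denominator is zero is reported as
`NA`, never coerced to 0. ROC ties take the half-credit convention, so
the trapezoid area under the ROC point list equals the rank statistic
exactly (asserted to 1e-9 in tests).

Differential analytics mirror the usual two-sample-logo toolchain:
per-sequence feature frequencies compared by Welch's t-test (AAC, CKSAAP
matrices, SSEC) and per-position symbol frequencies compared by a
two-proportion z-test in 5-residue terminal windows, flagged at raw
p < 0.05 by default to match the logo convention, with
Benjamini–Hochberg q-values reported alongside in all outputs.

## Consensus nomination and enrichment

External ACP predictors are never called over the network; their outputs
are ingested as tables with per-tool declared score scales (scales are
configuration, not inference, because published score conventions differ
across tools — some report percentages, some unit probabilities — and
they are not comparable across tools; scores are therefore only ever
thresholded per tool, never compared between tools). `integrate_votes()`
nominates a candidate when every declared tool calls it positive
(unanimity — the operative screening filter), with majority voting as a
mode; unanimous candidates are provably a subset of majority candidates,
and both monotonicity properties (adding an all-positive or all-negative
tool) are asserted in tests. Candidates are ranked by vote count, then by
the designated model's probability, then by id for determinism.

Term enrichment of the nominated candidates against the screened
background uses the one-sided hypergeometric test with BH correction —
the community default for over-representation — treating annotation terms
as flat labels (no ontology-graph propagation).

## The synthetic generator

`generate_peptides()` emulates the compositional contrast reported for
natural ACPs: positives enriched in K, G, L, F, W and C and depleted in
N, Q, D and E, at a 1:2 positive:negative ratio with lengths uniform on
10–50. The negative profile is uniform; the positive profile multiplies
the enriched residues by 2.0 and the depleted ones by 0.5 before
renormalizing. Residues are i.i.d. within a sequence; an optional
terminal motif can be pinned at a stated position with a stated
probability. What the generator deliberately does *not* emulate:
positional structure (beyond the optional motif), residue
autocorrelation, phylogenetic redundancy, and any genuine
structure–sequence coupling — so green pipeline tests demonstrate
correct mechanics and compositional discrimination, not performance on
real peptide collections.

A consequence worth stating precisely: under this i.i.d. contrast the
Bayes-optimal rule (the exact log-likelihood ratio using the true
generating profiles) has large-sample accuracy ≈ 0.899. The package's
cross-validated SVM reaches ≈ 0.895 mean accuracy and ≈ 0.77 mean MCC on
the default 150/300 dataset — within half a point of the information
ceiling, which is the right way to read those numbers (the AUC, less
threshold-sensitive, is ≈ 0.96). Published accuracies above 0.90 on real
ACP benchmarks reflect the richer structure of real sequences that the
generator intentionally leaves out.

## Problem sizes and numerical choices

The shipped tests and the acceptance script run the full pipeline at the
default design sizes (450 training peptides, 5 × 5 cross-validation,
1620-feature hybrid encoding) and complete in about a minute; encoder
correctness is asserted against brute-force oracles at 1e-12, AUC
identities at 1e-9, and composition sums at 1e-12. Degenerate inputs have
defined behavior throughout: empty FASTA files yield empty sets,
single-class training or evaluation errors, zero-denominator metrics are
`NA`, zero-variance features in the Welch test give p = 1 (equal means)
or 0, and clustering ties are broken lexicographically.

## Known limitations

* The propensity-based structure stand-in is first-order; SSEC-family
  results with it are qualitative.
* Identity is LCS-based global identity normalized by the shorter
  sequence; other identity conventions (BLAST-style local identity,
  alignment-length normalization) will cluster differently near the
  threshold.
* Cross-class near-duplicates are not removed during preprocessing.
* External predictor thresholds default to 0.5 on each tool's normalized
  scale; published tools may use other native operating points, and the
  vote outcome depends on that configuration.
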