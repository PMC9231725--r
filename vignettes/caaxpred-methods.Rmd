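---
title: "Predicting CaaX motif prenylation and cleavage: models and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting CaaX motif prenylation and cleavage: models and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(caaxpred)
```

## The biological question

CaaX-type prenylation attaches a farnesyl or geranylgeranyl isoprenoid to
the cysteine of a C-terminal Cxxx motif. For canonical substrates this is
followed by proteolytic removal of the terminal tripeptide and
carboxymethylation; other substrates are *shunted* — prenylated but never
cleaved. Because the proteases are more stringent than the transferase,
reporters that require the full canonical pathway systematically
under-report the prenylatable sequence space. `caaxpred` models the two
steps separately: a prenylation classifier trained on hits from both a
canonical (Ras-based) and a shunt-tolerant (Ydj1p-based) yeast reporter
screen, and a cleavage classifier trained on cleaved (canonical-reporter)
versus shunted (Ydj1p-reporter) motifs. The three-way fate of a motif —
unmodified, shunted, cleaved — is always *derived* by composing the two
binary calls, with cleavage evaluated only for prenylation-positive motifs;
no three-class model is ever fit, and the package asserts the
prenyl-dependence invariant on every output.

## Training-set curation

Screen hit tables carry a 37 °C enrichment score and occurrence counts at
two temperatures. Curation follows the published arithmetic exactly:

* prenylation positives: enrichment **> 3** (strict) at 37 °C and **≥ 5**
  occurrences; union of the Ras and Ydj1p screens, minus motifs native to
  the host proteome and motifs previously built into reporters;
* prenylation negatives: enrichment **≤ 0.036** (inclusive) at 37 °C and
  **≥ 5** occurrences at 25 °C, minus proteome-native motifs;
* cleavage positives: the top-scoring Ras-screen motifs minus Ydj1p
  overlaps, proteome-native and reporter motifs; cleavage negatives: the
  Ydj1p hits minus motifs genetically confirmed to be cleaved,
  proteome-native and reporter motifs.

The comparison directions (strict `>` for positives, inclusive `≤`/`≥`
elsewhere) are taken verbatim from the curation description. Exclusion
lists are explicit file inputs rather than constants, because users
applying the package to another organism will supply their own proteome.
Final positives and negatives are checked for disjointness, and curation is
idempotent.

The deposited training-set archive itself is not redistributed. Instead,
`synthetic_screen_archive()` constructs a *synthetic stand-in*: screen
tables and exclusion lists whose cardinalities and overlap structure
reproduce the published counts (369 + 153 positive hits with 8 overlaps,
21 + 4 exclusions → 489 positives; 514 − 6 → 508 negatives; 153 − 2 − 8 −
3 → 140 cleaved; 153 − 15 − 1 − 1 → 136 shunted), with motif identities
drawn from the sequence models below. Everything that depends only on the
curation arithmetic transfers exactly; everything that depends on the
actual motif identities (CV accuracy, PCA spectra) transfers only
approximately, as discussed under *Limitations*.

## What the synthetic screens emulate

The generator mirrors the qualitative structure reported for the screens:

* **Canonical positives** (Ras-like): x1 aliphatic with probability 0.5 and
  otherwise any non-charged residue; x2 drawn from L/I/V with probability
  `aliphatic_enrichment` (default 0.9); x3 unrestricted.
* **Non-canonical positives** (Ydj1p-like): each variable position drawn
  from the polar-uncharged pool (S, T, N, Q, A, G, H) with probability 0.8.
  The archive mixes canonical and non-canonical positives at the 369:153
  ratio of the two screens.
* **Negatives**: a charged residue (D, E, K, R) at x1 or x2 with
  probability `negative_charge_bias` (default 0.7), all other positions
  uniform.

Enrichment scores are drawn log-normally around class means and clamped to
the eligible side of the curation thresholds, so threshold filters are
exercised but class counts stay exact; a block of mid-range filler rows
fails both filters by construction. All generators are pure functions of
their seed, restore the caller's RNG state, and emit the same CSV and
AAindex1 dialects the real loaders consume.

What the synthetic data does **not** emulate: the true residue-level
preferences of FTase beyond the aliphatic/polar/charged caricature,
position interactions, codon-level sampling noise of the original screens,
and the exact usage skew of the deposited motif lists. Tests passing on
synthetic screens therefore demonstrate that the pipeline is sound and that
planted signal of realistic strength is recovered — not that any particular
accuracy will be attained on the real screen data.

## Feature encodings

* **One-hot (60)**: three 20-column blocks in fixed alphabetical residue
  order; the invariant cysteine is never encoded. The encoding is injective
  and decodable, and the alphabet order is serialized with every model.
* **AAindex (3K)**: each usable AAindex1 entry contributes one column per
  variable position. Each index's 20 residue values are min–max rescaled to
  [0, 1] *across residues*, not across a training sample — this makes the
  encoding a fixed property of the index set, so no training information
  leaks through the scaling. A constant index rescales to zero. Entries
  with missing values are dropped rather than imputed; with the 553 usable
  entries of the reference database snapshot the width is 1659, and the
  parser reports its own usable count rather than enforcing 553.
* **Embedding (5E)**: a motif is presented to a frozen protein language
  model as 100 unknown-residue pad symbols plus the four motif residues;
  the adapter adds begin/end tokens and returns the per-token matrix
  (E × 106 with defaults). The four motif-residue token vectors — the
  cysteine token is kept because the model encodes context — and the
  end-of-sequence vector are retained and flattened position-major (6400
  columns at E = 1280). The adapter is a plain function contract, so the
  package installs and tests without the external model; a deterministic
  mock adapter (labelled synthetic, carrying no learned information)
  exercises the geometry.

**PCA**: exact SVD, centring only; the retained component count k is the
smallest with cumulative explained variance at or above the target
(default 0.99). Component signs follow a deterministic convention (largest
loading positive) so serialized reducers reproduce. The reducer is fit on
training features only and everything else is projected — the fitting
population is not specified in the source description, and training-only
fitting is the choice that avoids leakage.

## Scoring models

**PSSM.** Position p, residue a:
`log_odds[p, a] = ln(((c + κ)/(n + 20κ)) / q_a)` with pseudocount κ = 0.05
applied per cell (the standard Laplace reading; a per-distribution variant
would only rescale the shrinkage) and `q` the BLOSUM62 background. The
background is the marginal of the published BLOSUM62 joint target-frequency
table, embedded as data and validated against the independently published
marginal frequencies; the log-odds form of BLOSUM62 distributed with
alignment packages cannot recover these frequencies. Scores are natural-log
sums over the three variable positions (the base only rescales the cutoff,
which is calibrated on the same scale). The cutoff maximizes training
accuracy over midpoints of adjacent sorted unique scores plus sentinels,
ties resolved toward the smallest threshold; a brute-force search over all
thresholds is kept as a test oracle.

**Freq.** The original frequency method's formula is not restated in the
source this package models, so the implementation documents its own form:
per-position log2 ratio of pseudocounted class frequencies, summed. The
published decision anchors (−1 for prenylation, 0 for cleavage) are kept
fixed; scores from this implementation need not equal the original
method's scores, but the anchors partition the score axis the same way
(identical training sets give score 0; positive-only residues score
positive).

**External predictors** enter only as pre-computed score columns with the
published cutoffs, −2 (PrePS) and −1.1 (FlexPepBind), both strict — every
cutoff comparison in the package is a strict `>`, matching the published
"scoring greater than" phrasing.

## Classifiers, grid search, calibration

The four families use the implementations a practitioner would reach for
(e1071 SVM and naive Bayes, class kNN, xgboost GBDT) behind one interface.
Grids are unpublished in the source description, so defaults are
conventional: SVM over kernel/cost/width (with a `1/(d·mean var)` scale
heuristic), kNN over odd k, GBDT over trees/depth/learning rate, naive
Bayes over a variance-smoothing floor (a fraction of the largest feature
variance added to class variances, stabilizing near-constant one-hot
columns). Each grid point is scored by mean accuracy on stratified inner
folds; ties go to the earlier grid row; the winner is refit on all data.

Platt scaling fits `P(y=1|d) = plogis(a + b·d)` on *cross-validated*
decision values (never resubstitution values, which give optimistic
sigmoids) with the standard smoothed targets. Calls use probability > 0.5
when calibrated and the decision sign otherwise; probabilities are
monotone in decision values by construction. Class weighting is not
applied: both tasks are near-balanced (489/508 and 140/136).

Determinism: one integer seed controls fold assignment and any stochastic
fit (xgboost runs single-threaded with a seeded booster), so refitting
with identical inputs reproduces hyperparameters, calls and probabilities
exactly. Stratified fold assignment continues its round-robin counter
across classes, so every fold is non-empty even in leave-one-out limits.

## Evaluation conventions

Metrics are accuracy, precision, recall and F1; zero-denominator ratios
are reported as 0 with an explicit flag rather than NaN. Cross-validation
is stratified (the source description is silent; stratification preserves
the near-balanced ratio in every fold and stabilizes the reported sd) and
fold-internal: cutoff calibration and grid search happen inside the
training folds. Validation tallies follow the empirical tables' rules:
every motif is eligible for prenylation; only motifs *observed* prenylated
are eligible for cleavage. False-call rates use the method's own calls as
denominators (wrong positive calls over all positive calls), matching the
summary-table convention of the empirical comparison.

## Problem sizes and numerical choices

The test suite and the acceptance script run the full pipeline at its
native sizes — the 8000-motif space, 997/276-motif training sets, 10×10
cross-validation for the score-based models — because the score models are
cheap. Classifier grid searches in tests use reduced grids and a few
hundred motifs; grids are configuration, not study conditions, so this
changes nothing about the modelled screens. Degenerate inputs are handled
explicitly: empty positive sets, single-class labels, inseparable score
sets (the calibrated cutoff falls back to the smallest sentinel), constant
AAindex entries, proteins shorter than four residues, and adapters
returning wrong shapes all error or degrade deterministically.

## Known limitations

* Quantities tied to the identities of the deposited training motifs are
  reproduced only approximately by the synthetic stand-in. The 10-fold
  PSSM accuracies land close to the published means (≈ 85% prenylation,
  ≈ 91% cleavage); the 99%-variance component count of one-hot features
  comes out 56 here versus the published 53, because the synthetic residue
  usage is less skewed than the real screens'.
* The published global partition of the 8000-motif space (67/18/15%) was
  produced with a trained language-model feature branch; without the
  frozen external embedding source, the package reports the partition of
  its PSSM + Freq pair instead, which is qualitatively consistent
  (unmodified majority, shunted > cleaved) but more permissive for
  prenylation.
* The Freq score scale is this package's documented reimplementation, not
  the original method's; only the decision anchors are shared.
* Predictions concern motif sequence only: no statement is made about
  expression, localization, structural burial, or which of the two
  transferases or proteases acts on a substrate.
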