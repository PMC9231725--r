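# caaxpred

Prediction of CaaX motif prenylation and cleavage in R.

## The problem

Proteins ending in a C-terminal **Cxxx motif** — an invariant cysteine
followed by three variable residues — can be prenylated by
farnesyltransferase (FTase). Canonical substrates are then proteolyzed
(losing the `xxx` tripeptide) and carboxymethylated; others are **shunted**
out of the pathway after prenylation alone (the yeast Hsp40 Ydj1p, motif
`CASQ`, is the textbook example). The classical `CaaX` consensus (aliphatic
`a1`/`a2`) under-describes the true substrate range of FTase, so
consensus-based predictors miss many real substrates.

`caaxpred` classifies each of the 20³ = 8000 possible Cxxx motifs into
three fates — **unmodified**, **shunted** (prenylated only), or **cleaved**
(canonically modified) — by composing two binary predictors trained on
yeast reporter-screen data:

1. a **prenylation** model (positives from canonical Ras-based and shunted
   Ydj1p-based screens; negatives from the low-scoring tail of the Ras
   screen), and
2. a **cleavage** model applied only to prenylation-positive motifs,
   because CaaX proteolysis is prenyl-dependent.

## Models

* **PSSM** — per-position log-odds of pseudocounted residue frequencies in
  the positive set against the BLOSUM62 background distribution:
  `S(m) = Σ_p ln[ ((c_{p,a} + κ) / (n + 20κ)) / q_a ]` with pseudocount
  κ = 0.05 and `q` the marginals of the BLOSUM62 joint target-frequency
  table. A decision cutoff is calibrated by exhaustive search for the
  threshold that best separates positive from negative training scores.
* **Freq** — positional log2 frequency-ratio score
  `Σ_p log2(f⁺_{p,a} / f⁻_{p,a})` with fixed decision anchors: score > −1
  calls prenylation, score > 0 calls cleavage.
* **Four classifier families** — SVM, Gaussian naive Bayes, kNN and
  gradient-boosted trees, each grid-searched on stratified inner folds and
  optionally **Platt-scaled** into calibrated probabilities. They consume
  any of three motif encodings: one-hot sequence (60 columns), AAindex
  physico-biochemical properties (3 per index, e.g. 1659 columns for 553
  usable indices), or per-token protein language-model embeddings through
  a pluggable adapter (5 retained tokens × embedding dimension, 6400
  columns at E = 1280).
* **External predictors** (PrePS, FlexPepBind) are consumed as
  pre-computed score columns with their published cutoffs (−2 and −1.1,
  strictly exceeded).

Evaluation is stratified 10-fold cross-validation reporting accuracy,
precision, recall and F1 (mean ± sd across folds), plus agreement tallies
against tables of empirically characterized motifs.

The deposited screen tables are emulated by a fully synthetic stand-in
(`synthetic_screen_archive()`) that reproduces the published curation
arithmetic — 489/508 prenylation and 140/136 cleavage training motifs —
with synthetic motif identities drawn from the documented screen sequence
models.

## Worked example

```r
library(caaxpred)

archive <- synthetic_screen_archive(seed = 1)  # synthetic screen stand-in
sets <- curate_archive(archive)                # threshold + exclusion curation
sets$prenylation
#> <training_set: prenylation>  489 positives, 508 negatives

pren <- train_pssm(sets$prenylation)           # PSSM + calibrated cutoff
clv  <- train_freq(sets$cleavage)              # Freq with cleavage anchor 0
pren
#> <pssm_model: prenylation>  n = 489, pseudocount = 0.05, cutoff = -0.4636126

tm <- training_matrix(sets$prenylation)
cross_validate(pssm_trainer(), tm$motifs, tm$labels, k = 10, seed = 1)
#> <cv_report> 10-fold, seed 1
#>   accuracy  85.3% +/- 3.4
#>   precision 84.7% +/- 4.6
#>   recall    85.7% +/- 5.4
#>   f1        85.1% +/- 3.5

predict_motifs(pren, c("CVIA", "CASQ", "CKQQ", "CDDD"))
#>   motif       score probability  call
#> 1  CVIA  1.82153474          NA  TRUE
#> 2  CASQ -0.09098597          NA  TRUE
#> 3  CKQQ -2.14885170          NA FALSE
#> 4  CDDD -5.86885947          NA FALSE

predict_space(pren, clv)                       # full 8000-motif partition
#> <space_prediction> 8000 motifs [pssm_prenylation + freq_cleavage]
#>   unmodified  4539  (56.7%)
#>   shunted     1972  (24.6%)
#>   cleaved     1489  (18.6%)
```

The canonical a-factor motif `CVIA` and the non-canonical shunted `CASQ`
are both called prenylated; the charged `CDDD` is rejected. The score is
the summed log-odds; the call applies the calibrated cutoff strictly.
Applied to the full space, the model pair leaves the majority of motifs
unmodified and predicts more shunted than cleaved motifs among the
prenylated ones. Proteome FASTA files are scanned with
`scan_proteome(fasta, pren, clv)`; a command-line wrapper over the same
pipeline lives in `inst/scripts/caaxpred.R`.

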