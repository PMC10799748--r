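---
title: "Methods: models, encoders and design choices in kmalsite"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, encoders and design choices in kmalsite}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The prediction problem

Malonylation attaches a negatively charged malonyl group to lysine (K)
residues.  Predicting which lysines of a protein are modified is cast as
binary classification of fixed-width peptide windows: a (2n+1)-mer centered
on a candidate K, labeled positive when the site is experimentally
annotated.  `kmalsite` implements the full chain — benchmark construction,
window encoding, classification, soft-voting ensemble and evaluation — with
every statistic that could leak label information fitted strictly on
training data.

## Benchmark construction

1. **Site labeling.** Every K of a (canonicalized) protein becomes exactly
   one site: positive if annotated, negative otherwise.  Annotations whose
   residue is not K are dropped with a warning; positions beyond the
   sequence are errors.  Canonicalization maps any non-standard letter
   (B, J, U, X, Z, lowercase) to a single dummy symbol `O`, the 21st letter
   of the fixed alphabetical residue order `ACDEFGHIKLMNPQRSTVWY` + `O`.
   One dummy class keeps every encoder total on arbitrary input.
2. **Homology reduction.** A greedy longest-first reducer in the CD-HIT
   spirit: proteins are visited in decreasing length order and discarded
   when their identity to any retained protein reaches the threshold
   (default 0.40).  The built-in identity estimate — best ungapped
   k-mer-anchored diagonal, matches over the shorter length — is
   deliberately simple and documented as approximate; an external CD-HIT
   binary can be delegated to when available.  The test suite checks the
   reducer against exact pairwise-alignment identity on clear-cut fixtures.
3. **Window extraction.** Default half-width n = 17 (window 35), the
   best-performing setting in this family of predictors; sites with a
   truncated flank are omitted by default (the common "trimmed sequence"
   rule) or padded with `O` on request.
4. **Balancing and splitting.** Negatives are undersampled to the positive
   count (seeded, without replacement).  The independent split is at the
   protein level — all fragments of a protein land on one side — because
   overlapping windows from one protein are near-duplicates and a
   fragment-level split would leak them across the boundary.

## Encoders

Stateless encoders map one fragment to a named feature block; corpus-fitted
encoders (`fit_*`/`encode_*`) carry an explicit state object fitted only on
training folds.  Conventions that were genuinely open and had to be fixed:

* **EAAC/EGAAC** slide a length-5 sub-window with stride 1 fully inside the
  fragment (the convention of the iFeature-style origin of these
  descriptors; the primary descriptions leave it unstated).  Denominator is
  the sub-window length, so dummy residues shrink the block sum below 1
  rather than distorting the composition.
* **DDE** uses codon multiplicities of the standard genetic code
  (C_H = 61, stop codons excluded) and is computed as (DC − TM)/√TV.  Some
  presentations typeset the numerator as DC·(1 − TM), which would duplicate
  the variance factor; the deviation-from-expected-mean reading is the
  defining one and is what the brute-force oracle in the tests transcribes.
* **CKSAAP** defaults to gaps {0,1,2,3,4}: the printed total dimensionality
  of 2205 = 5 × 441 forces five blocks even where the accompanying text
  says k = 1..4.
* **EBGW** is implemented as the standard three binary dichotomies
  (hydrophobic ∪ polar, hydrophobic ∪ acidic, hydrophobic ∪ basic) built
  from the four-class physicochemical grouping, with J = 5 nested prefixes
  of length int(j·L/J) and the fraction of ones per prefix.
* **PWAA** runs over flank offsets j = −m..m; the fixed central K carries
  weight j + |j|/m = 0 at j = 0, so including the center is harmless and
  the normalizer m(m+1) gives the closed form G = 1/m for a homogeneous
  fragment.
* **Profile encoding** emits the L-vector of per-position residue-type
  frequencies (the reading EBPR composes with); the alternative 20-vector
  reading would duplicate AAC.
* **TF-IDF** uses log base 10 and defines IDF = 0 for unseen terms.
  **TF-CRF** is made label-free at encode time: the category relevancy
  factor is emitted with respect to both classes (2 × 20 features), since
  using the sample's own class — as the original weighting does — would
  require the unknown test label.  The term frequency enters as
  log(1 + count) to avoid log 0.
* **BPB/PWM** use a pseudocount α = 1 over the 21 symbols (α = 0 reproduces
  raw frequencies).
* **KNN feature** uses min-max-normalized BLOSUM62 similarity (so
  sim ∈ [0,1] and Dist = 1 − mean sim ∈ [0,1]; the raw matrix maximum sits
  at (W,W)); pairs involving the dummy score 0.  Neighbor fractions default
  to 1, 2, 5 and 10 percent; when a training fragment is encoded during CV
  it is excluded from its own neighbor pool.
* **PSSM windows** take the log-odds (first) block of PSI-BLAST ASCII
  output; padded positions give zero rows.  **S-FPSSM** clips scores to
  [0, δ] with δ = 7 and sums rows grouped by residue identity into a 20×20
  vector.

Every encoder is verified against an independently written brute-force
transcription of its defining formula on seeded random fragments, and all
fitted states serialize round-trip to bit-identical encodings.

## Classifiers and the hybrid

All tabular learners share one contract: standardize features with
training-partition statistics (the scaler is stored and re-applied at
predict time; constant features get unit scale), train seeded, return
positive-class probabilities.  Defaults follow the grid-search optima of
the study this package operationalizes: random forest with 1000 trees and
√p features per split; RBF-SVM with cost 10 and γ = 0.001; KNN with K = 5;
gradient boosting with 1000 estimators of depth 6.  Grid domains: trees
100..1000 by 100; cost/γ decades 10⁻⁴..10⁴ and 10⁻⁴..1; odd K in 1..99;
estimators 100..1000, depth 3..8.  Ties in CV accuracy resolve to the first
grid point.

The dense network is the fixed seven-layer architecture
(512, 256, 128, 128, 64, 128, 256 units, batch normalization, ReLU, Adam at
0.001, categorical cross-entropy, 50 epochs, batch 32) with a 2-unit
softmax head; the positive probability is the second softmax component.
The published dropout list has six entries against seven layers; we apply
them after layers 1–5 and 7, reading the final 0.5 as guarding the last
hidden layer.  The LSTM member embeds the 21 integer-mapped residues
(dimension 64), runs one 64-unit LSTM layer and a sigmoid head; these
internals are our own choice, since the source adopts an LSTM member by
citation without architecture numbers.  Both networks are implemented as
plain matrix code with Adam, and their gradients are verified against
finite differences in the test suite.

The hybrid averages the probabilities of exactly four members — random
forest, SVM, gradient boosting (feature input) and the LSTM (raw residue
input) — with equal weights.  A vote of exactly 0.5 copies the label of the
member with the highest validation accuracy.  That accuracy is estimated on
a seeded stratified 20% internal hold-out (fit on 80%, score, then refit on
the full training partition) rather than an internal k-fold: the tie-break
only needs a coarse ranking of members, and k-fold validation would
multiply the training cost of every member by the fold count.

## Evaluation

Metrics are stored as fractions and rendered ×100 only for display, keeping
one internal convention.  Kappa uses the binary closed form
2(TP·TN − FN·FP)/((TP+FP)(FP+TN) + (TP+FN)(FN+TN)), which equals Cohen's
kappa for a 2×2 table.  Ratios with zero denominators are reported as NaN
with an `undefined` flag, never silently zeroed.  ROC curves sweep all
distinct thresholds; the trapezoid AUC then equals the Mann–Whitney
statistic with tied pairs counted one half, and the tests assert exactly
that identity (plus agreement with pROC).  The PR curve is integrated over
recall, anchored at recall 0 with the strictest threshold's precision.

Cross-validation is stratified by fragment label (the protein-level split
happens upstream).  Inside every fold the scaler and all corpus-fitted
encoder states are refitted on the training folds only — stricter than the
common practice of encoding the whole set once, and the package treats that
strictness as part of the contract: poisoning held-out labels must leave
predictions bit-identical, and a deliberately leaky scaler variant must
change them.

## The synthetic generator

The generator emulates exactly what the pipeline consumes: proteins drawn
from a background residue distribution (uniform by default), a requested
number of lysines marked positive, and the five upstream flank positions of
each positive re-drawn so that with probability `motif_strength` the
residue comes from the enriched set (D/E by default — an acidic upstream
signal chosen purely as a controllable statistical structure).  PSSM
fixtures carry an own-column score bonus plus noise, clipped to [−10, 12]
to resemble PSI-BLAST output.  All randomness flows from the single config
seed.

The default configuration — 60 proteins of length 200–400, 400 positive
sites, motif strength 0.8, window 35 — defines the study conditions for the
end-to-end recovery check: train ≈ 630 balanced fragments, independent test
≈ 60–100 fragments from held-out proteins.  With the planted motif the
Bayes-optimal AUC is close to 1 and the hybrid should exceed 0.9; with
motif strength 0 the pipeline must stay at chance.  Because a single
60–100-fragment test set has a null-AUC standard deviation near 0.07, the
chance-level check averages three independently generated replicates
(seeds derived from the base seed by fixed offsets) — a lower-variance
estimator of the same quantity.

What the generator does **not** emulate: real evolutionary conservation
(PSSMs are noise around an identity signal), species-specific sequence
composition, homologous families (every protein is independent, so the
homology reducer is exercised by dedicated fixtures instead), or the
extreme class imbalance of real proteomes beyond what undersampling
removes.  Passing the recovery check therefore shows the chain is wired
correctly and leak-free, not that it attains any particular accuracy on
real malonylation data.

## Numerical choices and degenerate inputs

* Scaler: per-feature mean/sd from the training partition; sd 0 → 1.
* Batch normalization: ε = 10⁻⁵, running-statistics momentum 0.9; training
  batches of size 1 are skipped (a batch statistic is undefined there).
* Soft-vote ties are exact comparisons with 0.5; probabilities are means of
  four values in [0,1], so the vote is bounded by the member extremes.
* All-dummy fragments yield zero AAC with a warning; fragments shorter than
  the EAAC sub-window raise an error suggesting padded extraction.
* Seeds fan out to stages by fixed small offsets so each stage is
  individually reproducible; all derived seeds stay far below 2³¹.

## Known limitations

* The built-in homology reducer estimates identity from ungapped k-mer
  anchored diagonals; gapped alignments can exceed the estimate, so
  borderline pairs near the threshold may be retained that CD-HIT would
  merge.
* The dense network and LSTM are compact pure-R implementations: adequate
  for the fragment scale used here, not for corpus-scale training.
* QSO, PseAAC, LOGO, structure-based descriptors (ASA, SS, HSE, backbone
  angles) and feature-selection wrappers are out of scope, as is running
  PSI-BLAST/POSSUM itself — profiles are always read from files.
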