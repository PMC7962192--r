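---
title: "Methods: window encodings, feature selection and score fusion for nitrotyrosine site prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: window encodings, feature selection and score fusion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The prediction problem

Tyrosine nitration is a post-translational modification in which reactive
nitrogen species (peroxynitrite in particular) convert a tyrosine residue to
3-nitrotyrosine. Which tyrosines of a proteome are susceptible is partly
encoded in the local sequence context, so the prediction task is: given a
protein sequence, score every tyrosine for its propensity to be nitrated.

`nitrosite` treats each tyrosine as an instance described by a fixed-length
sequence window of length `2w + 1` centred on the Y, with `w = 20` by default
(window length 41). Positions that fall outside the protein are padded with
`-`, which the encoders treat as a 21st letter (binary scheme) or as a
zero/skip (all other schemes), so terminal tyrosines remain predictable and
their truncation is itself visible to the model.

## Model overview

The predictor is an ensemble of four random forests, one per feature
encoding, whose probability outputs are fused linearly:

\[
\mathrm{score}(x) \;=\; \sum_{s} \omega_s \, P_s(\text{nitrated} \mid x),
\qquad \omega_s \ge 0,\; \textstyle\sum_s \omega_s = 1 ,
\]

with `s` ranging over the four encodings. The reference weight vector is
(binary, AAindex, CKSAAP, k-mer) = (0.01, 0.01, 0.30, 0.68); weights can also
be re-optimized for a new dataset by exhaustive search on the probability
simplex (coarse step 0.05, fine step 0.01 around the coarse optimum) using
*out-of-fold* probabilities only — optimizing on training-fold probabilities
would inflate the fused score's apparent advantage.

### The four encodings

* **binary** — per-position one-hot over 21 letters (20 amino acids + gap):
  41 × 21 = 861 features. Purely positional.
* **aaindex** — per-position physicochemical profile: 41 × 15 = 615
  features. The bundled default set of 15 AAindex properties spans
  hydropathy, hydrophilicity, polarity, isoelectric point, accessible
  surface, flexibility, polarizability, mutability, van der Waals volume,
  buried area, net charge, molecular weight, helix propensity and mean
  polarity; it is a documented default, fully replaceable via
  `read_aaindex()`. Values are z-standardized across the 20 letters so
  properties are commensurate and the gap encodes as 0 (the standardized
  mean).
* **cksaap** — composition of k-spaced amino-acid pairs: for each gap
  length `k` in 0..4 the frequencies of the 400 ordered pairs
  (residue at `i`, residue at `i + k + 1`), i.e. 5 × 400 = 2000 features.
  Pairs touching a padding gap (or an `X`) are skipped in the numerator
  while the denominator stays the number of pair slots `2w − k`; a heavily
  padded window therefore has a block sum below 1, a deliberate signal of
  terminal proximity.
* **kmer** — contiguous word composition for `K` = 1, 2, 3:
  20 + 400 + 8000 = 8420 features. (A `K = c(1, 3)` variant with 8020
  features is available; the arithmetic of the three blocks does not admit
  an 8020-dimensional K = 1,2,3 encoding, so both variants are exposed and
  the default is the self-consistent 8420.) Word slots containing a gap are
  skipped, denominators are slot counts, as for CKSAAP.

Feature names are canonical and documented (`bin_p<pos>_<letter>`,
`aai_p<pos>_<id>`, `cks_k<k>_<pair>`, `kmer_K<K>_<word>`; positions
ascending, alphabet alphabetical, k/K ascending) so selected-subset files
are portable across runs.

### Feature selection

Recursive feature elimination with a random-forest ranker: fit a probability
forest, drop the 50 features with the smallest impurity importance (ties
broken by canonical feature order), repeat on the survivors. The final
ranking is the reverse elimination order; the reported score is an
*elimination score* — rounds survived plus a within-round normalised
importance in [0, 1) — which is monotone along the ranking by construction
(raw importances from different rounds are not comparable). A single-shot
mode (`rerank = FALSE`) ranks once from one fit; permutation importance is
available via `importance = "permutation"`.

The retained subset size is then chosen on the grid top-50, top-100, …, all,
by stratified cross-validated AUC with a fresh forest per size, ties going
to the smaller size. AUC is the selection criterion because it is
threshold-free; accuracy at 0.5 is reported alongside but not optimized.

Two protocol variants are exposed in `cross_validate()`: selection nested
inside each training fold (`select = "rfe"`, the honest default when
selection is requested) and selection once on the full training set
(`select = "once"`), which mirrors the common reporting style of per-size
performance tables but leaks the test folds into the ranking and is
therefore optimistically biased — it exists for comparability, not
inference.

### Classifiers

The forests use 500 trees and `sqrt(p)` candidate features per split by
default — ordinary choices for wide, sparse feature matrices; both are
configurable and recorded in the model bundle. Training is deterministic
given the seed (single-threaded ranger). Naive Bayes and k-nearest
neighbour (k chosen from 3, 5, 7, 9 by cross-validated AUC) comparators sit
behind the same train/predict interface for benchmarking; they are not part
of the shipped predictor.

### Evaluation

Threshold metrics are computed from the confusion counts with the
ties-are-positive rule (score ≥ threshold → positive call):
Sn = TP/(TP+FN), Sp = TN/(TN+FP), Acc = (TP+TN)/n, and
MCC = (TP·TN − FP·FN)/√((TP+FN)(TN+FP)(TP+FP)(TN+FN)). A zero marginal in
the MCC denominator yields MCC = 0 with an explicit `mcc_undefined` flag
(the standard convention). AUC is computed as the Mann–Whitney statistic —
the probability a random positive outscores a random negative, ties counting
one half — and the ROC sweep is returned so trapezoidal integration can be
checked against it (the two agree to numerical precision; the test suite
also cross-checks against pROC).

Cross-validation is stratified (per-fold class proportions within one
sample of the global ones). The design data are balanced 1:1, and
stratification keeps every fold so; fold summaries report the mean and the
standard error across folds. Two operating points are reported by the
evaluation command: the plain 0.5 cut and a threshold calibrated to a
target specificity (default 0.80), the fixed-specificity convention common
in modification-site benchmarking.

### Dataset assembly conventions

Labelled windows are assembled as: every experimentally listed tyrosine of
a characterised protein is positive, every remaining tyrosine of that
protein negative, tyrosines of unlisted proteins unknown. Redundancy is
reduced at the window level (configurable) by greedy longest-first
clustering at 40 % identity — position-wise matches over the window length,
aligned gaps counting as matches; an externally produced CD-HIT `.clstr`
file can be ingested instead, since the greedy clustering is a convention,
not a reimplementation of CD-HIT. A stratified 20 % of each class is held
out as the independent set; the remaining windows are balanced 1:1 by
uniform random down-sampling of the majority class with a logged seed.

## The synthetic generator

Because curated nitrotyrosine datasets live on lab servers and cannot be
bundled, the package ships a generative benchmark. Proteins are drawn
i.i.d. from a background distribution (default uniform over the 20 amino
acids); each tyrosine is designated positive with probability 0.25; the
residues at offsets −5..+5 around a positive site are re-drawn from
`p(a) ∝ background(a) · boost(a)^effect_size` with boost 2.0 for K, R, E and
0.5 for Y, S, F, L — a compositional enrichment of charged residues and
depletion of Y/S/F/L near the modified site, the qualitative pattern seen
in real nitration data. `effect_size = 0` makes the classes identically
distributed (the null); the default 1.5 is a moderate, learnable signal;
3.0 is used as the "strong motif" benchmark.

What the generator deliberately does **not** emulate: homology structure
between proteins, positional (as opposed to compositional) motif structure,
non-uniform proteome composition, and label noise. Consequences worth
keeping in mind: with a purely compositional planted motif the positional
encodings (binary, AAindex) can dominate the pair/word encodings on
synthetic data — the reverse of what is typically seen on real nitration
data — so the synthetic benchmark validates the machinery (recovery,
calibration, fusion arithmetic), not the relative merits of encodings on
real proteins.

## Numerical and design choices

* Positions are 1-based in every user-facing table; internal indices are
  0/1-based as R requires. The padding character is `-`, identical to the
  binary encoder's 21st letter.
* Non-standard residue letters (B, J, O, U, Z) are collapsed to `X` on
  input with a warning; `X` encodes as an all-zero block in every scheme.
* Grid/importance ties break deterministically (canonical feature order;
  smaller subset; sparser weight vector with the largest single-scheme
  mass), so every stage is byte-identical under a fixed seed.
* All randomness derives from one top-level seed expanded deterministically
  per stage (`split`, `rank`, `grid`, `train`, `fuse`, `cv`).
* Degenerate inputs: sequences without tyrosine yield empty window sets
  (prediction warns and writes an empty table); single-class labels are
  validation errors wherever AUC or fold stratification is required.

## Problem sizes used by the shipped benchmarks

The test suite and the acceptance script run the full pipeline at desk
scale, chosen so the whole suite completes in a few minutes on one core:
strong-motif recovery on 1,000 windows (w = 20) with 200-tree forests and
5 folds; null calibration as the mean over 10 generator seeds of 300-window
runs with 100-tree forests; RFE recovery on a 600 × 200 matrix with 20
planted informative columns (class shift 0.8 SD) and 300-tree forests.
These sizes are stated here as the package's benchmark conditions; larger
runs only sharpen the same comparisons.

## Known limitations

* The greedy identity clustering is a window-level convention; protein-level
  redundancy control requires an external CD-HIT run (supported via
  `.clstr` ingestion).
* The bundled AAindex property set is a documented default; the historically
  "correct" 15-property set for this task is not recoverable, so results
  depend (weakly, in our benchmarks) on the chosen properties.
* `select = "once"` reproduces a common but leaky reporting protocol; use
  the nested mode for honest generalization estimates.
* KNN prediction resolves distance ties by seeded sampling; exact
  reproducibility across platforms is guaranteed only for the forest models.
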