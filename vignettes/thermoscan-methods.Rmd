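---
title: "thermoscan: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{thermoscan: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thermoscan)
```

## The problem and the model

Thermophilic organisms (optimum growth temperature ≥ 60 °C) maintain
folded, functional proteins at temperatures that denature most mesophilic
proteins. The compositional fingerprint of that adaptation — notably a
strong enrichment of charged residues such as lysine and aspartate — is
visible in the raw sequence, which makes thermophilicity a classic target
for sequence-only supervised classification. `thermoscan` implements the
full workflow: descriptor encoding, ensemble feature ranking with
PageRank fusion, forward-adding dimensionality selection, and an
RBF-kernel SVM evaluated by stratified cross-validation.

The classifier sees each protein only through fixed-length descriptor
vectors; no alignment, homology, or structural information is used. That
is both the appeal (fast, annotation-free) and the main assumption: the
class signal must live in k-mer composition statistics.

## Sequence screening

Input sequences must be non-empty strings over the 20 canonical residues.
Ambiguity codes (B, J, O, U, X, Z), stop characters and gaps are rejected;
lowercase is uppercased first, since case is a file artifact rather than a
biological statement. Selenocysteine (U) records are dropped rather than
recoded to cysteine — the descriptor tables below have no U entry and
silent recoding would fabricate composition. Upstream dataset-construction
filters used for real data (manual annotation status, fragment flags,
inferred-by-homology evidence, redundancy clustering) are metadata-level
operations on database records and are deliberately out of scope: they
cannot be computed from the sequence alone.

## Descriptor encodings

All k-mer counts use overlapping windows, so a length-*n* sequence
contributes *n−1* dipeptides and *n−2* tripeptides; this fixes the
denominators and makes every composition-type encoder a probability
vector.

| Encoder | Dim. | Definition |
|---|---|---|
| AAC | 20 | residue frequency `n(i)/n` |
| DPC | 400 | dipeptide frequency `n_xy/(n−1)` |
| TPC | 8000 | tripeptide frequency `n_xyz/(n−2)` |
| DDE | 400 | `(D_c − T_m)/√T_v` (below) |
| GDPC | 25 | DPC on the 5-group recoded sequence |
| GTPC | 125 | TPC on the 5-group recoded sequence |
| CKSAAGP | 150 | 25 group-pair frequencies at gaps 0–5 |
| CTDC | 39 | 3 group fractions × 13 properties |
| CTDT | 39 | between-group transition rates × 13 properties |
| CTriad | 343 | 7-class triad frequencies `count/(n−2)` |

**DDE.** The dipeptide deviation from expected mean standardizes the
observed dipeptide composition `D_c(x,y) = n_xy/(n−1)` against a
codon-usage null: `T_m(x,y) = (C_x/C_n)(C_y/C_n)`, where `C_x` is the
number of codons encoding residue *x* under the standard genetic code and
`C_n = 61` after removing the three stop codons, and
`T_v(x,y) = T_m(1−T_m)/(n−1)`. Because `0 < T_m < 1`, the variance is
strictly positive and every DDE value is finite and shares its sign with
`D_c − T_m`.

**CTD property set.** The composition/transition descriptors use the
standard 13-attribute set of three-group residue partitions
(Tomii–Kanehisa main clusters): seven hydrophobicity normalizations plus
normalized van der Waals volume, polarity, polarizability, charge,
secondary structure and solvent accessibility. The full table ships in
`ctd_properties()` and each property is verified (by test) to partition
the alphabet exactly. Transition features are reported for the unordered
pairs (g1,g2), (g2,g3), (g3,g1), counting crossings in both directions
over the *n−1* adjacent pairs.

**Grouped encoders.** GDPC, GTPC and CKSAAGP first recode residues into
five physicochemical groups — aliphatic {G,A,V,L,M,I}, aromatic {F,Y,W},
positively charged {K,R,H}, negatively charged {D,E}, uncharged
{S,T,C,P,N,Q} (`aa_groups_5()`). The k-spaced pair encoder is the
*grouped* variant: 25 group pairs at residue separations 0–5, 150
features, with each gap block normalized by its own `n−k−1` window count.
An ungrouped k-spaced pair encoder would have 400 features per gap; the
150-dimension grouped form is the one consistent with the rest of the
descriptor family here.

**CTriad.** Conjoint-triad classes follow the seven-class
electrostatics/volume partition ({A,G,V}, {I,L,F,P}, {Y,M,T,S}, {H,N,Q,W},
{R,K}, {D,E}, {C}); values are plain frequencies `count/(n−2)` rather than
the min–max rescaled variant, so the vector sums to one and is directly
checkable against a counting oracle. Switching to the rescaled variant is
a one-line monotone transform that does not change any ranking.

TPC deliberately emits all 8,000 tripeptide features with no silent
dropping of empty or near-constant columns; dimensionality reduction is
the selection stage's job, not the encoder's.

Feature names are canonical and stable — `ENCODER:token` with tokens in
lexicographic alphabet order — so residue-level features like `AAC:K`,
`AAC:D` and `DPC:LK` are addressable across runs.

## Ensemble feature selection

Seven rankers each produce a full ordering of the feature columns: one-way
ANOVA F; mutual information after equal-width binning into 10 bins
(a deterministic stand-in for the maximal-information-coefficient family);
greedy mRMR (max-scaled F relevance minus mean absolute correlation with
the already-selected set); the coefficient magnitudes of an L1-regularized
logistic model taken at a fixed point of the regularization path (the
densest model `glmnet` computes, so the score is deterministic);
point-biserial correlation magnitude; chi-squared on quartile-binned
features; and a deterministic ReliefF (every instance is a probe, k = 5
nearest hits/misses by Manhattan distance on min–max normalized features).
Constant columns score zero under every method and sink to the ranking
tail in canonical column order, and all remaining ties break by canonical
order, so every ranking is reproducible bit for bit.

**PageRank fusion.** The rankings are fused on an endorsement graph:
within each ranking, every feature casts a unit-weight directed edge to
*each* feature ranked above it. The fused order is the stationary PageRank
distribution (damping 0.85, dangling mass redistributed uniformly,
convergence tolerance 1e−10, at most 10,000 power iterations). We chose
transitive endorsement over linking only adjacent rank positions after
observing that the adjacent-only graph does not concentrate weight on the
consensus winner: a feature placed first by *all seven* rankers receives
flow only from the seven runner-up features and can end up with
near-uniform weight, defeating the purpose of fusion. With transitive
edges, a single input ranking reproduces itself exactly (the stationary
weights are strictly decreasing along the ranking) and a unanimous top
feature collects endorsements from the entire feature set and dominates.

**Forward adding.** The fused ranking is scanned from the top, evaluating
stratified cross-validated SVM accuracy at prefix sizes 1, 2, … (step 1 up
to 200 features, then step 5, always including the full set — a bounded
number of evaluations at negligible loss, since accuracy curves are flat
at those sizes). The selected dimensionality is the *smallest* prefix
attaining the maximum of the curve; ties therefore always resolve toward
fewer features. The internal evaluator is the package's own
`cross_validate()` with default SVM settings, 5 folds, and a fixed
internal seed, so selection results are self-consistent with the reported
accuracies and reproducible.

## Classification

The SVM is libsvm's C-classification with RBF kernel (via `e1071`).
Features are affinely scaled to [−1, 1] with parameters fitted on the
training partition only and applied unchanged to test folds (test values
may fall outside the interval; constant features map to 0). Scaling can
be disabled (`scale = FALSE`) for raw-feature behavior. The grid-search
default is the libsvm convention — C over 2^−5…2^15 and γ over 2^−15…2^3
in steps of 2² — with ties broken toward smaller C, then smaller γ; the
full grid table is returned for audit. Cross-validation is stratified
(per-class round-robin after a seeded shuffle), defaults to k = 10, and
pools the confusion counts over folds before computing

  SE = TP/(TP+FN), SP = TN/(TN+FP), ACC = (TP+TN)/(TP+FN+TN+FP),

the micro-averaged convention under which single SE/SP/ACC triples are
conventionally reported. A metric whose denominator is empty (one-class
input) is returned as `NA` with a warning rather than silently dropped.
Class imbalance is not reweighted by default (an option exists), matching
the plain two-class protocol.

## The synthetic generator

`default_profiles()` encodes the compositional contrast the classifier is
meant to detect: the thermophilic-like class has lysine frequency 0.08 and
aspartate 0.06 with a 2× enrichment of the LK dipeptide; the
non-thermophilic-like class has lysine at 0.03; in both classes all
remaining probability mass is spread uniformly over the other residues
(real proteomes are not uniform, but no other residue's class contrast is
being modeled, and a uniform background avoids planting accidental
signals). Sequences are drawn from a first-order Markov chain whose rows
equal the profile frequencies; the LK enrichment multiplies the L→K
transition and renormalizes that row, which perturbs the stationary lysine
frequency by well under one percentage point. Lengths are uniform on
50–600 residues, a typical protein-length range. Within-class spread of
the lysine fraction is therefore purely binomial in sequence length; no
additional overdispersion is modeled.

What passing tests on this generator do show: the encoders measure what
they claim, the ensemble ranking recovers a planted compositional signal,
and the SVM converts that signal into calibrated accuracy (chance on
permuted labels). What they do not show: performance on real proteomes,
where composition varies with GC content, taxonomy and subcellular
localization, classes overlap far more, and redundancy between homologs
inflates naive cross-validation. Published accuracies on curated
thermophile datasets (≈ 93–96%) are benchmarks for that harder problem
and are not reproduced by, or comparable to, the synthetic numbers here.

## Numerical choices and degenerate inputs

- Encoder preconditions are hard errors naming the sequence and encoder
  (length ≥ 2 for dipeptide windows, ≥ 3 for tripeptide windows,
  ≥ gap + 2 for k-spaced pairs).
- Oracle-equivalence tests run every encoder against an independent
  naive-counting implementation on 200 random sequences (lengths 3–100)
  at tolerance 1e−12; normalization invariants are tested at 1e−9.
- PageRank uses dense power iteration; at the descriptor sizes used for
  selection here (tens to hundreds of columns) the O(p²) graph is
  negligible. For the 8,000-feature TPC block, rank single methods and
  fuse on a pre-filtered subset instead.
- ANOVA F on a zero-within-variance, nonzero-between-variance column is
  capped at 1e300 to keep scores finite and ordered.
- Simulation sizes in the test suite (40–200 sequences per class,
  AAC/AAC+DPC descriptors, 5–10 folds, 10–50 replicates) were chosen so
  the planted effect sizes give comfortable statistical margins for the
  asserted bounds.

## Known limitations

- No evolutionary-profile (PSSM) or structure-derived features; the
  descriptor family is sequence-only by design.
- The selection stage's seven rankers are a documented, configurable set;
  other ensemble compositions will produce different (generally similar)
  fusions, and no attempt is made to byte-match any external selection
  tool.
- Cross-validation folds are always stratified, so k is bounded by the
  minority-class size; a full jackknife (leave-one-out) protocol is not
  offered. The default is seeded 10-fold.
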