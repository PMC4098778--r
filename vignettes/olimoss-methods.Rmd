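---
title: "Predicting protein-specific RBP targets with olimoss"
author: "olimoss authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting protein-specific RBP targets with olimoss}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(olimoss)
```

## The problem and the model

RNA-binding proteins (RBPs) recognise specific mRNAs, typically through
elements in the 3'UTR. Given experimentally determined bound ("positive")
and non-bound ("negative") sequence sets for one protein, olimoss trains a
binary classifier for that protein alone — binding is protein-specific, so
one model per RBP captures its preferences better than a single generic
model.

The classifier is a linear support-vector machine over one of three nested
sequence representations:

* **oli** — the 256 tetranucleotide counts of the sequence. Every width-4
  window (step 1) is counted; windows containing an ambiguity code are
  skipped. 4-mers are a sweet spot: very short words carry little
  specificity, while much longer words make almost all frequencies zero on
  3'UTR-length sequences and inflate the cost of the balancing step.
* **olimo** — oli plus the 10 highest motif scores, 266 features. A motif is
  a position-specific scoring matrix (PSSM); a window score is
  $\mathrm{score}(\hat s_i) = \sum_{k=1}^{m} \mathrm{pssm}(b_{i+k}, k)$,
  the sum over motif positions of the matrix cell for the base observed
  there. Because binding sites tend to recur on regulated UTRs, the sequence
  is summarised by its 10 best windows.
* **olimoss** — olimo plus secondary structure, 525 features: the predicted
  folding energy (read from the input, never recomputed — thermodynamic
  folding is out of scope), the stem density (fraction of paired bases), the
  number of stems, and 256 binary accessibility indicators. A
  tetranucleotide is *accessible* when one of its occurrences lies entirely
  inside a run of at least four consecutive unpaired bases.

Counts are used raw by default: dividing by sequence length (`normalize =
TRUE`, the convention of some comparable tools) is supported but disabled,
since in this protocol normalisation tends to wash out the frequency
differences the classifier exploits.

## Training protocol

Negative sets are typically much larger than positive sets, so each training
set is rebalanced with SMOTE: synthetic positives are interpolated between a
positive sample and one of its `k = 5` nearest positive neighbours
(Euclidean distance on the raw feature scale), up to parity with the
negatives by default. Three deliberate choices:

* SMOTE runs in the input space, which ties the classifier to the linear
  kernel — balancing in a nonlinear kernel's feature space would be a
  different (and unimplemented) operation.
* Interpolated accessibility bits are left fractional rather than
  re-thresholded; re-binarising would be an extra, undocumented step on top
  of the standard algorithm.
* Features are not standardised before SMOTE; the raw scale is part of the
  representation.

The cost parameter C of the linear SVM is selected by grid search: for each
candidate C an inner stratified cross-validation on the balanced training
data estimates the mean Matthews correlation coefficient (MCC), and the
highest mean wins, ties going to the smallest C (the least complex model).
MCC with an empty margin is defined as 0 so the search is total. The default
grid is the conventional coarse range $2^{-5}, 2^{-3}, \dots, 2^{15}$; the
fit itself is LIBSVM (via e1071). Reported scores in $[0,1]$ come from a
Platt-style logistic calibration fitted on the inner out-of-fold decision
values; the label rule is score $\ge 0.5 \Rightarrow +1$.

## Evaluation without leakage

`runCV()` runs a stratified k-fold cross-validation (default 10). Inside
each fold, in this order:

1. motif PSSMs are rebuilt from the fold's *positive training* sequences
   only (the `pssmProvider` contract) — rebuilding motifs per fold avoids
   the circularity of discovering a motif on data you then test on;
2. SMOTE is applied to the training fold only, and synthetic samples are
   flagged so they can never reach a test fold;
3. C is grid-searched by inner-CV MCC and the model refit;
4. the untouched test fold is scored once.

The report keeps a per-fold audit of which sequence ids fed PSSM
construction and SMOTE; `assertNoLeakage()` re-checks it mechanically.
Stratification is used even though plain k-fold would also do, because on
heavily unbalanced data unstratified folds can lose a class entirely.

Metrics: AUC is computed as the Mann–Whitney probability that a random
positive outscores a random negative (ties 1/2); precision is evaluated at
threshold 0.5; ROC and PR curves come from a threshold sweep over the pooled
out-of-fold scores (pooled rather than fold-averaged — the simplest reading
of a cross-validated curve). Paired method comparisons use the two-sided
Wilcoxon signed-rank test at $\alpha = 0.01$, dropping zero differences.
When negatives are random background transcripts rather than measured
non-targets, the AUC's sensitivity to that choice is quantified by
`negativeResamplingCI()`: the negative pool is exchanged over 10 disjoint
draws and a Student-t interval is formed over the per-draw AUCs (the
interval construction is this package's choice; only the confidence level is
inherited from the protocol).

Feature relevance is ranked by information gain. The features are
real-valued, and IG needs a discretisation: each feature is split at the
single threshold (midpoints of sorted distinct values) maximising
$H(y) - H(y \mid \text{split})$ in bits. A median split is a cheaper
alternative, but the best-split scan is exact for single features and cheap
at these dimensions.

`crossRbpSensitivity()` applies each protein's model to every protein's
positive set. Resubstitution diagonals are optimistic by construction;
out-of-fold sensitivities from each model's own CV can replace them.

## The synthetic benchmark

Real training data for this problem are CLIP-style bound sets plus either
measured non-targets or randomly drawn 3'UTRs. The generator
(`generateDataset()`) emulates that shape at desk scale: negatives are
i.i.d. sequences from a uniform ACGU background; positives additionally
carry planted instances of a consensus motif (default `UGUAUAUA`, a
Pumilio-family element) at uniform non-overlapping positions, each base
independently mutated at rate 0.05; 90% of positives carry at least one
instance. A bound sequence receives `1 + Poisson(1.5)` instances (about 2.5
on average): CLIP experiments find multiple binding clusters on a typical
bound 3'UTR, and recurring sites are precisely why the encoding keeps a
sequence's ten best motif scores rather than its single best. Lengths are
uniform on 200–1500 nt, the 3'UTR-length regime where tetranucleotide
counts are informative but sparse. `hairpin-toy` mode adds schematic
dot-bracket structures — hairpins scattered over unpaired background, with
planted sites kept single-stranded — which exercise the accessibility
features without pretending to be thermodynamics.

What the generator does *not* emulate: real 3'UTR base composition and
repeat structure, shared targets between proteins, expression-dependent
negative contamination, and realistic folding. Passing benchmarks here shows
the pipeline recovers planted signal under its own assumptions, not that it
reaches any particular accuracy on CLIP data.

The benchmark configuration used by the acceptance script and the heavier
tests is 400 positives / 800 negatives with 10-fold CV, per-fold PSSMs from
the planted sites of training positives, inner 2-fold grid search over
$C \in \{2^{-5}, 2^{-1}\}$, and an optimiser tolerance of 0.01. The reduced
grid and inner-fold count are a deliberate problem-size choice: on this
benchmark the inner-CV MCC is flat across the wider C range (the planted
signal is linear and low-C models already saturate it), so the extra grid
points buy nothing, and small C values keep the quadratic-programming solve
well conditioned on raw count features.

## Numerical choices and edge cases

* Sequences shorter than 4 nt encode as all-zero count vectors (with a
  warning); sequences shorter than a motif contribute no windows, and the
  top-10 block is padded with the minimum observed score (or 0 when nothing
  was scored) rather than $-\infty$, keeping the feature scale bounded.
* When several motifs are supplied, the top-10 block pools windows across
  all of them ("ten best sites anywhere"); `perMotif = TRUE` instead leads
  with each motif's single best score. Pooling is the default because de
  novo motif discovery returns a variable number of motifs.
* Window scores are computed on the matrix as stored. Whether probabilities
  or log-odds are the right scale is left to the caller; the in-package site
  PSSM builder produces base-2 log-odds against the background, and
  `toLogOdds()` converts probability matrices.
* Dot-bracket parsing accepts only `.`, `(`, `)` — nested structures, as
  minimum-free-energy folders emit. A "stem" is a maximal helix of
  consecutive stacked pairs; a bulge on either strand ends the stem. This is
  the standard helix definition, chosen because the feature set's origin
  does not pin one down.
* SMOTE with `k` at least the number of positives clamps `k` with a
  warning; fewer than two positives is an error.
* Platt calibration on separable inner folds can diverge; the slope is
  capped (preserving the decision threshold) and degenerate fits fall back
  to the identity-like logistic.
* Fold assignment, SMOTE, permutation nulls and the generator all consume
  one user seed; fixed seed means byte-identical outputs.

## A small worked run

```{r example, eval = FALSE}
d <- generateDataset(nPos = 60, nNeg = 120, lengthRange = c(100, 300),
                     seed = 5)
report <- runCV(d$dataset, "olimo",
                pssmProvider = pssmProviderFromSites(d$sites),
                folds = 5, cValues = 2^c(-5, -3, -1), innerFolds = 3,
                seed = 11)
report
assertNoLeakage(report)
```

## Limitations

Only RNA-side features are modelled; the protein is represented solely by
its training set. Motif discovery itself is external: the package consumes
PSSMs (MEME minimal format) or builds frequency matrices from known aligned
sites for benchmarking. Secondary structures are consumed, not predicted —
`foldExternal()` is a thin adapter around an RNAfold-compatible executable
when one is available. Accessibility is a coarse single-strandedness
indicator, not solvent accessibility. And as with any protein-specific
approach, a model can only be trained for proteins with an experimental
binding dataset.
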