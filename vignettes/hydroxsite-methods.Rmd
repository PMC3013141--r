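---
title: "Methods: window encoding, mRMR/IFS feature selection and nearest-neighbour prediction of hydroxylation sites"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: window encoding, mRMR/IFS feature selection and nearest-neighbour prediction of hydroxylation sites}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hydroxsite)
```

## The problem and the classification unit

Hydroxylation of proline (at the γ-carbon, giving 4-hydroxyproline) and of
lysine (at the δ-carbon) is a post-translational modification central to
collagen stability and cross-linking, and — for proline — to the hypoxia
response. Experimentally mapping hydroxylation sites is slow; the package
implements a sequence-based predictor: every proline (or lysine) in a
protein is a candidate, represented by the 13-residue window consisting of
the candidate plus six residues on each side, and a binary classifier
decides whether the candidate is hydroxylated.

Positive windows are the experimentally annotated sites; all remaining
candidate windows form the negative pool, from which negatives are sampled
uniformly without replacement at a fixed 2:1 ratio to positives. The 2:1
imbalance mirrors the benchmark design this method family uses: it retains
class imbalance (so MCC is informative) while keeping jackknife runtimes
workable. The draw is global across proteins, not stratified, and requires
an explicit seed, which every output manifest records.

### Terminus handling

Whether near-terminus candidates were padded or discarded is an open choice
in this design. The default policy pads with a placeholder residue `X`
encoded class-neutrally: each AAindex feature takes that index's mean over
the 20 residues, the PSSM row is zeros, and the disorder score is 0.5 (the
midpoint of the predictor's range). Padding preserves every annotated site,
which matters on small benchmarks; an `exclude` policy is available when a
user prefers only fully observed windows.

## The feature space

Three per-residue descriptions are concatenated per window position:

* **AAindex** (physicochemical/biochemical property indices): one value per
  usable index. Indices with missing values are dropped at read time —
  the full AAindex1 release then yields 506 usable indices — and the count
  is never hard-coded: the dimension follows the data.
* **PSSM conservation**: the 20 log-odds scores of the residue's row in the
  PSI-BLAST position-specific scoring matrix. The ASCII dump carries two
  20-column blocks (log-odds and weighted percentages); the reader defaults
  to log-odds, the conventional conservation encoding in PTM predictors,
  with the percentage block selectable.
* **Disorder**: the residue's predicted intrinsic-disorder score in [0, 1].

The centre residue is the same letter in every window of a task, so its
AAindex features are constant and are omitted: the centre contributes
20 + 1 features, each flank position A + 21, for a total of
12(A + 21) + 21 = 6,345 when A = 506. Feature identity is explicit: the
canonical order is position-major, kinds ordered aaindex → pssm → disorder
within a position, sub-identifiers sorted lexicographically; every ranked
list, matrix header and analysis table uses the resulting
`p07|pssm|L`-style names, and `describe_feature()`/`locate_feature()` are
mutually inverse over the whole space.

No feature scaling is applied by default. The cosine distance used
downstream is scale-sensitive *across* features — PSSM integers and
[0, 1] disorder scores contribute very differently — and this property is
kept as-is because it is the method's stated form; `standardize = TRUE`
exists in `encode_windows()` for users who want the variance-equalized
variant.

## Feature ranking: MaxRel and mRMR

Relevance and redundancy are mutual information (MI) on 3-state
discretized features: each feature maps to low/mid/high by thresholds at
mean ± k·SD of that feature, with k = 1 by default (the classical mRMR
preprocessing constant). Values at or beyond a threshold take the outer
state; constant features map to the middle state, making them exactly
uninformative. MI is the plug-in estimate in bits (log₂), recorded in the
ranked-list metadata.

* **MaxRel** sorts features by I(feature; class), descending.
* **mRMR** selects greedily: the first feature is the MaxRel top; each
  subsequent feature maximizes relevance minus the mean MI with the
  already-selected features (the MID "difference" scheme), or
  relevance divided by mean redundancy (MIQ, `scheme = "quotient"`).

Which scheme and discretization constant the method family originally used
is not recoverable; MID with k = 1 is the documented default of the
reference mRMR program, so those are the defaults here, and both knobs are
exposed. All ties break by canonical feature order, making ranked lists
reproducible bit-for-bit.

## Classifier and evaluation

The nearest-neighbour rule assigns a query the class of the training
window minimizing D(u, v) = 1 − cos(u, v) ∈ [0, 2]. Distance ties break to
the lowest training index. Two numerical conventions matter:

* A zero-norm vector has no direction. The two-vector `nna_distance()`
  refuses it; batch computations (prediction, jackknife, IFS) assign it
  similarity 0 with everything — i.e. treat it as uncorrelated — because
  short feature prefixes of integer PSSM scores routinely produce all-zero
  sub-vectors and the IFS loop must remain total. The convention is
  deterministic and symmetric.
* Computed similarities are clamped to [−1, 1] to guard rounding excursions
  an ulp past ±1.

Evaluation is jackknife (leave-one-out) cross-validation only: each sample
is predicted from the remaining n − 1. Metrics are Sn, Sp, AC and MCC from
the pooled confusion counts; a degenerate margin (e.g. no predicted
positives) makes the MCC denominator zero, in which case MCC is defined as
0 and a message is emitted. A k-fold mode is deliberately absent: the
jackknife is the evaluation the method is defined with.

## Incremental feature selection

Given the mRMR list, IFS evaluates the jackknife metrics on every nested
prefix S_k (first k features), k = 1..N, and selects the peak. Accuracy is
the objective (the IFS curve's y-axis); equal-AC ties resolve to the
smallest k — fewer features at the same accuracy; optimizing MCC instead
is available behind `objective = "MCC"`. The per-k similarity matrix is
updated incrementally from the running Gram matrix and squared norms, so
the whole curve costs O(N·n²) rather than O(N²·n²).

## The synthetic benchmark

`generate_synthetic()` emulates every input: random sequences with the
target residue placed at non-overlapping window slots, integer PSSMs with
N(0, 3) noise, disorder tracks with N(0.5, 0.08) noise truncated to
[0, 1], and a miniature AAindex table (3 indices by default) with cluster
labels. A chosen set of descriptors (10 by default) is planted as
informative: in positive-class windows the underlying PSSM cell or
disorder value aligned with each planted descriptor is shifted by
`effect_size` within-class SDs (3 by default). Planting is restricted to
pssm/disorder kinds because all AAindex features of a position are jointly
determined by one residue letter — an exact chosen subset of them cannot
be shifted independently of the rest.

Default study conditions — 20 proteins × 150 residues, 67 positive sites,
2:1 negatives (201 samples), 10 planted features at 3 SD — are a size at
which ranking and jackknife estimates are stable yet a full
generate→encode→rank→IFS replicate runs in under a second; the test suite
and the acceptance script run 20 replicates. What passing shows: the
pipeline recovers feature-level signal and its stages compose correctly.
What it does not show: performance on real proteins, where class signal is
weaker, spread over correlated residues and positions, embedded in
non-uniform sequence composition, and entangled with evolutionary
conservation — none of which the generator models. The headline benchmark
accuracies of the real datasets require Swiss-Prot annotations and
UniRef100 PSI-BLAST profiles and are not recomputable offline; the
package instead verifies their internal consistency (the reported Sn/Sp
and class sizes imply the reported AC and MCC via `compute_metrics()`).

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `window_length` | 13 | residues per window (candidate ± 6) |
| `ratio` | 2 | negatives sampled per positive |
| `terminus_policy` | `"pad"` | pad near-terminus windows with `X` vs exclude |
| `top_n` | 500 | ranked-list length feeding IFS |
| `k_sigma` | 1 | discretization half-width, SD units |
| `scheme` | `"difference"` | mRMR combination (MID) vs `"quotient"` (MIQ) |
| `objective` | `"AC"` | IFS peak criterion |
| `block` | `"logodds"` | PSSM block harvested from the ASCII dump |
| `effect_size` | 3 | synthetic class shift, within-class SDs |

## Known limitations

* Cosine distance over unscaled heterogeneous features weights kinds by
  their numeric range; this is faithful to the method, not statistically
  ideal.
* The plug-in MI estimator is biased upward on small samples; rankings are
  still consistent because all features share the sample size.
* Window lengths other than 13 are parameterized but only exercised at 13.
* Per-protein PSSM and disorder inputs are trusted as given; the package
  never runs PSI-BLAST or a disorder predictor.
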