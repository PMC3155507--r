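---
title: "Beta-turn prediction with shape strings and a two-layer SVM: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Beta-turn prediction: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(betaturn)
```

## The prediction problem

A β-turn is four consecutive residues *i..i+3* that do not form an
α-helix and whose Cα(i)–Cα(i+3) distance is below 7 Å. `betaturn`
predicts, window by window, whether the central four residues of an
8-residue sliding window constitute a β-turn, using three per-residue
feature tracks:

* a position-specific scoring matrix (PSSM) row — 20 substitution
  log-odds, squashed into [0, 1] by the standard logistic function
  $f(x) = 1/(1+e^{-x})$;
* a one-hot 3-state secondary-structure code, H → (1,0,0),
  E → (0,1,0), C → (0,0,1);
* a one-hot 9-state shape-string code over S, R, U, V, K, A, T, G plus
  X for positions with no assignment. Shape strings discretise the φ/ψ
  torsion pairs into eight clustered regions and carry finer backbone
  information than the 3-state alphabet.

With all tracks on, a window sample is a 256-dimensional vector
(8 residues × 32 values), every entry in [0, 1].

## Shape-string transfer

Shape strings for a query are not computed from structure; they are
transferred from a database of sequences with known shape strings. The
procedure is a single greedy pass:

1. a search backend returns local alignments of the query against the
   database, each with an e-value;
2. hits with e-value < 10⁻⁵ are kept and sorted ascending (ties broken
   by database id so the pass is deterministic);
3. walking the ranked list, every aligned query position that is still
   unassigned takes the shape character of its aligned database
   position; positions never claimed by any hit become X.

"Matched part" is read per position, not per segment: a gap inside a
good hit leaves that position open for a later hit. The pass never
re-searches leftover fragments — one ranked judgment loop. Accuracy is
reported over **all** positions by default (X never matches), because
the alternative covered-only denominator flatters low-coverage
predictions; `shape_accuracy(covered_only = TRUE)` exposes it anyway.

Two backends satisfy the same contract `(chain_id, sequence, db) -> hits`:
the built-in deterministic Smith–Waterman search (BLOSUM62, affine gaps
10/0.5) with a Karlin–Altschul-style surrogate e-value
$E = Kmn\,e^{-\lambda S}$ (λ = 0.267, K = 0.041, the customary gapped
BLOSUM62 constants), and any external profile-search adapter the user
supplies. Only the *order* of e-values matters to the greedy pass; the
surrogate ranks stronger alignments first and leaves unrelated sequences
far above the 10⁻⁵ cutoff.

## The two-layer architecture

Positive windows are heterogeneous — turn types populate at least two
distinct regions of feature space — so a single decision boundary pays a
precision penalty. The architecture therefore:

1. splits the positive training windows into **two K-means clusters** on
   the original variables;
2. trains one RBF SVM per cluster against freshly drawn negatives at a
   1:3 positive:negative ratio, with probability calibration (libsvm's
   pairwise-coupling sigmoid fit, via `e1071`). These "clustered
   models" are *variable generators*, not predictors: each may be wrong
   on samples from the other mode;
3. pushes **all** training samples through both frozen clustered models
   and trains a second-layer RBF SVM on the 4-vector
   $(p_{1+}, p_{1-}, p_{2+}, p_{2-})$. The judgment of which generator
   to trust is learned by this layer.

Defaults are the published operating point: (C, γ) = (0.5, 2⁻⁷) for both
clustered models, (32, 8) for the second layer; `grid_search_svm()`
offers the customary exhaustive sweep (C ∈ 2⁻⁵..2¹⁵, γ ∈ 2⁻¹⁵..2³,
multiplicative step 4, 5 inner folds, ties to the smallest C then γ)
when tuning is wanted.

Two ambiguities were decided as follows. The second layer is trained on
the meta-features of the same samples that built the first layer — the
protocol "all the samples enter both clustered models" is taken
literally for plain training, which is mildly optimistic; the
cross-validation protocol below removes that optimism where it matters.
And the two negative sets are drawn independently per clustered model,
so they may overlap.

## Evaluation protocol

`cross_validate()` forms **sample-level** random folds of equal size
(remainder spread one per fold, default k = 7). For each fold the entire
model — K-means split, both clustered models, second layer — is refit on
the remaining folds; the held-out fold is scored once. Pooled
predictions give

$$Q_{total} = 100\frac{TP+TN}{N},\quad
  Q_{predicted} = 100\frac{TP}{TP+FP},\quad
  Q_{observed} = 100\frac{TP}{TP+FN},$$

$$MCC = \frac{TP\cdot TN - FP\cdot FN}
 {\sqrt{(TP+FP)(TP+FN)(TN+FP)(TN+FN)}},$$

plus the ROC and its area computed by the midrank Mann–Whitney method.
Zero-denominator conventions are ours: Q_predicted is 0 with a warning
when nothing is predicted positive, MCC is 0 when any factor is zero; an
evaluation set without observed positives is an error. Measures are
window-level (the protocol's samples); `reduce_to_residues()` maps
window scores to per-residue calls (max over windows centring the
residue) as clearly-labelled plumbing for downstream use.

Sample-level folding lets windows of one chain span folds — a homology
leakage the protocol accepts by construction. `chain_level = TRUE`
offers leak-free folding with a warning that it departs from the
protocol and yields unequal folds.

## Parameters that matter

| parameter | default | units / range | why |
|---|---|---|---|
| `distance_cutoff` | 7 | Å, strict `<` | the geometric turn definition |
| `helix_rule` | `"all"` | all/any of the quadruple | weakest reading of the helix veto; `"any"` is stricter |
| e-value threshold | 1e-5 | — | homology-transfer admission cutoff |
| `window_size` | 8 | residues, even ≥ 4 | central four well defined |
| `neg_ratio` | 3 | neg:pos | class-balance of each clustered model |
| `k_clusters` | 2 | — | two positive modes |
| first layer (C, γ) | (0.5, 2⁻⁷) | — | clustered-model operating point |
| second layer (C, γ) | (32, 8) | — | stacked-model operating point |
| CV folds | 7 | — | evaluation protocol |

## Numerical and degenerate-input choices

* K-means: base `stats::kmeans`, Euclidean distance, `nstart = 10`
  random restarts, `iter.max = 100`, deterministic under the seed.
  Clusters are renumbered so cluster 1 is the larger (ties to the
  smaller centroid norm). An empty cluster triggers up to five retries
  with derived seeds, then an error.
* All randomness (fold assignment, negative sampling, K-means restarts,
  libsvm's calibration shuffle) is driven through one master seed;
  per-fold and per-cluster seeds are derived from it by fixed offsets,
  and the caller's RNG state is restored afterwards.
* Chains shorter than the window produce zero samples, not an error;
  chains shorter than four residues produce an empty turn annotation.
  The first two and last five residues are never window centres — no
  terminal padding is invented.
* Non-standard amino-acid letters map to X; X residues keep their
  (scaled) PSSM row and contribute zero to no track.
* `scale_pssm()` refuses already-scaled input so the squash cannot be
  applied twice; trained models refuse samples whose feature width
  disagrees with their encoding.
* Deterministic tie-breaks everywhere: e-value then db id in hit
  ranking; smallest C then smallest γ in grid search.

## What the synthetic generators emulate — and what they do not

`make_geometric_chain()` realises the turn predicate by construction: an
extended 3.8 Å-per-step backbone (end-to-end 11.4 Å per quadruple) with
a square hairpin folded at each requested start (end-to-end 3.8 Å);
consecutive hairpins alternate sides so no unrequested quadruple closes.
The constructor re-checks itself against `label_beta_turns()` before
returning.

`make_feature_world()` plants exactly the structure the architecture
assumes: two compact positive modes (separation 10 within-cluster SDs,
the modes jointly offset from a broad negative background) in 256
dimensions, 2,000 samples at a 1:3 ratio, logistically squashed into
[0, 1]. `make_full_study()` writes a complete miniature study in the
real input dialects — 40 chains of 30–60 residues, turn-opening density
0.08 per eligible position (≈ a quarter of residues inside turns, the
biological rate), PSSM mean shifts on turn rows in one of two column
blocks (two turn flavours → two feature modes), coil-enriched secondary
structure and T/G-enriched shape states at turns, and a shape database
of 10 %-mutated copies.

None of this mimics real amino-acid composition, real PSSM marginals or
real turn-type geometry. Passing tests therefore demonstrate that the
pipeline is *correct* (readers, encodings, greedy transfer, stacking,
protocol) and that it *recovers planted structure*; they say nothing
about accuracy on real proteins, which depends on real PSSMs, real
secondary-structure predictions and a real shape database. Likewise the
geometric labels approximate, but are not, PROMOTIF output: PROMOTIF
additionally classifies turn types from dihedrals, which is out of
scope here.

Test and verification problem sizes — 2,000-sample planted worlds,
40-chain studies, 100–200-instance property sweeps — were chosen as the
smallest sizes at which the planted structure is unambiguous; the
generators scale to larger studies by changing `fixture_spec()`.

## Known limitations

* On sparse, realistic class balances (turn windows ≪ 25 % of samples)
  the stacked model's *ranking* (AUC) can trail the flat baseline even
  while its precision leads; the architecture optimises the
  high-precision operating point, and the score is a calibrated
  probability only at the second layer.
* The built-in search backend's e-values are surrogates: correct in
  order, not calibrated against any database size. Use an external
  profile-search adapter when real e-values matter.
* A naive all-vs-all identity filter is the only redundancy reduction
  provided; it is adequate for fixture-scale sets only.
* Sample-level cross-validation shares chains across folds (see above).
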