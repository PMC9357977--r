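---
title: "Forest graph-embedded feature selection with SVM classification: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Forest graph-embedded feature selection with SVM classification: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Virtual screening asks whether a candidate molecule is likely active
against a disease-relevant target, given a small set of known actives
and a larger set of presumed-inactive decoys. `forgenet` implements a
feature-selection-then-classification approach for this setting: fused
molecular fingerprints are very wide (thousands of columns) while
screens are small (a few hundred compounds), so a classifier benefits
from a prior step that ranks and prunes features. The ranking here
comes from a *forest graph-embedded deep feed-forward network*: a
random forest supplies a feature graph, the graph constrains the first
layer of a neural network, and the trained network's connection weights
score each feature.

## Feature construction

Each compound, given as a SMILES string, is expanded into three blocks:

* **ECFP6** — a circular (Morgan) fingerprint of radius 3 (diameter 6)
  hashed to 2048 presence/absence bits;
* **MACCS** — the 167 predefined substructure keys;
* **2D descriptors** — a frozen, ordered list of 208 physicochemical
  descriptors (molecular weight, logP, ring and atom counts,
  topological indices, fragment counts, ...), shipped as
  `inst/extdata/rdkit_descriptors_208.txt` so the block's width and
  order never drift with toolkit upgrades.

The blocks are concatenated in that fixed order, giving
2048 + 167 + 208 = 2423 fused columns, and every fused column maps back
to exactly one (block, index) pair. Fingerprint bits are left as 0/1;
the descriptor span is z-scored by default, with statistics fitted on
training rows only and re-applied to test rows, because unscaled
descriptors (molecular weight is in the hundreds) would otherwise
dominate the binary bits in any distance- or weight-based learner.
Non-finite descriptor values are replaced by 0 with a warning rather
than propagated; an empty or unparsable SMILES is an error naming the
offending compound id, never a silent all-zero row, because silent
zeros would corrupt a decoy set unnoticed.

The chemistry itself (SMILES parsing, fingerprint and descriptor
evaluation) is delegated to the RDKit toolkit, invoked as a batched
subprocess through the `python` interpreter on the PATH; the package
contains no hand-rolled SMILES parser. Reference bit patterns for small
molecules (ethanol, benzene) were computed once from that toolkit and
are frozen in the test suite as the featurization contract.

## From forest to feature graph

A classification random forest with `p` trees (default 1000, Gini
impurity, bootstrap resampling, `sqrt(d)` feature subsampling) is
fitted on the training matrix. Each tree is read as a directed graph
over *features*: walking every root-to-leaf path, each parent split
feature sends an edge to the split feature of each of its non-leaf
children; leaves contribute nothing. The per-tree edge sets are then
combined by plain set union.

Two finalization choices are deliberate:

* **Symmetrization and unit diagonal.** The union graph is made
  symmetric (`A | t(A)`) and every feature receives a self-loop. The
  graph's only consumer is a Hadamard mask on a weight matrix, where
  direction has no meaning, and the self-loop guarantees each feature
  reaches its own hidden unit even if no tree ever paired it with
  another feature.
* **Binary adjacency.** Edge multiplicity across trees is discarded;
  the union is a set union, not a weighted sum. A count-weighted mask
  would conflate the forest's feature-usage frequency with the
  network's own learning, and the importance score below already
  reflects usage through degree.

Features never split on end up with only their self-loop, so they can
still carry weight but receive no lateral connectivity.

## The graph-embedded network and GCW scores

The network is `d -> d (masked) -> 64 -> 16 -> 2`: the input layer maps
to one hidden unit per feature through a `d x d` weight matrix
Hadamard-multiplied by the adjacency, followed by two dense ReLU layers
and a 2-class softmax head trained by cross-entropy. Defaults follow
the method's published protocol where one exists — learning rate
1e-4, 50 epochs, linear-kernel SVM downstream, 1000 trees — and
otherwise are ordinary small-network choices documented here: hidden
widths 64 and 16 (a small funnel adequate for d in the hundreds to low
thousands), ReLU activations, Adam optimization, mini-batch size 32.
Weight initialization is He-scaled Gaussian. Class imbalance (1 active
: 3 decoys) is left unweighted by default, with an optional
class-weight argument.

Masking is enforced exactly, not approximately: the masked gradient is
applied and the weight matrix is re-multiplied by the mask after every
update, so `W_in * (1 - A) == 0` holds bit-for-bit at any point in
training. Weight init and batch shuffling draw from R's RNG under the
caller's seed; the update loop itself (compiled with RcppArmadillo) is
deterministic arithmetic, which is what makes end-to-end runs
reproducible by seed. A non-finite training loss aborts with a
diagnostic rather than continuing silently.

The **Graph Connection Weights** score of feature *i* sums the absolute
masked first-layer weights into and out of unit *i*, plus the absolute
weights from unit *i* into the next hidden layer:

    c_i = sum_a |W_in[i,a]| 1(A[i,a]=1)
        + sum_b |W_in[b,i]| 1(A[b,i]=1)
        + sum_c |W1[i,c]|

The third sum is implemented ungated. The gated variant one might write
(`gated = TRUE`) conditions it on the feature's self-loop indicator,
which is identically 1 on finalized graphs, so the two variants
coincide there; the flag exists to make that reading explicit and
testable. Scores are non-negative by construction and 1-homogeneous in
the weights. Ranking is by descending score with ascending-index
tie-break, making `select_top_k` deterministic and idempotent.

Note what GCW rewards: a feature's score grows both with its trained
weight magnitudes and with its graph degree, i.e. with how often the
forest paired it with other features. That coupling is the point of the
method — forest usage and network learning reinforce each other — but
it also means GCW is not a pure measure of the trained network.

## The SVM stage

The top-k features (k = 900 on 2423-wide fused data, per the published
protocol's grid choice) feed a soft-margin kernel SVM. The dual

    min_a  1/2 sum_ij a_i a_j y_i y_j K(x_i, x_j) - sum_i a_i
    s.t.   sum_i a_i y_i = 0,   0 <= a_i <= C

is solved by sequential minimal optimization with maximal-violating-
pair working-set selection; training stops when the violating pair's
gap falls below `tol` (default 1e-4). Pairwise updates preserve the
equality constraint exactly, so `|sum_i a_i y_i|` is at machine
precision in any returned model. The published formulation is the
hard-margin dual (`a_i >= 0` unbounded above); a box constraint C
(default 1) is introduced because fused chemical data are not
separable, and the hard-margin behaviour is recovered at large C. The
bias is the mean over free support vectors of `y_k - f(x_k)`, falling
back to the feasible-interval midpoint when every support vector is at
bound. Four kernels are provided — linear (the default, matching the
published choice), polynomial `((x.z)+1)^d`, RBF
`exp(-||x-z||^2/(2 sigma^2))`, sigmoid `tanh(k(x.z)+theta)` — and
`sign(0)` maps to the positive class so tie behaviour is deterministic.

The solver contract, not the algorithm, is what the tests pin down: on
small problems the attained dual objective is compared against an
exhaustive KKT-subsystem enumeration (all 3^n assignments of each
multiplier to {0, C, free}) written independently of the solver, and
against an established SVM library as a second opinion.

## Evaluation protocol

* **Metrics.** TPR, FPR, Precision, Specificity, F1 from the confusion
  counts; any zero-denominator rate is reported as undefined and
  rendered blank (F1 uses the count form `2TP/(2TP+FP+FN)`, which
  stays defined when precision is undefined but recall is not). AUC is
  the tie-aware normalized Mann-Whitney statistic; ROC points come
  from a threshold sweep.
* **Cross-validation.** Stratified k-fold (default 10) with per-class
  remainders staggered so fold sizes differ by at most one. Headline
  numbers pool confusion counts across folds (micro aggregation), with
  per-fold reports and their mean also returned, since pooling versus
  averaging is a genuine protocol ambiguity. The pooled AUC
  concatenates held-out decision values across folds.
* **Selection scope.** `per_fold` (default) refits forest, network and
  selection inside each training fold, so the held-out fold never
  influences selection; `global` performs one selection pass on the
  full data first, mimicking a single-pass protocol at the cost of
  leakage. The suite checks the expected direction: global pooled F1
  is at least per-fold's on planted data.
* **70/30 split.** Stratified with floor allocation to the test set,
  so 94 actives / 282 decoys yield 28 positive and 84 negative test
  compounds.
* Reports render rates at six decimals and are byte-identical across
  reruns with the same config and seed.

## The synthetic generator

Real screens of this kind are built from undeposited compound lists,
so the package ships a planted-feature generator that emulates the
*structure* the method assumes: `m = 94` actives and `3m = 282` decoys
(the 3-per-active, sampled-without-replacement convention), a wide
binary span plus a narrow real-valued "descriptor" span, and a small
informative subset. Defaults, fixed once: d = 500 columns (40 of them
real-valued), 20 informative columns drawn uniformly across the width,
informative bits firing at 0.6 in actives vs 0.2 in decoys, background
bits at 0.1, informative real columns shifted by +1 standard deviation
in actives. d = 500 rather than the full 2423 keeps the repeated
cross-validation studies desk-scale; a `planted_spec_fullwidth()`
profile exists for full-width integration runs. On synthetic runs the
pipeline uses `k_selected = 100` (~top 20% of 500), since the
real-data default k = 900 exceeds the synthetic width.

What the generator does *not* emulate: correlated fingerprint bits
(real ECFP bits co-fire along substructures), property-matched decoys
(real decoy services match molecular weight and charge, making the
task harder), and any chemistry in the column identities. Passing the
planted-recovery and AUC suites therefore demonstrates that the
pipeline finds independent planted signal at realistic sample sizes —
not that it would match published screening performance on real
compounds.

The study sizes used by the test suite and the acceptance script —
5 seeds for the recovery and cross-validated AUC medians, 1000 trees,
50 epochs — are the package's chosen defaults for a desk-scale
reproduction of the protocol.

## Numerical and degenerate-input choices

* Masked entries are exactly zero: the masked layer's update touches
  only the graph's nonzero entries, so the complement never moves off
  its zero initialization.
* Network training runs in single precision (the standard working
  precision for neural-network training) with denormal flushing —
  Adam's second-moment decay otherwise drifts into subnormal floats,
  where x86 arithmetic slows by orders of magnitude. Importance
  scores are accumulated in double precision from the final weights.
* Softmax is computed with row-max shifting; probabilities are clamped
  at 1e-12 inside the log.
* SMO uses second-order (max-gain) working-set selection with a
  periodic error-cache refresh against floating drift; non-positive
  pair curvature is clamped at 1e-12 and blocked pairs fall through to
  the next-best partner. If no pair can move, the solver stops at its
  progress floor (the gap is then at tolerance scale); exceeding the
  iteration cap is an error.
* Ties: feature ranking breaks by ascending index; `sign(0) = +1`;
  AUC gives half-credit to tied scores.
* Single-class inputs, fold/class starvation, width mismatches, k out
  of range, undersized decoy pools and unparsable SMILES all raise
  typed errors early.

## Known limitations

* GCW's degree coupling (above) means very high-degree features can
  rank highly with modest trained weights.
* The forest-to-graph rule reads parent-child split adjacency only;
  it does not weight edges by split quality or depth.
* The SMO solver is plain R over a precomputed Gram matrix: fine for
  hundreds of training rows (this method's regime), not for tens of
  thousands.
* Featurization requires a Python interpreter with RDKit on the PATH;
  all downstream stages are pure R/C++ and run without it, e.g. on
  pre-featurized TSV inputs or synthetic data.
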