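---
title: "DTW clustering with exact lower-bound pruning: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{DTW clustering with exact lower-bound pruning: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(warpclust)
```

This vignette is the package's own account of the methods it implements: the
distance model and its bounds, the two clustering engines built on them, the
agreement indices, the synthetic benchmark generator, and the narrative-arc
stage, together with the numerical and design choices made where more than
one defensible option existed.

## The distance model

Two equal-length series $q, t \in \mathbb{R}^m$ are compared with windowed
dynamic time warping. A warping path is a sequence of index pairs starting at
$(1,1)$, ending at $(m,m)$, advancing by $(1,0)$, $(0,1)$ or $(1,1)$ (so the
alignment is monotone and non-crossing) and confined to the Sakoe–Chiba band
$|i - j| \le W$. The DTW distance is

$$\mathrm{dtw}(q, t; W) \;=\; \sqrt{\min_{\text{paths}} \sum_{(i,j) \in \text{path}} (q_i - t_j)^2}.$$

**Local cost convention.** The accumulated cost uses squared differences and
the square root is taken once at the end. This choice is what makes the two
bounds commensurate with the distance itself: the identity alignment is a
legal path, so the pointwise Euclidean distance is a true upper bound, and
the LB_Keogh quantity below — which also takes a root of summed squared
penalties — is a true lower bound. With an absolute-difference local cost
neither bracketing would hold, and the exactness proof for pruning would
collapse. Sum-of-absolute-differences DTW is therefore deliberately not
offered.

**Window.** $W$ is specified as a fraction of the series length and converted
by $W = \max(1, \lfloor f \cdot m \rfloor)$ (`dtw_window()`). The default
$f = 0.05$ is the setting commonly found optimal for archive-scale
benchmarking; the narrative stage uses $f = 0.10$ (one decile of its
ten-point series). The floor of 1 keeps the band meaningful for very short
series; $W = m$ recovers unconstrained DTW. Window endpoints at the series
edges are clipped to $[1, m]$ when building the envelope — the alternative
(virtual padding) would manufacture values the data does not contain.

**Bounds.** For a query $q$ the envelope is $U_i = \max(q_{i-W..i+W})$,
$L_i = \min(q_{i-W..i+W})$, and for a candidate $t$

$$\mathrm{LB}(t; U, L) = \sqrt{\sum_{i=1}^m
  \begin{cases}(t_i - U_i)^2 & t_i > U_i\\ (t_i - L_i)^2 & t_i < L_i\\ 0 & \text{otherwise.}\end{cases}}$$

The package maintains the sandwich
$\mathrm{LB} \le \mathrm{dtw} \le \mathrm{euclidean}$ as a tested invariant
(property tests over seeded random pairs, and equality of the DTW
implementation with an independent full-matrix dynamic programme and, at tiny
$m$, exhaustive path enumeration).

## Exact pruning

To find the DTW-nearest among $n$ candidates: compute all $n$ Euclidean
distances, set the threshold to their minimum, evaluate LB_Keogh per
candidate, and run full DTW only where $\mathrm{LB} \le$ threshold. A pruned
candidate satisfies $\mathrm{dtw} \ge \mathrm{LB} >$ threshold
$\ge \mathrm{euclidean}(q, c^\*) \ge \mathrm{dtw}(q, c^\*)$ for the
Euclidean-minimising candidate $c^\*$, so it can never be the argmin: pruning
is exact, which is the central property of the package and is asserted
end-to-end (identical labels, weights and index values with pruning on and
off, for the same seed).

Numerical choices:

* Candidates whose lower bound *equals* the threshold are kept (the prune
  test is strictly greater). On degenerate inputs — e.g. a constant query,
  whose envelope has zero width — the lower bound and the threshold are
  mathematically equal but can differ by a few units in the last place
  because they are summed in different orders; a relative epsilon
  ($10^{-9}$) on the prune test absorbs this. The epsilon can only *keep*
  candidates, so exactness is unaffected.
* Ties in the DTW argmin break toward the lowest candidate index, making
  searches deterministic in the input order, with or without pruning.
* The search consumes no random numbers, so toggling pruning cannot shift
  any seeded trajectory — this is what makes the bitwise pruned/unpruned
  comparisons meaningful.
* Searches with a surviving set of size one still compute that candidate's
  DTW (its Euclidean distance would overstate the reported distance).

## The self-organizing map engine

`train_som()` trains a 2-D mesh of $M = \text{rows} \times \text{cols}$
nodes whose weights are themselves length-$m$ series. Per epoch, every
observation (in a seeded shuffled order) finds its best matching unit (BMU)
by pruned search, then all node weights move toward it:

$$w_i \leftarrow w_i + \alpha_t\, e^{-d^2 / 2 r_t^2}\, (x_i - w_i),$$

with $d$ the (optionally toroidal) grid distance to the BMU and linear decay
$\alpha_t = \alpha_0 (1 - t/E)$, $r_t = \max(1, r_0 (1 - t/E))$ over the
fixed budget of $E$ epochs (default 100; no early stopping).

Design choices that were genuinely open:

* **Initialisation** samples node weights uniformly (with replacement) from
  the dataset. Weights start inside the data range, so DTW windows and
  envelopes are meaningful from epoch 0 and the convex update keeps them
  there — a tested invariant.
* **Kernel and decay.** A Gaussian neighbourhood kernel with linear decay,
  $\alpha_0 = 0.9$ and $r_0 = \max(\text{rows}, \text{cols})/2$. The radius
  floor of 1 means adjacent nodes always retain a residual pull
  ($e^{-1/2} \approx 0.61$ of the BMU's rate). A consequence worth knowing:
  on very small meshes the stationary weights are *contractions* of the
  cluster means toward each other, not the means themselves. Cluster
  membership and classification are unaffected (the ordering of distances is
  preserved), and this is how the degenerate two-cluster fixture is asserted
  in the tests.
* **Updates are pointwise**, not along the warping path: all series share a
  length, so index-wise averaging is well defined and keeps the update a
  convex combination per time step. Path-wise (Kohonen–Somervuo) averaging
  would be required for variable-length data, which is out of scope.
* **Topology** is toroidal by default (no privileged edge nodes);
  configurable.
* **Classification mode** (`k = ...`) lays out a $1 \times k$ mesh and uses
  BMU indices directly as class assignments.

The U-matrix (`som_umatrix()`) is the per-node mean DTW distance to its
4-neighbours (wrapping when toroidal) and is all zeros exactly when all
weights coincide. Per-epoch instrumentation records learning rate, radius
and the pruning counters, whose conservation
($n_\text{pruned} + n_\text{dtw} = n_\text{candidates}$) is asserted at
every epoch. As the map organises, node weights approach the data and the
Euclidean thresholds tighten, so DTW calls per epoch drift downward — the
package asserts the first-to-last-quartile decline on the default benchmark.
With only $k$ nodes the absolute pruning fraction is modest (a few percent);
the k-means engine, whose centroids stabilise quickly, prunes half or more
of its comparisons under the same instrumentation.

## The k-means engine

`dtw_kmeans()` alternates pruned DTW assignment with centroid updates for at
most `iterations` rounds (default 10), stopping early when the labelling
repeats. Choices:

* **Centroid update** is the pointwise arithmetic mean of the members —
  valid for equal-length series, cheap, and deterministic. DTW barycenter
  averaging would better centre heavily warped clusters but costs an inner
  optimisation per centroid per round; with the modest warps this package
  targets, the mean was chosen.
* **Initialisation** draws $k$ distinct members (seeded, no replacement).
* **Empty clusters** are re-seeded with the observation farthest (by DTW)
  from its assigned centroid, so exactly $k$ centroids always survive.
* Like any Lloyd-style procedure the result is a local optimum: on the
  default benchmark an occasional seed splits one class across two initial
  centroids and plateaus below perfect agreement. This is inherent to the
  procedure, not to pruning, which never changes an assignment.

## Agreement indices

`cluster_metrics()` computes ARI (Hubert–Arabie), AMI, RI, homogeneity,
completeness and Fowlkes–Mallows from the contingency table alone, making
all six invariant to label renaming. Conventions, where the literature
allows several:

* **AMI normaliser** is $\max(H(U), H(V))$.
* **Homogeneity / completeness** are defined as 1 when the corresponding
  entropy is zero (a single-class reference is trivially homogeneous, etc.),
  and the expected mutual information uses the exact hypergeometric form.
* Degenerate ARI cases (both partitions trivial) score 1; a single
  observation is rejected as degenerate input.

The implementation is cross-checked in the tests against an independent
reference implementation on hundreds of random label pairs at $10^{-9}$, and
against brute-force all-pairs counting.

## The synthetic benchmark generator

`synth_dataset()` is the package's test bed: distinct smooth prototypes
(sinusoids of differing frequency/phase), each copy passed through a random
*monotone* time re-indexing with displacement at most `warp_steps` and
Gaussian observation noise, then shuffled. The warping construction — add a
smooth random displacement field to the index vector, round, clip, sort —
guarantees monotonicity and the displacement bound simultaneously (sorting
values each within $w$ of their position keeps every one within $w$).

The default specification is 3 classes × 20 series, $m = 60$, `warp_steps`
= 3 (matching the default 5% DTW window) and `noise_sd` = 0.1 against
unit-amplitude prototypes. These are the generator's study conditions: class
structure is recoverable under DTW (within-class distances sit below
between-class distances) but copies are not lock-step aligned, so the
warping machinery is actually exercised. What the generator does *not*
emulate: variable lengths (excluded by design throughout), trends or
non-stationary noise, class-dependent variance, or the shape diversity of
real archives — a perfect score here shows the pipeline recovers planted
warped-prototype structure, not that it will score highly on any particular
real dataset.

## The narrative-arc stage

`decile_series()` stratifies a conversation into ten equal word-count bins
("narrative time") and computes, per bin, the proportion of future-tense
verbs among past- plus future-tense verbs; 0.5 is the neutral point.
`savgol_smooth()` applies the classical Savitzky–Golay filter (order 2,
window 9 by default), `build_corpus()` filters short conversations, smooths
and clamps. Decisions:

* **Empty deciles** (no past/future verb) take the neutral value 0.5 rather
  than NA or zero — any other fill would bias the series toward one talk
  direction on sparse bins.
* **Length filter in words**, default 2000 (roughly a 15-minute conversation
  at typical speaking rates), because the stage sees transcripts, not audio
  with timestamps.
* **Boundary handling** for a 9-point window on a 10-point series: boundary
  points take the value, at their own position, of the polynomial fitted on
  the nearest full window — no padding is invented. The filter is linear
  (tested) and reproduces constants and straight lines exactly.
* **Clamping to [0, 1]** happens after smoothing (a quadratic fit can
  overshoot a proportion scale), and only in `build_corpus()`, so
  `savgol_smooth()` itself stays linear.

The stage's end-to-end test plants two conversation styles (future-leaning
vs past-leaning token streams) and requires the SOM two-node classification
to recover them.

## Problem sizes and determinism

Every stochastic step takes an explicit integer seed and is reproducible
from it; pruned and unpruned runs under one seed are bitwise identical. The
test suite and the acceptance script run the engines at the default
benchmark scale (60 series of length 60, 100 epochs, five seeds), with 500
randomized search instances, 1000 bound-sandwich pairs, and oracle
comparisons up to $m = 100$ — sizes chosen so the full evidence chain (exact
primitives → exact pruning → unchanged clustering) is established in a few
seconds of compute while still exercising each pathway at a scale where
pruning visibly pays.

## Known limitations

* Equal-length, univariate series only; no z-normalisation is applied
  internally (archive-style inputs are assumed normalised upstream if
  desired).
* No early abandoning inside the DP recursion and no additional bound
  cascades; the pruning here is the envelope bound alone.
* K-means can stall in local optima (above); the SOM's small-mesh weights
  are contracted toward each other by the neighbourhood floor (above).
* The temporal-reference tagger itself is out of scope: the narrative stage
  consumes pre-tagged tokens.
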