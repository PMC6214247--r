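---
title: "Topological pain markers in time-varying connectomes: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Topological pain markers in time-varying connectomes: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(painmark)
```

## The analysis problem

painmark analyses how the topology of a functional brain connectome
reorganizes while pain becomes chronic, and whether that reorganization
tracks a behavioural readout of pain. The data model is a *time-varying
connectome series*: at each of a handful of recording time steps (hours to
days after a nerve injury), an ensemble of hundreds of short-time weighted
adjacency matrices over the same set of probes (here 31 nodes spanning
primary somatosensory cortex, S1, and the ventral posterolateral thalamus,
VPL), plus one behavioural value per step — a Von Frey mechanical withdrawal
threshold in grams, where *lower* values mean *more* pain.

The pipeline has three independent arms:

1. **Correlation analysis.** Fourteen topological measures are computed on
   every matrix of every ensemble; their per-step means form 14 time
   courses. Each course, and the behavioural course, is interpolated on an
   hourly grid and their correlation (Pearson and Spearman) is assessed with
   a dedicated permutation significance test.
2. **Unsupervised comparison.** The 15 interpolated signals are embedded
   with PCA (linear) and Minimum Curvilinear Embedding (nonlinear), to check
   without labels which topological markers cluster with the behavioural
   signal.
3. **Engram analysis.** A representative connectome per step is selected,
   its links are split into intra-S1, intra-VPL and inter-regional, and the
   links retained between consecutive representatives are counted —
   persistent connectivity read as a topological memory trace.

## The fourteen measures

Nine measures are deterministic: average node degree (AND), characteristic
path length (CPL), average efficiency (AE), average clustering coefficient
(ACC), average closeness centrality (ACCE), average node and edge
betweenness centrality (ANBC, AEBC), average radiality (AR), and the
local-community-paradigm correlation (LCP-corr). LCP-corr is the odd one
out: for every link whose endpoints share more than one common neighbour
(CN), it also counts the links *among* those common neighbours (LCL, the
local community links), and summarizes the network by the Pearson
correlation between the CN and LCL arrays. High values (above about 0.7)
mean the network is organized in local communities whose members
cross-interact — the architecture under which adding links inside a
community (rather than re-weighting existing ones) is the natural mode of
learning.

Five measures are stochastic, i.e. defined against randomized null
networks: small-worldness sigma (clustering and path length against
degree-preserving randomizations), small-worldness omega (clustering
against a latticized equivalent, path length against a randomization —
robust to the small and noisy clustering of random nulls), the power-law
goodness-of-fit p-value of the degree distribution, modularity Q of the
best partition found, and structural consistency (link predictability from
a first-order eigen-perturbation after random link removal).

Conventions that the formulas leave open are fixed as follows:

* All measures operate on *binarized* connectomes only; calling one on a
  weighted connectome is an error, never a silent cast. The default
  binarization threshold is 0 (any positive coherence is a link), a
  configurable choice since the upstream coherence pipeline does not fix
  one.
* Disconnected graphs: CPL and closeness average over connected
  (reachable) pairs only; efficiency gives unreachable pairs a zero
  contribution; radiality is undefined (`NA`) unless the graph is connected
  with diameter at least 2. Ensembles of short-time functional connectomes
  transiently disconnect, and dropping whole matrices would bias the step
  means.
* Betweenness sums over unordered pairs with endpoints excluded, with no
  normalization beyond the leading `1/n` (or `1/|E|`).
* Clustering of nodes with degree below 2 is 0 (the formula is 0/0 there).
* Undefined values (radiality on a complete graph, LCP-corr with constant
  arrays) are explicit `NA`s, carried through summaries as dropped-and-
  counted, never as zeros.

### Null networks

Degree-preserving randomization uses double-edge swaps (10 attempted swaps
per link by default), resampling any swap that would disconnect a connected
input. Latticization accepts a swap only when it reduces the total
wrap-around band distance `sum min(|i-j|, n-|i-j|)` of the link set — a
greedy band-compaction whose fixed point is a ring lattice, which matters
because the omega index compares a near-lattice graph's clustering to its
latticized null and should find them equal. Both run in compiled code with
R's RNG, so a single seed makes every null ensemble reproducible. The
default of 10 null realizations per index follows the package's stability
check (`stability_check()`): across seeds the standard error of sigma and
omega on 31-node study graphs is small against their means.

### Power-lawness

The degree-distribution fit follows the standard discrete recipe: exponent
by the approximate discrete maximum-likelihood estimator
`alpha = 1 + n / sum(log(x / (xmin - 0.5)))`, lower cutoff `xmin` chosen to
minimize the Kolmogorov–Smirnov distance between empirical and fitted tail
CDFs, and a goodness-of-fit p-value by semi-parametric bootstrap (body
resampled empirically, tail from the fitted law, each replicate refitted;
1000 replicates by default). The power-law hypothesis is accepted at
`p >= 0.1` — deliberately not 0.05; the acceptance threshold is a
convention of the goodness-of-fit literature, and in this pipeline the
p-value itself (not the verdict) is the time-varying marker. Zeta tail sums
are truncated with an integral correction; the truncation enters observed
and bootstrap statistics identically.

### Modularity and structural consistency

Modularity optimization is heuristic: seeded multilevel (Louvain)
restarts, greedy agglomeration, seeded random partitions and the
single-module partition (Q = 0) as a floor, each polished by a greedy
refinement that interleaves single-node moves (including splitting a node
into a fresh singleton) with pairwise community merges until neither
improves. The floor makes the reported Q never negative; the random
restarts guard against all deterministic starts sharing one basin of
attraction. Plain greedy agglomeration alone does not reliably reach the
optimum even on tiny graphs; on all small graphs we test (n ≤ 8, against
exhaustive partition enumeration) the combination attains the exact
optimum.

Structural consistency removes a random 10% of links, eigendecomposes the
remainder, rebuilds a first-order perturbed matrix with corrected
eigenvalues and unperturbed eigenvectors, and scores the fraction of the
removed links ranked among the top non-observed entries; the mean over 10
repeats is reported. Degenerate eigenvalues are resolved by the
decomposition's deterministic ordering and flagged with a warning.
Perturbation fraction and repeat count are exposed because the measure's
literature leaves them open.

## Interpolation and the significance test

The recording schedule is irregular (hour 3, then days 4, 6, 9, 11, 12, 15,
16 — mapped to hours as 3 and 24·d, the unique affine reading of a grid
that runs from hour 3 of day 1 to hour 24 of day 16). All signals are
interpolated on the hourly grid from hour 3 to hour 384 — 382 points — with
monotone piecewise cubic Hermite interpolation (PCHIP): knot derivatives
are weighted harmonic means of neighbouring secant slopes, zeroed where the
slope changes sign. The implementation is in the package because the
contract matters downstream: knots are reproduced exactly, linear data is
reproduced exactly, monotone spans stay monotone, and no interval ever
leaves its local sample range. (R's `splinefun(method = "monoH.FC")`
preserves monotonicity but can overshoot around extremum knots, which would
leak interpolation artefacts into the correlations.) Interpolation uses the
per-step ensemble means only; the standard errors are carried for reporting
but not propagated, since they are small against the between-step dynamics.

Correlating two signals reconstructed by the *same* interpolation scheme
from only 8 points invites the objection that the interpolation itself
manufactures correlation. The significance test addresses exactly that
null hypothesis: draw a random behavioural 8-tuple, interpolate it the same
way, correlate it with the interpolated topological signal, repeat M times
(default 10,000), and report the two-tailed
`p = 2 min(#[C_rand <= c], #[C_rand >= c]) / M`. Two null models are used —
`G`, standard-normal white noise, and `DP`, permutations of the observed
behavioural values (distribution-preserving) — and the summary table keeps,
for the correlation of larger absolute value, the *larger* of the two
null-model p-values, the conservative choice. Two guard rails: the printed
formula can exceed 1 at the null median under ties, so the reported p is
capped at 1; and a continuity-corrected `(k+1)/(M+1)` companion value is
logged alongside but never substituted. Degenerate (zero-variance) null
interpolants are redrawn with a logged count, capped at 10·M attempts.
Under a true null the test is calibrated: across 500 simulated studies its
rejection rate at 0.05 stays within [0.03, 0.07] and its p-values are
near-uniform.

## Embeddings

For the unsupervised arm the 15 interpolated signals are z-scored row-wise
and sign-aligned: any signal anti-correlated with the behavioural reference
is multiplied by −1 (zero-correlation rows are left alone). PCA runs on
that matrix. MCE additionally requires quantile normalization of the rows
(enforced by a flag), then: Euclidean distances between rows, minimum
spanning tree (ties broken by lexicographic edge index, so the embedding is
reproducible), all-pairs path distances *over the tree* as the MC-kernel,
and SVD of the kernel **without** centering; coordinates are left singular
vectors scaled by singular values. Axis signs are arbitrary, so all tests
compare orderings up to a global flip. Some MCE variants drop the first
component; this is exposed as `skip_first` (default `FALSE`) rather than
guessed. Sign alignment precedes quantile normalization, a single
preprocessing chain. On signals generated along a warped one-dimensional
latent, MCE recovers the latent ordering on one of its first two axes with
|Spearman| > 0.9 while PCA needs two dimensions and plateaus below that —
the property that motivates carrying both embeddings.

## Engram analysis

The representative connectome of a step is the ensemble member whose
LCP-corr is closest to the step's mean LCP-corr (ties to the lowest index,
logged). Its links are classified by the region partition, and consecutive
representatives are intersected: "retained" is the exact edge-set
intersection, the minimal reading of a link maintained across an interval.
Intervals are labelled `3 h/4d`, `4d/6d`, … after their endpoints.

## The synthetic study generator

No public recordings exist for the study design this pipeline targets, so
the generator is the package's test bed and defines its study conditions. A
latent pain trajectory in [0, 1] — default
`c(0.2, 0.9, 0.5, 0.45, 0.6, 0.65, 0.7, 0.7)` over the 8 steps: an acute
spike at day 4, recovery, then a chronic rise and plateau from day 11 —
drives everything:

* **Behaviour**: `grams = 60 (1 − latent) + N(0, 1)`. 60 g is a realistic
  Von Frey ceiling for an uninjured rat hind paw; 1 g of noise keeps the
  monotone latent–behaviour link strong but not exact.
* **Topology**: the latent-0 end point is a structured connectome — two
  region-aligned ring-lattice communities (each node linked to its three
  nearest neighbours per side within its region) joined by six seeded
  bridges — whose LCP-corr is high, as in normal brain connectomes. A
  seeded trajectory of degree-preserving double-edge swaps, filtered so
  that each accepted swap does not increase LCP-corr, is truncated at
  `round(latent × 0.1 |E|)` to give each step's base graph. One trajectory
  is shared by all steps, so nearby latent levels share most of their
  links and the degree sequence never changes — average node degree is
  thereby a *planted negative control*, while LCP-corr is the planted
  positive marker. The swap budget of 0.1·|E| keeps the degraded ensembles
  above the noise floor that link-flip variability imposes on ensemble
  means; larger budgets push the planted range into a regime where the
  within-step noise dominates and the coupling is no longer recoverable.
* **Within-step variability**: each of the 1000 matrices per step flips
  every node pair independently with probability 0.02 (link noise rather
  than weight noise, because the downstream measures are binary); the
  middle 400 matrices are kept, mirroring the recording pipeline's
  reliability window.
* **Stability schedule**: the steps at days 4–9 additionally receive
  turnover — double-edge swaps accepted only when they leave LCP-corr
  within ±0.02 — so that the middle of the study is rewired independently
  step-to-step while the final steps share their backbone. Retained-link
  counts read this schedule out (consolidation from day 11 onward) without
  the turnover contaminating the planted behavioural coupling.

What the generator does *not* emulate: coherence-weighted matrices with
realistic weight distributions (weights exist only to exercise
binarization), electrophysiological autocorrelation between consecutive
short-time matrices, inter-animal variability, and any biophysics of LFP or
spiking. Passing tests therefore demonstrate that the pipeline recovers
planted structure of the study's shape and size — not that any particular
biological claim holds on real recordings.

## Problem sizes and reproducibility

Every stochastic operation takes an explicit seed, and one master seed
cascades to sub-seeds through a single helper, so studies, null ensembles
and reports are bit-reproducible. The test suite runs the full default
study (8 × 1000 → 400 matrices of 31 nodes) for the recovery checks with
M = 1000 null iterations, 500 simulated studies at M = 200 for test
calibration, exhaustive oracle comparison over every connected graph with
up to 6 nodes (142 isomorphism classes), and reduced ensembles elsewhere;
the pipeline's paper-fidelity configuration (M = 10,000, 1000 bootstrap
replicates per matrix) is available through `validate_config()` for
overnight-scale runs.

## Known limitations

* The two-tailed permutation p has resolution 2/M; at M = 1000 the smallest
  non-zero p is 0.002, and exact zeros are reported as printed (the
  continuity-corrected companion is available).
* The latticized null is a greedy local optimum, not the globally most
  clustered graph with the given degree sequence; omega inherits that
  approximation (as do all swap-based latticizations).
* The modularity heuristic is exact on small graphs but carries no
  optimality guarantee at 31 nodes; Q values are lower bounds.
* With 8 time steps, correlations are driven by few effective degrees of
  freedom; the significance test quantifies exactly this, which is why the
  pipeline reports its p-values rather than correlation magnitudes alone.
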