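---
title: "Methods: probabilistic Boolean rules, pseudo-attractors and perturbation scores"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: probabilistic Boolean rules, pseudo-attractors and perturbation scores}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(booleabayes)
```

# Scope and assumptions

This package infers a stochastic Boolean model of a transcription-factor
(TF) network from steady-state expression data and uses it to find
semi-stable network states ("pseudo-attractors") and to rank in-silico TF
perturbations by how strongly they destabilize those states.

The method assumes:

* **Steady-state, one-state-per-sample data.** Each sample (e.g. a bulk
  RNA-seq profile of a cell line) is treated as a noisy observation of one
  attractor state of the network. Within-sample mixtures of phenotypes
  violate this and blur the binarization.
* **A sparse, given network.** The regulator→target edge list is an input;
  in-degree must be far below the node count. The rule for a target with
  $N$ regulators is a dense vector over $2^N$ regulator configurations
  (leaves), so the loader refuses in-degrees above a hard cap (default
  20).
* **Bimodal expression of every network gene.** Rules are fitted on
  per-gene ON-probabilities from a two-component mixture; a gene that
  does not vary across phenotypes carries no binarizable signal. Such
  genes are flagged degenerate and contribute only maximal uncertainty
  (probability 0.5).
* **Partial constraint is a feature.** With $M$ samples concentrated at a
  few phenotypes and $2^N \gg$ the number of observed configurations,
  most leaves of most rules remain at 0.5. The dynamics then diffuse
  randomly in unobserved regions instead of extrapolating — this is what
  lets the model say "unknown" rather than overfit.

# Binarization

Each gene's values across samples are fitted with a univariate
two-component Gaussian mixture with **tied variance** (`mclust`, model
`"E"`), and every value is mapped to the posterior probability of the
larger-mean component. Tied variance guarantees the posterior is monotone
in expression; with unequal variances the wider component would dominate
both tails and high expression could map to low ON-probability.

Numerical choices:

* **Degeneracy.** A gene is degenerate — all probabilities set to exactly
  0.5 — when its total variance is below $10^{-12}$, the mixture fit
  fails, or the fitted means differ by less than $10^{-3}$ sample
  standard deviations.
* **Posterior snapping.** Posteriors within $10^{-6}$ of 0 or 1 are
  snapped to exact 0/1. Posterior "certainty" beyond that level is
  numerically meaningless at realistic sample sizes, and the snap makes
  an observation's membership weight in regulator configurations it does
  not realize exactly zero. Without it, unvisited leaves acquire tail
  weights of $10^{-30}$–$10^{-9}$, the fitted confidence drifts off 0.5
  by floating-point noise, and the strict pruning inequality (below)
  randomly misreads that noise as certainty, producing artifact
  attractors.

# Rule inference

For a target with ordered regulators $x_1,\dots,x_N$ (lexicographic;
first regulator = most significant bit of the leaf index), observation
$i$ constrains leaf $j$ with weight
$w_{ij} = P_j(R'_i) = \prod_k {R'_{ik}}^{b_k}(1-R'_{ik})^{1-b_k}$, where
$b$ is leaf $j$'s bit pattern; the weights of one observation sum to 1
over leaves. Leaf uncertainty is $u_j = 1-\max_i w_{ij}$ (the max over an
empty observation set is 0, so no data means $u_j = 1$), and the rule is

$$v_j \;=\; \frac{\sum_i t'_i w_{ij} + 0.5\,u_j}{\sum_i w_{ij} + u_j}.$$

Consequences worth knowing:

* Leaves never touched by data have $v_j = 0.5$ exactly; inconsistent
  observations at a leaf also average back toward 0.5.
* A node with zero regulators is the $N = 0$ limit: a single leaf with
  every observation at weight 1, so $v_0$ is the plain mean of the
  target's ON-probabilities.
* A self-loop makes the target an ordinary input of its own rule.
* Edge signs are carried through for reporting and for the deterministic
  baseline schemes, but inference itself is unsigned.
* `fitRule()` implements the formulas exactly (no tolerance, no
  regularization); the test suite holds it to $10^{-12}$ against an
  independent naive-loop oracle.

For validation, the prediction for an uncertain regulator state is the
leaf-probability-weighted expectation $\sum_j P_j(R') v_j$ — the only
estimator consistent with the leaf decomposition. Cross-validation
repeatedly splits samples 80/20 (train fraction floor), refits on the
training split, and reports per-gene mean squared error on both
partitions plus all (prediction, truth) pairs; the
confidence-stratified correlation curve restricts those pairs to
predictions below $x$ or above $1-x$ for a grid of window half-widths.

# Dynamics and the transition graph

Updates are general-asynchronous: one TF is chosen uniformly (fixed TFs
excluded, the choice renormalized over the rest) and flips with
probability equal to the rule output $v_j$ at the current leaf if it is
OFF, or $1-v_j$ if it is ON. The stored rule output is always the
ON-probability; the **flip probability** is derived from it and the
current value. This is the only reading under which a state where every
flip probability is below 0.5 has, for every possible update, at least a
50% chance of remaining unchanged — the defining property of a
pseudo-attractor. Self-transitions are implicit and never stored as
edges.

The bounded state-transition graph (STG) around an initial state gives
every state within Hamming radius $R$ one out-edge per TF, weighted by
that TF's flip probability; states just beyond the radius get a single
weight-1 edge to an out-of-bounds sink and are not expanded. The sink
prevents anything touching the boundary from being reported as stable.
A memory guard (default $3\times10^5$ vertices) aborts pathological
searches rather than thrashing.

# Pseudo-attractor search

Edges with flip probability **strictly below** the threshold $P_T$
(default 0.5) are pruned; strongly connected components of the pruned
graph that contain no sink and have no retained out-edge are the
pseudo-attractors. The strict inequality matters: a flip probability of
exactly 0.5 — the signature of an unconstrained rule — keeps its edge, so
fully uncertain regions leak toward the boundary and are not reported as
stable. Multi-state components (e.g. the six-state cycle of a
three-gene repression ring) are reported with all member states; the
lexicographically smallest member is the representative and seeds
downstream random walks.

Initial states come from the data: per cluster, each gene's mean
ON-probability is thresholded at 0.5 (ties to 0). Random-restart
search from uniform random states supplements the cluster-mean searches;
results are deduplicated by member-state set, and the attractor order is
canonical (by representative), so the set is independent of exploration
order. Attractors are assigned to the cluster whose reference state is
nearest in Hamming distance; ties go to the alphabetically first cluster
and are flagged, and all pairwise distances are retained.

The two classical deterministic schemes — inhibitory-dominant (ON iff at
least one activator ON and all inhibitors OFF) and majority (ON iff
strictly more activators than inhibitors ON) — are provided as baselines
over the same machinery; they require signed edges.

# Perturbation scoring

A random walk from an attractor state counts update events (including
non-flipping ones) until the Hamming distance from the start exceeds the
escape radius (default 4 TF changes). A perturbation holds one TF at 0
(knockdown) or 1 (activation); the start state is first modified to the
held value, distance is measured to the modified start (so the held TF
contributes 0 by construction), and the held TF is excluded from
updates. Escape must be possible: the escape radius must be below the
number of free TFs. The escape criterion is Hamming distance, not
graph-path length. Walks are censored at a step cap (default 5000;
deterministic attractors would otherwise never terminate) and censoring
counts are reported.

The stability score is $(\bar s - \bar s_{\mathrm{ref}})/\bar
s_{\mathrm{ref}}$ over 1000 walks per condition, against an unperturbed
reference from the same state; negative scores destabilize. Each
(attractor, perturbation) condition draws from its own recorded sub-seed,
so conditions are reproducible independently and in any order. Per-cluster
scores are unweighted means over the cluster's attractors; knockdown
scores at or below −0.2 define master regulators, activation scores at or
below −0.2 master destabilizers.

Expected escape times can also be computed exactly
(`expectedEscapeSteps()`) by making all states beyond the radius
absorbing and solving $(I-Q)\,t = \mathbf 1$ over the transient states;
the test suite holds the Monte-Carlo means to within three standard
errors of this solve, and the solve itself to a closed-form birth–death
reduction on an independent-gene fixture.

# Synthetic data generator

The generator emulates the package's intended input: a small TF network
whose attractor states are observed as expression clusters. Defaults
(chosen once, as the package's standard study conditions): 12 nodes, 4
attractor-clusters, 12 samples per cluster, OFF/ON means 1 and 6, noise
SD 0.5 on the log scale — a 10σ separation, so binarization is
near-deterministic and the recovery suite isolates the inference and
search machinery. A stress setting (σ = 1.5) exercises the uncertain
regime, where the confidence-stratified correlation curve becomes
informative. Values are truncated at zero by redrawing, matching the
non-negative log-expression input contract.

Two design points deserve explanation:

* **Planted fixed points.** `simulateDataset()` draws the cluster states
  first — distinct, and with every gene taking both values across them —
  and then samples regulators and truth tables consistent with those
  states being fixed points (`plantedBooleanNetwork()`; draws that would
  force two planted states to conflict on a shared leaf are rejected).
  Purely random networks almost never have four fixed points that vary
  in every gene, and a gene constant across all clusters is unimodal,
  binarizes to 0.5, and makes its phenotype states unrecoverable by
  construction. Real TF-network studies select differentially expressed
  TFs, which is exactly what the varying-gene condition emulates. The
  plain `randomBooleanNetwork()` (random tables, resample until a fixed
  point exists, exhaustively verified) is kept for property tests.
  Planted networks may own additional emergent fixed points beyond the
  planted four; these are genuine properties of the generating dynamics,
  and when the observed clusters happen to constrain one, finding it is
  correct inference, not an artifact.
* **Maximum in-degree 5.** With in-degree ≤ 3 a rule has at most 8
  leaves and 4 observed states cover most of them, so inference is
  nearly fully constrained — the opposite of the partially-constrained
  regime the method is designed for — and blends of cluster patterns
  become emergent fixed points at high rate. In-degree up to 5 gives 32
  leaves against 4 observed states (and in-degree well below the 12
  nodes), restoring the intended regime.

What the generator does **not** emulate: sequencing count noise
(library size, overdispersion), within-phenotype regulatory
heterogeneity, partially penetrant ("leaky") rules, or correlated noise
across genes. Passing the recovery suite therefore shows the
binarize→fit→search chain is correct under clean bimodal conditions; it
does not certify performance on real RNA-seq, where separation is weaker
and cluster purity imperfect.

# Test and acceptance problem sizes

The suite verifies rule fits on 200 random instances ($M\le20$,
$N\le4$) at $10^{-12}$; bounded attractor search against exhaustive
pruned-STG enumeration on 50 random probabilistic networks ($g\le8$);
Monte-Carlo escape times on two five-gene fixtures at 1000 walks per
condition against exact linear solves; end-to-end recovery on 20 seeded
12-node datasets; and cross-validation with 70 iterations of 80/20
splits. These sizes are the package's standard verification conditions;
all randomness is seeded.

# Known limitations

* Exhaustive checks (fixed-point enumeration, exact escape-time solves)
  are limited to small networks ($\le$ 12–14 nodes, by memory).
* The mixture is strictly two-component; graded (dose-like) expression
  or more than two expression states per gene are out of scope, as are
  multi-TF combination perturbations.
* Attractor↔cluster assignment uses Hamming distance on the discretized
  states; the assignment metric is recorded in the output so downstream
  consumers can revisit it.
* The random walk counts update events; an alternative reading of escape
  time (graph shortest-path length back to the start) exists in the
  field, would give systematically smaller numbers, and is intentionally
  not implemented.
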