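---
title: "A Boolean model of cofilin-1 signalling in pancreatic cancer: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A Boolean model of cofilin-1 signalling in pancreatic cancer: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cfl1bn)
```

## The model and its assumptions

`cfl1bn` analyzes a 33-node logical model of cofilin-1 (CFL1) signalling
in pancreatic ductal adenocarcinoma. Nodes are proteins or pooled protein
groups, each either inactive (0) or active (1); regulation is encoded as
Boolean expressions over AND/OR/NOT literals, curated from the
experimental literature. Three simplifications matter for interpretation:

- **Synchronous updates.** All nodes recompute simultaneously each time
  step. Time steps are logical, not physical: a step is "one round of
  signal propagation". Landmark statements such as "STAT3 becomes active
  at step 8" order events; they do not measure minutes.
- **Pooled nodes.** "Anti-apoptotic proteins", "Pro-apoptotic proteins"
  and "Caspases" are single nodes summarizing families (BCL2L1/MCL1;
  BAD/BAX/BAK; caspase-3/9). Predictions about them are qualitative.
- **Constitutive KRAS.** The KRAS node has the constant rule 1, since
  activating KRAS mutations are near-universal in this tumor type. The
  canonical initial condition — only KRAS active — models the earliest
  oncogenic lesion acting on an otherwise quiescent network.

### Time-delayed regulators

Three interactions are curated with explicit delays: `RHOA(-3)` on newly
polymerized F-actin, `RAC1(-2)` on ARP2/3, and
`Phosphorylated-CFL1(-3)` on RAC1. Each stands for a linear multi-step
cascade (e.g. RHOA→ROCK→DIA) collapsed into one edge. The adopted
semantics: a literal `X(-k)`, read while computing the state at time
`t + 1`, takes the value of `X` at time `t + 1 - k`, so `X(-1)` is the
ordinary synchronous regulator. `expand_delays()` compiles delays into
shift registers — `X.d1(t+1) = X(t)`, `X.d2(t+1) = X.d1(t)` — so a source
used with maximum delay `k` contributes `k − 1` registers (five for this
model, 38 nodes total) and the result is a plain synchronous network.

The off-by-one alternative (reading `X` at `t − k`) was rejected because
only the adopted convention, with the initial state indexed as step 0 and
registers initialized to their source's initial value ("constant
history"), reproduces the model's published event order on the canonical
trajectory — STAT3 at step 8, transient CYCS at step 9, CCND1 at step 12 —
which the test suite asserts.

At any fixed point every register equals its source, so fixed points of
the expanded network restrict to fixed points of the original rule system
with delays read as plain literals; this is checked property-style on 200
seeded random delayed networks.

## Dynamics, attractors, basins

`simulate_network()` iterates the synchronous update until a state
recurs, recording the transient and cycle; a trajectory that does not
resolve within `max_steps` (default 1000; the bound exists because the
caller may pass a tiny value) is flagged `unresolved`, never silently
truncated.

Attractor search combines two routes:

- **Exact fixed points** (`fixed_points()`): complete backtracking search
  with three-valued constraint propagation over the node assignments —
  each node's truth table is evaluated under the partial assignment, and
  any forced value `f_i(x) = x_i` is propagated. No sampling is involved.
  Only length-1 attractors are enumerated exactly; the model's reported
  attractors are fixed points, and complete cycle enumeration on 2^38
  states is out of scope.
- **Sampled cycles** (`find_attractors()`): trajectories from `n_starts`
  uniformly random initial states (default 100,000 where the analysis
  scale matters; biological nodes independent Bernoulli(1/2), registers
  constant-history). Attractors are deduplicated by the canonical key of
  the cycle restricted to biological nodes — the lexicographically least
  rotation — so attractors differing only in register phase are not
  double-counted. Results merge in the exact fixed points (basin 0 if
  never sampled) and are reproducible bit-for-bit given the seed.

Sampling all 33 biological nodes uniformly (including KRAS, which
converges to 1 after one step) is the least-commitment choice: register
history is unobservable, and constant history makes the sampled subspace
exactly the observable states. For oracle testing against brute force on
*delayed* networks, `register_init = "random"` instead samples the full
expanded state space, making exact agreement with
`brute_force_attractors()` achievable; the delay-free oracle corpus does
not need this.

`brute_force_attractors()` is the independent oracle: it tabulates the
full transition function (refusing state spaces above 2^20) and follows
every state, giving exact attractors and basins. The test suite checks
that sampled-plus-exact enumeration equals brute force on over a hundred
seeded random networks of 8–12 nodes.

## Interventions and the screen

An intervention clamps 1–2 nodes to constants (knockout/overexpression),
applied *before* delay expansion so a clamp also pins a node's delayed
history. The screening universe excludes only the caspase node (the
readout): 32 nodes × 2 values for singles plus 4·C(32,2) value pairs =
2048 interventions.

The screening criterion follows the biology: an intervention "induces
apoptosis fully" iff **every** attractor of the intervened network has
caspases active in every cycle state; the basin fraction of
caspase-active attractors (from 100,000 random starts in the headline
analyses) corroborates the verdict and quantifies near-complete hits. On
this model the full-verdict singles are exactly the CD44, STAT3 and
TWIST1 knockouts; AURKA and PAK1 knockouts exceed 99% apoptotic basin.
Two readings of "per-cent apoptosis" exist (attractor counts vs basin
mass); the package computes the basin-fraction reading and reports the
attractor sets alongside. Pair hits are reported completely, annotated by
whether they contain a single hit as a subset — no pruning rule is
imposed, because any particular shortlist criterion would be arbitrary.

The composite `cfl1_sirna_knockout()` clamps both CFL1 forms
(`CFL1` and `Phosphorylated-CFL1`), as an siRNA depletes total protein;
it is a labelled convenience outside the 2048-universe, which treats the
two forms as separate clampable nodes (they are separate model rows).

## Expression binarization

To compare model states with tumor-versus-normal expression data, each
gene is binarized by a ROC-derived threshold: candidate cutpoints are the
midpoints between consecutive sorted distinct values, the chosen cutpoint
maximizes Youden's J (sensitivity + specificity − 1), and a sample is
called **active** when its value lies strictly above the threshold.
Design choices, made where the procedure was genuinely underdetermined:

- **Direction follows the labels.** The ROC orientation is chosen
  automatically (as in common ROC software): if tumors lie below normals,
  J is maximized for the down orientation and tumors come out *inactive*.
  A fixed tumor-high orientation would instead pick a meaningless
  boundary cutpoint on down-regulated genes.
- **Tie-breaks.** Equal-J cutpoints resolve to the smallest threshold;
  equal-J orientations resolve to "up". Midpoint construction means no
  observed value ever equals the threshold; the strict "above = active"
  rule is documented anyway for hand-supplied thresholds.
- **Replicates.** Technical replicate groups are averaged (arithmetic
  mean per gene) into single samples first; mixed-label groups are an
  error. The operation is idempotent.

Calls are rank-based and therefore invariant under any strictly
increasing transform of a gene's values, which the suite verifies, along
with agreement of thresholds and AUC with an independent ROC
implementation (pROC) on seeded data.

## Synthetic data: what it emulates, and what it does not

`synth_expression()` draws normals from Normal(μ0, σ) and tumors from
Normal(μ0 + δ, σ) per gene — the standard emulation of RMA-normalized
(log-scale) microarray data — with technical replicates sharing a latent
sample value plus Normal(0, σ/2) measurement noise. Defaults μ0 = 6 and
σ = 1 are typical normalized log2 levels. The generator does not mimic
probe structure, batch effects, inter-gene correlation or heavy tails;
passing tests therefore validate the *operators* (thresholding, averaging,
separation behavior), not any claim about specific clinical datasets,
which are deliberately out of scope. `random_network()` (≤ 14 nodes,
bounded in-degree, optional delayed literals, rules as random truth
tables rendered in sum-of-products form) exists solely to feed the
brute-force oracle.

All generators are pure functions of their spec including a mandatory
seed; nothing depends on ambient RNG state.

## Numerical and interface choices

- **State encoding:** states are 64-bit words in fixed node order; the
  38-node expanded model fits comfortably. The truth-table compiled form
  caps in-degree at 20 (the model's maximum is 7).
- **Problem sizes:** the bundled analyses use 100,000 random starts for
  basin estimates (binomial s.e. ≈ 0.03% near p = 0.99, ample for a 99%
  claim) and 8–12-node corpora for oracle equality, where full
  enumeration is cheap. Property-style tests run hundreds of seeded
  repetitions.
- **Determinism:** attractor sets are ordered by canonical key, start
  sampling is seeded, and report writers are plain-text (CSV/JSON), so
  identical seeds give byte-identical outputs.
- **Rule files:** the `targets, factors` dialect with `#` comments;
  Unicode (∧∨¬) and ASCII (&|!) connectives are both parsed, ASCII is
  canonical on output for portability. Node names keep their biological
  punctuation (`ARP2/3`, `F-actin_new`); names with spaces are quoted.
  `read_network(write_network(net))` is exact, including header comments.
- **Counting conventions:** `network_summary()` reports distinct
  regulator→target edges (66 for this model, self-loops included) and
  literal occurrences. Interaction counts quoted elsewhere for this model
  do not match either convention, so no such figure is asserted.

## Known limitations

- Asynchronous and probabilistic update schemes are out of scope; all
  statements are about the synchronous dynamics.
- Exact enumeration covers fixed points only; a hypothetical long cycle
  with a tiny basin could escape both routes (none was ever observed on
  this model across seeds).
- Basin fractions are estimates with binomial sampling error; verdicts
  ("full") are exact only because they quantify over the enumerated
  attractor set.
- The binarization operator is validated on synthetic data; applying it
  to real expression matrices requires the user's own normalization
  upstream (the package consumes already-normalized values).
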