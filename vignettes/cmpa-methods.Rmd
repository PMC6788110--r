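---
title: "Scoring causal mechanism networks with cmpa"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring causal mechanism networks with cmpa}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cmpa)
```

## The model

A *mechanism* is a signed directed graph of causal statements between
biological entities (genes, proteins, processes), curated in the BEL idiom:
`increases`/`directlyIncreases` edges carry sign $+1$,
`decreases`/`directlyDecreases` carry $-1$, and all other relations
(`association`, `hasComponent`, ...) are non-causal and discarded before
scoring. The entities converge on a designated **central node** — the
phenotype or process whose degree of perturbation we want to quantify, e.g.
*mitochondrial dysfunction*. Gene-level log2 fold changes $\beta_i$ from a
differential-expression contrast are attached to the nodes as weights.

A **hub** is a node with at least one incoming and one outgoing causal
edge — a node that both receives and transmits regulation. Each hub $h$
gets an **Impact Factor**

$$ \mathrm{IF}_h = \beta_h + \sum_{i=1}^{N} S_i\,v_i, $$

the hub's own weight plus the signed sum over its $N$ incoming edges, where
$S_i \in \{+1,-1\}$ is the edge sign and $v_i$ the current value of the
source node. The mechanism's score — the **candidate mechanism perturbation
amplitude (CMPA)** — is the sum of Impact Factors over all $M$ hubs:

$$ \mathrm{CMPA} = \sum_{j=1}^{M} \mathrm{IF}_j. $$

A positive score means the mechanism is upregulated for that dataset, a
negative score downregulated, zero no change.

Hubs are evaluated in an order in which every hub is scored only after all
hubs feeding into it (a Kahn-style topological order over the hub-to-hub
edge relation), so that an upstream hub's value is available before it is
passed on. Among simultaneously ready hubs the order is lexicographic by
label; this tie-break only affects logs — the score is order-invariant,
which the test suite checks by relabelling.

### Two readings of the incoming value

The formula above leaves open what $v_i$ is when the source node is itself
an already-scored hub. `cmpa` exposes both readings:

* `propagate = TRUE` (default): a scored hub contributes its Impact
  Factor — values accumulate downstream, so the central node receives the
  aggregated signal of its whole upstream network. This matches the
  narrative logic of values being passed along chains (in a chain
  `H -> G -> D -> X`, `H`'s value reaches `X` through `G` and `D`).
* `propagate = FALSE`: every contribution is the raw log2 fold change, the
  literal reading of the formula.

Both modes are linear in the weight vector, conserve
`score == sum(impact_factors)`, and are covered by the same oracle tests.
On the chain `A -> B -> X` with unit weights the two give 5.0 and 4.0.

### The central node

The amplitude is computed *for* the central node, whose outgoing edges are
removed before scoring (`extract_mechanism()`): the central node connects
onward only to other mechanisms and must not leak value out of the
subgraph. After removal the central node would no longer qualify as a hub
under the in-and-out rule, yet it is the one node that must be scored — so
it is a hub by construction. Mechanism extraction keeps the nodes that can
reach the central node along causal edges within `radius` hops (default 5
nearest neighbours, the conventional mechanism size), following edge
direction: regulation flows toward the central node, so the neighbourhood
is the upstream one.

## Statistical assessment

A score is only meaningful if it is specific to the real weight
assignment. `null_distribution()` re-scores the mechanism under random
reassignments of the observed weight pool to the nodes (default 10,000
permutations). Two pool semantics are provided, since "assign each gene a
random value from the pool" is ambiguous:

* `shuffle` (default): a uniform permutation of the observed multiset,
  without replacement — the pool is preserved exactly;
* `resample`: i.i.d. draws with replacement from the pool.

All node weights enter the pool by default, including the zeros of
unmeasured nodes — they are part of the realized weight vector;
`measured_only = TRUE` restricts the permutation to measured nodes.

`one_sample_t_test()` then tests the null hypothesis that the mean of the
permuted scores equals the observed score:
$t = (\bar s_{\mathrm{null}} - s_{\mathrm{obs}})/(\mathrm{sd}/\sqrt{n})$,
two-sided, $n-1$ degrees of freedom, rejection threshold 0.05. The test is
reported exactly in this classical form; because permutation scores are not
an i.i.d. sample in the usual sense and the $t$ magnitude grows with
$\sqrt{n_{\mathrm{perm}}}$, the package also always reports the add-one
empirical p-value
$(1 + \#\{|s_i| \ge |s_{\mathrm{obs}}|\})/(n_{\mathrm{perm}}+1)$, which is
distribution-free, bounded below by $1/(n_{\mathrm{perm}}+1)$, and remains
valid when the null is degenerate (zero variance — e.g. an all-zero weight
vector — makes the t-test an error, caught and reported as such).

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `radius` | 5 | upstream hops kept around the central node (hops, dimensionless) |
| `propagate` | `TRUE` | hub values accumulate downstream |
| `missing_policy` | `"zero"` | unmeasured nodes get weight 0, the neutral element of the IF sum |
| `n_perm` | 10000 | permutations for the null |
| `mode` | `"shuffle"` | permutation pool semantics |
| `break_cycles` | `FALSE` | error on hub cycles rather than silently repairing |
| $\alpha$ | 0.05 | rejection threshold of the t-test |

Unmeasured nodes default to weight 0 rather than exclusion because 0
contributes nothing to any Impact Factor; the strict alternative
(`missing_policy = "error"`) aborts when a measurable node has no weight,
while process nodes (`kind = "bioprocess"`) are always zero-filled — they
have no expression value by nature.

## Numerical and degenerate-input choices

* Summation is in input order after lexicographic scheduling; internal
  consistency checks use a relative tolerance of 1e-9. The score is exactly
  antisymmetric under weight negation and exactly homogeneous under
  power-of-two scalings (IEEE arithmetic guarantees only those exactly;
  general scalings hold to 1e-12 relative).
* Self-loops are rejected at load with a warning — the hub recursion is
  undefined on them. Parallel edges are kept; each contributes a term.
* A cycle among hubs is an error naming the strongly connected component.
  With `break_cycles = TRUE` the in-cycle edge whose source has the
  smallest absolute weight is removed (ties lexicographic by source, then
  target), logged, and scheduling retried — deterministic, so reproducible.
* Labels are matched case-sensitively after whitespace trimming.
* Duplicate rows in a weight table are averaged with a warning — a
  deterministic local policy for multi-probe artifacts, since upstream
  differential-expression processing is out of scope.

## The synthetic generator, and what it does not emulate

`generate_mechanism()` builds a random spanning in-tree toward the central
node `X` and adds forward extra edges, so every generated network is a DAG
in which all nodes drain into `X` — the structure the algorithm assumes.
Defaults emulate the scale of curated neurodegeneration mechanism
subgraphs: 30 nodes, ~54 causal edges, an even mix of activating and
inhibitory statements, 10% of nodes unmeasured.

`generate_weights()` plants a coherent upregulation: each node's weight is
`effect_size * parity + N(0, noise_sd)`, where `parity` is the sign of the
node's net influence on the score. The score is linear in the weight
vector, so this influence coefficient is computed exactly by scoring
indicator vectors; a single-path parity (product of edge signs along the
path) coincides with it on trees but not once parallel paths disagree.
With this planting every measured node pushes the score upward, making
"upregulated mechanism → positive, significant score" a testable property.
Two caveats follow directly from permutation-test logic and are worth
knowing when interpreting results on real data:

* a shuffle null can only detect signal if the weight pool is
  sign-diverse; a mechanism whose measured genes all move the score the
  same way with equal magnitudes is indistinguishable from its own
  shuffles, however strongly perturbed;
* the generator does not emulate probe-level noise, expression correlation
  between neighbouring genes, or annotation errors in the network — so
  passing tests demonstrate algorithmic correctness and statistical
  calibration under the stated model, not robustness to those real-data
  features.

The generator is seeded: the network derives from `seed`, the weights from
`seed + 1`, so each is reproducible on its own.

## Problem sizes used in the checks

The shipped verification uses: engine-vs-oracle agreement on 200 random
DAG mechanisms of up to 15 nodes (both propagation modes, relative 1e-9);
an exhaustive 3! permutation null on a two-parent star against 6,000
sampled permutations; empirical-p calibration over 200 replicates of
exchangeable weights on a 10-node mechanism at 199 permutations, expected
to stay inside the exact binomial 99% band around 0.05; and planted-signal
power over 100 replicates at effect size 2.0 versus noise 0.1, where the
t-test should reject in at least 95%. These sizes give stable verdicts for
the properties being checked while keeping the whole suite quick to run.

## A worked chain

```{r chain}
net <- causal_network(data.frame(
  source   = c("H", "G", "D"),
  relation = "increases",
  target   = c("G", "D", "X")
))
mech <- extract_mechanism(net, "X")
identify_hubs(mech)
fit <- cmpa_score(mech, c(H = 1, G = 1, D = 1, X = 1))
summary(fit)
```

## Known limitations

* The hub t-test inherits the classical form exactly; its p-values at
  10,000 permutations are essentially always tiny whenever the null mean
  differs at all from the observed score. Use `empirical_p` when a
  conservative, rank-based statement is wanted.
* Reachability, and hence mechanism membership, is purely topological;
  edge confidence or evidence counts are not modelled.
* The propagation flag changes score magnitudes (not signs of the planted
  examples); comparisons across datasets should fix one mode.
* Scores scale with network size and measured-gene coverage, so raw CMPA
  values are comparable across datasets for a fixed mechanism, not across
  mechanisms of different sizes.
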