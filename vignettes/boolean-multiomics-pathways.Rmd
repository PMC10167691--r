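---
title: "Executable Boolean pathway models from multiomics data: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Executable Boolean pathway models from multiomics data: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(boolomics)
```

# Overview

`boolomics` learns executable Boolean models of prior-knowledge signaling
pathways (PKNs) from combined multiomics abundance data — typically
transcriptomics, proteomics and phosphoproteomics profiled under matched
conditions — and uses the fitted models for topology-aware pathway
enrichment. The pipeline has three stages:

1. **Preparation.** PKNs are read from graphml (or converted from KEGG
   KGML), gene identifiers are normalized, self-loops and duplicate edges
   are removed, and pathways sharing fewer than `min_overlap` (default 5)
   genes with the data are dropped. Nodes with more than three regulators
   are capped at three (see *In-degree truncation* below).
2. **Rule inference.** Each node's regulatory logic is an OR-of-AND formula
   over its signed regulators (inhibitors enter negated). A genetic
   algorithm finds a well-fitting whole-network rule assignment; a
   node-local exhaustive search then scans every candidate rule per node and
   returns the *equivalent rule set* (ERS): all rules that fit the training
   data equally well. The ERS size is a per-node measure of inferential
   uncertainty — 1 means the data pin the logic down, 127 (the three-input
   maximum) means they say nothing.
3. **Scoring.** Node importance is measured by in-silico perturbation:
   clamping a node to 0 (knockout) versus 1 (knock-in) and accumulating the
   steady-state differences it induces across the rest of the network.
   Importance is combined with contrast fold-changes, coefficients of
   variation and cross-layer evidence into node and pathway modulation
   scores, whose significance comes from a pooled-resampling null.

# The model

## Rule space

For a node with $k \le 3$ regulators there are $2^k - 1$ possible AND
clauses (nonempty regulator subsets) and therefore
$2^{2^k - 1} - 1$ distinct OR-of-AND rules: 1, 7 and 127 for $k = 1, 2, 3$.
Clause sets are stored literally (no absorption-law reduction), so rule
identity is clause-set identity and these counts are exact. This matters
because ERS sizes are only comparable across nodes and datasets if the
enumeration is canonical.

## Dynamics

Networks are simulated synchronously: every node updates simultaneously
from the previous state, in-degree-0 nodes hold their state and act as
inputs (stimuli). A synchronous trajectory on $n$ nodes is deterministic
and enters a fixed point or limit cycle within $2^n$ steps. The
steady-state summary of a node is its mean bit over the final `window`
states of a `steps`-step run — 0 or 1 at a fixed point, the cycle average
on a limit cycle. Defaults `steps = 100`, `window = 20` comfortably cover
cycle entry at pathway scale (tens of nodes); both are configurable, and
the test suite checks the summary against exhaustive state-transition-graph
attractor analysis for networks up to 8 nodes. The inner update loop is
implemented in C++ with an analytic fixed-point early exit, because rule
inference evaluates millions of trajectories.

## Training states and fitness

Each omics layer is binarized per gene at the midpoint of its (min, max)
across that layer's samples (strictly above → 1; constant genes → 0).
Midpoint thresholding is scale-robust for log data, invariant to additive
shifts, and matches the high/low reading of executable models; a per-gene
median split is a reasonable alternative but makes the threshold depend on
the condition balance of the sample set. Every (layer, sample) pair yields
one training state; multiomics integration is simply the concatenation of
these states as independent constraints, which is also why additional
layers can only shrink (never grow) a node's ERS on noise-free data.

Fitness is mask-aware: a training state initializes the network from its
binarized bits, genes the layer does not measure start at 0, and the
per-node error — mean $|$steady value $-$ observed bit$|$ — is accumulated
only over states in which that node is measured. Unmeasured entries never
contribute; starting unmeasured nodes at 0 avoids fabricating observations
and is immaterial for acyclic pathways, where non-input steady states are
init-independent.

## Genetic algorithm and local search

The GA is generational with tournament selection (size 3), uniform per-node
crossover (probability 0.6 that a pair recombines), per-node rule
resampling mutation (probability 0.3 per node), one elite, population 24,
50 generations, and a fully seeded RNG; the elite's fitness is
non-increasing by construction. These are pathway-scale defaults — the
rule-assignment space for a 10-node pathway is typically $10^6$–$10^{15}$,
and the GA only needs to land near a consistent assignment because the
local search then scans *every* candidate rule per node (at most 127)
while holding the other nodes at the incumbent. ERS membership uses exact
error ties (equality after rounding to 12 decimal places) so that ERS
sizes are reproducible integers rather than tolerance-dependent counts.

## Importance, modulation, and the permutation null

For each of `n_rule_samples` (default 10) concrete models drawn uniformly
from the per-node ERSs, every node $g$ is clamped to 0 and to 1 in every
training state and the resulting steady states $O_{i,j}$ and $Z_{i,j}$
compared:
$$I_g = \frac{1}{S}\sum_{s=1}^{S}\sum_{i}\sum_{j \ne g} |O_{i,j} - Z_{i,j}|.$$
The perturbed node is excluded from the sum so $I_g$ quantifies influence
over the *rest* of the network; including it would only add a constant
offset per state. $I_g$ depends on topology and rules alone, never on a
contrast.

Per contrast $C$ and gene $g$, with $E_g$ the number of layers measuring
$g$ (with a nonzero value somewhere), $\mathrm{FC}_{C,d,g}$ the difference
of condition means of log abundance in layer $d$, and $\mathrm{CV}_{d,g}$
the coefficient of variation (sample SD over mean, guarded at zero mean)
over the contrast's samples:
$$M_g = I_g \cdot E_g \cdot \sum_{d=1}^{D} |\mathrm{FC}_{C,d,g}| \cdot \mathrm{CV}_{d,g},
\qquad M_p = \sum_{g \in p} M_g.$$
Absolute fold-changes are used so up- and down-regulation both count as
modulation. Fold-changes are computed on the log scale (differences of
means), the natural scale for the log-transformed inputs.

The null keeps $I_g$ and $E_g$ fixed and redraws each measured
(gene, layer) cell's $(\mathrm{FC}, \mathrm{CV})$ pair uniformly with
replacement from the gene-wise pool of the same contrast and layer over
the whole dataset; pairs are drawn jointly to preserve their empirical
dependence. 1000 replicates (configurable) give a null distribution, the
observed $M_p$ is standardized to $z$, and $p = 1 - \Phi(z)$ — one-sided
upper tail, per the modulation reading of the score. A degenerate null
(SD 0) yields $p = 0.5$ when the observed score equals the null value,
else 0 or 1 by sign. Benjamini–Hochberg adjustment is applied within each
contrast.

**Calibration and its premise.** The $z$-to-$p$ mapping is calibrated when
the observed per-gene $(\mathrm{FC}, \mathrm{CV})$ values are exchangeable
with the pool they are compared against. The package's null fixture
(`generate_multiomics(null_mode = TRUE)`) realizes that premise exactly:
identically distributed conditions and a common baseline abundance, under
which 200 seeded pathways give KS-uniform p-values. When baselines are
heterogeneous — e.g. important upstream genes sitting systematically at
low abundance, where the same additive noise produces a larger CV — the
pooled null is mildly miscalibrated (we observe mean $z \approx +0.4$ in
such fixtures). This is an inherent property of pooled-resampling nulls,
not of this implementation; pathway p-values on real heterogeneous data
should be read as rankings with approximate error control rather than
exact tail probabilities.

# Design decisions

* **In-degree truncation.** Nodes with more than three network regulators
  keep the three whose binarized states have the highest absolute Pearson
  correlation with the target's binarized state over all (layer, sample)
  states where both are measured, ties broken alphabetically. Correlation
  is the cheapest data-driven relevance proxy that needs no model fit.
* **Graphml sign dialect.** Edge attribute `signal` or `interaction`,
  values `a`/`activation`/`+` vs `i`/`inhibition`/`-`; anything else
  defaults to activation with a warning. The package writes `signal` with
  `a`/`i`, so its own files round-trip exactly.
* **KGML conversion.** Relation subtypes `activation`/`expression` map to
  +1 and `inhibition`/`repression` to −1; a relation with neither defaults
  to +1 (many KGML relations carry only mechanism subtypes such as
  `phosphorylation`). Group entries are expanded to member genes with
  edges replicated; compound entries are collapsed through, the bridged
  edge's sign being the product of the in- and out-signs. Gene symbols are
  taken from the KGML graphics name, the only symbol-bearing field.
* **`log2rpm` transform.** Implemented as log2(reads-per-million + 1):
  plain log2(RPM) is undefined at zero counts and would violate the
  nonnegativity the downstream code assumes.
* **Seed fan-out.** One global seed is hashed with a stage label
  (`derive_seed`) into per-stage, per-pathway seeds, so any stage can be
  reproduced in isolation and adding a pathway does not shift the RNG
  stream of the others.

# The synthetic fixture generator

`generate_network` draws nodes in random order, each non-root node taking
1–3 regulators from its predecessors: connected, acyclic, in-degree ≤ 3 by
construction, so every true rule is enumerable and all attractors are
fixed points. `generate_ground_truth` assigns uniform random rules,
resampling (bounded) until no gene is constitutively high under both
canonical input clamps — such genes carry no between-condition signal, so
data-driven binarization cannot represent them and their logic is
unidentifiable from expression data by any method.

`generate_multiomics` turns attractors into data: conditions clamp the
input nodes (all-low, all-high, then alternating patterns), attractor bits
map to mean log2 abundance 4 (low) and 8 (high) — placing the binarization
midpoint between classes — with additive Gaussian noise and per-layer gene
dropout (defaults 0/0.25/0.25, keeping one complete reference layer)
emulating the partial gene overlap of real multiomics designs. Input nodes
are exempt from dropout so each layer's samples remain attributable to
their condition. `null_mode = TRUE` produces the calibration null
described above.

What the fixtures do *not* emulate: feedback loops (real PKNs cycle; the
simulator and scorer handle cycles, and are tested on them, but the
recovery guarantees are stated for the acyclic fixtures), mass-spectrometry
intensity-dependent error and missingness, correlated noise between layers,
and phosphosite-level structure. Passing the fixture suite therefore shows
the machinery is correct and calibrated under its stated assumptions, not
that rule recovery will be near-perfect on noisy real data.

# Problem sizes and budgets

The shipped tests and the acceptance script use 8–10-node pathways, 3
layers, 2–3 conditions with 3–4 samples each, GA populations of 8–24 over
6–50 generations, 200–1000 permutation replicates, and 200 pathways for
the calibration study. These sizes were chosen so a full run completes in
minutes on one CPU while still exercising every code path at realistic
pathway scale; all of them are plain function arguments, and larger
analyses only change runtime, not code paths.

# Known limitations

* Synchronous updating only; asynchronous schemes can reach different
  attractors.
* Rules beyond three regulators are truncated, not marginalized; a hub's
  dropped regulators contribute nothing to its inferred logic.
* The importance score collapses the ERS by uniform sampling
  (`n_rule_samples` draws); for very large ERSs the score inherits
  sampling noise, controllable via `n_rule_samples`.
* Identifier harmonization (protein/phosphosite → gene symbol) must happen
  upstream; the package only uppercases and trims.
* The pooled permutation null's calibration premise is gene
  exchangeability, as discussed above.
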