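---
title: "Pathway network efficiency and flux: model, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pathway network efficiency and flux: model, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pathflux)
```

## The model

`pathflux` treats a signalling pathway as a directed graph whose nodes are
enzymes, receptors, second messengers and terminal events, and whose edges
point downstream. Signal "conductance" is summarised by two quantities
computed from weighted shortest paths (Dijkstra, following edge direction,
all weights positive):

* **Network efficiency**, `NE = sum over ordered pairs i != j of 1/d_ij`,
  where `d_ij` is the minimum total edge weight of a directed path from `i`
  to `j`; unreachable pairs contribute 0 (`1/Inf = 0`), the standard
  convention for efficiency on disconnected graphs.
* **Network flux**, the same sum restricted to destinations in the exit set
  — the pathway's terminal event. NF is a subset of NE's terms, so
  `NF <= NE` always. Flux exists because NE is global and blind to *where*
  in the pathway a perturbation sits; a node just upstream of the terminal
  event matters more for output than a peripheral one, and NF sees that.

A compound perturbs the network through its docking scores. For each docked
target the score is transformed to an **edge value**

`EV = 10^(2.30 * score_ligand / score_reference)`, clamped to `[10, 99999]`,

and assigned to (replacing, not scaling) every edge leaving that target.
All other edges keep the initial weight. Higher EV means the target's
outgoing connections are harder to traverse, i.e. the target is more
inhibited. NE and NF of the reweighted network are then expressed as
percent decreases from the unperturbed baseline, and their geometric mean
(the *combination score*) is the headline efficacy predictor. Predictions
are validated by the Pearson correlation of these decreases with
experimental inhibition.

## Parameters and defaults

| parameter | default | meaning |
|---|---|---|
| initial weight | 10 | baseline weight of every edge (dimensionless) |
| weight floor | 10 | lower clamp of EV; scores with ratio below `log10(10)/2.30 ≈ 0.4348` have no effect |
| weight cap | 99999 | "fully blocked" edge; keeps EV finite for scores far above the reference |
| exponent constant | 2.30 | taken as exactly 2.30, so the reference-ligand EV is `10^2.30 = 199.53` (commonly quoted as 200), not `ln 10` |
| pair mode | ordered | see below |
| exit set | auto | explicit declaration wins; otherwise the sinks (out-degree 0) |

All of these are overridable in `runConfig()`, in a `key = value` config
file, and as CLI flags; the defaults are the model's published operating
point and the CLI logs the constants in use on every run.

## Design choices where the design was open

**Ordered versus unordered pairs.** The efficiency of a directed network is
sometimes written as a sum over `N(N-1)/2` pairs even though directed
distances are asymmetric. We sum over ordered pairs by default: directed
arrows make the unordered distance ill-defined, and the ordered sum is the
convention for directed efficiency. An `"unordered"` mode (one term per
pair, using the shorter of the two directed distances) is provided for
sensitivity analysis; on acyclic networks the two modes coincide because at
most one direction of any pair is reachable.

**Exit detection.** Terminal events are rarely annotated in edge lists, so
`detectExits()` defaults to the sinks; a cyclic network without sinks is a
configuration error rather than a silent guess. The bundled platelet
network declares its exit ("Platelet aggregation") explicitly.

**Replacement, not multiplication.** Applying a profile *reassigns* the
target's outgoing edges to EV rather than multiplying the baseline; EV is
an absolute edge cost on the same scale as the initial weight.

**Negative or missing scores.** Both fall below the floor after the
exponential transform, so missing scores are treated as 0 (reported via a
message) and negative decreases (efficiency rising under perturbation) are
kept as diagnostics everywhere except inside the combination score, where
they are clamped to 0 so the square root stays real.

**Correlations.** "Linear correlation" is Pearson's r of the least-squares
fit (not r²); the slope and intercept of `inhibition ~ predictor` are
returned alongside. The non-glycoside subset drops the seven
sugar-conjugated compounds whose flexible moieties make docking scores
unreliable; the two approved drugs stay in.

**The bundled activity table.** A few of its published combination cells
disagree slightly with the geometric-mean formula applied to the published
1-dp decreases (most likely the original values were computed from
unrounded decreases). The fixture therefore stores the published column as
printed *and* a `combination_recomputed` column from the formula.
Correlations on the fixture use the published column — it is the data being
reproduced — while the screening pipeline always computes fresh combination
scores from its own NE/NF decreases.

## The synthetic generator

`generatePathwayNetwork()` emulates the statistical shape of a curated
pathway: a small receptor layer of pure sources, a terminal exit layer of
sinks, and a scale-free-ish body. Nodes are laid out in a fixed order
(receptors, intermediates, exits) and all edges point forward, so the
result is acyclic. A two-pass scaffold first gives every non-receptor an
in-edge from an earlier node (preferring parents without an out-edge, which
bounds the scaffold by `nodeCount - 1` edges) and every non-exit an
out-edge to a later node; this guarantees every node lies on some
receptor-to-exit path, which raw preferential attachment does not. The
remaining budget is filled by out-preferential attachment with probability
proportional to `(in-degree + 1)^attachmentBias`. Defaults (64 nodes, 91
edges, 6 receptors, 1 exit) mirror the curated platelet network's size and
average degree (2.84); 6 receptors reflects the major platelet agonist
inputs (ADP, ATP, thrombin, thromboxane, collagen, epinephrine). Generators
are pure functions of their seed and restore the caller's RNG state.

What the generator does *not* emulate: feedback loops (real pathways cycle
through secreted agonists; the generator is a DAG so that layering is
guaranteed), typed small-molecule intermediates, and realistic docking-score
correlation structure (`generateScores()` plants `potency * reference` plus
independent Gaussian noise). Tests passing on synthetic networks therefore
validate the algebra and the ranking machinery, not the biological fidelity
of any particular curation.

## The curated platelet network

`loadFixture("platelet_network")` is a best-effort, synthetic
reconstruction of the platelet-aggregation pathway (64 nodes, 91 edges,
all 19 docking targets present, single terminal aggregation event),
assembled from public pathway knowledge (KEGG platelet activation,
Reactome). It is a fixture for exercising the pipeline at realistic scale,
not a faithful copy of any published diagram: its baseline NE is 47.148
(the published network's is 48.496, within 3%) and its unweighted mean
directed path length is 7.21 versus the published 5.69. The
`test-acceptance.R` block comparing these endpoints documents the residual
gap rather than asserting fidelity the fixture cannot have.

## Numerical notes

Path lengths and reciprocal sums are accumulated in double precision; ties
between equal-weight paths are irrelevant because only lengths enter the
metrics. Weight serialisation uses 17 significant digits so that
write/read round-trips are bit-exact. Degenerate inputs are errors, not
guesses: empty exit sets, nonpositive weights, self-loops, duplicate edges,
unknown compounds/targets, and correlations on fewer than 3 points or
zero-variance columns all fail loudly. Node-id matching is exact and
case-sensitive throughout, so curation typos surface instead of silently
fuzzy-joining.

## Problem sizes used in the test suite

Oracle comparisons (a hand-written Floyd–Warshall in plain R) run on 100
seeded random digraphs of up to 12 nodes; closed-form checks use directed
paths up to 8 nodes; recovery experiments screen 6 planted compounds on
25-node generated networks over 20 seeds. These sizes make the brute-force
oracle exact and keep the suite quick while exercising every code path the
full-size platelet fixture uses.

## Known limitations

* Docking scores are inputs; the package performs no docking and cannot
  compensate for scoring-function bias (glycosides being the documented
  example).
* Edge weights encode inhibition only; activation versus inhibition
  semantics of an interaction are not modelled — a perturbed edge always
  *impedes* flow.
* NE/NF treat all node pairs (or all pairs into the exit) uniformly;
  no per-node biological weighting beyond topology is applied.
* The combination score is undefined for negative decreases and clamps
  them; strongly "efficiency-raising" compounds rank as inactive rather
  than as a separate class.
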