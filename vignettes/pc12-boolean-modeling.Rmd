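---
title: "Boolean modeling of the PC12 cell-fate decision: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Boolean modeling of the PC12 cell-fate decision: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(booltrain)
```

PC12 cells decide between proliferation and neuron-like differentiation
depending on which growth factor they receive: NGF drives differentiation,
EGF drives proliferation, and the decision is implemented not by protein
signalling alone but by a transcriptional response that feeds back into the
signalling layer over hours.  `booltrain` models this decision as a
synchronous Boolean network spanning receptor-proximal kinase cascades
(MAPK/ERK, PI3K/AKT, JNK), the transcription-factor layer (AP1 and the
immediate-early genes), and an autocrine uPAR/integrin feedback loop, and
provides the training and analysis machinery around it: discretization of
expression time courses, genetic-algorithm topology selection against
perturbation data, attractor and basin analysis, and the supporting
time-course analytics (smoothing, regulation filtering, clustering,
embedding).

This vignette records the modelling conventions, parameter choices and
their rationale, what the synthetic generators do and do not emulate, and
the known limitations.

## The Boolean model and its update semantics

A model is a set of named nodes, each with one transition rule over parent
nodes built from AND/OR/NOT.  Updates are *synchronous*: all nodes are
replaced simultaneously, making the dynamics deterministic — from any state
the trajectory enters a terminal cycle (the attractor; a cycle of length 1
is a steady state).  Asynchronous semantics are deliberately out of scope:
the biological claims the model encodes (sequential pathway activation,
delay of AP1 by Zfp36, transience of growth-arrest genes) are statements
about the synchronous update order.

Three conventions matter in practice:

* **Input nodes self-maintain.**  A node without a rule (the stimulus NGF)
  keeps its value, so "all nodes off except NGF" is a well-posed initial
  condition in which the stimulus persists.
* **Clamping overrides rules.**  A stimulus is clamped on, an inhibited
  kinase clamped off, for the entire run.  Inhibitors are modelled as
  whole-run clamps rather than transient knock-downs because the
  corresponding experiments pre-incubate the inhibitor before stimulation.
* **Edge removal is partial evaluation.**  Deleting an edge substitutes 0
  for the source inside the target's rule (an activating occurrence
  becomes FALSE, an inhibiting occurrence becomes vacuously TRUE).  This
  gives knock-out semantics without re-deriving rules by hand.

### Attractor detection and basin estimation

`run_to_attractor()` hashes visited states and stops at the first repeat;
for an *N*-node network this terminates within $2^N + 1$ steps.
`brute_force_attractors()` enumerates all $2^N$ states (refused above 16
free nodes) and returns exact basin fractions; it is the oracle against
which the sampling path is tested.  `robustness_sample()` draws seeded
uniform random initial states over the unclamped nodes and advances all of
them in one batched matrix with Brent-style cycle detection (a per-row
snapshot refreshed at doubling intervals), so $10^5$ trajectories cost a
few vectorised sweeps.  Attractors are canonicalised by rotating the cycle
to its minimal state key, making attractor identity comparable across
detection paths.

## Discretization of expression data

Fold changes from qRT-PCR (computed by the $2^{-\Delta\Delta Ct}$ method)
are rescaled per node to $[0,1]$ across all conditions and timepoints
jointly, then passed through the Hill function

$$f(x) = \frac{x^n}{x^n + k^n}, \qquad n = 2,\; k = 0.5,$$

whose midpoint $f(k) = 1/2$ defines the "on" threshold; binarization is
strict ($> 0.5$).  Because the Hill function is monotone with a fixed
midpoint at $k$, the binarized calls are invariant to the Hill coefficient
($1 \le n \le 6$ is exercised in the tests) unless a rescaled value sits
exactly on $k$.  Two conventions are documented choices rather than given
facts: rescaling is per node across conditions jointly (preserving
cross-condition contrast, with a `per = "node_condition"` switch), and a
constant series maps to all-zero with a warning so whole-table processing
never aborts.

## Topology training

The hypothesis space is a prior-knowledge network (PKN): signed directed
edges with node roles (stimulus / inhibited / measured / hidden) and a
fixed-edge flag.  Training proceeds in three stages.

1. **Compression** removes nodes with no path from a stimulus or to a
   measured/inhibited node and collapses hidden single-in/single-out
   chains into one edge whose sign is the product of the collapsed signs.
   Designated nodes are never removed.  Collapsed chains are recorded so
   expansion can restore them.
2. **Scoring.**  A candidate is a bitstring over the optional edges; the
   model is synthesized with activators OR-combined and each inhibitor
   contributing AND NOT (explicitly declared AND gates, e.g. the dimeric
   AP1 complex requiring Fosl1 and Jund, are conjoined instead).  Each
   condition is simulated from the all-off state with its clamps, one
   synchronous step per sorted measurement timepoint, and the fitness is
   the mean squared deviation from the $[0,1]$ data plus a size penalty
   `size_penalty_weight * selected/optional` (default $10^{-4}$) that
   breaks fit ties toward sparser models.  The step-per-timepoint
   alignment is the key modelling convention: it treats the measurement
   grid as the network's logical clock.
3. **GA with consensus.**  A binary genetic algorithm (population 50,
   binary tournament selection, uniform crossover at rate 0.5, per-bit
   mutation 0.01, elitism 1) runs `runs = 100` times from sub-seeds
   `seed + 1000*run`; each run stops at a wall-time cap (100 s), at a
   relative-improvement plateau (tolerance 0.01 over a 100-generation
   stall window — small windows stop before rare single-bit improvements
   are found), or at `max_generations`.  An optional edge enters the
   consensus when it appears in at least 70% of the runs' best models;
   fixed edges are exempt from selection by construction, which also
   resolves the question of whether retention is computed over optional or
   all edges.

Re-expansion (`expand_network()`) restores collapsed chains whose
collapsed edge survived, appends curated downstream target genes, and
attaches negative autoregulation to designated transient nodes.

## The packaged PC12 networks

The package ships a 63-node / 109-edge PKN and the trained, re-expanded
32-node / 52-edge final model.  Both are *synthetic reconstructions*: the
original machine-readable supplements were not available for
transcription, so the fixtures were assembled from the published main-text
statements — the fixed-edge list (NGF → PI3K/RAS/PLC, MEK/ERK & JNK →
Jund/Junb, Fosl1 & Jund → AP1, Mmp10 → RAS, RAS → MEK, PLC → MEK, AP1 →
Npy), the described pathway structure (TrkA-proximal cascades, uPA/uPAR →
plasmin → MMPs → integrin/FAK feedback, AP1 → NPY → NPYY1 → PKC/PLC
feedback) and the described transient regulators (Klf4, Btg2, Zfp36 with
negative autoregulation; Zfp36 delaying AP1) — at the published node and
edge counts.  Transcription precedence and the synthetic provenance are
stated in the fixture file headers.

Rule details that realise the described dynamics under synchronous
updating:

* **AP1 self-maintenance.**  `AP1 = Fosl1 & Jund & (AP1 | !Zfp36)`: the
  Zfp36 veto delays the first activation by one step, and the
  self-conjunct latches AP1 thereafter so the transient Zfp36 pulse cannot
  retrigger.  Under synchronous updating a pure `!Zfp36` veto would
  oscillate against Zfp36's own negative autoregulation.
* **Transient regulators.**  Klf4/Btg2 (`trigger & !self & !AP1`) and
  Zfp36 (`MEK_ERK & JNK & !self & !AP1`) each pulse before the attractor
  and are silenced permanently once AP1 latches — auto-inhibition plus a
  sustained late terminator, the minimal synchronous realisation of
  "transiently active, then off".
* **Feedback closure.**  Mmp10 → RAS, FAK → MEK_ERK, FAK → JNK and NPYY1
  → PLC close the autocrine loops, so the differentiated attractor
  survives NGF withdrawal (bistable memory); removing the transcriptional
  entry AP1 → uPA disconnects the loop and the phenotype collapses.
* **Readout.**  Differentiation is called when a *strict* majority of the
  late gene set (Klf2, Klf5, Cited2, Npy, Serpine1, Mmp3, Mmp10 — the
  uPAR/AP1-dependent late genes annotated in the fixture) is persistently
  active together with uPAR.  Ties on an even-sized set are conservatively
  non-differentiating.  Maff and Klf10 are modelled as AKT targets and
  excluded from the readout set, because PI3K inhibition is described as
  affecting only PI3K/AKT/Maff/Klf10 while differentiation persists.
* **MEK inhibition** clamps the lumped MEK_ERK node in the final model and
  MEK proper in the PKN.

## Synthetic data: what it emulates and what it does not

`random_network()` plants a ground truth inside a decoy-padded PKN: an
activating backbone guarantees a stimulus path to every node, extra true
edges (optionally inhibiting) are accepted only if they remain essential
leave-one-out (removing any one changes the noise-free data under the
generated scenario set), and decoys that are single-substitution
dynamically equivalent to a planted edge are rejected — without these two
identifiability guards the benchmark would punish the optimiser for
ambiguities no method can resolve.  `simulate_timecourse_expression()`
renders Boolean states as `state + N(0, sd)` clipped to $[0,1]$ (default
sd 0.05, at which binarization errors are vanishingly rare); the timepoint
grid defaults to the study's 1–24 h design (1, 2, 3, 4, 5, 6, 8, 12,
24 h).  `planted_cluster_matrix()` emulates the two observed response
classes — pulse-like (rise and return) and sustained (rise and hold) —
with cluster-specific peak/onset times and Gaussian noise on the log2
scale.

What passing recovery tests does **not** show about real data: the
generator draws measurements for *all* non-stimulus nodes, uses the same
logic-synthesis family as the scorer, and adds independent Gaussian noise;
real transcriptome training data measure a small subset of nodes through
hidden signalling layers, with correlated biological noise and
model-mismatch (continuous kinetics, unmodelled regulators).  Recovery
performance here is therefore an upper bound that validates the machinery,
not a claim about microarray-scale inference.

## Expression analytics

* **Smoothing**: least-squares polynomial of order 5 (requiring more
  timepoints than the order), evaluated at the original grid.
* **Top-regulation filter**: |log2 FC| > 1.7 at two *consecutive*
  timepoints with the *same sign* both times — the same-sign reading is a
  documented choice; mixed-sign exceedances would conflate inverse
  regulation with strong regulation.
* **CAST clustering**: affinity is Pearson correlation mapped to $[0,1]$
  via $(r+1)/2$, so the threshold $t = 0.8$ corresponds to $r = 0.6$; the
  affinity normalisation is a documented choice since only $t$ itself is
  standard.  Greedy growth/removal against $t\cdot|\text{cluster}|$, no
  preset cluster count; constant series are excluded with a warning.
* **Anti-correlation**: opposite-sign slopes, both significant at
  $\alpha = 0.05$ on the slope t-test (the significance level is a
  documented choice), and both linear fits with $r^2$ strictly above 0.7.
* **HiT-MDS**: the embedding maximises the Pearson correlation between
  input and embedded distances; the optimiser is seeded stochastic
  gradient ascent over point pairs (2000 iterations default, geometric
  step decay) initialised from classical scaling, and the reported stress
  $1 - r$ is tracked best-so-far, hence non-increasing.  For degenerate
  all-equal distance targets the correlation is undefined and a relative
  mismatch score substitutes.
* **Uniqueness p-values**: a bivariate skew-normal is fitted by maximum
  likelihood (location, Cholesky-parameterised scale, skewness vector;
  Nelder–Mead then BFGS).  The p-value of a point is the fitted
  probability mass at locations of density $\le$ its own — a
  lowest-density-tail quantile, chosen because only the distribution
  family, not the test statistic, is standard.  The mass is evaluated by
  Monte Carlo draws from the fitted distribution (20 000 by default,
  seeded, floored at $1/(n_{mc}+1)$ so p-values stay in $(0,1]$).
  Collinear or coincident clouds are rejected as unidentifiable.

## Problem sizes and determinism

The test-suite and acceptance computations use: $10^5$ random
initializations for the robustness experiment (the published experiment
used $10^7$; with a unique attractor the sampled frequency is 1.0 at
either size), 50 random networks of up to 12 nodes with $10^5$ samples
each for the engine-oracle comparison (3 binomial standard errors), and a
15-node / 10-optional-edge recovery benchmark with 20 GA runs.  Every
stochastic step takes an explicit seed; multi-run GA sub-seeds are derived
by fixed offsets so consensus results are bit-reproducible.

## Known limitations

* Synchronous-only semantics; no asynchronous or probabilistic updating,
  no ODE conversion.
* The packaged networks are main-text reconstructions at the published
  counts, not transcriptions of the original supplementary tables; rule
  details beyond the described constraints (e.g. exact gating of
  moderately responding genes) are the package's own curation.
* The GA explores bitstrings over optional edges only; it does not search
  over gate structure (AND vs OR), which is fixed by the synthesis
  convention and the declared gates.
* The skew-normal p-value is a density quantile, not a calibrated
  frequentist p-value; it is used as an outlier ranking with the
  conventional 0.01 cut.
* Multi-edge equivalence classes (two or more decoys jointly mimicking
  true edges) are not excluded by the generator's identifiability guards;
  at the benchmark's edge densities they were not observed, but they are
  possible in principle.
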