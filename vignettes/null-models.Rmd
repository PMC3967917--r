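---
title: "Null models and multiscale diagnostics for brain networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Null models and multiscale diagnostics for brain networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(brainnull)
```

## What this package models

Diffusion imaging reduces a brain to a weighted matrix of streamline
counts between parcellated regions. `brainnull` works with the
*topological* reduction of that matrix: an undirected simple graph whose
edge (i, j) records that any tract of any strength links the two regions
(`binarize()`). The scientific question the package serves is a
comparative one: which generative ingredients — randomness, degree
constraints, mesoscale modularity, growth, spatial embedding, wiring
economy — push a synthetic network's multiscale statistics toward those
of an empirical connectome?

The package therefore has three layers: a battery of thirteen
generators, a panel of nine diagnostics, and a comparison/fitting layer
that reduces a model-data comparison to a single difference metric.

All thirteen generators share two hard conventions. First, they return a
simple undirected graph with exactly *N* nodes and exactly *M* edges, so
that every model in a comparison has identical size and density — static
models achieve this by weighted sampling *without replacement* of exactly
*M* pairs rather than independent coin flips per pair. Second, all
randomness flows through R's global RNG, so `set.seed()` makes any
pipeline, including the command-line tools, bit-reproducible.

## The diagnostics

For a graph with degrees $k_i$ and $m$ edges:

* **Assortativity** $r$ is the Pearson correlation of the degrees at
  either end of an edge, computed over the directed edge list (each edge
  in both orientations). For a regular graph the correlation is
  undefined; the package returns a flagged `NA` rather than 0, because a
  silent zero would corrupt the difference metric downstream.
* **Local clustering** $C_i = 2T_i / (k_i(k_i-1))$ counts the fraction of
  triangles among the triples through node $i$ ($C_i = 0$ when
  $k_i < 2$); the global $C$ is the mean over all nodes. The smallest
  nonzero value attainable at degree $k$ is $2/(k(k-1))$ — one triangle —
  which is why sparse randomized graphs show a spurious-looking
  hierarchy driven by their low-degree nodes.
* **Hierarchy** $\beta$ is the fitted exponent of $C_i \propto
  k_i^{-\beta}$: ordinary least squares of $\log_{10} C_i$ on
  $\log_{10} k_i$, one point per node with $k_i \ge 2$ and $C_i > 0$, no
  binning. Binning choices change $\beta$ slightly; per-node OLS is the
  simplest reproducible convention and at least three usable nodes are
  required.
* **Path metrics**: mean shortest path $P$ over unordered reachable pairs
  and diameter $D$, by breadth-first search on the largest connected
  component. Empirical parcellations contain isolated nodes, and
  restricting to the largest component keeps $P$ and $D$ finite while the
  component fraction is reported alongside.
* **Modularity** $Q(\gamma) = \frac{1}{2m}\sum_{ij}\left[A_{ij} - \gamma
  \frac{k_i k_j}{2m}\right]\delta(g_i, g_j)$ with resolution $\gamma = 1$
  by default. Maximization is NP-hard; `optimize_modularity()` runs a
  Louvain-style greedy optimization repeatedly (100 restarts by default)
  with the node sweep order randomized per restart by relabelling the
  vertices from the RNG, and reports the best partition, the per-run
  values, and the mean community count across runs (a non-integer in
  general). Each reported $Q$ is recomputed by the package's own quality
  function, so optimizer and metric cannot drift apart.
* **Topological fractal dimension** $d_B$: cover the network with boxes
  of topological diameter $< l_B$ and fit $N_B \propto l_B^{-d_B}$. The
  covering uses the standard greedy-coloring realization (random node
  order; a node joins the first box all of whose members are within
  $l_B - 1$). Tilings are stochastic, so counts are averaged over 50
  tilings by default.
* **Topological Rent exponent** $p_T$: recursively bisect the node set
  into balanced halves (sizes differing by at most one) while
  heuristically minimizing the cut, and fit $e \propto n^{p_T}$ over the
  recorded (partition size, boundary edges) pairs. The bisection is
  spectral — a Fiedler-vector median split — refined by Kernighan–Lin
  swap passes with best-prefix rollback, and ignores any node
  coordinates.

## Numerical choices that matter

**Box-counting fit window.** The forced endpoints $N_B(1) = N$ and
$N_B(l_B > D) = 1$ never enter the fit. The smallest informative scale,
$l_B = 2$ (boxes are cliques), carries the strongest finite-size bias:
for an ideal 2-D torus the minimal counts follow $\sim 1/(l_B+1)^2$
rather than $1/l_B^2$, which flattens a fit anchored at $l_B = 2$ to
about 1.67 even for a *perfect* covering. The fit therefore starts at
$l_B = 3$ (falling back to 2 when the diameter allows nothing else).
With this window the estimator reproduces $d_B \approx 1$ on a 64-cycle
and $d_B \approx 1.8$–$2$ on a $16\times16$ torus; the residual
downward bias of greedy covering is visible in those numbers and is the
known cost of the standard algorithm. Within a tiling, the count at each
scale is the best cover found at any smaller scale as well (a valid
cover remains valid when boxes may grow), which enforces monotone
counts.

**Rentian boundary counting.** For each bisection step the package
records, for both halves, the number of edges crossing between the two
halves of the subgraph being split — the min-cut value of that step.
Counting instead against the whole graph makes the coarsest partitions
saturate (a half of a finite mesh has a boundary that stops growing),
and drives the fitted exponent of a $16\times16$ mesh far below the
$e \sim \sqrt{n}$ law that balanced min-cuts of a 2-D mesh must follow;
per-step counting recovers it. Partitions smaller than `min_part`
(default 8) are excluded from the fit as discreteness-dominated.

**Modularity's null term.** The quality function uses the standard
Newman–Girvan convention: $m$ is the edge count and the null term is
$k_i k_j / (2m)$. This is the only convention under which reported
connectome modularity values near 0.6 are on the right scale.

**Gaussian band-width fitting.** `fit_band_kappa()` must reorder an
arbitrary adjacency matrix so that band structure, if present, hugs the
diagonal. It uses spectral envelope reduction — nodes sorted by their
Fiedler-vector coordinate, component-wise — which recovers the
generating order of a banded graph up to reversal and local noise;
breadth-first (Cuthill–McKee style) orderings scramble locally and
inflate the fitted width by tens of percent. The Gaussian
$a\,e^{-d^2/2\kappa^2}$ is then least-squares fitted to the edge density
of the first 400 off-diagonals.

**Distance-kernel fitting.** `fit_distance_kernel()` bins all node-pair
distances (50 equal-width bins), computes per-bin connection
frequencies, drops bins with fewer than 20 pairs or zero connections,
and fits in log–log space weighted by per-bin pair counts — tail bins
are few-pair and log-noisy, and unweighted fits chase them. The
`"single"` form is a truncated power law fitted as a segmented line:
flat below a scale $r_0$ (the region where the kernel is capped, and
where sampling saturates), power-law decay above; the smallest
breakpoint within 5% of the best fit is preferred so that genuinely
flat (distance-independent) profiles are not given spurious plateaus.
The `"piecewise"` form frees both segment slopes with continuity at the
breakpoint and anchors $g(0) = 1$ by capping. With a hemisphere label
column, intra- and inter-hemispheric pairs are fitted separately.

**Ties and degeneracies.** Distance ties in `gen_mw()`/`gen_dd()` break
by lexicographic pair order with a warning on duplicate coordinates; a
flat clustering–degree profile with a single support point returns
$\beta = 0$ by convention; undefined diagnostics abort the difference
metric with the offending names rather than being zero-filled.

## The generators: design decisions

Most generators follow their textbook definitions; the points below are
where a genuine choice had to be made.

**Ring lattice (`gen_rl`).** Base band of $2\lfloor M/N \rfloor$
neighbors per node; the remainder edges go uniformly at random among
unused pairs. With a width-4 band and no remainder every node has
$C_i = 3(k-2)/(4(k-1)) = 1/2$, a closed form the tests pin down.

**Fractal hierarchical (`gen_fh`).** 256 four-node cliques are paired
over eight levels; cross-pair edges at level $l$ appear independently
with probability $p_l = \min(1, \rho^l)$ — a geometric probability
ladder with the modules themselves complete. $1024 - N$ nodes are then
deleted uniformly at random. The drop-off rate $\rho$ is found by
bisection over full regenerations until the realized edge count matches
$M$; a final uniformly random trim/top-up closes any residual gap, with
a warning if it exceeds 0.5% of $M$.

**Preferential attachment (`gen_ba`).** Growth starts from a single
edge; each arriving node attaches to $m_t$ distinct targets with
probability $\propto k^{\gamma}$. The per-node budgets $m_t$ are spread
as evenly as possible (capped early, remainder pushed to later arrivals)
so the final count is exactly $M$. $\gamma = 1$ reproduces the classical
degree exponent near 3; $\gamma = 0$ is uniform attachment and
approaches an Erdős–Rényi graph.

**Affinity growth (`gen_af`).** Each node holds a fixed latent affinity
$a_i \sim U(0,1)$. After $M_0$ uniform seed edges, a source is drawn
with probability $\propto a_i^{\gamma}$ among nodes with spare capacity,
a candidate uniformly, and the edge accepted with probability
$\exp(-|a_i - a_j| / (\delta a_i^{\epsilon}))$. The qualitative contract
is that low-affinity (low-degree) nodes are the choosiest, hard-coding
assortativity *and* a decaying clustering–degree relation. The second
half of that contract constrains the constants: the edge density inside
an affinity band around $a$ scales as $a^{\gamma - \epsilon}$ (sources
arrive at rate $a^{\gamma}$, spread over a window of width
$\propto \delta a^{\epsilon}$), so hierarchy — denser neighborhoods at
low affinity — requires $\epsilon > \gamma$. The defaults
($\gamma = 1$, $\delta = 0.4$, $\epsilon = 2$) are this package's
calibration of that requirement; with them both $r > 0$ and $\beta > 0$
hold in essentially every realization at $N = 500$, while
$\delta \to \infty$ removes the affinity selectivity and the
assortativity with it.

**Embedded models.** `gen_rg` samples coordinates uniformly in a
brain-scale cuboid (140 × 170 × 110 mm by default) and, like `gen_mw`
on supplied coordinates, connects the $M$ globally shortest pairs.
`gen_dd` draws exactly $M$ pairs with weights $g(r_{ij})$; with a step
kernel at the $M$-th smallest distance it reproduces minimal wiring
edge-for-edge. `gen_ddg` grows from $M_0$ uniform seeds: source uniform
among positive-degree nodes, target uniform among non-neighbors,
acceptance $g(r_{ij})$. Its seed default is $M/100$: the broadening of
the degree distribution — the property growth exists to deliver — comes
from early-activated nodes accumulating edges over their lifetime, and
dense seeding (everything active from the start) suppresses it.
`gen_hdg` seeds with the $M_0$ shortest pairs (default 4000 at the
998-region scale) and grows the rest by the same rule, interpolating
between wiring economy and stochastic long-range shortcuts.

## The difference metric and fitting

`panel_delta()` sums the absolute relative difference of the nine
characteristics, equally weighted — there is no principled biological
weighting to prefer, and an explicit equal-weight metric is at least
transparent. It is normalized by the data panel and hence asymmetric; it
is zero on identical panels and errors on undefined or zero-valued data
entries. `normalized_profile()` divides each diagnostic's relative
differences by the worst model's value, so each column's maximum is
exactly 1 and profiles are invariant to rescaling any single
diagnostic.

`fit_model()` wraps Nelder–Mead (derivative-free, as appropriate for a
stochastic simulation objective) around any generator: each evaluation
regenerates $R$ networks with *common random numbers* (the same seed
sequence at every parameter value), computes their panels at reduced
sub-procedure settings, and averages Δ. Box constraints are enforced by
clamping, integer parameters by rounding, inside the objective. The
default $R = 5$ is a desk-scale compromise; the full-scale convention
would be 100 realizations.

## The synthetic pseudo-brain

`make_surrogate()` stands in for an empirical dataset: $N/2$ points per
hemisphere on jittered spherical shells (radius 60 mm, jitter 15 mm),
exactly mirrored across the midline, with hemisphere labels, and a
network generated on them by a named embedded model with a recorded
truth block sufficient for bit-identical regeneration. The jitter
default makes the cloud volume-like; a thin shell is too homogeneous to
produce the spatial-density heterogeneity behind hierarchy in embedded
models. What the surrogate emulates is the *geometry* real parcellations
give embedded models — bilateral symmetry, realistic distance spread,
hemisphere labels. What it does not emulate: true anatomical positions,
homologous-region correspondence, tractography noise, or any weighted
structure. Tests passing on the surrogate therefore validate the
machinery and the designed-in properties of the models, not agreement
with any particular subject's connectome, whose headline values require
the external imaging dataset itself.

## Problem sizes

The package's own checks run at desk scale, chosen so the full suite
completes in minutes: diagnostics oracles at $N \le 60$, lattice closed
forms at 64–256 nodes, generator contracts over 100 seeds at $N = 60$,
parameter recovery at $N = 300$–500, and the Erdős–Rényi dispersion law
at the full $N = 998$. The same functions run unchanged at the
998-region scale; only the stochastic sub-procedure counts (tilings,
community runs, fit realizations) should then be raised to their
full-scale defaults.

## Known limitations

* Greedy box covering biases $d_B$ downward by a few percent even with
  50 tilings; exact covering is NP-hard and the greedy realization is
  the field's standard.
* Spectral + Kernighan–Lin bisection is a heuristic; on graphs with many
  balanced near-optimal cuts the recorded boundary counts, and hence
  $p_T$, carry algorithmic variance (the dispersion is reported).
* All diagnostics are topological; weighted variants are out of scope.
* The affinity model's printed functional forms are this package's
  realization of a qualitative mechanism; the parameter defaults are a
  calibration, not estimates from data.
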