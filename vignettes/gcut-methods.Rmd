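---
title: "Segmenting interweaving neuron clusters: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Segmenting interweaving neuron clusters: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gcut)
```

## The problem

Densely labeled brain tissue, traced by automated single-neuron
reconstruction software, frequently yields a *neuron cluster*: one connected
graph in which the neurites of several cells are fused by spurious links
wherever two branches passed within the imaging resolution of each other.
The parent/child direction recorded in such a tracing is meaningless — the
tracer assumed one root — so `gcut` discards it and treats the input as an
undirected geometric graph with a known set of soma nodes. Segmentation then
means assigning every branch (a curve between two topological nodes — somas,
bifurcations, or tips) to exactly one soma, so that each soma's branches form
a connected tree.

## The growth-orientation model

Neurites tend to extend smoothly *away* from their soma. The Growth
Orientation Feature (GOF) of a directed branch with respect to a candidate
soma $\mathbf{s}$ quantifies how much a branch violates that tendency:

$$\mathrm{GOF}(\mathbf{C},\mathbf{s}) \;=\; \frac{1}{L}\int_0^L
\arccos\!\Big\langle \tfrac{\mathbf{C}(l)-\mathbf{s}}
{|\mathbf{C}(l)-\mathbf{s}|},\, \mathbf{C}'(l)\Big\rangle\, dl,$$

the length-weighted mean angle between the branch tangent and the radial
direction from the soma. On a polyline it is evaluated per segment at the
segment midpoint (`branch_gof()`); the discretization error vanishes as the
sampling step shrinks, which the test suite verifies against dense numeric
integration. A branch growing straight away from the soma scores $0$, one
growing straight back scores $\pi$, and the value depends on traversal
direction.

How *unusual* a given GOF value is, is judged against an empirical corpus
distribution: `build_gof_distribution()` histograms the GOF of every branch
of a corpus of single neurons (oriented away from their own soma), and the
tail probability $\mathrm{TailDist}(x) = 1 - \mathrm{CDF}(x)$ acts as the
likelihood that a real branch-soma pair shows a GOF of at least $x$. The
penalty of assigning directed branch $a{\to}b$ to soma $s$ is

$$g_{a \to b,\,s} = \mathrm{weight}(a{\to}b)\,
\bigl\{1 - \mathrm{TailDist}[\mathrm{GOF}(a{\to}b, s)]\bigr\},$$

with $\mathrm{weight} = L$, the branch arc length, by default. Length
weighting makes the penalty dimensionally commensurate with path costs and
keeps very short (often artifactual) branches from dominating decisions;
`weight_mode = "normalized"` divides by the total cluster length instead,
which changes nothing about any individual optimum (it is a global rescale)
but makes objectives comparable across clusters.

Distributions are binned at 1° over $[0, \pi]$ (180 bins) with linear
interpolation of the CDF inside bins; the bin count is a convention, not a
sensitivity — any reasonably fine grid gives indistinguishable penalties.
The packaged default distribution (`default_gof_distribution()`) is built
from the package's own procedural template neurons and labeled provenance
`"fixture"`; it is appropriate for the simulator's clusters and for
smoke-testing, **not** a substitute for a distribution built from a real
morphology corpus of the species and brain region under study
(`build_gof_distribution()` accepts any directory of single-neuron SWC
files). `kl_divergence()` quantifies how far two corpus distributions
diverge, which is how one decides whether corpora can be pooled.

## Reduction: fixed branches, directions, independent units

Three exact reductions shrink the optimization problem:

1. **Unambiguous branches.** Delete the soma nodes; any residual component
   adjacent to exactly one soma can only have grown from that soma, so all
   its branches are fixed outright (`assign_unambiguous()`).
2. **Branch directions.** For each soma, a shortest-path search over
   *directed branches* — traversing a branch in a given orientation costs
   that orientation's penalty — yields, for every reachable branch, the
   orientation and the parent branch on its minimal-penalty growth path
   (`soma_tree()`). Ties are broken by fewer branch hops, then smaller
   branch id, making every run deterministic.
3. **Independent units.** The minimal-penalty *common path* between two
   somas (`common_paths()`) is computed with the exit cost of every
   non-source soma set to infinite — implemented as a hard expansion guard,
   not a large float, so no overflow artifacts arise. Somas joined by
   nonempty common paths form connected components; each component plus its
   common-path branches is an *independent unit* (`independent_units()`)
   whose assignment cannot influence any other unit.

Two design points deserve justification, as the choices were genuinely open:

* `soma_tree()` on the full graph does **not** forbid paths through other
  somas — its contract is the plain minimal-penalty path, which is also what
  the brute-force oracle in the tests enumerates. Inside
  `segment_cluster()`, however, the per-unit trees are built on the unit
  subgraph *with* non-source somas blocked: a growth path that threads
  through another cell body is biologically impossible, and the same
  infinite-exit rule already governs common-path identification.
* Ambiguous branches that hang *off* a common path (side subtrees reachable
  from two somas only through the path) are not optimized individually:
  whichever soma wins the branch they attach to necessarily owns them, so
  they are resolved by propagation after the unit optimum is found. This
  keeps every unit LP at the size of its common paths.

## The assignment linear program

Within a unit with somas $S$ and ambiguous branches $C$, the membership
$w_{C,s} \in [0,1]$ of branch $C$ in soma $s$ is optimized jointly:

$$\min \sum_{s \in S} \langle \mathbf{w}_{\cdot,s},
\mathbf{g}_{\cdot,s}\rangle
\quad\text{s.t.}\quad
\sum_{s} w_{C,s} = 1,\qquad w_{C,s} \ge 0,\qquad
w_{C,s} \le w_{\mathrm{par}(C,s),\,s},$$

where $\mathrm{par}(C,s)$ is the parent of $C$ in the tree of $s$. The last
constraint encodes growth topology: a downstream branch cannot belong to a
soma more than the branch it grew from. Pairs unreachable in a soma's tree
get $w_{C,s} \equiv 0$; a parent outside the unit's branch set (a branch
already fixed to $s$) imposes no constraint beyond $w \le 1$.

The relaxation is solved exactly by a dense two-phase primal simplex with
Bland's anti-cycling rule (`solve_unit()`). These LPs are tiny but extremely
degenerate — most penalties are zero or near-zero and every parent row has a
zero right-hand side — and Bland's rule guarantees finite, deterministic
termination where heuristic pivoting stalls. Costs are pre-scaled by
$1/\max g$; returned solutions are audited against all constraints to
$10^{-8}$ and a violation is a hard error, never a warning. On every
oracle-checked instance (units with $\le 3$ somas and $\le 8$ branches,
where exhaustive enumeration of topology-consistent integral assignments is
feasible) the LP optimum has matched the enumeration minimum exactly and has
been integral; the fraction of fractional weights is still reported as a
per-run diagnostic because integrality of the relaxation is not proven in
general.

Discretization (`finalize_assignment()`) takes $\arg\max_s w_{C,s}$ per
branch, ties to the smallest soma id. Because a fractional optimum could in
principle orphan a branch from its growth path, a repair pass (parents
first) moves any branch whose parent went elsewhere to the parent's soma and
counts the repairs; on integral optima it is a no-op.

## The synthetic cluster generator

`generate_cluster()` emulates how real clusters arise: single neurons at
random rigid poses, fused wherever neurites nearly touch.

* **Templates** (`template_neuron()`) are random outward-growing binary
  trees: 4–6 stems, up to two bifurcation levels (75% bifurcation
  probability per tip), branch lengths 60–120 µm meandering at a 4 µm step
  with a mild radial bias, daughter angles of 20–40°. These reproduce the
  features the method actually exploits — branches oriented away from their
  soma, realistic lengths, bifurcating topology, arbors spanning a few
  hundred µm — and deliberately omit imaging noise, radius variation, and
  tracing errors. Passing tests on them therefore demonstrates the
  correctness of the optimization machinery, not robustness to upstream
  tracing artifacts.
* **Placement** (`place_neurons()`): uniform translations in a
  220 µm box with somas at least 50 µm apart, Haar-uniform rotations —
  packing densities at which neighbouring dendritic arbors interdigitate,
  as in densely labeled cortical tissue.
* **Linking** (`link_proximal()`): wherever two branches of different
  neurons pass within 5 µm (about the blur at which tracing fuses adjacent
  dendrites), one spurious edge joins the closest node pair of that branch
  pair — at most one link per branch pair, so the entanglement count equals
  the number of fused contacts. Clusters that fail to connect all neurons
  are rejected and redrawn; connected clusters therefore carry at least
  `scale - 1` links. A single seed drives template choice, poses, and all
  rejection loops, so any dataset is reproducible byte for byte.

Ground truth is retained at node, edge and branch level; removing the
spurious links must disconnect the cluster back into the posed originals,
and the tests assert exactly that.

## Evaluation: Miss-Extra-Scores

`mes()` scores a segmented neuron against its ground-truth counterpart
geometrically, since node ids and topology differ between tracings. Both
morphologies are resampled to arc-length pieces of at most `tol/2`; truth
length not within `tol` of the test is *miss*, test length not within `tol`
of the truth is *extra*, and

$$\mathrm{MES} = \frac{L_{gt} - \mathrm{miss}}{L_{gt} + \mathrm{extra}}
\in [0, 1],$$

equal to 1 exactly for a perfect reconstruction. The default tolerance is
2 µm; on clean synthetic data the score moves by less than 0.01 as `tol`
varies over 1–3 µm (only the few µm of arc around a cut junction are
tol-sensitive). The formula and tolerance are conventions of this package's
implementation of the metric; published variants differ in detail, so
scores from different implementations should be compared qualitatively, not
digit by digit.
`random_baseline()` provides the chance floor: ambiguous unit branches
assigned uniformly at random (fixed branches keep their topological
assignment), averaged over seeded draws.

## Problem sizes and numerical conventions

The validation workloads are sized for a laptop-class single core: 50
random polylines for the discretization check; 200 random small units
(≤ 3 somas, ≤ 8 ambiguous branches) for LP-vs-enumeration; 100 clusters
(20 per scale 2–6, entanglement capped at scale + 2) for ground-truth
recovery, where mean MES is required to reach 0.9 and to beat the random
baseline on every cluster; and 30 scale-6 clusters stratified over three
entanglement bins (5–8, 9–12, 13+ links; free draws rarely reach the tail)
for the degradation trend (Spearman ρ < 0 at p < 0.05). Larger corpora
only narrow the confidence intervals.

Numerical conventions, in one place: penalties and path costs compare with
an absolute slack of 1e-9 (tie-breaking then falls to hop count and branch
id); LP feasibility is audited at 1e-8; weights within 1e-6 of {0, 1} count
as integral; zero-length segments are skipped with a warning; a soma
coinciding with a segment midpoint contributes angle 0 (the most favorable
value) with a warning; empty histogram bins receive 1e-10 mass before KL
divergence; SWC coordinates are written at `%.9g` precision.

## Known limitations

* Upstream tracing errors (broken branches, missed junctions) are neither
  modeled nor corrected; the input graph's connectivity is trusted.
* The fixture GOF distribution reflects procedural templates; real analyses
  should supply a corpus matched to their preparation.
* Axonal morphology — long, thin, differently oriented — is outside the
  model; the orientation prior is a dendritic one.
* A multi-soma cluster with cycles cannot be serialized as SWC; the
  vertex/edge-list writer covers that case.
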