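---
title: "Multi-scale and persistent Jones polynomials: methods and conventions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-scale and persistent Jones polynomials: methods and conventions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pjones)
```

## The model

`pjones` measures the entanglement of a collection $L$ of disjoint open or
closed polygonal curves in 3-space.  Classical knot invariants only exist
for closed curves; the route to open curves is geometric: project $L$ onto
the plane with unit normal $\xi$, obtaining a *linkoid diagram* — a
multi-component open-ended link diagram with labeled endpoints — and average
the resulting invariant-like quantity over all projection directions.

For a single diagram the quantity is a Kauffman-style bracket.  Each of the
$c$ crossings is smoothed in one of two planar ways (A or B); a *state* $S$
is a choice at every crossing.  After smoothing, the diagram decomposes
into closed loops (counted by $|S|_{circ}$) and open strands.  The open
strands induce a pairing $\hat S$ of the endpoint labels
$G = \{1,\dots,2n\}$, which together with the diagram pairing
$\hat L = (1,2)(3,4)\cdots(2n-1,2n)$ yields *segment cycles*: orbits of
$\hat L \circ \hat S$ merged with their $\hat L$-translates.  The number of
segment cycles $|S|_{cyc}$ satisfies $1 \le |S|_{cyc} \le n$ and plays the
role of a loop count for open strands.  The bracket is the exact state sum

$$\langle L \rangle \;=\; \sum_S A^{\sigma(S)}\, d^{\,|S|_{circ} + |S|_{cyc} - 1},
\qquad d = -A^2 - A^{-2},$$

with $\sigma(S)$ the number of A minus B smoothings, and $|S|_{cyc} = 0$
for diagrams without open components (recovering the classical
$d^{|S|-1}$).  The writhe-normalized bracket
$f_L = (-A^3)^{-\mathrm{Wr}(L)} \langle L \rangle$ is averaged
coefficient-wise over projection directions, and evaluated through
$A = t^{-1/4}$.  For closed collections every regular direction yields the
same polynomial — the classical Jones polynomial — which the test suite
verifies on unknot, Hopf-link and trefoil fixtures; for open curves the
average is a continuous, real-coefficient entanglement measure that
converges to the closed invariant as the endpoint gaps close.

Two localizations sit on top of this global quantity:

* **Multi-scale:** for a segmentation $P_n = l_1,\dots,l_n$ of $L$ and a
  ladder of half-open distance shells $[r_k, R_k)$, entry $(i,k)$ of the
  *characteristic matrix* is the Jones value (at fixed $t$) of the
  sub-collection containing $l_i$ and every segment whose distance from
  $l_i$ falls in the shell.  Rows localize along the curve, columns scan
  the length scale.
* **Persistent:** the Vietoris–Rips complex of the inter-segment distance
  matrix changes only at its critical values (the distinct pairwise
  distances).  `pjones` tracks the *facets* (maximal cliques) across these
  values: each vertex set that is ever maximal gets a birth, a death and a
  *weight* — the Jones value of its segments.  The result is a weighted
  barcode / persistence diagram; two diagrams are compared with a weighted
  bottleneck distance whose matching cost is
  $\max(|\Delta b|, |\Delta d|, |\Delta w|)$ and whose unmatched cost is
  half the lifespan.

## Conventions fixed by the implementation

Several choices are left open by the mathematics and are fixed (and
documented) here:

* **Crossing sign.** A crossing is $+1$ when the under-strand direction,
  rotated counterclockwise by less than $\pi$, aligns with the over-strand
  direction.  The A-smoothing joins the two regions swept by rotating the
  over-strand counterclockwise onto the under-strand.  These two
  conventions are fixed jointly: with them the normalized bracket is
  direction-independent for closed curves and invariant under adding a
  kink, and the package's `"trefoil"` fixture evaluates to
  $-t^{-4}+t^{-3}+t^{-1}$ (0.1009 at $t=10$).  Chirality conventions only
  act through $t \leftrightarrow 1/t$.
* **Endpoint labels.** Open component $j$ (in component order) carries head
  $2j-1$ at its leading vertex and leg $2j$ at its trailing vertex, so
  $\hat L$ is always $(1,2)(3,4)\cdots$; closed components carry no labels.
  Any consistent labeling gives the same cycle structure.
* **Irregular projections.** Tangential or collinear overlaps, triple
  points, crossings within $10^{-9}$ (relative) of an edge endpoint, and
  depth ties are treated as irregular — a measure-zero set of directions —
  and evaded by a seeded rotation of at most $10^{-4}$ rad, retried up to
  10 times before an explicit error.
* **Quadrature.** The sphere average defaults to a deterministic spherical
  Fibonacci lattice (100 points for global values; 20 for the many
  sub-collection evaluations inside matrices and barcodes, where the
  curves are short and the per-direction spread is small).  Uniform random
  directions with a required seed are available for statistical checks.
* **Crossing cap.** The state sum is exponential in $c$; diagrams above
  `max_crossings` (default 20) raise a typed error.  Skipping and counting
  over-cap directions is opt-in (`skip_overfull`), because silently
  dropping directions changes the estimand.
* **Shared endpoints.** Midpoint segments of a chain share breakpoints;
  sub-collections assembled from them retract every open segment by
  $10^{-6}$ of its length at both ends, making components disjoint without
  measurably moving the curve.
* **Vietoris–Rips rule.** Edges use the closed threshold $d \le r$, so
  births are attained at critical values; distances within $10^{-9}$ are
  grouped as one critical value.  Every vertex is born at $r = 0$; the
  final all-vertex facet dies at $+\infty$ and can be dropped
  (`drop_infinite`) for bottleneck work.
* **Weight convention.** The default facet weight is *relative*:
  $J(t) - d(t)^{|F|-1}$, the departure from the crossing-free value of an
  $|F|$-component collection, so geometrically trivial facets weigh exactly
  0 (this is what makes single-segment bars report weight 0).  `"raw"`
  reports $J(t)$ itself.  Facets larger than `max_weight_size` (default 8)
  keep an "uncomputed" (`NA`) weight unless forced.

## Distance metrics

Between curve segments two metrics are provided.  The *representative*
metric is the distance between representative points — for proteins, the
C$\alpha$ atoms, which is the convention the protein pipeline uses
throughout.  The *sup* metric bounds how far two segments stray from each
other: the larger of the two one-sided suprema of point-to-polyline
distance, evaluated on a configurable dense sampling (32 interior points
per edge by default).  The symmetrized form was chosen because a one-sided
supremum is not symmetric and a distance matrix feeding a Vietoris–Rips
filtration must be; the representative metric is the default wherever a
segmentation carries representative points.

## The protein pipeline

`bfactor_features()` implements the flexibility pipeline: one segment per
residue (cut at C$\alpha$–C$\alpha$ midpoints), C$\alpha$ distances, shells
$r = 4, 4.25, \dots, 15$ Å with $R = r + 1$ Å (45 shells, spanning 4–16 Å;
the mean C$\alpha$ spacing is ≈3.8 Å so the first shells isolate immediate
neighbors), Jones values at $t = 10$, then column z-scoring.
`fit_bfactor()` fits experimental B-factors with an L1-penalized linear
model at penalty 0.16.  The penalty is interpreted on the standardized
scale — features are z-scored and the response is standardized internally
(fitted values are returned in original units) — because a fixed numeric
penalty is only meaningful scale-free: B-factor magnitudes vary by orders
of magnitude across structures.  Reported performance is the per-protein
in-sample Pearson correlation between fitted and experimental values, the
convention of the flexibility-prediction literature.

A statistical note the tests rely on: an in-sample fit with $p$ features
has a positive correlation bias under the null.  With the penalty on the
standardized scale the Lasso selects nothing under a permutation null once
$0.16 > \sqrt{2\log p / n}$, i.e. for chains of a few hundred residues at
$p = 45$.  The parameter-recovery and permutation-null tests therefore use
$n = 400$ synthetic residues: at that size the planted-signal fit recovers
$r > 0.99$ while the shuffled-feature null collapses to $r \approx 0$.  At
$n \lesssim 100$ no in-sample procedure has a near-zero null; interpreting
per-protein correlations for very short chains requires that caveat.

## What the synthetic generator emulates — and what it does not

The fixtures are the study conditions of the test suite:

* `make_ideal_helix(19, radius = 2.3, rise = 1.5, twist = 100)` — the
  canonical α-helix C$\alpha$ geometry (3.6 residues/turn, 1.5 Å rise,
  consecutive C$\alpha$ distance ≈3.83 Å).  Its facet barcode has 19
  zero-dimensional bars of length ≈3.83 Å, 18 adjacent-pair bars dying at
  ≈5.43 Å and 16 short-lived non-adjacent bars born at ≈5.05 Å.
* `make_parallel_strands(8, intra = 3.8, inter = 4.8)` — a parallel
  β-strand pair with standard C$\alpha$ spacings; barcode counts 16/14/8.
* `make_polygonal_knot()` — closed controls (unknot, Hopf link, trefoil)
  whose classical Jones polynomials are known exactly.

Ideal geometry is *degenerate* in a way real proteins are not: all
equivalent distances coincide, so e.g. helix triangles complete at the same
critical value as the 4-cliques that absorb them and never become facets —
the ideal fixtures have no 2-dimensional facet bars, while real
(non-ideal) helices show short-lived ones.  Passing tests on these
fixtures validate the machinery and the published bar counts; they do not
exercise coordinate noise, missing residues, alternate conformations or
chain breaks beyond what the perturbation tests cover.

## Stability

The perturbation model displaces every vertex independently and uniformly
in the ball of radius $\varepsilon$, so the sup-norm displacement is below
$\varepsilon$ by construction.  Distances then move by at most
$2\varepsilon$, every matched facet's birth/death by at most
$2\varepsilon$, and the weighted bottleneck distance between the original
and perturbed diagrams is bounded by $\max(2\varepsilon, \varepsilon_J)$
with $\varepsilon_J$ the largest per-facet weight drift.  The stability
tests run the 19-residue helix at $\varepsilon = 10^{-2}$ and $10^{-3}$ Å
(seeded), with a 6-shell scheme over 4–7.5 Å, 20 Fibonacci directions and
weights computed for facets of up to 4 segments, and assert that both the
maximal characteristic-matrix drift and the bottleneck distance shrink
with $\varepsilon$ and respect their bounds (drift below 0.05 at
$\varepsilon = 10^{-2}$ under these conditions).  At these amplitudes the
drift is often exactly zero: a perturbation too small to change any
projected crossing pattern leaves every bracket unchanged — the invariant
is locally constant, which is stability in its strongest form.

## Numerical and algorithmic notes

* The bracket enumerates all $2^c$ states; states are tallied by
  $(\sigma, \text{d-exponent})$ so the polynomial is assembled from a few
  dozen terms regardless of $c$.  An independent recursive skein expansion
  (incremental arc merging) lives in the test helpers and must agree
  coefficient-exactly on every diagram with $\le 8$ crossings.
* Facet tracking recomputes maximal cliques per critical value
  (igraph's Bron–Kerbosch) and diffs consecutive facet sets; adequate for
  segmentations up to a few hundred segments.  A bitmask subset-enumeration
  oracle checks it exhaustively for $n \le 8$.
* The weighted bottleneck distance is exact: a binary search over the
  finite candidate set (all pair costs and half-lifespans) with a
  bipartite perfect-matching feasibility test (points plus per-point
  diagonal copies).  Points with infinite death may only match each other.
  One behavior worth knowing: for short bars the diagonal is a legitimate
  shortcut, so a pure weight difference only costs what the definition
  says it costs — two copies of a bar with lifespan 2 and weights 0 and 5
  are at distance 1 (both to the diagonal), not 5; for persistent enough
  bars the weight term dominates.
* Jones evaluations use a real $A = t^{-1/4}$ with $t > 0$; complex $t$ is
  out of scope.

## Problem sizes

The default test and acceptance runs use the 19-residue helix and the
8+8-residue strand pair (19 and 16 segments), 20 Fibonacci directions per
sub-collection Jones value, facet weights up to 4 segments, 200 random
linkoid diagrams with ≤8 crossings for the state-sum properties, and 100
random ≤8-point configurations for the facet oracle.  These sizes were
chosen so the whole suite exercises every code path in minutes on one
core; all of them scale up by changing the corresponding arguments.

## Known limitations

* The state sum is exponential in the projected crossing number; dense
  collections (many long segments in one shell or facet) hit the crossing
  cap.  No Reidemeister simplification is attempted before the state sum.
* No Čech complex and no homology: persistence is of facets, which is a
  different (finer-grained, non-homological) summary than persistent
  homology barcodes.
* Polylines only: smooth curves must be discretized by the caller.
* Real-protein secondary-structure barcodes depend on which residues are
  selected; the package takes explicit residue ranges and makes no attempt
  at automatic secondary-structure assignment.
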