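---
title: "Topological invariants of (5,6)-fullerenes: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Topological invariants of (5,6)-fullerenes: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fullerzz)
```

## The objects

A (5,6)-fullerene C~n~ is a closed carbon cage whose faces are exactly 12
pentagons and n/2 − 10 hexagons; as a graph it is cubic, planar and
2-connected. `fullerzz` represents any pentagon/hexagon polycyclic system
(cages, but also open systems such as corannulene, where degree-2 carbons
stand for CH positions) as a `plane_graph`: vertices, edges, a rotation
system (the cyclic neighbour order at each vertex, which *is* the plane
embedding) and the face list traced from it. Face tracing uses every
directed edge exactly once, so V − E + F = 2 is checked on every
construction; cages follow the sphere convention in which the Schlegel
"outer" face counts as an ordinary pentagon or hexagon.

Two resonance-theoretic structures live on these graphs. A *Kekulé
structure* is a spanning subgraph whose components are single edges (K~2~):
a perfect matching, chemically a pattern of alternating double bonds. A
*Clar cover* generalizes this by also allowing 6-cycles (C~6~, aromatic
sextets) as components; its *order* k is its number of sextets. Collecting
covers by order gives the Zhang–Zhang (Clar covering) polynomial

$$\mathrm{ZZ}(B, x) = \sum_{k=0}^{Cl} c_k\, x^k,$$

from which all invariants used here follow: the Kekulé count
K = c~0~ = ZZ(B, 0), the Clar count C = ZZ(B, 1), the Clar number
Cl = deg ZZ (the maximal number of simultaneously accommodated sextets) and
the Clar-formula count c~Cl~ (covers attaining Cl).

```{r corannulene}
co <- fixture_corannulene()
zz(co)
c(K = kekule_count(co), C = clar_count(co), Cl = clar_number(co))
```

## Recovering the embedding

Spiral-generated cages come with a canonical embedding (below). For
adjacency-only or XYZ input the package does not run a general
planarity-embedding algorithm; it exploits a structural fact about this
class of molecules: the bounded faces of a pentagon/hexagon system are
exactly its simple 5- and 6-cycles. The builder enumerates those cycles,
requires every edge to lie in one or two of them, orients the cycles
consistently (faces sharing an edge must traverse it in opposite
directions, propagated by BFS), and assembles the rotation system from the
resulting corner constraints. Anything that violates these conditions —
wrong degrees, faces of other sizes, non-planar input — is rejected with a
diagnostic rather than embedded incorrectly, and the Euler check guards the
result. Degenerate acyclic molecules (a lone C–C bond, used in contract
examples) get the trivial one-face embedding.

For fullerene cages the same fact is re-checked at run time by
`sextet_candidates()`: the 6-cycles found by search must coincide with the
hexagonal faces. This holds for every cage in the supported range (n ≤ 70);
if it ever failed the engine would stop rather than silently use
non-facial sextets.

XYZ input perceives a bond wherever two carbons are closer than 1.70 Å
(configurable). The cutoff is our choice, not a literature constant: C–C
bonds in these cages span roughly 1.37–1.48 Å while next-nearest contacts
stay above 2.2 Å, so any value in between works and 1.70 Å sits safely in
the gap. Hydrogens are ignored. The complementary `spherical_layout()`
(adjacency-eigenvector placement on a sphere) exists only to write readable
XYZ files and to round-trip tests; it is not a geometry optimizer.

## The ring spiral

A spiral code lists the positions of the 12 pentagons in the face sequence
that peels the cage like an orange. `windup()` rebuilds the cage in the
dual picture: each new face fuses to the previous face and to the earliest
boundary face that still has open valences; whenever a boundary face fills
up it leaves the boundary and the fusion wraps to its neighbour; the final
face must consume every remaining valence exactly. A failure position is
reported instead of an error so that enumeration can prune.

`canonical_spiral()` unwinds the cage from every start (each face × each
adjacent face × both directions) and keeps the lexicographically smallest
pentagon tuple. `generate_isomers()` runs a depth-first search over face
sequences (pentagon before hexagon, which makes the output order
lexicographic), prunes on windup failure, and keeps a completed spiral only
if it equals its own canonical spiral — isomorph rejection without storing
graphs. The label n:m means the m-th isomer in this order:

```{r spirals}
length(generate_isomers(36, build_graphs = FALSE))  # 15 isomers of C36
canonical_spiral(fixture_dodecahedron())
```

The enumeration is deterministic and exhaustive for n ≤ 70; beyond that a
warning notes that unbranched spirals can miss isomers in principle (the
package does not implement top-down generation).

## Computing ZZ polynomials

The engine uses a vertex-branching recursion: pick the live vertex u with
the fewest live neighbours (ties to the smallest index); every Clar cover
assigns u either to one incident edge or to one candidate sextet through
it, so

$$\mathrm{ZZ}(G[S]) = \sum_{v \in N(u) \cap S} \mathrm{ZZ}(G[S \setminus \{u,v\}])
  + x \sum_{h \ni u,\; V(h) \subseteq S} \mathrm{ZZ}(G[S \setminus V(h)]).$$

Because every recursion state is an induced subgraph, the memo key is the
live-vertex bit set — exact and collision-free with no graph
canonicalization. The memo lives per invocation (bond-order tables share
one table across all edge- and ring-deleted subgraphs of a call); no cache
is kept across isomers, a simplicity trade-off that still computes the full
ZZ polynomial of the icosahedral C60 in milliseconds. Coefficients are
64-bit integer counts, exact far beyond the C20–C70 range (counts there
stay below 10^7^; doubles returned to R are exact to 2^53^). Inputs above
120 vertices are refused by default. The zero polynomial (odd vertex
counts, uncoverable graphs) is represented explicitly and `clar_number()`
reports −1 with no-cover semantics instead of raising, so batch sweeps
never abort.

Three independent oracles guard the engine in the tests: exhaustive
Clar-cover backtracking (`enumerate_clar_covers()`, guarded to 32
vertices), a memoization-free edge-branching matching counter
(`matching_count_oracle()`), and the exact counts printed for corannulene
and small cages.

## Pauling bond orders

Averaging the π character of a bond over all Kekulé structures gives the
Pauling–Kekulé order p~K~(e) = K(G−u−v)/K(G); over all Clar covers — where
a bond may also be a sextet member with weight ½ — the Pauling–Clar order
p~C~(e) = [C(G−u−v) + ½ Σ~h∋e~ C(G−V(h))]/C(G). Orders are kept as exact
integer numerator/denominator pairs (p~C~ numerators in halves), so the
per-vertex sum rule Σ p = 1 is asserted without any floating-point
tolerance.

```{r bond-orders}
head(bond_order_report(fixture_dodecahedron()), 3)
```

Bond lengths correlate linearly with these orders; the shipped models
(length = 1.5096 − 0.2016·p~C~ and 1.5708 − 0.3851·p~K~, in Å) were fitted
over DFTB-optimized geometries of the full C20–C70 isomer set and are
provided as constants, with `regress_orders_vs_lengths()` available to
refit on user-supplied geometries. Reproducing the published fit quality
would require those DFTB geometries and is out of scope. The regression is
length-on-order, matching the form of the shipped models.

## Stability analyses

Quantum-chemical energies are consumed, never computed: an energy table
(TSV with n, m, energy, unit ∈ {hartree, kcal/mol}; 1 hartree =
627.5094740631 kcal/mol) joins the invariant records. On top of that the
package reports Clar-number populations (integer percentages, rounded half
away from zero to match the usual table formatting), C-versus-K statistics
(C ≥ K always holds and is asserted; the lower boundary of the C-vs-K
wedge is operationalized as the minimum C/K ratio — the simplest reading
consistent with the quoted bounds, and flagged as an interpretation in the
report header), the Zhang–Ye–Liu hypothesis (does the global energy
minimum maximize K among isomers with maximal Cl?) and its Clar-count
variant. Ties in any optimum are reported as label sets, never silently
broken; verdicts are invariant under energy units and increasing affine
transformations. `uniqueness_check()` groups records by the full
coefficient vector; distinct isomers with n ≤ 70 are expected to have
distinct ZZ polynomials, and the test suite verifies this for every isomer
with n ≤ 40.

## Problem sizes and numerical choices

The test and acceptance workloads were sized so a full run stays
comfortable on a single CPU: oracle cross-validation on all graphs ≤ 28
vertices, matching-oracle agreement and uniqueness sweeps to C36–C40,
exact sum rules to C30, and the printed-value checks (corannulene, C36,
C50, C60 including the exhaustive 1812-isomer enumeration, about half a
minute). All of these are exact integer comparisons; the only tolerance
anywhere is in the floating-point regression test, which uses a 3-standard-
error band under a fixed seed.

Known limitations: no 3D geometry generation or optimization beyond the
naive spherical layout; no symmetry-group assignment; no (5,6,7)-cages; no
top-down generation for spiral-incomplete cages (n > 70); energies must be
supplied externally.
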