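# fullerzz

Topological invariants of (5,6)-fullerenes and related pentagon/hexagon
polycyclic carbon frameworks, for cheminformatics work on fullerene isomer
stability: exhaustive ring-spiral isomer generation with the canonical
lexicographic `n:m` labelling, Zhang–Zhang (Clar covering) polynomials, the
derived Kekulé/Clar invariants, Pauling π bond orders with linear
bond-length models, and stability analyses over externally supplied energy
tables.

## The invariants

A (5,6)-fullerene C<sub>n</sub> is a cubic planar cage with 12 pentagonal
and n/2 − 10 hexagonal faces. A *Kekulé structure* is a perfect matching
(alternating double bonds); a *Clar cover* additionally allows aromatic
sextets (6-cycles) as components, its *order* being the sextet count.
The Zhang–Zhang polynomial collects covers by order,

ZZ(B, x) = Σ<sub>k=0..Cl</sub> c<sub>k</sub> x<sup>k</sup>,

so that the Kekulé count K = c₀ = ZZ(B, 0), the Clar count C = ZZ(B, 1),
the Clar number Cl = deg ZZ, and the number of Clar formulas is the leading
coefficient c<sub>Cl</sub>. The package computes ZZ exactly by a memoized
vertex-branching decomposition, generates isomers by the ring-spiral
algorithm with canonical-spiral isomorph rejection, and derives
Pauling–Kekulé orders p<sub>K</sub>(e) = K(G−u−v)/K(G) and Pauling–Clar
orders p<sub>C</sub>(e) = [C(G−u−v) + ½ Σ<sub>h∋e</sub> C(G−V(h))]/C(G)
in exact rational arithmetic.

## Worked example

```r
library(fullerzz)

co <- fixture_corannulene()          # 1 pentagon fused to 5 hexagons, C20H10
zz(co)
#> ZZ polynomial(corannulene): 11 + 15 x + 5 x^2
c(K = kekule_count(co), C = clar_count(co), Cl = clar_number(co))
#>  K  C Cl
#> 11 31  2
```

Corannulene has 11 Kekulé structures, 15 Clar covers with one sextet and 5
Clar formulas with the maximal two sextets — 31 Clar covers in all. The
same machinery on the icosahedral C60 (built from solid-geometry
coordinates via distance-based bond perception):

```r
zz(fixture_truncated_icosahedron())
#> ZZ polynomial(truncated icosahedron (C60 Ih)): 12500 + 41580 x + 67650 x^2
#> + 66900 x^3 + 42000 x^4 + 16352 x^5 + 3620 x^6 + 360 x^7 + 5 x^8
```

K = 12,500 and Cl = 8 for the buckminsterfullerene cage. Isomer sweeps use
the spiral order; e.g. the 15 isomers of C36 and their invariants:

```r
inv <- isomer_invariants(36)
head(inv[, 1:6], 3)
#>    n m   K   C Cl cCl
#> 1 36 1 275 559  3   4
#> 2 36 2 319 695  2  76
#> 3 36 3 290 623  3   3
clar_population(inv)
#>   Cl count percent
#> 1  2     7      47
#> 2  3     6      40
#> 3  4     2      13
```

Bond orders with the built-in length models (Å):

```r
head(bond_order_report(fixture_dodecahedron()), 3)
#>   u  v        pK        pC len_pred_K len_pred_C
#> 1 1  9 0.3333333 0.3333333   1.442433     1.4424
#> 2 1 13 0.3333333 0.3333333   1.442433     1.4424
#> 3 1 17 0.3333333 0.3333333   1.442433     1.4424
```

## Command line

`inst/cli/fullerzz` is a thin Rscript over the same functions:

```sh
Rscript inst/cli/fullerzz fixtures --name corannulene --out c.adj
Rscript inst/cli/fullerzz zz --adj c.adj          # prints: 11 15 5
Rscript inst/cli/fullerzz generate --n 60 --limit 10 --out spirals.txt
Rscript inst/cli/fullerzz invariants --n 36 --out inv.tsv
Rscript inst/cli/fullerzz analyze --invariants inv.tsv --energies e.tsv --report out/
```

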