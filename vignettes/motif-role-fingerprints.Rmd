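---
title: "Motif-role fingerprints: models, conventions and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Motif-role fingerprints: models, conventions and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(motifroles)
```

## The counting model

A directed, binary, loop-free network on $N$ nodes is described by its
adjacency matrix $A$ ($a_{ij} = 1$ iff $i \to j$, $a_{ii} = 0$). On three
nodes there are exactly 13 isomorphism classes of weakly connected directed
graphs ("motifs", $m = 1..13$), and partitioning the nodes of each class by
its automorphism group yields 30 node orbits ("motif-roles",
$r = 1..30$). Both numbers are not assumptions but outputs of the package's
own enumeration: all $2^6 = 64$ labelled triple configurations are
canonicalized by exhaustive minimization over the $3! = 6$ node
permutations (`enumerate_motif_classes()`, `orbits_of()`). The same
machinery enumerates 199 connected classes on four nodes.

Every statistic in the package comes in two flavors:

* **functional** (partial-subgraph): a pattern occurs on a node triple
  whenever its edges are a *subset* of the edges present; each distinct
  edge set counts once (automorphism-deduplicated), so a fully
  bidirectional triad contributes, among others, six two-paths.
* **structural** (induced-subgraph): each weakly connected triple is
  classified by *exactly* the edges present and contributes to exactly one
  motif, and one role per member node.

The **role fingerprint matrix** is the $30 \times N$ integer matrix whose
column $i$ counts the occurrences in which node $i$ plays each role.
Summing roles within a motif gives motif fingerprints ($13 \times N$);
summing fingerprints over nodes and dividing by three gives global motif
counts; role counts are plurality-weighted motif counts, which is what the
`role_layout()` table makes explicit.

## The fast functional pass

Functional fingerprints are computed without any triple loop. The 30 roles
fall into nine *ego-pattern families* — the multiset of the reference
node's connections to the other two nodes, drawn from
$\{\text{out}, \text{in}, \text{recip}\}$ — and each family is evaluated
with at most one $N \times N$ matrix product plus a Hadamard product,
using $A$, $A^{\mathsf T}$ and the reciprocal-edge matrix
$R = A \circ A^{\mathsf T}$. Representative identities (writable directly
from the definitions) are

$$
F_{10} = \binom{d^{\text{in}}}{2}, \quad
F_{13} = \binom{d^{\text{out}}}{2}, \quad
F_{16} = d^{\text{in}} d^{\text{out}} - d^{\leftrightarrow}, \quad
F_{28} = \binom{d^{\leftrightarrow}}{2},
$$

$$
F_{17} = \operatorname{diag}(A^3), \qquad
F_{18} = \operatorname{diag}(A A^{\mathsf T} A),
$$

with $d^{\leftrightarrow}$ the reciprocal degree $R\mathbf 1$. Triple
products are evaluated as `rowSums((X %*% Y) * t(Z))`, i.e. one product and
one Hadamard mask, never a full triple product. All arithmetic is exact:
counts are integers well below $2^{53}$, so the `double` intermediates are
lossless and are rounded back to integer storage.

The independent oracle (`method = "bruteforce"`) enumerates all
$\binom{N}{3}$ triples and classifies each through a precomputed table over
the 64 configurations (for functional counting, every connected edge
subset of every configuration). The table is built from the catalog's
orbit descriptors and shares nothing with the algebraic formulas; equality
of the two paths is asserted exactly, over all roles and nodes, on 50
seeded random digraphs in the test suite.

## Functional–structural conversion

A structural occurrence of motif $s$ contains a fixed number of functional
occurrences of each pattern $f$ as connected spanning edge subsets.
Counting those containments per role (at most $2^6$ subsets per motif)
gives the $30 \times 30$ matrix $T$ with

$$ F_{\text{col}} = T\, S_{\text{col}} $$

for every node's fingerprint column. This package fixes the orientation
convention "functional$(f) = \sum_s \text{contains}(s,f) \cdot
\text{structural}(s)$", which is dimensionally unambiguous; all shipped
matrices are derived under it and never hand-typed (they are regenerated
by `role_conversion_matrix()` / `motif_conversion_matrix()` and shipped as
versioned TSVs that the tests compare bit-exactly against a fresh
derivation). Sorted by the edge count of the source motif, $T$ is
triangular with unit diagonal, hence unimodular, so its inverse is an
integer matrix and structural statistics follow from the fast functional
pass by one exact matrix multiplication — this is how
`role_fingerprints(g, "structural")` works by default. Converting a vector
that could not have come from a real graph (negative or fractional
structural counts) is reported as an error rather than silently rounded.

`empirical_conversion()` re-derives $T$ blind, the way one would at
subgraph sizes where subset enumeration has not been tabulated: sample
random digraphs, count both flavors per node, and solve the linear system
across all fingerprint columns. A deliberate design point: the system is
solved at *fingerprint* (per-node) level, not on global count vectors,
because global role counts always equal plurality times motif count and
therefore span at most a 13-dimensional subspace — a count-level system is
permanently rank-deficient no matter how many networks are sampled.
Rank is checked and a deficient sample is an error. With the default
protocol (100 graphs, $N = 15$, $p = 0.3$) the rounded solution reproduces
the combinatorial matrices exactly.

## The numbering registry

Numeric ids matter because users quote roles by number. The anchors fixed
by the accompanying analyses are enforced at construction time (violations
are errors): motif 2 is the directed two-path, motif 5 the cyclic
triangle, motif 9 the feed-forward triangle, motif 13 the fully
reciprocal triad; role 10 = two in-edges (no cross edge), role 13 = two
out-edges, role 16 = two-path middle (the three clustering denominators,
all invariant in expectation under in/out-degree-preserving nulls for
roles 10 and 13), role 14 = two out-edges plus an edge between the
destinations, role 28 = two reciprocal partners with no cross edge, and
role 30 = the complete-triad role, the only role whose functional and
structural counts always coincide.

Beyond the anchors the ordering is a package convention, chosen once and
shipped (`role_registry()`, `extdata/role_registry.tsv`): role ids follow
the nine ego-pattern families in the order {out}, {in}, {recip}, {in,in},
{out,out}, {in,out}, {recip,out}, {recip,in}, {recip,recip}; within a
family, roles are sorted by required cross-edge count and remaining
orientation ties by the id of the motif the role belongs to (so role 17
is the cycle role, from motif 5, and role 18 the feed-forward middle,
from motif 9). Unpinned motif ids fill the free slots in (edge count,
canonical key) order. These tie-breaks are not derivable from the textual
anchors alone; they are deterministic, versioned, and must not be
silently renumbered — any future re-anchoring against an external id
table should happen by editing the pinning layer, which will loudly fail
its registry checks if inconsistent.

## Clustering coefficients and transitivities

Per node, the closed directed triangle count is
$b = \tfrac12 \operatorname{diag}\!\big((A + A^{\mathsf T})^3\big)$ and the
potential count is $D = d^{\text{tot}}(d^{\text{tot}} - 1) -
2 d^{\leftrightarrow}$; the total directed clustering coefficient is
$C^{\text{tot}} = b \oslash D$. Note that with this normalization the
fully bidirectional triad has $b = D = 8$ per node and $C^{\text{tot}} =
1$, as a clustering coefficient must at the complete graph; the factor-2
weighting of reciprocal edges in $A + A^{\mathsf T}$ is part of the
definition, not an artifact. The tests also verify the exact identity
$b = F_{11} + F_{14} + F_{17} + F_{18}$, with the integer weights derived
by brute force over the 64 triple configurations rather than assumed.

The subtypes divide the closed triangles by the reference node's
orientation:

| subtype | numerator | denominator |
|---|---|---|
| in | $0.5\,F_{11}$ | $F_{10}$ |
| out | $0.5\,F_{14}$ | $F_{13}$ |
| middleman | $F_{18}$ | $F_{16}$ |
| cycle | $F_{17}$ | $F_{16}$ |
| 3-feedforward | $F_{11} + F_{14} + F_{18}$ | $2F_{10} + 2F_{13} + F_{16}$ |

The 0.5 factors reflect the two edges that can close an open in-in or
out-out wedge into a feed-forward triangle. The 3-feedforward blend is
defined here as the role-consistent combination of all three feed-forward
roles over all their openings: it quantifies the total fraction of
possible non-cyclic directed closed triangles, reduces to the single-role
subtypes on nodes exposing only one opening type, and is documented as an
interpretation (the source formula is not recoverable verbatim).
Divisions by zero yield 0 by convention. Global means are reported both
over all nodes and over the $n^*$ nodes with a nonzero denominator; the
$n^*$ variant is the headline number.

Transitivities are ratios of network totals (not means of ratios):
$T = \sum_i \text{num}_i / \sum_i \text{den}_i$ per subtype. The cycle
denominator is the total two-path count, identical whichever of the three
two-path roles is summed — a consequence of each partial two-path having
exactly one source, one middle and one sink. The undirected transitivity
is computed from structural motif counts ($3 N_\triangle / (3 N_\triangle
+ N_{\text{open}})$ over the seven triangle-projection and six open
classes) and is tested to equal the standard transitivity of the
direction-collapsed graph computed independently by igraph.

## Null models and overabundance

`rewire_degree_preserving()` performs attempted double-edge swaps
$(a\!\to\!b, c\!\to\!d) \Rightarrow (a\!\to\!d, c\!\to\!b)$, rejecting
self-loops and duplicates; in- and out-degree sequences are preserved
exactly, reciprocal degree deliberately is not (an optional
`preserve_reciprocal` mode swaps single edges and reciprocal pairs in
separate pools, off by default). The attempt budget defaults to 100 times
the edge count — a standard mixing heuristic, configurable; a graph
admitting no legal swap (e.g. the 3-cycle) is returned unchanged with a
warning and a `degenerate` flag rather than looping forever.
`ensemble_metrics()` runs seeded replicates (`seed + i` per replicate) and
summarizes by mean and sample standard deviation; no parametric test is
implied. `overabundance()` compares each node's observed functional role
fingerprint with the null mean, optionally scaling the excess by total
degree so that high-degree hubs do not dominate the ranking; zero-degree
nodes report 0, never NaN. Reciprocal-edge-rich roles are expected to show
large excesses under the default null precisely because reciprocal degree
is not preserved — that is a feature of the comparison, not a bug.

## What the random-graph generator does and does not emulate

`random_digraph(n, p)` is the independent-edge model; with
`reciprocity = rho` it draws unordered pair states so the marginal edge
probability stays $p$ while a present edge is reciprocated with
probability $\rho$ (feasible iff $p(2 - \rho) \le 1$). This captures the
one second-order feature (reciprocity) that dominates triad statistics in
real directed networks, and nothing else: no degree heterogeneity,
community structure, or spatial wiring cost, all prominent in neuronal
connectomes. Passing tests on these graphs therefore certify the
*counting machinery* — exact oracle equivalence, conversion identities,
bounds — on dense and sparse regimes, not any biological claim.

## Problem sizes and tolerances

The test suite fixes its scales once: oracle equivalence on 50 digraphs
with $N = 25$, $p \in \{0.05, 0.2, 0.5\}$ (about 2300 triples each —
large enough to exercise every role family at all three densities);
empirical conversion from 100 graphs with $N = 15$, $p = 0.3$ (1500
fingerprint columns for a 30-unknown-per-row system); degree-preservation
asserted per replicate across 100 rewirings of a 200-node graph; bounds
checked across 180 graphs spanning $p = 0.05$ to $0.9$. All count
comparisons are exact integer identities; the only tolerances in the
package are $10^{-9}$ rounding guards when integer results pass through
floating-point linear algebra, and statistical 3-standard-error bands for
the generator's own calibration checks.

## Known limitations

* Computations are defined on binary adjacency only; weighted inputs are
  binarized with a warning (weighted "intensity" variants are out of
  scope).
* Four-node support covers class/orbit enumeration, not fingerprints or a
  shipped conversion matrix; `empirical_conversion()` is the intended
  route for users who need one.
* The brute-force counter is $O(N^3)$ and guarded at 2000 nodes; the fast
  path is dense $O(N^2)$ memory, adequate for connectome-scale networks
  (hundreds to a few thousand nodes) but not for web-scale graphs.
* Structural-flavor clustering coefficients (same formulas on structural
  counts) are exposed as an experimental variant; unlike the functional
  versions they are not bounded by 1 and have no literature-standard
  normalization.
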