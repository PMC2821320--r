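---
title: "Measuring genome assembly complexity from idealized short reads"
author: "asmcomplexity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring genome assembly complexity from idealized short reads}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(asmcomplexity)
```

## The model

`asmcomplexity` studies an idealized instance of the short-read assembly
problem: for a read length $k$, we assume we are given every length-$k$
substring of a genome $g$ together with its exact number of occurrences.
This abstracts away sequencing error, non-uniform coverage, and
reverse-complement orientation (all reads are taken forward-strand), and
isolates the one unavoidable obstacle to assembly: the repeat structure of
the genome at scale $k$.

The information in the $k$-mer multiset is captured exactly by a de Bruijn
multigraph: one node per distinct $(k-1)$-mer, and one edge instance per
$k$-mer occurrence, connecting the node of its $(k-1)$-prefix to the node
of its $(k-1)$-suffix. Parallel edges and self-loops are kept, with edge
multiplicities $a_{uv}$ stored as integer counts. Every genome consistent
with the read data corresponds to an Eulerian traversal: a circular
chromosome yields a balanced graph traversed by circuits, a linear one may
instead have a single imbalanced terminal pair $(s, t)$ traversed by
trails. Spelling a traversal concatenates node sequences with an overlap
of $k - 2$ symbols at every step.

Nodes are classified by their distinct neighbors: a *forward decision* has
more than one successor but a single predecessor, a *backward decision*
the mirror, a *full decision* both. Decision nodes are the only places a
traversal can go wrong; non-decision nodes are forced. (We deliberately
count distinct neighbor *nodes*, not edge instances: in a balanced graph
instance-counting would make in- and out-degree equal at every node, so no
half decisions could ever exist and half-decision splitting would be
vacuous. A node whose single successor is reached by two parallel edges is
not a decision: both exits spell the same sequence. After the final
node-to-edge conversion stage, differently labeled parallel edges do
represent distinct choices, so the structural postcondition there is read
on edge records instead.)

## Information-preserving simplification

Five transformations shrink the graph without changing the set of spelled
reconstructions:

1. **Path compression** merges $(u, v)$ whenever $v$ is the sole successor
   of $u$ and $u$ the sole predecessor of $v$ (parallel $u \to v$ edges are
   allowed and consumed). Whole non-branching chains are merged in one
   pass; a chain that closes on itself collapses to a single node whose
   wrap edge becomes a self-loop.
2. **Tree-like region collapse**: regions whose cycle-decomposition
   structure is a tree have a unique local traversal. Rather than building
   the cycle graph explicitly, leaves are collapsed recursively: a pendant
   node $v$ whose only neighbor is $u$ (with $u$ having exactly one
   external in- and out-edge) is absorbed as the forced excursions
   $u \to v \to u$, and self-loops at a node with single external in/out
   edges are absorbed likewise. The collapsed node spells its unique local
   Eulerian sub-tour with the $k-2$ overlap at every step — the only
   spelling that preserves the word set, which the test suite checks
   against exhaustive enumeration.
3. **Half-decision splitting** replaces a backward decision $v$ (predecessors
   $u_1 \ldots u_m$, single successor) by $m$ copies, each inheriting the
   matching in-multiplicity on both sides, then the mirror for forward
   decisions; newly enabled compressions run after each split and the
   process cascades ("unzips") while new half decisions appear. Backward
   decisions are processed before forward ones. A generous iteration cap
   guards against pathological cascades; every intermediate graph is
   already word-equivalent, so stopping early would be safe.
4. **Pigeonhole inference** (off by default): if the heaviest in-edge
   $u \to v$ (count $c_u$) and heaviest out-edge $v \to w$ (count $c_w$)
   satisfy $c_u > d^+(v) - c_w$ with $u \neq w$, then
   $f = c_u + c_w - d^+(v)$ traversals are forced through $u \to v \to w$
   and are rerouted through a dedicated copy of $v$. It is applied only at
   decision nodes and ships disabled because it tends to interact badly
   with the other transformations and enlarge final graphs.
5. **Non-decision-to-edge conversion** removes remaining 1-in/1-out nodes
   by replacing them with an edge labeled by their sequence, leaving either
   a single node or only decision nodes.

`maximal_compress()` applies them in a fixed order — compression, tree
collapse, compression, backward then forward splitting with compressions,
conversion — and reports per-stage edge counts with reductions relative to
the previous stage plus the total relative to the post-compression
baseline.

In graphs of linear genomes, any merge whose justification is "every visit
to $u$ exits to $v$" is skipped when it touches a trail terminal: the
trail start is visited once without being entered, the end once without
being exited, and merging across them corrupts the spelled word. This
costs at most a couple of merges per graph.

## Counting reconstructions

For an Eulerian graph and a terminal node $t$ (forced by the degree
imbalance, otherwise arbitrary — the implementation picks the lowest node
id), let $r_u = d^+(u)$, except $r_t = d^+(t) + 1$, and let $L$ be the
matrix with $r_u - a_{uu}$ on the diagonal and $-a_{uv}$ elsewhere. The
number of distinct words spelled by traversals ending with $t$ is

$$
W(G, t) \;=\; \det L_{\bar t\bar t} \cdot \prod_u (r_u - 1)! \;\Big/\; \prod_{(u,v)} a_{uv}!,
$$

where $L_{\bar t\bar t}$ deletes row and column $t$. The determinant is the
number of spanning arborescences toward $t$ (matrix–tree), the factorial
product extends it to Eulerian trails (BEST theorem), and the division by
$\prod a_{uv}!$ collapses orderings of parallel edges, which spell the same
word. Dropping that division yields the trail count with distinguishable
parallel edges — on the classic toy string `sababababab` at $k = 5$, a
three-node graph with $3!\,3! = 36$ trails that all spell the single
consistent word. Both counts are validated against an exhaustive
backtracking oracle on every small test graph.

For a circular genome, cyclically equivalent rotations should be counted
once: the number of distinct circular reconstructions is $W(G,t)/d^+(t)$,
which is independent of $t$. The correction fails only for *periodic*
graphs — those traversable as a $c$-fold repetition of a closed subtour
($c > 1$), e.g. `ATATAT` at $k = 3$. `detect_periodicity()` returns `"no"`
whenever the gcd of edge multiplicities is 1 (in particular when any
sequence of length $\ge k-1$ is unique in the genome), decides small
graphs exhaustively, and reports `"possibly"` otherwise; `count_circular()`
refuses periodic graphs and asserts divisibility by $d^+(t)$ rather than
rounding.

Counting is performed on graphs simplified by path compression and tree
collapse only. Those stages keep node sequences distinct (every merged
node retains a distinct $(k-1)$-mer prefix), which the word-counting
theorem needs; splitting duplicates node sequences and conversion
introduces labeled edges, so counting happens before them.

### Numerical choices

Reconstruction counts grow astronomically (hundreds of bits), and no
arbitrary-precision integer package is available to this package, so exact
mode uses a small internal big-integer module (sign + base-$10^7$ digit
vectors). The determinant is computed exactly by Chinese remaindering:
modular Gaussian eliminations over primes just below $2^{26}$ (so products
stay exact in doubles), with the prime count set by the Hadamard bound,
recombined with only big-by-small multiplications — big-by-big division is
never needed, because the factorial divisions proceed factor by small
factor and every prefix of an exact division chain stays exact. `log2`
mode instead uses base R's `determinant(..., logarithm = TRUE)` plus
`lgamma`, and agrees with exact mode to $10^{-9}$ relative error wherever
both run; exact mode refuses graphs beyond 2000 nodes (configurable) where
log scale is the sensible output anyway.

## Idealized contigs and N50

Each edge of the maximally compressed graph represents an unambiguous
stretch: one contig is emitted per edge *instance* (an edge of multiplicity
$m$ yields $m$ identical contigs), with length
$\mathrm{len}(u) + \mathrm{len}(u,v) - 2(k-2)$ for labeled edges and
$\mathrm{len}(u) - (k-2)$ for unlabeled ones, so every $k-2$ overlap is
counted exactly once. Under this per-instance reading — and only under it —
contig lengths sum exactly to the circular chromosome length, which the
suite asserts for every synthetic genome and every tested $k$. For linear
genomes the sum falls short by $k - 1$ by construction; linear N50 values
carry that caveat rather than an adjustment. N50 is the largest realized
length $m$ such that contigs of length $\ge m$ cover at least half the
genome; the relative N50 divides by genome length to compare chromosomes
of different sizes.

## Gene reconstructibility

A gene is reconstructible when its whole coding interval lies inside the
region covered by the unambiguous walk from its start codon. The walk runs
on a graph simplified by path compression and tree collapse only (so nodes
still map cleanly onto genome positions), anchored via node occurrence
positions, and traces the gene's true genomic path: entering a node with
more than one predecessor *pollutes* the walk, and the walk terminates at
the first node with more than one successor entered after that — a full
decision counts as both at once. The terminating node's own sequence is
still included in the covered region: the ambiguity is about which branch
follows it, not about its own content. Pure forward decisions before any
pollution do not stop the walk.

Two interpretation points were genuinely open and are resolved as follows.
First, when the start base lies in the $k-2$ overlap of two adjacent tour
slots, the slot extending furthest in the walking direction is chosen
(deterministic, and it maximizes the honest walk). Second, reverse-strand
genes: the graph is forward-strand only, and walking *forward* from a minus
gene's coding start (its rightmost base) could never cover the gene, so
minus genes are walked right-to-left with the decision roles mirrored —
exactly the forward walk of the edge-reversed graph, and the faithful
reading of "from start codon to stop codon" for that strand. No
stop-to-start rescue walk is attempted for genes that fail.

Summaries report the reconstructible fraction and, over non-reconstructible
genes whose description does not say "hypothetical", case-insensitive
substring tallies of mobile-element keywords (`transpos`, `insertion
sequence`, `integrase`, `phage`), since mobile genetic elements are the
dominant cause of non-reconstructible genes.

## The synthetic-genome generator

`simulate_genome()` produces the controlled ground truth for all of the
above: a circular genome over ACGT with planted repeat families (exact
copies, interspersed or tandem) in a random background that is
rejection-sampled until every duplicated `unique_k`-mer lies wholly inside
a planted repeat region — so the planted repeats are the only source of
ambiguity at the target $k$. Placement keeps a `unique_k` gap between
blocks and avoids wrapping the origin; generation is deterministic given
the mandatory seed, and a manifest records every planted position.

What it emulates: the interspersed/tandem repeat families (insertion
sequences, rRNA operons, prophages) that dominate real prokaryotic
assembly ambiguity, at exact-copy fidelity. What it does not: diverged
repeat copies, strand asymmetry, sequencing error, coverage variation, or
plasmids. Passing tests therefore demonstrate correctness of the
combinatorics on exact-repeat genomes, not performance on noisy data —
which is precisely the idealization the method is about.

Test problem sizes were chosen once to keep the whole suite fast while
still exercising every regime: oracle-equivalence checks use 100 seeded
circular genomes of length 6–14 (a circular genome of length $L$ has
exactly $L$ edge instances, and the exhaustive oracle is capped at 14 by
design), over both two- and four-letter alphabets since small alphabets
force dense repeat structure; conservation and structural postconditions
use 0.8–1.5 kb genomes with planted 55–80 bp families at
$k \in \{15, 25, 35, 50\}$; count monotonicity uses a 400 bp genome at
$k \in \{4, 6, 8, 10\}$, where exact counts span from $2^{400+}$ down
to 1.

The exhaustive oracle itself enumerates every Eulerian trail (or circuit
from a fixed start) by backtracking with parallel instances weighted in,
spells each per the overlap rule, and reports the trail count, the
distinct word set, and — for balanced graphs — the set of canonical
rotations of the underlying circular words. Canonical rotations are the
right comparison currency across simplification, because a merged graph's
linear spellings start at coarser units while representing the same
circular genome.

## Known limitations

* Forward strand only; no reverse-complement canonicalization (matching
  the idealization, but real read sets need it).
* Exact counting assumes distinct node sequences; it is intentionally not
  offered on split/converted graphs.
* `detect_periodicity()` can return `"possibly"` on large graphs whose
  edge-multiplicity gcd exceeds 1, in which case `count_circular()` warns
  rather than answering definitively.
* The pigeonhole inference is implemented and oracle-validated but
  excluded from the default pipeline, mirroring its poor interaction with
  the other transformations.
* Linear-genome support exists throughout but with conservative guards at
  trail terminals; the primary, fully invariant-checked case is circular.
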