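# asmcomplexity

How hard is a genome to assemble from reads of length *k*? `asmcomplexity`
answers the question in its cleanest form: assume perfect, error-free,
forward-strand reads covering every length-*k* substring, with known
multiplicities. Under that idealization the read data is exactly a de
Bruijn multigraph — one node per (k−1)-mer, one edge instance per k-mer
occurrence — and every genome consistent with the reads is an Eulerian
traversal of it. Whatever ambiguity remains is caused by the genome's
repeat structure alone, so the numbers this package computes are *upper
bounds* on what any assembler could achieve with reads of that length:
a yardstick for evaluating real assemblers, aimed at people studying
assembly algorithms or the repeat structure of (mostly prokaryotic)
genomes.

The package provides:

* **Graph construction** (`build_kmer_graph`) for circular or linear
  genomes, with parallel edges and self-loops kept as multiplicities
  `a_uv`, and decision-node classification (`classify_node`).
* **Information-preserving simplification** (`maximal_compress` and the
  individual stages `path_compress`, `collapse_trees`,
  `split_half_decisions`, `convert_nondecision_to_edges`, plus the
  off-by-default `infer_pigeonhole_paths`): shrinks the graph to a single
  node or a core of decision nodes without changing the set of spellable
  genomes, and reports per-stage edge reductions.
* **Exact reconstruction counting** (`count_words`, `count_circular`,
  `count_eulerian_trails`): for terminal node *t*, with `r_u = d+(u)`
  except `r_t = d+(t) + 1`, and `L` the matrix with `r_u − a_uu` on the
  diagonal and `−a_uv` off it,

  ```
  W(G, t) = det(L minor at t) · Π_u (r_u − 1)!  /  Π_(u,v) a_uv!
  ```

  counts distinct words ending with *t* (matrix-tree × BEST theorem,
  corrected for parallel edges); dividing by `d+(t)` counts cyclically
  distinct circular reconstructions, with periodic graphs detected and
  refused. Exact arithmetic is arbitrary-precision; `log2` mode handles
  counts in the 2^900 range.
* **Idealized contigs and N50** (`extract_contigs`, `n50`,
  `contig_report`): one contig per edge instance of the compressed graph,
  with lengths that provably sum to the chromosome length.
* **Gene reconstructibility** (`classify_genes`, `is_reconstructible`):
  walks each annotated gene forward from its start codon through the
  compressed graph until a backward-then-forward decision pair, and asks
  whether the full coding interval fits in the unambiguous region.
* **Synthetic data and an oracle** (`simulate_genome`, `enumerate_words`):
  seeded circular genomes with planted repeat families whose background is
  rejection-sampled repeat-free, and an exhaustive Eulerian enumeration
  oracle that validates every counting result and transformation on small
  graphs.
* **I/O**: FASTA (Biostrings), GenBank `.ptt` protein tables, optional
  GFF3 (rtracklayer), GFA 1.0 graph export/import, TSV reports, and a thin
  CLI (`exec/asmcomplexity`) with subcommands `build`, `simplify`,
  `count`, `contigs`, `genes`, `simulate`, `report`.

## Worked example

The classic toy string `sababababab` at k = 5 compresses the whole
problem into three nodes:

```r
library(asmcomplexity)
g  <- genome("sababababab", topology = "linear", alphabet = c("s", "a", "b"))
kg <- build_kmer_graph(g, k = 5)
kg
#> <kmer_graph> k=5, linear: 3 nodes, 3 edge records (7 instances)
#>   trail terminals: s=n000003 t=n000001
count_eulerian_trails(kg)
#> [1] 36
count_words(kg)
#> <word_count> words ending at n000001: 1 (log2 = 0.000, trail)
```

The seven 5-mers give nodes `SABA`, `ABAB`, `BABA` with edges
`SABA→ABAB ×1`, `ABAB→BABA ×3`, `BABA→ABAB ×3`. There are 3!·3! = 36
Eulerian trails because the parallel edges can be traversed in any order —
but all 36 spell the same word, so the read set determines the genome
uniquely: `count_words` returns exactly 1.

On a synthetic 1.5 kb circular chromosome with an 80 bp repeat planted in
three copies:

```r
sim <- simulate_genome(sim_spec(1500,
         list(list(length = 80, copies = 3, type = "interspersed")),
         unique_k = 15, seed = 11))
assembly_complexity_report(sim$genome, c(15, 25, 50))
#>    k nodes_final edges_final percent_edge_reduction log2_reconstructions ...
#> 1 15           1           3                     50                    1
#> 2 25           1           3                     50                    1
#> 3 50           1           3                     50                    1
#>   n50 relative_n50 contig_count
#>   930           62            3
```

At every read length shorter than the repeat, the graph compresses to a
single decision point with three self-edges: `log2_reconstructions = 1`
means 2 distinct circular genomes are consistent with the reads (the two
orderings of the segments between repeat copies), the best achievable
assembly is 3 contigs, and the relative N50 is 62% of the chromosome.
Reads longer than the 80 bp repeat would resolve it completely.

## Scope

Forward-strand, error-free, known-multiplicity reads only: no
reverse-complement modeling, no coverage or sequencing-error simulation,
no paired-end modeling (long reads are the conservative proxy). See the
methods vignette (`vignettes/assembly-complexity.Rmd`) for the model,
parameter choices, and limitations.
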