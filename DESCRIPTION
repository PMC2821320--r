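Package: asmcomplexity
Title: Assembly Complexity of Genomes from Idealized Short Reads
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Measures how hard a genome is to assemble from idealized,
    error-free reads of length k. Builds the de Bruijn multigraph of a
    circular or linear genome, applies information-preserving graph
    simplifications (path compression, collapse of tree-like regions,
    half-decision splitting, conversion of non-decision nodes to labeled
    edges), counts the exact number of genome reconstructions consistent
    with the k-mer multiset using an Eulerian-circuit counting theorem
    adapted for parallel edges, derives idealized contigs and N50
    statistics, and classifies annotated genes as reconstructible or not
    from a local walk around their start codon. Includes a seeded
    synthetic-genome generator with planted repeat families and an
    exhaustive Eulerian enumeration oracle for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    rtracklayer,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
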