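# Whole-pipeline convenience report across read lengths.

#' Assembly-complexity report for a genome across read lengths
#'
#' For each k: builds the de Bruijn graph, records the simplification
#' statistics, counts reconstructions (log2 scale; cyclically corrected for
#' circular genomes unless the graph is periodic), extracts idealized
#' contigs and the (relative) N50, and, when annotations are supplied, the
#' fraction of reconstructible genes.
#'
#' @param genome A [genome()].
#' @param ks Integer vector of read lengths.
#' @param genes Optional gene annotation `data.frame`.
#' @return A `data.frame` with one row per k: `k`, `nodes_final`,
#'   `edges_final`, `percent_edge_reduction`, `log2_reconstructions`,
#'   `unique_reconstruction`, `n50`, `relative_n50`, `contig_count`,
#'   `percent_genes_reconstructible`.
#' @export
assembly_complexity_report <- function(genome, ks, genes = NULL) {
  rows <- lapply(ks, function(k) {
    raw <- build_kmer_graph(genome, k)
    mc <- maximal_compress(raw)
    cnt <- tryCatch(count_reconstructions(genome, k, mode = "log2"),
                    error = function(e) NULL)
    log2c <- if (is.null(cnt)) NA_real_ else cnt$log2_count
    contigs <- extract_contigs(mc$graph, k)
    rep_n50 <- n50(contigs$length, genome$length)
    gene_frac <- NA_real_
    if (!is.null(genes) && nrow(genes) > 0L) {
      gene_frac <- classify_genes(genome, genes, k)$summary$fraction_reconstructible
    }
    data.frame(
      k = k,
      nodes_final = nrow(mc$graph$nodes),
      edges_final = mc$stats$edges_after_conversion,
      percent_edge_reduction = mc$stats$percent_total,
      log2_reconstructions = log2c,
      unique_reconstruction = !is.na(log2c) && abs(log2c) < 1e-9,
      n50 = rep_n50$n50,
      relative_n50 = rep_n50$relative_n50,
      contig_count = rep_n50$contig_count,
      percent_genes_reconstructible = gene_frac,
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
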