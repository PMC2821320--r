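# Idealized contigs and N50 from a maximally compressed graph.

#' Extract idealized contigs from a simplified graph
#'
#' One contig is created per edge INSTANCE (an edge of multiplicity m yields
#' m identical contigs): this is the reading under which the sum of contig
#' lengths equals the chromosome length exactly, because adjacent node and
#' edge sequences overlap by k - 2 symbols and every overlap is then counted
#' once. The contig of an edge u -> v is the sequence of u, concatenated
#' with the spelled edge label when present; lengths are
#' length(u) + length(label) - 2(k - 2) for labeled edges and
#' length(u) - (k - 2) for unlabeled ones.
#'
#' @param graph A `kmer_graph`, typically the graph of
#'   [maximal_compress()] (labeled edges exist only after the conversion
#'   stage).
#' @param k Read length; must match `graph$k`.
#' @param with_sequence Also emit the contig sequences.
#' @return A `data.frame`: `contig_id`, `from`, `to`, `instance`, `length`
#'   and optionally `sequence`.
#' @export
extract_contigs <- function(graph, k = graph$k, with_sequence = FALSE) {
  if (k != graph$k) {
    stop(sprintf("k = %d inconsistent with graph built at k = %d", k, graph$k))
  }
  k <- as.integer(k)
  e <- graph$edges
  if (nrow(e) == 0L) {
    out <- data.frame(contig_id = character(), from = character(),
                      to = character(), instance = integer(),
                      length = integer(), stringsAsFactors = FALSE)
    if (with_sequence) out$sequence <- character()
    return(out)
  }
  ov <- k - 2L
  seqs <- stats::setNames(graph$nodes$seq, graph$nodes$id)
  rows <- list()
  for (i in seq_len(nrow(e))) {
    u <- e$from[[i]]; v <- e$to[[i]]; m <- e$mult[[i]]; lab <- e$label[[i]]
    len <- if (!is.na(lab)) nchar(seqs[[u]]) + nchar(lab) - 2L * ov
           else nchar(seqs[[u]]) - ov
    stopifnot(len >= 1L)
    row <- data.frame(
      contig_id = sprintf("%s_%s_%d", u, v, seq_len(m)),
      from = u, to = v, instance = seq_len(m), length = len,
      stringsAsFactors = FALSE)
    if (with_sequence) {
      row$sequence <- if (!is.na(lab)) seq_merge(seqs[[u]], lab, ov)
                      else seqs[[u]]
    }
    rows[[length(rows) + 1L]] <- row
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' N50 and relative N50 of a contig length set
#'
#' N50 is the largest length m in the contig length multiset such that
#' contigs of length >= m cover at least 50% of the genome; the relative
#' N50 divides it by the genome length (in percent), making chromosomes of
#' different sizes comparable.
#'
#' @param contig_lengths Positive integer vector.
#' @param genome_length Genome length in symbols.
#' @return An `n50_report` list: `n50`, `relative_n50`, `contig_count`,
#'   `genome_length`.
#' @export
n50 <- function(contig_lengths, genome_length) {
  if (length(contig_lengths) == 0L) stop("empty contig length list")
  stopifnot(all(contig_lengths >= 1L), genome_length >= max(contig_lengths))
  cand <- sort(unique(contig_lengths), decreasing = TRUE)
  n50_val <- NA_integer_
  for (m in cand) {
    if (sum(contig_lengths[contig_lengths >= m]) >= genome_length / 2) {
      n50_val <- m
      break
    }
  }
  if (is.na(n50_val)) {
    stop("contigs cover less than half the genome; N50 undefined")
  }
  structure(list(n50 = n50_val,
                 relative_n50 = 100 * n50_val / genome_length,
                 contig_count = length(contig_lengths),
                 genome_length = genome_length),
            class = "n50_report")
}

#' @export
print.n50_report <- function(x, ...) {
  cat(sprintf("<n50_report> N50 = %d (%.2f%% of %d bp, %d contigs)\n",
              x$n50, x$relative_n50, x$genome_length, x$contig_count))
  invisible(x)
}

#' Idealized contig/N50 report for a genome at read length k
#'
#' Runs [maximal_compress()] and [extract_contigs()] and summarizes with
#' [n50()]. For circular genomes the contig lengths sum exactly to the
#' genome length; for linear genomes the sum is short by k - 1 by
#' construction and the relative N50 carries that caveat.
#'
#' @param genome A [genome()].
#' @param k Read length.
#' @return An `n50_report`.
#' @export
contig_report <- function(genome, k) {
  mc <- maximal_compress(build_kmer_graph(genome, k))
  contigs <- extract_contigs(mc$graph, k)
  n50(contigs$length, genome$length)
}
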