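#' Genome sequence with explicit topology
#'
#' Container for a single chromosome (or toy test string). The sequence is
#' stored uppercased; the topology is always explicit because circular
#' genomes wrap k-mers across the origin while linear genomes do not.
#'
#' @param sequence Single character string of symbols.
#' @param id Identifier (FASTA header word).
#' @param topology `"circular"` or `"linear"`.
#' @param alphabet Character vector of admitted single-character symbols,
#'   or `NULL` to admit any symbol. Default is the DNA alphabet.
#' @return An object of class `genome`: a list with fields `id`, `seq`,
#'   `topology`, `length`.
#' @examples
#' g <- genome("acgtacgt", id = "toy", topology = "circular")
#' g$length
#' @export
genome <- function(sequence, id = "genome", topology = c("circular", "linear"),
                   alphabet = c("A", "C", "G", "T")) {
  topology <- match.arg(topology)
  stopifnot(is.character(sequence), length(sequence) == 1L)
  seq <- toupper(sequence)
  if (nchar(seq) < 1L) {
    stop("genome sequence must have length >= 1")
  }
  if (!is.null(alphabet)) {
    alphabet <- toupper(alphabet)
    sym <- strsplit(seq, "", fixed = TRUE)[[1L]]
    bad <- which(!(sym %in% alphabet))
    if (length(bad) > 0L) {
      stop(sprintf("symbol '%s' at position %d of '%s' is outside the alphabet {%s}",
                   sym[bad[1L]], bad[1L], id, paste(alphabet, collapse = ",")))
    }
  }
  structure(
    list(id = as.character(id), seq = seq, topology = topology,
         length = nchar(seq)),
    class = "genome"
  )
}

#' @export
print.genome <- function(x, ...) {
  cat(sprintf("<genome> %s: %d bp, %s\n", x$id, x$length, x$topology))
  invisible(x)
}

#' @export
as.character.genome <- function(x, ...) x$seq

# Circular-aware substring: 0-based start, length n, wrapping the origin.
genome_subseq <- function(g, start0, n) {
  L <- g$length
  if (g$topology == "linear") {
    stopifnot(start0 >= 0L, start0 + n <= L)
    return(substr(g$seq, start0 + 1L, start0 + n))
  }
  start0 <- start0 %% L
  if (start0 + n <= L) {
    substr(g$seq, start0 + 1L, start0 + n)
  } else {
    ext <- strrep(g$seq, ceiling((start0 + n) / L))
    substr(ext, start0 + 1L, start0 + n)
  }
}

#' Annotated gene coordinates
#'
#' External formats (.ptt, GFF3) are 1-based inclusive; this constructor
#' keeps that convention and flags genes whose interval wraps the circular
#' origin (`end < start`). All internal graph coordinates are 0-based
#' half-open; conversion happens at the point of use.
#'
#' @param gene_id Identifier.
#' @param start,end 1-based inclusive coordinates.
#' @param strand `"+"` or `"-"`.
#' @param product Free-text functional description.
#' @return A one-row `data.frame` with class `gene_annotation` rows:
#'   columns `gene_id`, `start`, `end`, `strand`, `product`, `wraps`.
#' @export
gene_annotation <- function(gene_id, start, end, strand = "+", product = "") {
  stopifnot(start >= 1L)
  data.frame(
    gene_id = as.character(gene_id),
    start = as.integer(start),
    end = as.integer(end),
    strand = as.character(strand),
    product = as.character(product),
    wraps = end < start,
    stringsAsFactors = FALSE
  )
}
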