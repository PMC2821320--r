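# Brute-force Eulerian enumeration oracle.
#
# Exponential by design and capped at a small number of edge instances: it
# exists to validate the polynomial-time counting formula and the
# word-preservation of every graph transformation, not for production use.

canonical_rotation <- function(s) {
  n <- nchar(s)
  if (n <= 1L) return(s)
  doubled <- paste0(s, s)
  rots <- substring(doubled, seq_len(n), seq_len(n) + n - 1L)
  min(rots)
}

#' Exhaustively enumerate Eulerian trails/circuits and their spelled words
#'
#' Enumerates every Eulerian trail (imbalanced graphs, from s to t) or every
#' Eulerian circuit from a fixed start node (balanced graphs), treating
#' parallel edge instances as distinguishable for the trail count. Each
#' traversal is spelled with the k - 2 overlap rule (the last node is also
#' output when it is entered for the last time), and the distinct spelled
#' words are collected. For balanced graphs the cyclically distinct
#' reconstructions are also reported (canonical rotations of the first N
#' symbols of each word, N being the genome length).
#'
#' @param graph A `kmer_graph` (labeled edges are supported).
#' @param start Start node id for balanced graphs (default: lowest id).
#' @param max_edges Refuse graphs with more edge instances than this.
#' @return A list: `trails` (count with distinguishable parallel edges),
#'   `distinct_words`, `distinct_count`, `cyclic_words` (balanced graphs
#'   only), `node_tours`, `mode`, `start`, `end`.
#' @export
enumerate_words <- function(graph, start = NULL, max_edges = 14L) {
  E <- edge_count(graph)
  if (E == 0L) stop("graph has no edges")
  if (E > max_edges) {
    stop(sprintf("graph has %d edge instances > cap %d: too large for exhaustive enumeration",
                 E, max_edges))
  }
  bal <- kg_balance(graph)
  if (bal$balanced) {
    if (is.null(start)) start <- sort(graph$nodes$id, method = "radix")[[1L]]
    end <- start
    mode <- "circuit"
  } else {
    if (!is.null(start) && !identical(start, bal$s)) {
      stop(sprintf("trail graphs must start at s = '%s'", bal$s))
    }
    start <- bal$s
    end <- bal$t
    mode <- "trail"
  }
  e <- graph$edges
  ov <- graph$k - 2L
  seqs <- stats::setNames(graph$nodes$seq, graph$nodes$id)
  out_idx <- split(seq_len(nrow(e)), e$from)

  acc <- new.env(parent = emptyenv())
  acc$words <- new.env(parent = emptyenv())
  acc$tours <- list()

  rec <- function(cur, rem, used, parts, tour) {
    if (used == E) {
      if (cur == end) {
        word <- paste(parts, collapse = "")
        assign(word, TRUE, envir = acc$words)
        acc$tours[[length(acc$tours) + 1L]] <- tour
        return(1)
      }
      return(0)
    }
    total <- 0
    for (i in out_idx[[cur]] %||% integer(0L)) {
      m <- rem[[i]]
      if (m == 0L) next
      rem[[i]] <- m - 1L
      v <- e$to[[i]]
      piece <- if (!is.na(e$label[[i]])) {
        paste0(seq_suffix(e$label[[i]], ov), seq_suffix(seqs[[v]], ov))
      } else {
        seq_suffix(seqs[[v]], ov)
      }
      total <- total + m * rec(v, rem, used + 1L, c(parts, piece), c(tour, v))
      rem[[i]] <- m
    }
    total
  }

  trails <- rec(start, e$mult, 0L, seqs[[start]], start)
  words <- sort(ls(acc$words))
  cyc <- NULL
  if (mode == "circuit" && length(words) > 0L) {
    n_genome <- nchar(words[[1L]]) - nchar(seqs[[end]])
    cyc <- sort(unique(vapply(words, function(w)
      canonical_rotation(substr(w, 1L, n_genome)), character(1L),
      USE.NAMES = FALSE)))
  }
  list(trails = trails, distinct_words = words,
       distinct_count = length(words), cyclic_words = cyc,
       node_tours = acc$tours, mode = mode, start = start, end = end)
}
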