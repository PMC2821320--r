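# de Bruijn multigraph machinery.
#
# Nodes represent (k-1)-mers (or, after simplification, longer forced
# stretches); edges carry integer multiplicities a_uv, so parallel edges are
# stored as counts rather than as individual objects. Edge records may in
# addition carry a spelled label (populated only by the non-decision-node to
# edge conversion); records with the same endpoints but different labels are
# kept as separate rows because their traversals spell different sequences.

kg_new <- function(k, topology, nodes, edges, terminals = NULL,
                   next_id = NULL, occ = NULL) {
  if (is.null(next_id)) next_id <- nrow(nodes) + 1L
  structure(
    list(k = as.integer(k), topology = topology, nodes = nodes,
         edges = edges, terminals = terminals, next_id = as.integer(next_id),
         occ = occ),
    class = "kmer_graph"
  )
}

kg_empty_edges <- function() {
  data.frame(from = character(), to = character(), mult = integer(),
             label = character(), stringsAsFactors = FALSE)
}

# overlap-merge two spelled sequences sharing ov symbols
seq_merge <- function(a, b, ov) {
  stopifnot(nchar(b) >= ov)
  paste0(a, substr(b, ov + 1L, nchar(b)))
}

seq_suffix <- function(s, ov) substr(s, ov + 1L, nchar(s))

kg_node_seq <- function(g, id) g$nodes$seq[match(id, g$nodes$id)]

#' Total number of edge instances in a graph
#'
#' Sums multiplicities over all edge records, i.e. counts parallel edge
#' instances individually. For an unsimplified graph of a circular genome
#' this equals the genome length.
#'
#' @param graph A `kmer_graph`.
#' @return Integer edge-instance count.
#' @export
edge_count <- function(graph) {
  if (nrow(graph$edges) == 0L) return(0L)
  sum(graph$edges$mult)
}

# out-/in-degrees counting edge instances, named by node id
kg_dplus <- function(g) {
  d <- stats::setNames(rep(0L, nrow(g$nodes)), g$nodes$id)
  if (nrow(g$edges) > 0L) {
    s <- tapply(g$edges$mult, g$edges$from, sum)
    d[names(s)] <- as.integer(s)
  }
  d
}

kg_dminus <- function(g) {
  d <- stats::setNames(rep(0L, nrow(g$nodes)), g$nodes$id)
  if (nrow(g$edges) > 0L) {
    s <- tapply(g$edges$mult, g$edges$to, sum)
    d[names(s)] <- as.integer(s)
  }
  d
}

# distinct successor / predecessor node ids
kg_succ <- function(g, u) unique(g$edges$to[g$edges$from == u])
kg_pred <- function(g, u) unique(g$edges$from[g$edges$to == u])

kg_has_node <- function(g, u) u %in% g$nodes$id

kg_fresh_id <- function(g) sprintf("n%06d", g$next_id)

# aggregate parallel records with identical (from, to, label)
kg_dedup_edges <- function(edges) {
  if (nrow(edges) <= 1L) return(edges)
  key <- paste(edges$from, edges$to, ifelse(is.na(edges$label), "", edges$label),
               sep = "\r")
  if (!anyDuplicated(key)) return(edges)
  m <- tapply(edges$mult, key, sum)
  first <- !duplicated(key)
  out <- edges[first, , drop = FALSE]
  out$mult <- as.integer(m[paste(out$from, out$to,
                                 ifelse(is.na(out$label), "", out$label),
                                 sep = "\r")])
  rownames(out) <- NULL
  out
}

# check Eulerian balance; returns list(balanced, s, t) or errors
kg_balance <- function(g) {
  dp <- kg_dplus(g)
  dm <- kg_dminus(g)
  diff <- dp - dm
  s <- names(diff)[diff == 1L]
  t <- names(diff)[diff == -1L]
  other <- names(diff)[abs(diff) > 1L]
  if (length(other) > 0L || length(s) != length(t) || length(s) > 1L) {
    stop("graph violates Eulerian balance: more than one imbalanced (s, t) pair")
  }
  if (length(s) == 1L) list(balanced = FALSE, s = s, t = t)
  else list(balanced = TRUE, s = NULL, t = NULL)
}

#' Build the de Bruijn multigraph of a genome
#'
#' Nodes are the distinct (k-1)-mers of the genome; there is one edge
#' instance per k-mer occurrence, connecting the node of its (k-1)-prefix to
#' the node of its (k-1)-suffix. Parallel edges and self-loops are allowed
#' and stored as integer multiplicities. Circular genomes wrap k-mers across
#' the origin, so their graphs are Eulerian-balanced; linear genomes are
#' balanced or have a single imbalanced terminal pair (s, t), recorded in
#' the `terminals` field.
#'
#' Node ids are assigned by lexicographic rank of the node sequence at
#' construction, so graphs are reproducible across runs.
#'
#' @param genome A [genome()].
#' @param k Read length, integer >= 2.
#' @return A `kmer_graph` object.
#' @examples
#' g <- genome("sababababab", topology = "linear", alphabet = c("s","a","b"))
#' kg <- build_kmer_graph(g, k = 5)
#' nrow(kg$nodes)  # 3
#' @export
build_kmer_graph <- function(genome, k) {
  stopifnot(inherits(genome, "genome"))
  k <- as.integer(k)
  if (k < 2L) stop("k must be >= 2")
  L <- genome$length
  if (genome$topology == "linear" && L < k) {
    stop(sprintf("linear genome of length %d is shorter than k = %d", L, k))
  }
  if (genome$topology == "circular" && L < k - 1L) {
    stop(sprintf("circular genome of length %d is shorter than k - 1 = %d",
                 L, k - 1L))
  }
  if (genome$topology == "circular") {
    ext <- genome_subseq(genome, 0L, L + k - 1L)
    starts <- seq_len(L)
  } else {
    ext <- genome$seq
    starts <- seq_len(L - k + 1L)
  }
  kmers <- substring(ext, starts, starts + k - 1L)
  pref <- substr(kmers, 1L, k - 1L)
  suff <- substr(kmers, 2L, k)
  node_seqs <- sort(unique(c(pref, suff)), method = "radix")
  ids <- sprintf("n%06d", seq_along(node_seqs))
  nodes <- data.frame(id = ids, seq = node_seqs, stringsAsFactors = FALSE)
  from <- ids[match(pref, node_seqs)]
  to <- ids[match(suff, node_seqs)]
  key <- paste(from, to, sep = "\r")
  first <- !duplicated(key)
  mult <- as.integer(table(key)[key[first]])
  edges <- data.frame(from = from[first], to = to[first], mult = mult,
                      label = NA_character_, stringsAsFactors = FALSE)
  edges <- edges[order(edges$from, edges$to, method = "radix"), , drop = FALSE]
  rownames(edges) <- NULL
  g <- kg_new(k, genome$topology, nodes, edges,
              next_id = length(ids) + 1L)
  bal <- kg_balance(g)
  if (!bal$balanced) g$terminals <- c(s = bal$s, t = bal$t)
  g
}

#' Classify a node as decision or non-decision
#'
#' Decision status is determined by counts of distinct predecessor and
#' successor nodes (a self-loop makes a node its own predecessor and
#' successor): `forward_decision` nodes have more than one successor but at
#' most one predecessor, `backward_decision` the mirror, `full_decision`
#' both, and `non_decision` neither. Decision nodes are the sources of
#' ambiguity when reconstructing a genome by an Eulerian traversal.
#'
#' @param graph A `kmer_graph`.
#' @param u Node id.
#' @return One of `"non_decision"`, `"forward_decision"`,
#'   `"backward_decision"`, `"full_decision"`.
#' @export
classify_node <- function(graph, u) {
  if (!kg_has_node(graph, u)) stop(sprintf("unknown node id '%s'", u))
  ns <- length(kg_succ(graph, u))
  np <- length(kg_pred(graph, u))
  if (ns > 1L && np > 1L) "full_decision"
  else if (ns > 1L) "forward_decision"
  else if (np > 1L) "backward_decision"
  else "non_decision"
}

#' Fill node occurrence lists from the source genome
#'
#' Records, for every node, all 0-based start positions of its sequence in
#' the genome (occurrences wrap across the origin for circular genomes).
#' Needed by the gene reconstructibility walk, which must anchor graph nodes
#' back onto genome coordinates.
#'
#' @param graph A `kmer_graph` built (and possibly simplified) from `genome`.
#' @param genome The source [genome()].
#' @return The graph with its `occ` field populated (named list of integer
#'   vectors).
#' @export
locate_occurrences <- function(graph, genome) {
  stopifnot(inherits(graph, "kmer_graph"), inherits(genome, "genome"))
  L <- genome$length
  occ <- stats::setNames(vector("list", nrow(graph$nodes)), graph$nodes$id)
  for (n_len in sort(unique(nchar(graph$nodes$seq)))) {
    idx <- which(nchar(graph$nodes$seq) == n_len)
    if (genome$topology == "circular") {
      ext <- genome_subseq(genome, 0L, L + n_len - 1L)
      starts <- seq_len(L)
    } else {
      if (n_len > L) {
        stop(sprintf("node sequence longer than linear genome (%d > %d)",
                     n_len, L))
      }
      ext <- genome$seq
      starts <- seq_len(L - n_len + 1L)
    }
    subs <- substring(ext, starts, starts + n_len - 1L)
    pos <- split(starts - 1L, subs)
    for (i in idx) {
      hits <- pos[[graph$nodes$seq[[i]]]]
      if (is.null(hits)) {
        stop(sprintf("node '%s' sequence absent from genome '%s': graph/genome mismatch",
                     graph$nodes$id[[i]], genome$id))
      }
      occ[[graph$nodes$id[[i]]]] <- as.integer(hits)
    }
  }
  graph$occ <- occ
  graph
}

#' @export
print.kmer_graph <- function(x, ...) {
  cat(sprintf("<kmer_graph> k=%d, %s: %d nodes, %d edge records (%d instances)\n",
              x$k, x$topology, nrow(x$nodes), nrow(x$edges), edge_count(x)))
  if (!is.null(x$terminals)) {
    cat(sprintf("  trail terminals: s=%s t=%s\n",
                x$terminals[["s"]], x$terminals[["t"]]))
  }
  invisible(x)
}
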