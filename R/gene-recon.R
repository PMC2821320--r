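# Gene reconstructibility from a tree-collapsed de Bruijn graph.
#
# A gene is reconstructible when its whole coding interval lies inside the
# region covered by the unambiguous walk from its start codon: walking
# forward through the graph, nodes with more than one predecessor "pollute"
# the walk, and once a node with more than one successor is reached after
# such a pollution the true branch can no longer be determined locally; a
# full decision node counts as both at once. The walk traces the gene's
# true genomic path, anchored through node occurrence positions.

#' Prepare the graph used for gene reconstructibility testing
#'
#' Path compression and tree-like-region collapse only (no half-decision
#' splitting and no node-to-edge conversion, which would duplicate node
#' sequences or remove the nodes the walk needs), then node occurrences are
#' located on the genome.
#'
#' @param genome A [genome()].
#' @param k Read length.
#' @return A `kmer_graph` with occurrences filled.
#' @export
prepare_recon_graph <- function(genome, k) {
  g <- build_kmer_graph(genome, k)
  g <- path_compress(g)
  g <- collapse_trees(g)
  g <- path_compress(g)
  locate_occurrences(g, genome)
}

# tiling maps: which node occupies the tour slot starting (or, for the
# leftward walk, ending) at each genome position
kg_tiling <- function(graph, genome) {
  L <- genome$length
  ov <- graph$k - 2L
  by_start <- rep(NA_integer_, L)
  by_right <- rep(NA_integer_, L)
  for (i in seq_len(nrow(graph$nodes))) {
    id <- graph$nodes$id[[i]]
    len <- nchar(graph$nodes$seq[[i]])
    for (o in graph$occ[[id]]) {
      sp <- (o %% L) + 1L
      rp <- ((o + len - ov) %% L) + 1L
      if (!is.na(by_start[[sp]]) && by_start[[sp]] != i) {
        stop("inconsistent tiling: two nodes claim the same tour slot")
      }
      by_start[[sp]] <- i
      by_right[[rp]] <- i
    }
  }
  list(by_start = by_start, by_right = by_right)
}

# nodes covering 0-based position p (circularly), with coverage extents
kg_covering_nodes <- function(graph, genome, p) {
  L <- genome$length
  hits <- list()
  for (i in seq_len(nrow(graph$nodes))) {
    id <- graph$nodes$id[[i]]
    len <- nchar(graph$nodes$seq[[i]])
    for (o in graph$occ[[id]]) {
      off <- (p - o) %% L
      if (off < len) {
        hits[[length(hits) + 1L]] <- list(node = id, occ = o, offset = off,
                                          downstream = len - off)
      }
    }
  }
  hits
}

#' Locate the node representing a gene's coding start
#'
#' Returns the graph node whose occurrence interval contains the base of
#' the gene's coding start (position `start` for + genes, `end` for -
#' genes), with the offset of that base inside the node sequence. When
#' several nodes cover the base (adjacent tour slots overlap by k - 2), the
#' node whose slot extends furthest in the walking direction is chosen:
#' downstream for + genes, upstream for - genes.
#'
#' @param graph A `kmer_graph` with occurrences (see
#'   [prepare_recon_graph()]).
#' @param genome The source [genome()].
#' @param gene One row of a gene annotation table.
#' @return A list: `node`, `occurrence` (0-based start), `offset`.
#' @export
locate_start_node <- function(graph, genome, gene) {
  if (is.null(graph$occ)) stop("graph occurrences not located")
  p <- if (gene$strand == "-") gene$end - 1L else gene$start - 1L
  hits <- kg_covering_nodes(graph, genome, p %% genome$length)
  if (length(hits) == 0L) {
    stop("position not covered by any node interval: graph/genome mismatch")
  }
  score <- vapply(hits, function(h) {
    if (gene$strand == "-") h$offset else h$downstream
  }, numeric(1L))
  best <- hits[[which.max(score)]]
  list(node = best$node, occurrence = best$occ, offset = best$offset)
}

#' Test whether a gene is reconstructible
#'
#' Walks the gene's true genomic path from the node containing its coding
#' start. For + genes the walk moves rightward; a node with more than one
#' distinct predecessor marks the walk as polluted, and the walk terminates
#' on the first node with more than one distinct successor entered after
#' that (the terminating node's own sequence is still included in the
#' covered region). For - genes the walk moves leftward with the decision
#' roles mirrored (the forward walk of the edge-reversed graph). The gene is
#' reconstructible iff its full coding interval lies inside the covered
#' region.
#'
#' @param graph A `kmer_graph` from [prepare_recon_graph()].
#' @param genome The source [genome()].
#' @param gene One row of a gene annotation table.
#' @return A list: `reconstructible` (flag), `reason`, and `outcome` (walk
#'   details: `start_node`, `path`, `covered`, `passed_backward`,
#'   `terminated`).
#' @export
is_reconstructible <- function(graph, genome, gene) {
  L <- genome$length
  ov <- graph$k - 2L
  a <- gene$start - 1L
  b <- gene$end - 1L
  if (b < a) b <- b + L  # wraps the circular origin
  if (b - a + 1L > L) stop("gene interval longer than the genome")

  start <- tryCatch(locate_start_node(graph, genome, gene),
                    error = function(e) NULL)
  if (is.null(start)) {
    return(list(reconstructible = FALSE, reason = "start not locatable",
                outcome = NULL))
  }
  tiles <- kg_tiling(graph, genome)
  idx_of <- stats::setNames(seq_len(nrow(graph$nodes)), graph$nodes$id)
  lens <- stats::setNames(nchar(graph$nodes$seq), graph$nodes$id)
  nsucc <- stats::setNames(integer(nrow(graph$nodes)), graph$nodes$id)
  npred <- stats::setNames(integer(nrow(graph$nodes)), graph$nodes$id)
  pairs <- unique(graph$edges[, c("from", "to")])
  ts <- table(pairs$from); nsucc[names(ts)] <- as.integer(ts)
  tp <- table(pairs$to); npred[names(tp)] <- as.integer(tp)

  leftward <- identical(gene$strand, "-")
  pollute_deg <- if (leftward) nsucc else npred
  stop_deg <- if (leftward) npred else nsucc

  cur <- start$node
  # unroll the start occurrence so that the walk coordinate is anchored at
  # the strand-appropriate gene end
  p <- if (leftward) b else a
  o <- p - start$offset
  covered_lo <- o
  covered_hi <- o + lens[[cur]]
  polluted <- FALSE
  terminated <- FALSE
  path <- cur
  E <- edge_count(graph)
  steps <- 0L

  visit <- function(v) {
    if (pollute_deg[[v]] > 1L) polluted <<- TRUE
    if (polluted && stop_deg[[v]] > 1L) terminated <<- TRUE
  }
  visit(cur)

  need_more <- function() {
    if (leftward) a < covered_lo else b >= covered_hi
  }

  while (!terminated && need_more() && steps <= E + 2L) {
    steps <- steps + 1L
    if (leftward) {
      prev_i <- tiles$by_right[[(covered_lo %% L) + 1L]]
      if (is.na(prev_i)) stop("tiling gap during leftward walk")
      nxt <- graph$nodes$id[[prev_i]]
      covered_lo <- covered_lo - (lens[[nxt]] - ov)
    } else {
      nxt_start <- covered_hi - ov
      nxt_i <- tiles$by_start[[(nxt_start %% L) + 1L]]
      if (is.na(nxt_i)) stop("tiling gap during rightward walk")
      nxt <- graph$nodes$id[[nxt_i]]
      covered_hi <- nxt_start + lens[[nxt]]
    }
    path <- c(path, nxt)
    cur <- nxt
    visit(cur)
  }

  ok <- if (leftward) a >= covered_lo else b < covered_hi
  reason <- if (ok) "interval within unambiguous walk"
            else sprintf("walk terminated at decision node %s before covering the gene",
                         cur)
  list(reconstructible = ok, reason = reason,
       outcome = list(start_node = start$node, path = path,
                      covered = c(covered_lo, covered_hi - 1L),
                      passed_backward = polluted, terminated = terminated))
}

#' Summarize per-gene reconstructibility
#'
#' Computes the reconstructible fraction and tallies, over the
#' non-reconstructible genes whose product description does not mention
#' "hypothetical", how many descriptions contain each keyword
#' (case-insensitive substring match). The default keywords target mobile
#' genetic elements, the dominant cause of non-reconstructible genes.
#'
#' @param flags Logical vector, one per gene.
#' @param annotations Gene annotation `data.frame` (same order).
#' @param keywords Character vector of keywords.
#' @return A `gene_recon_report` list: `fraction_reconstructible` (percent,
#'   `NA` for an empty annotation set), `n_genes`, `n_reconstructible`,
#'   `keyword_tallies`.
#' @export
summarize_reconstructibility <- function(flags, annotations,
                                         keywords = c("transpos",
                                                      "insertion sequence",
                                                      "integrase", "phage")) {
  stopifnot(length(flags) == nrow(annotations))
  n <- length(flags)
  frac <- if (n == 0L) NA_real_ else 100 * sum(flags) / n
  bad <- annotations[!flags, , drop = FALSE]
  bad <- bad[!grepl("hypothetical", bad$product, ignore.case = TRUE), ,
             drop = FALSE]
  tallies <- vapply(keywords, function(kw) {
    sum(grepl(tolower(kw), tolower(bad$product), fixed = TRUE))
  }, integer(1L))
  structure(list(fraction_reconstructible = frac, n_genes = n,
                 n_reconstructible = sum(flags),
                 keyword_tallies = tallies),
            class = "gene_recon_report")
}

#' @export
print.gene_recon_report <- function(x, ...) {
  cat(sprintf("<gene_recon_report> %d/%d genes reconstructible (%.2f%%)\n",
              x$n_reconstructible, x$n_genes, x$fraction_reconstructible))
  if (any(x$keyword_tallies > 0L)) {
    cat("  keyword tallies among non-reconstructible, non-hypothetical genes:\n")
    for (kw in names(x$keyword_tallies)) {
      cat(sprintf("    %-20s %d\n", kw, x$keyword_tallies[[kw]]))
    }
  }
  invisible(x)
}

#' Classify every annotated gene of a genome
#'
#' Builds the reconstructibility graph once ([prepare_recon_graph()]) and
#' walks each gene.
#'
#' @param genome A [genome()].
#' @param genes Gene annotation `data.frame` (from [read_ptt()],
#'   [read_genes_gff3()] or [simulate_genome()]).
#' @param k Read length.
#' @param keywords Passed to [summarize_reconstructibility()].
#' @return A list: `per_gene` (`data.frame` with `gene_id`, `start`, `end`,
#'   `strand`, `reconstructible`, `reason`), `summary` (a
#'   `gene_recon_report`).
#' @export
classify_genes <- function(genome, genes, k,
                           keywords = c("transpos", "insertion sequence",
                                        "integrase", "phage")) {
  graph <- prepare_recon_graph(genome, k)
  res <- lapply(seq_len(nrow(genes)), function(i) {
    is_reconstructible(graph, genome, genes[i, , drop = FALSE])
  })
  flags <- vapply(res, `[[`, logical(1L), "reconstructible")
  per_gene <- data.frame(
    gene_id = genes$gene_id, start = genes$start, end = genes$end,
    strand = genes$strand,
    reconstructible = flags,
    reason = vapply(res, `[[`, character(1L), "reason"),
    stringsAsFactors = FALSE)
  list(per_gene = per_gene,
       summary = summarize_reconstructibility(flags, genes, keywords))
}
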