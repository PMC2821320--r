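# Information-preserving graph simplifications.
#
# Every transformation here preserves the exact set of genome
# reconstructions spelled by the graph (checked exhaustively against the
# enumeration oracle in the test suite). In linear-genome graphs,
# transformations whose correctness argument requires "every visit to u
# exits to v" (or the mirror) skip candidates involving a trail terminal:
# the trail start is visited once without being entered and the trail end
# once without being exited.

kg_guard_ids <- function(g) {
  if (g$topology == "linear" && !is.null(g$terminals)) unname(g$terminals)
  else character(0L)
}

kg_check_unlabeled <- function(g, what) {
  if (nrow(g$edges) > 0L && any(!is.na(g$edges$label))) {
    stop(sprintf("%s cannot be applied to graphs with labeled edges", what))
  }
}

kg_sort_edges <- function(e) {
  e <- e[order(e$from, e$to, method = "radix"), , drop = FALSE]
  rownames(e) <- NULL
  e
}

# assert the k-2 overlap invariant when merging spelled sequences
kg_overlap_merge <- function(a, b, k) {
  ov <- k - 2L
  if (ov > 0L && substr(a, nchar(a) - ov + 1L, nchar(a)) != substr(b, 1L, ov)) {
    stop("internal error: spelled sequences do not overlap by k - 2 symbols")
  }
  seq_merge(a, b, ov)
}

# distinct successor/predecessor tables for all nodes at once
kg_adjacency_sets <- function(g) {
  e <- g$edges
  pairs <- unique(e[, c("from", "to")])
  list(succ = split(pairs$to, pairs$from), pred = split(pairs$from, pairs$to))
}

#' Path compression
#'
#' Collapses adjacent node pairs (u, v) where v is the only successor of u
#' and u is the only predecessor of v (parallel u->v edges are allowed and
#' are consumed by the merge). Whole non-branching chains are merged in one
#' pass and the process is iterated to a fixpoint. A chain closing on itself
#' (a simple cycle of forced pairs) collapses to a single node whose
#' wrap-around edge becomes a self-loop. The set of genome reconstructions
#' spelled by the graph is unchanged.
#'
#' @param graph A `kmer_graph`.
#' @return The compressed `kmer_graph`.
#' @export
path_compress <- function(graph) {
  kg_check_unlabeled(graph, "path compression")
  g <- graph
  guard <- kg_guard_ids(g)
  repeat {
    if (nrow(g$edges) == 0L || nrow(g$nodes) <= 1L) break
    adj <- kg_adjacency_sets(g)
    froms <- names(adj$succ)
    cand_from <- froms[vapply(adj$succ, length, 1L) == 1L]
    nxt <- vapply(adj$succ[cand_from], `[`, character(1L), 1L)
    ok <- cand_from != nxt &
      vapply(nxt, function(v) length(adj$pred[[v]]) == 1L, logical(1L)) &
      !(cand_from %in% guard) & !(nxt %in% guard)
    next_of <- nxt[ok]
    names(next_of) <- cand_from[ok]
    if (length(next_of) == 0L) break

    # assemble maximal chains of the functional graph next_of (indegree <= 1)
    is_target <- names(next_of) %in% unname(next_of)
    heads <- names(next_of)[!is_target]
    visited <- character(0L)
    chains <- list()
    walk_chain <- function(h) {
      chain <- h
      cur <- h
      wrap <- FALSE
      while (!is.na(next_of[cur] %||% NA_character_)) {
        nx <- unname(next_of[[cur]])
        if (nx == chain[[1L]]) { wrap <- TRUE; break }
        if (nx %in% chain) break  # re-entry mid-chain cannot happen; safety
        if (!(nx %in% names(next_of)) ) { chain <- c(chain, nx); break }
        chain <- c(chain, nx)
        cur <- nx
      }
      list(ids = chain, wrap = wrap)
    }
    for (h in heads) {
      ch <- walk_chain(h)
      chains[[length(chains) + 1L]] <- ch
      visited <- c(visited, ch$ids)
    }
    # remaining candidate nodes lie on pure cycles
    left <- setdiff(names(next_of), visited)
    while (length(left) > 0L) {
      h <- sort(left, method = "radix")[[1L]]
      ch <- walk_chain(h)
      chains[[length(chains) + 1L]] <- ch
      visited <- c(visited, ch$ids)
      left <- setdiff(left, ch$ids)
    }

    e <- g$edges
    seqs <- stats::setNames(g$nodes$seq, g$nodes$id)
    drop_nodes <- character(0L)
    ov <- g$k - 2L
    for (ch in chains) {
      ids <- ch$ids
      if (length(ids) < 2L) next
      head_id <- ids[[1L]]
      tail_id <- ids[[length(ids)]]
      merged <- paste0(seqs[[head_id]],
                       paste(vapply(seqs[ids[-1L]], seq_suffix, character(1L),
                                    ov = ov),
                             collapse = ""))
      # verify overlaps pairwise (cheap, catches wiring faults)
      for (i in seq_len(length(ids) - 1L)) {
        kg_overlap_merge(seqs[[ids[[i]]]], seqs[[ids[[i + 1L]]]], g$k)
      }
      seqs[[head_id]] <- merged
      internal <- paste(ids[-length(ids)], ids[-1L], sep = "\r")
      key <- paste(e$from, e$to, sep = "\r")
      e <- e[!(key %in% internal), , drop = FALSE]
      if (ch$wrap) {
        wsel <- e$from == tail_id & e$to == head_id
        e$from[wsel] <- head_id
        e$to[wsel] <- head_id
      } else {
        e$from[e$from == tail_id] <- head_id
      }
      drop_nodes <- c(drop_nodes, ids[-1L])
    }
    g$nodes <- g$nodes[!(g$nodes$id %in% drop_nodes), , drop = FALSE]
    g$nodes$seq <- unname(seqs[g$nodes$id])
    rownames(g$nodes) <- NULL
    g$edges <- kg_sort_edges(kg_dedup_edges(e))
    g$occ <- NULL
  }
  g
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0L) b else a

#' Collapse tree-like regions
#'
#' Regions whose cycle-decomposition structure is a tree admit a unique
#' local Eulerian traversal and can be replaced by a single node spelling
#' that traversal. Rather than constructing the cycle graph explicitly, the
#' tree-like regions are collapsed recursively from the leaves. Two leaf
#' shapes are recognized: (1) a pendant node v whose only predecessor and
#' only successor is u, where u has exactly one in-edge and one out-edge not
#' adjacent to v - the forced excursions u -> v -> u are absorbed into u;
#' (2) a node u with self-loops and exactly one non-self in-edge and one
#' non-self out-edge - the self-loop traversals are absorbed into u. After
#' each collapse, newly possible path compressions are performed. Words are
#' spelled with the k - 2 overlap at every step, so the reconstruction set
#' is unchanged.
#'
#' @param graph A `kmer_graph`.
#' @return The collapsed `kmer_graph`.
#' @export
collapse_trees <- function(graph) {
  kg_check_unlabeled(graph, "tree collapse")
  g <- path_compress(graph)
  guard <- kg_guard_ids(g)
  ov <- g$k - 2L
  repeat {
    if (nrow(g$edges) == 0L || nrow(g$nodes) <= 1L) break
    dp <- kg_dplus(g)
    dm <- kg_dminus(g)
    e <- g$edges
    self_mult <- stats::setNames(rep(0L, nrow(g$nodes)), g$nodes$id)
    sl <- e$from == e$to
    if (any(sl)) {
      sm <- tapply(e$mult[sl], e$from[sl], sum)
      self_mult[names(sm)] <- as.integer(sm)
    }
    adj <- kg_adjacency_sets(g)
    seqs <- stats::setNames(g$nodes$seq, g$nodes$id)

    # leaf rule 1: pendant two-node cycle u <-> v
    applied <- FALSE
    for (v in sort(g$nodes$id, method = "radix")) {
      if (v %in% guard) next
      pv <- adj$pred[[v]] %||% character(0L)
      sv <- adj$succ[[v]] %||% character(0L)
      if (length(pv) != 1L || length(sv) != 1L) next
      u <- pv[[1L]]
      if (sv[[1L]] != u || u == v || u %in% guard) next
      a_uv <- sum(e$mult[e$from == u & e$to == v])
      a_vu <- sum(e$mult[e$from == v & e$to == u])
      if (dm[[u]] - a_vu != 1L || dp[[u]] - a_uv != 1L) next
      stopifnot(a_uv == a_vu)
      exc <- paste0(seq_suffix(seqs[[v]], ov), seq_suffix(seqs[[u]], ov))
      kg_overlap_merge(seqs[[u]], seqs[[v]], g$k)
      kg_overlap_merge(seqs[[v]], seqs[[u]], g$k)
      seqs[[u]] <- paste0(seqs[[u]], strrep(exc, a_uv))
      e <- e[!((e$from == u & e$to == v) | (e$from == v & e$to == u)), ,
             drop = FALSE]
      g$nodes <- g$nodes[g$nodes$id != v, , drop = FALSE]
      g$nodes$seq <- unname(seqs[g$nodes$id])
      g$edges <- kg_sort_edges(e)
      applied <- TRUE
      break
    }
    if (applied) { g <- path_compress(g); next }

    # leaf rule 2: absorb self-loops at a node with single external in/out
    for (u in sort(g$nodes$id, method = "radix")) {
      s <- self_mult[[u]]
      if (s < 1L || u %in% guard) next
      if (dm[[u]] - s != 1L || dp[[u]] - s != 1L) next
      seqs[[u]] <- paste0(seqs[[u]], strrep(seq_suffix(seqs[[u]], ov), s))
      e <- e[!(e$from == u & e$to == u), , drop = FALSE]
      g$nodes$seq <- unname(seqs[g$nodes$id])
      g$edges <- kg_sort_edges(e)
      applied <- TRUE
      break
    }
    if (applied) { g <- path_compress(g); next }
    break
  }
  g$occ <- NULL
  g
}

# shared worker for forward/backward half-decision splitting
kg_split_pass <- function(g, side, max_iter) {
  guard <- kg_guard_ids(g)
  iter <- 0L
  repeat {
    g <- path_compress(g)
    if (nrow(g$nodes) <= 1L) break
    adj <- kg_adjacency_sets(g)
    e <- g$edges
    has_self <- unique(e$from[e$from == e$to])
    cand <- NULL
    for (v in sort(g$nodes$id, method = "radix")) {
      if (v %in% guard || v %in% has_self) next
      np <- length(adj$pred[[v]] %||% character(0L))
      ns <- length(adj$succ[[v]] %||% character(0L))
      hit <- if (side == "backward") np >= 2L && ns == 1L
             else np == 1L && ns >= 2L
      if (hit) { cand <- v; break }
    }
    if (is.null(cand)) break
    iter <- iter + 1L
    if (iter > max_iter) {
      warning("half-decision splitting stopped before fixpoint (iteration cap)")
      break
    }
    v <- cand
    seq_v <- kg_node_seq(g, v)
    if (side == "backward") {
      others <- sort(adj$pred[[v]], method = "radix")
      w <- adj$succ[[v]][[1L]]
    } else {
      others <- sort(adj$succ[[v]], method = "radix")
      w <- adj$pred[[v]][[1L]]
    }
    new_rows <- list()
    new_nodes <- list()
    for (x in others) {
      m <- if (side == "backward") sum(e$mult[e$from == x & e$to == v])
           else sum(e$mult[e$from == v & e$to == x])
      vid <- kg_fresh_id(g)
      g$next_id <- g$next_id + 1L
      new_nodes[[length(new_nodes) + 1L]] <-
        data.frame(id = vid, seq = seq_v, stringsAsFactors = FALSE)
      if (side == "backward") {
        new_rows[[length(new_rows) + 1L]] <- data.frame(
          from = c(x, vid), to = c(vid, w), mult = c(m, m),
          label = NA_character_, stringsAsFactors = FALSE)
      } else {
        new_rows[[length(new_rows) + 1L]] <- data.frame(
          from = c(w, vid), to = c(vid, x), mult = c(m, m),
          label = NA_character_, stringsAsFactors = FALSE)
      }
    }
    e <- e[e$from != v & e$to != v, , drop = FALSE]
    e <- rbind(e, do.call(rbind, new_rows))
    g$nodes <- rbind(g$nodes[g$nodes$id != v, , drop = FALSE],
                     do.call(rbind, new_nodes))
    rownames(g$nodes) <- NULL
    g$edges <- kg_sort_edges(kg_dedup_edges(e))
  }
  g
}

#' Split half-decision nodes
#'
#' A backward decision node v (several distinct predecessors, a single
#' successor) is replaced by one copy per predecessor; each copy inherits
#' the corresponding in-edge multiplicity on both sides, shifting the
#' decision toward the unique successor. Forward decision nodes are treated
#' by the mirror construction. All backward decisions are split first, then
#' all forward decisions; newly enabled path compressions are applied after
#' each split, and splitting cascades while new half decisions appear.
#' Nodes with self-loops are left untouched (a self-loop makes a node its
#' own predecessor and successor). The reconstruction set is unchanged.
#'
#' @param graph A `kmer_graph`.
#' @return The split-and-compressed `kmer_graph`.
#' @export
split_half_decisions <- function(graph) {
  kg_check_unlabeled(graph, "half-decision splitting")
  max_iter <- 200L + 10L * edge_count(graph)
  g <- kg_split_pass(graph, "backward", max_iter)
  g <- kg_split_pass(g, "forward", max_iter)
  path_compress(g)
}

#' Infer forced paths from edge multiplicities (pigeonhole rule)
#'
#' For a node v, let u -> v be the highest-multiplicity in-edge (count c_u)
#' and v -> w the highest-multiplicity out-edge (count c_w), with u != w.
#' If c_u > d+(v) - c_w, then at least f = c_u + c_w - d+(v) traversals of v
#' must enter from u and leave to w, so f traversals can be rerouted through
#' a dedicated copy of v, which path compression then merges into a spelled
#' u-v-w stretch. This inference is disabled by default in
#' [maximal_compress()] because it tends to interact badly with the other
#' simplifications and enlarge the final graphs.
#'
#' @param graph A `kmer_graph`.
#' @return The rewritten `kmer_graph`.
#' @export
infer_pigeonhole_paths <- function(graph) {
  kg_check_unlabeled(graph, "pigeonhole inference")
  g <- graph
  guard <- kg_guard_ids(g)
  max_iter <- 100L + edge_count(g)
  iter <- 0L
  repeat {
    dp <- kg_dplus(g)
    e <- g$edges
    applied <- FALSE
    for (v in sort(g$nodes$id, method = "radix")) {
      if (v %in% guard) next
      ins <- e[e$to == v & e$from != v, , drop = FALSE]
      outs <- e[e$from == v & e$to != v, , drop = FALSE]
      if (nrow(ins) == 0L || nrow(outs) == 0L) next
      # the inference is about pairing edges at decision nodes; applying it
      # to non-decision nodes would merely copy them forever
      if (length(unique(ins$from)) < 2L && length(unique(outs$to)) < 2L) next
      bi <- which.max(ins$mult)
      bo <- which.max(outs$mult)
      u <- ins$from[[bi]]; c_u <- ins$mult[[bi]]
      w <- outs$to[[bo]]; c_w <- outs$mult[[bo]]
      if (u == w) next
      f <- c_u + c_w - dp[[v]]
      if (f <= 0L) next
      pid <- kg_fresh_id(g)
      g$next_id <- g$next_id + 1L
      e$mult[e$from == u & e$to == v] <- c_u - f
      e$mult[e$from == v & e$to == w] <- c_w - f
      e <- e[e$mult > 0L, , drop = FALSE]
      e <- rbind(e, data.frame(from = c(u, pid), to = c(pid, w),
                               mult = c(f, f), label = NA_character_,
                               stringsAsFactors = FALSE))
      g$nodes <- rbind(g$nodes,
                       data.frame(id = pid, seq = kg_node_seq(g, v),
                                  stringsAsFactors = FALSE))
      # v may have lost all its traversals to the rerouted copy
      if (!(v %in% e$from) && !(v %in% e$to)) {
        g$nodes <- g$nodes[g$nodes$id != v, , drop = FALSE]
      }
      rownames(g$nodes) <- NULL
      g$edges <- kg_sort_edges(kg_dedup_edges(e))
      g <- path_compress(g)
      applied <- TRUE
      break
    }
    iter <- iter + 1L
    if (!applied || iter > max_iter) break
  }
  g
}

#' Convert remaining non-decision nodes to labeled edges
#'
#' A node v with exactly one predecessor u and one successor w that cannot
#' be path-compressed (because u and w are decision nodes) is removed and
#' replaced by an edge u -> w labeled with the sequence of v. After this
#' transformation the graph contains either a single node or only decision
#' nodes with both more than one predecessor and more than one successor.
#'
#' @param graph A `kmer_graph`.
#' @return A `kmer_graph`, possibly with labeled edge records.
#' @export
convert_nondecision_to_edges <- function(graph) {
  g <- if (nrow(graph$edges) > 0L && any(!is.na(graph$edges$label))) graph
       else path_compress(graph)
  guard <- kg_guard_ids(g)
  e <- g$edges
  # a node is convertible when a single in edge record feeds a single out
  # edge record (labeled parallel records are distinct reconstruction
  # choices, so they are counted individually)
  cands <- character(0L)
  for (v in sort(g$nodes$id, method = "radix")) {
    if (v %in% guard) next
    pin <- which(e$to == v)
    pout <- which(e$from == v)
    if (length(pin) == 1L && length(pout) == 1L &&
        e$from[[pin]] != v && e$to[[pout]] != v) {
      cands <- c(cands, v)
    }
  }
  for (v in cands) {
    pin <- e[e$to == v, , drop = FALSE]
    pout <- e[e$from == v, , drop = FALSE]
    stopifnot(nrow(pin) == 1L, nrow(pout) == 1L,
              is.na(pin$label), is.na(pout$label),
              pin$mult == pout$mult)
    e <- e[e$to != v & e$from != v, , drop = FALSE]
    e <- rbind(e, data.frame(from = pin$from, to = pout$to, mult = pin$mult,
                             label = kg_node_seq(g, v),
                             stringsAsFactors = FALSE))
  }
  g$nodes <- g$nodes[!(g$nodes$id %in% cands), , drop = FALSE]
  rownames(g$nodes) <- NULL
  g$edges <- kg_sort_edges(kg_dedup_edges(e))
  g$occ <- NULL
  g
}

#' Maximal compression pipeline
#'
#' Applies the transformations in a fixed order: path compression, collapse
#' of tree-like regions, another round of path compression, splitting of all
#' backward then all forward decision nodes with the newly possible
#' compressions, and finally conversion of non-decision nodes into labeled
#' edges. Pigeonhole inference can optionally be inserted before the
#' conversion stage, but is off by default (it tends to enlarge the final
#' graphs).
#'
#' @param graph A `kmer_graph` (typically fresh from [build_kmer_graph()]).
#' @param enable_pigeonhole Apply [infer_pigeonhole_paths()] as well.
#' @return A list with elements `graph` (the maximally compressed
#'   `kmer_graph`) and `stats` (a `reduction_stats` object; see
#'   [reduction_stats_table()]).
#' @export
maximal_compress <- function(graph, enable_pigeonhole = FALSE) {
  g1 <- path_compress(graph)
  e0 <- edge_count(g1)
  g2 <- collapse_trees(g1)
  e1 <- edge_count(g2)
  g3 <- split_half_decisions(g2)
  if (enable_pigeonhole) g3 <- infer_pigeonhole_paths(g3)
  e2 <- edge_count(g3)
  g4 <- convert_nondecision_to_edges(g3)
  e3 <- edge_count(g4)
  pct <- function(prev, now) if (prev == 0L) 0 else 100 * (1 - now / prev)
  stats <- structure(
    list(edges_initial = e0, edges_after_trees = e1, edges_after_split = e2,
         edges_after_conversion = e3,
         percent_trees = pct(e0, e1),
         percent_split = pct(e1, e2),
         percent_conversion = pct(e2, e3),
         percent_total = pct(e0, e3)),
    class = "reduction_stats"
  )
  list(graph = g4, stats = stats)
}

#' Reduction statistics as a table
#'
#' Per-stage edge-instance counts with percentage reductions relative to the
#' previous stage and the total reduction relative to the
#' post-path-compression baseline.
#'
#' @param stats A `reduction_stats` object from [maximal_compress()].
#' @return A `data.frame` with columns `stage`, `edges`, `percent_reduction`.
#' @export
reduction_stats_table <- function(stats) {
  data.frame(
    stage = c("path_compression", "collapse_trees", "split_half_decisions",
              "convert_to_edges", "total"),
    edges = c(stats$edges_initial, stats$edges_after_trees,
              stats$edges_after_split, stats$edges_after_conversion,
              stats$edges_after_conversion),
    percent_reduction = c(0, stats$percent_trees, stats$percent_split,
                          stats$percent_conversion, stats$percent_total),
    stringsAsFactors = FALSE
  )
}

#' @export
print.reduction_stats <- function(x, ...) {
  print(reduction_stats_table(x))
  invisible(x)
}
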