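# Exact and log-scale counting of genome reconstructions.
#
# The number of words consistent with an Eulerian de Bruijn multigraph and
# ending with a chosen node t is
#
#     W(G, t) = det(L with row and column t deleted)
#               * prod_u (r_u - 1)!  /  prod_{(u,v)} a_uv!
#
# where r_u = d+(u), except r_t = d+(t) + 1, and L has r_u - a_uu on the
# diagonal and -a_uv off-diagonal. The determinant factor is the number of
# spanning arborescences toward t (matrix-tree), the factorial product
# extends it to Eulerian trails ending at t (BEST theorem), and dividing by
# the parallel-edge factorials collapses edge orderings that spell the same
# word. Dropping the a_uv! division yields the trail count with
# distinguishable parallel edges. Both are validated exhaustively against
# the enumeration oracle in the test suite.

gcd2 <- function(a, b) if (b == 0L) a else gcd2(b, a %% b)

# weak connectivity over nodes incident to at least one edge
kg_connected <- function(g) {
  e <- g$edges
  if (nrow(e) == 0L) return(nrow(g$nodes) <= 1L)
  ids <- unique(c(e$from, e$to))
  nbr <- split(c(e$to, e$from), c(e$from, e$to))
  seen <- stats::setNames(rep(FALSE, length(ids)), ids)
  stack <- ids[[1L]]
  seen[[stack]] <- TRUE
  while (length(stack) > 0L) {
    cur <- stack[[length(stack)]]
    stack <- stack[-length(stack)]
    for (v in unique(nbr[[cur]])) {
      if (!seen[[v]]) { seen[[v]] <- TRUE; stack <- c(stack, v) }
    }
  }
  all(seen)
}

# ---- exact integer determinant by Chinese remaindering -------------------

det_primes_cache <- new.env(parent = emptyenv())

det_primes <- function(n_needed) {
  have <- det_primes_cache$primes
  if (!is.null(have) && length(have) >= n_needed) return(have[seq_len(n_needed)])
  is_prime <- function(x) {
    if (x %% 2 == 0) return(FALSE)
    d <- 3
    while (d * d <= x) {
      if (x %% d == 0) return(FALSE)
      d <- d + 2
    }
    TRUE
  }
  primes <- have %||% numeric(0L)
  cand <- if (length(primes) > 0L) primes[[length(primes)]] - 2 else 67108859
  while (length(primes) < n_needed) {
    if (is_prime(cand)) primes <- c(primes, cand)
    cand <- cand - 2
  }
  det_primes_cache$primes <- primes
  primes[seq_len(n_needed)]
}

det_mod_p <- function(m, p) {
  n <- nrow(m)
  if (n == 0L) return(1)
  a <- m %% p
  det <- 1
  for (i in seq_len(n)) {
    piv <- which(a[i:n, i] != 0)
    if (length(piv) == 0L) return(0)
    j <- i + piv[[1L]] - 1L
    if (j != i) {
      tmp <- a[i, ]; a[i, ] <- a[j, ]; a[j, ] <- tmp
      det <- (p - det) %% p
    }
    det <- (det * a[i, i]) %% p
    if (i < n) {
      inv <- pow_mod(a[i, i], p - 2, p)
      rows <- (i + 1L):n
      factors <- (a[rows, i] * inv) %% p
      nz <- which(factors != 0)
      if (length(nz) > 0L) {
        rows <- rows[nz]
        a[rows, ] <- (a[rows, , drop = FALSE] -
                        outer(factors[nz], a[i, ])) %% p
      }
    }
  }
  det
}

pow_mod <- function(b, e, p) {
  r <- 1
  b <- b %% p
  while (e > 0) {
    if (e %% 2 == 1) r <- (r * b) %% p
    b <- (b * b) %% p
    e <- e %/% 2
  }
  r
}

# exact determinant of a small-entry integer matrix, as a bignum
det_exact <- function(m) {
  n <- nrow(m)
  if (n == 0L) return(big_one())
  # Hadamard bound on log2 |det|
  row_norms <- sqrt(rowSums(m^2))
  bound <- sum(log2(pmax(row_norms, 1))) + 2
  n_primes <- max(2L, ceiling(bound / 25) + 1L)
  primes <- det_primes(n_primes)
  residues <- vapply(primes, function(p) det_mod_p(m, p), numeric(1L))
  x <- big_zero()
  M <- big_one()
  for (i in seq_along(primes)) {
    p <- primes[[i]]
    cur <- big_mod_small(x, p)
    mp <- big_mod_small(M, p)
    delta <- (residues[[i]] - cur) %% p
    v <- (delta * pow_mod(mp, p - 2, p)) %% p
    x <- big_add(x, big_mul_small(M, v))
    M <- big_mul_small(M, p)
  }
  # balanced residue: values above M/2 represent negatives
  twice <- big_mul_small(x, 2)
  if (big_cmp_mag(twice, M) > 0L) x <- big_sub(x, M)
  x
}

# ---- count matrix bundle -------------------------------------------------

#' Build the counting matrix L and the r vector for a terminal node
#'
#' If the graph is balanced, t may be chosen arbitrarily (auto mode picks
#' the lowest node id); otherwise t is forced to the unique node with
#' d+(t) = d-(t) - 1. r_u = d+(u) for all nodes except r_t = d+(t) + 1; L is
#' the n x n matrix with r_u - a_uu on the diagonal and -a_uv in entry
#' (u, v).
#'
#' @param graph A balanced or single-(s,t)-imbalanced `kmer_graph`.
#' @param t Node id, or `"auto"`.
#' @return A `count_matrix` list: `node_order`, `L`, `r`, `t`.
#' @export
build_count_matrix <- function(graph, t = "auto") {
  bal <- kg_balance(graph)
  if (!bal$balanced) {
    if (!identical(t, "auto") && !identical(t, bal$t)) {
      stop(sprintf("t is forced to '%s' by the degree imbalance; got '%s'",
                   bal$t, t))
    }
    t <- bal$t
  } else if (identical(t, "auto")) {
    t <- sort(graph$nodes$id, method = "radix")[[1L]]
  } else if (!kg_has_node(graph, t)) {
    stop(sprintf("unknown node id '%s'", t))
  }
  ids <- sort(graph$nodes$id, method = "radix")
  n <- length(ids)
  A <- matrix(0, n, n, dimnames = list(ids, ids))
  e <- graph$edges
  if (nrow(e) > 0L) {
    for (i in seq_len(nrow(e))) {
      A[e$from[[i]], e$to[[i]]] <- A[e$from[[i]], e$to[[i]]] + e$mult[[i]]
    }
  }
  r <- rowSums(A)
  r[[t]] <- r[[t]] + 1
  L <- diag(r, n) - A
  dimnames(L) <- list(ids, ids)
  structure(list(node_order = ids, L = L, r = r, t = t, A = A),
            class = "count_matrix")
}

# factorial bookkeeping shared by the two counters; returns bignum
big_apply_factorials <- function(x, r, divide_mults = NULL) {
  for (ru in r) {
    f <- 2
    while (f <= ru - 1) {
      x <- big_mul_small(x, f)
      f <- f + 1
    }
  }
  if (!is.null(divide_mults)) {
    for (m in divide_mults) {
      f <- 2
      while (f <= m) {
        d <- big_div_small(x, f)
        if (d$r != 0) stop("internal error: inexact division in word count")
        x <- d$q
        f <- f + 1
      }
    }
  }
  x
}

log2_word_count <- function(bundle, divide = TRUE, mults = NULL) {
  i <- match(bundle$t, bundle$node_order)
  minor <- bundle$L[-i, -i, drop = FALSE]
  ld <- if (nrow(minor) == 0L) {
    list(modulus = 0, sign = 1)
  } else {
    d <- determinant(minor, logarithm = TRUE)
    list(modulus = as.numeric(d$modulus), sign = d$sign)
  }
  if (ld$sign <= 0 && ld$modulus > -Inf) {
    # determinant of a reduced arborescence Laplacian is >= 0; a negative
    # sign can only be floating-point noise around zero
    return(-Inf)
  }
  out <- ld$modulus / log(2) + sum(lgamma(bundle$r)) / log(2)
  if (divide) out <- out - sum(lgamma(mults + 1)) / log(2)
  out
}

#' Count genome reconstructions consistent with a graph
#'
#' Computes the number of distinct words spelled by Eulerian trails (or
#' circuits) ending with node t. Exact mode returns an arbitrary-precision
#' integer; log2 mode returns only the base-2 logarithm (cheap for graphs
#' whose counts are astronomically large). Intended for graphs whose node
#' sequences are distinct, i.e. freshly built or simplified by path
#' compression / tree collapse (half-decision splitting duplicates node
#' sequences and node-to-edge conversion introduces labeled edges; counting
#' is performed before those stages).
#'
#' @param graph A `kmer_graph` satisfying the Eulerian balance invariant.
#' @param t Terminal node id or `"auto"` (see [build_count_matrix()]).
#' @param mode `"exact"` or `"log2"`.
#' @param max_exact_nodes Exact mode refuses above this size (use log2).
#' @return A `word_count` list: `exact` (bignum or NULL), `exact_str`,
#'   `log2_count`, `mode` (trail/circuit), `t`, `circular_corrected`,
#'   `periodic`.
#' @export
count_words <- function(graph, t = "auto", mode = c("exact", "log2"),
                        max_exact_nodes = 2000L) {
  mode <- match.arg(mode)
  if (nrow(graph$nodes) == 0L || edge_count(graph) == 0L) {
    stop("cannot count words of an empty graph")
  }
  if (!kg_connected(graph)) stop("graph is not connected")
  bundle <- build_count_matrix(graph, t)
  bal <- kg_balance(graph)
  walk_mode <- if (bal$balanced) "circuit" else "trail"
  mults <- graph$edges$mult
  if (mode == "exact" && nrow(graph$nodes) > max_exact_nodes) {
    stop(sprintf("graph has %d nodes > max_exact_nodes = %d; use mode = 'log2'",
                 nrow(graph$nodes), max_exact_nodes))
  }
  if (mode == "exact") {
    i <- match(bundle$t, bundle$node_order)
    minor <- bundle$L[-i, -i, drop = FALSE]
    w <- det_exact(minor)
    w <- big_apply_factorials(w, bundle$r, divide_mults = mults)
    structure(
      list(exact = w, exact_str = big_to_string(w), log2_count = big_log2(w),
           mode = walk_mode, t = bundle$t, circular_corrected = FALSE,
           periodic = NA_character_),
      class = "word_count")
  } else {
    structure(
      list(exact = NULL, exact_str = NA_character_,
           log2_count = log2_word_count(bundle, TRUE, mults),
           mode = walk_mode, t = bundle$t, circular_corrected = FALSE,
           periodic = NA_character_),
      class = "word_count")
  }
}

#' Count Eulerian trails with distinguishable parallel edges
#'
#' The trail count ending at t (for balanced graphs: circuits from a fixed
#' start t), treating each parallel edge instance as distinct. Always at
#' least the word count.
#'
#' @param graph A `kmer_graph`.
#' @param t Terminal node id or `"auto"`.
#' @return The exact count: a numeric if it fits double precision exactly,
#'   otherwise a decimal string.
#' @export
count_eulerian_trails <- function(graph, t = "auto") {
  if (nrow(graph$nodes) == 0L || edge_count(graph) == 0L) {
    stop("cannot count trails of an empty graph")
  }
  if (!kg_connected(graph)) stop("graph is not connected")
  bundle <- build_count_matrix(graph, t)
  i <- match(bundle$t, bundle$node_order)
  minor <- bundle$L[-i, -i, drop = FALSE]
  w <- det_exact(minor)
  w <- big_apply_factorials(w, bundle$r)
  if (big_log2(w) < 53) big_to_num(w) else big_to_string(w)
}

#' Detect periodic circular graphs
#'
#' A balanced graph is periodic if some Eulerian circuit is a c-fold
#' repetition (c > 1) of a closed subtour, in which case the cyclic word
#' count is not W(G, t) / d+(t). If the gcd of all edge multiplicities is 1
#' (in particular if any sequence of length >= k - 1 is unique in the
#' genome), the graph cannot be periodic. Small graphs are checked
#' exhaustively; otherwise `"possibly"` is returned.
#'
#' @param graph A `kmer_graph`.
#' @param max_edges Exhaustive-check bound (edge instances).
#' @return `"no"`, `"possibly"` or `"yes"`.
#' @export
detect_periodicity <- function(graph, max_edges = 14L) {
  bal <- kg_balance(graph)
  if (!bal$balanced) return("no")  # trail graphs are not circular
  if (edge_count(graph) == 0L) return("no")
  g <- Reduce(gcd2, graph$edges$mult)
  if (g == 1L) return("no")
  if (edge_count(graph) <= max_edges) {
    res <- enumerate_words(graph, max_edges = max_edges)
    for (tour in res$node_tours) {
      cyc <- tour[-length(tour)]
      n <- length(cyc)
      for (c in setdiff(which(n %% seq_len(n) == 0), 1L)) {
        period <- n / c
        if (c > 1L && all(cyc == rep(cyc[seq_len(period)], c))) return("yes")
      }
    }
    return("no")
  }
  "possibly"
}

#' Count cyclically distinct reconstructions of a circular genome
#'
#' For a balanced (circuit) graph of a non-periodic circular genome, the
#' number of distinct circular genome reconstructions is W(G, t) / d+(t),
#' independent of the choice of t. Divisibility by d+(t) is asserted, never
#' silently rounded; a periodic graph is refused.
#'
#' @param graph A balanced `kmer_graph` from a circular genome.
#' @param t Node id or `"auto"`.
#' @param mode `"exact"` or `"log2"`.
#' @return A `word_count` with `circular_corrected = TRUE`.
#' @export
count_circular <- function(graph, t = "auto", mode = c("exact", "log2")) {
  mode <- match.arg(mode)
  bal <- kg_balance(graph)
  if (!bal$balanced) stop("count_circular requires a balanced (circuit) graph")
  per <- detect_periodicity(graph)
  if (per == "yes") {
    stop("graph is periodic: cyclic word count is not W(G, t)/d+(t)")
  }
  if (per == "possibly") {
    warning("graph may be periodic; W(G, t)/d+(t) is only valid if it is not")
  }
  res <- count_words(graph, t, mode)
  dt <- kg_dplus(graph)[[res$t]]
  if (mode == "exact") {
    d <- big_div_small(res$exact, dt)
    if (d$r != 0) {
      stop(sprintf("W(G, t) = %s is not divisible by d+(t) = %d: periodicity or implementation fault",
                   res$exact_str, dt))
    }
    res$exact <- d$q
    res$exact_str <- big_to_string(d$q)
    res$log2_count <- big_log2(d$q)
  } else {
    res$log2_count <- res$log2_count - log2(dt)
  }
  res$circular_corrected <- TRUE
  res$periodic <- per
  res
}

#' Count reconstructions of a genome at read length k
#'
#' Convenience pipeline: builds the de Bruijn graph, shrinks it with path
#' compression and tree collapse (which preserve both the word set and the
#' distinctness of node sequences), then counts circular reconstructions
#' (circular genomes) or words ending at the forced/auto terminal (linear
#' genomes).
#'
#' @param genome A [genome()].
#' @param k Read length.
#' @param mode `"exact"` or `"log2"`.
#' @return A `word_count`.
#' @export
count_reconstructions <- function(genome, k, mode = c("exact", "log2")) {
  mode <- match.arg(mode)
  g <- collapse_trees(path_compress(build_kmer_graph(genome, k)))
  if (genome$topology == "circular") count_circular(g, mode = mode)
  else count_words(g, mode = mode)
}

#' @export
print.word_count <- function(x, ...) {
  lab <- if (x$circular_corrected) "cyclic reconstructions" else
    sprintf("words ending at %s", x$t)
  if (!is.null(x$exact)) {
    cat(sprintf("<word_count> %s: %s (log2 = %.3f, %s)\n",
                lab, x$exact_str, x$log2_count, x$mode))
  } else {
    cat(sprintf("<word_count> %s: log2 = %.3f (%s)\n",
                lab, x$log2_count, x$mode))
  }
  invisible(x)
}
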