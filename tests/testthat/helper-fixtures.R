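# Shared fixtures: all built programmatically, no data files.

toy_alphabet <- c("s", "a", "b")

sab_genome <- function() {
  genome("sababababab", id = "toy", topology = "linear",
         alphabet = toy_alphabet)
}

sab_graph <- function() build_kmer_graph(sab_genome(), 5)

node_by_seq <- function(g, s) g$nodes$id[match(s, g$nodes$seq)]

rnd_seq <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

rand_circular_genome <- function(n, alphabet = c("A", "C", "G", "T")) {
  genome(rnd_seq(n, alphabet), topology = "circular", alphabet = alphabet)
}

# words of a graph in a topology-appropriate comparable form: cyclic
# canonical rotations for balanced graphs, full spelled trails otherwise
comparable_words <- function(graph, max_edges = 25L) {
  res <- enumerate_words(graph, max_edges = max_edges)
  if (res$mode == "circuit") res$cyclic_words else res$distinct_words
}

# circular genome with two interleaved 2-copy repeat families
# (A R B S C R D S): the canonical structure with exactly 2 cyclic
# reconstructions (swapping B and D) whose graph keeps two full decision
# nodes after compression
interleaved_fixture <- function(seed = 21L, seg = 150L, rep_len = 40L) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  A <- rnd_seq(seg); B <- rnd_seq(seg)
  C <- rnd_seq(seg); D <- rnd_seq(seg)
  R <- rnd_seq(rep_len); S <- rnd_seq(rep_len)
  g <- genome(paste0(A, R, B, S, C, R, D, S), id = "interleaved",
              topology = "circular")
  list(genome = g, seg = seg, rep_len = rep_len,
       # 0-based starts of the planted copies
       r_starts = c(seg, 3L * seg + 2L * rep_len),
       s_starts = c(2L * seg + rep_len, 4L * seg + 3L * rep_len))
}
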