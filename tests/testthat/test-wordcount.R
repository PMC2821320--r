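# Counting reconstructions: matrix construction, exact/log2 counts,
# circular correction, periodicity.

test_that("the counting matrix matches the hand-derived toy values", {
  kg <- sab_graph()
  b <- build_count_matrix(kg)
  seqs <- stats::setNames(kg$nodes$seq, kg$nodes$id)
  ord <- seqs[b$node_order]
  expect_identical(b$t, node_by_seq(kg, "ABAB"))  # forced by the imbalance
  r <- stats::setNames(unname(b$r), ord)
  expect_identical(r[["SABA"]], 1)
  expect_identical(r[["ABAB"]], 4)
  expect_identical(r[["BABA"]], 3)
  L <- b$L
  dimnames(L) <- list(ord, ord)
  expect_identical(L[["SABA", "ABAB"]], -1)
  expect_identical(L[["ABAB", "BABA"]], -3)
  expect_identical(L[["BABA", "ABAB"]], -3)
  expect_identical(L[["ABAB", "ABAB"]], 4)
  expect_identical(L[["BABA", "BABA"]], 3)
  expect_identical(L[["SABA", "SABA"]], 1)
  # rows sum to r_u - d+(u): 0 everywhere except 1 at t
  rs <- rowSums(L)
  expect_identical(unname(rs[b$node_order == b$t]), 1)
  expect_true(all(rs[b$node_order != b$t] == 0))
  # an explicit t conflicting with the forced one is refused
  expect_error(build_count_matrix(kg, t = node_by_seq(kg, "SABA")), "forced")
})

test_that("a balanced single-node self-loop graph counts one word", {
  pc <- path_compress(build_kmer_graph(genome("ACGGTA", topology = "circular"), 3))
  b <- build_count_matrix(pc)
  expect_identical(unname(b$r), 2)
  expect_identical(unname(b$L[1, 1]), 1)
  expect_identical(count_words(pc)$exact_str, "1")
  expect_identical(count_circular(pc)$exact_str, "1")
})

test_that("graphs with more than one imbalanced pair are rejected", {
  nodes <- data.frame(id = sprintf("n%06d", 1:4),
                      seq = c("AB", "BC", "CD", "DE"),
                      stringsAsFactors = FALSE)
  edges <- data.frame(from = c("n000001", "n000003"),
                      to = c("n000002", "n000004"),
                      mult = c(1L, 1L), label = NA_character_,
                      stringsAsFactors = FALSE)
  g <- asmcomplexity:::kg_new(3L, "linear", nodes, edges)
  expect_error(build_count_matrix(g), "balance")
})

test_that("exact counts and trail counts match exhaustive enumeration", {
  set.seed(40)
  for (i in 1:30) {
    alpha <- if (i %% 2 == 0) c("A", "C") else c("A", "C", "G", "T")
    g <- rand_circular_genome(sample(6:12, 1), alpha)
    kg <- build_kmer_graph(g, 3)
    if (!asmcomplexity:::kg_connected(kg)) next
    or <- enumerate_words(kg)
    wc <- count_words(kg, t = or$start)
    expect_equal(asmcomplexity:::big_to_num(wc$exact), as.numeric(or$distinct_count))
    expect_equal(count_eulerian_trails(kg, t = or$start), or$trails)
    expect_gte(or$trails, or$distinct_count)
    # log2 mode agrees with the exact count
    expect_equal(count_words(kg, t = or$start, mode = "log2")$log2_count,
                 log2(or$distinct_count), tolerance = 1e-9)
  }
})

test_that("a simple directed cycle admits exactly one circuit from a fixed start", {
  g <- genome("ACGT", topology = "circular")
  kg <- build_kmer_graph(g, 3)
  expect_identical(count_eulerian_trails(kg), 1)
  expect_identical(count_circular(kg)$exact_str, "1")
})

test_that("cyclic counting divides by d+(t) and is invariant in t", {
  fix <- interleaved_fixture()
  pg <- collapse_trees(path_compress(build_kmer_graph(fix$genome, 15)))
  vals <- vapply(pg$nodes$id, function(t) count_circular(pg, t = t)$exact_str,
                 character(1L))
  expect_identical(unique(unname(vals)), "2")
  # cross-check against the oracle on a small interleaved analogue
  # (unique segments a, b, c, d; repeats TT and GG, each twice)
  small <- genome("acTTabGGcTTdGG", topology = "circular", alphabet = NULL)
  skg <- build_kmer_graph(small, 3)
  or <- enumerate_words(skg)
  cc <- tryCatch(count_circular(skg), warning = function(w) NULL)
  if (!is.null(cc)) {
    expect_equal(asmcomplexity:::big_to_num(cc$exact),
                     as.numeric(length(or$cyclic_words)))
  }
})

test_that("periodicity is detected and blocks the circular correction", {
  per <- build_kmer_graph(genome("ATATAT", topology = "circular"), 3)
  expect_identical(detect_periodicity(per), "yes")
  expect_error(count_circular(per), "periodic")

  uniq <- build_kmer_graph(genome("ACGGTA", topology = "circular"), 3)
  expect_identical(detect_periodicity(uniq), "no")  # degree-1 nodes exist

  # a doubled word too large for the exhaustive check is only "possibly"
  set.seed(42)
  unit <- rnd_seq(9)
  doubled <- build_kmer_graph(genome(strrep(unit, 2), topology = "circular"), 3)
  if (all(doubled$edges$mult %% 2 == 0)) {
    expect_identical(detect_periodicity(doubled), "possibly")
  }

  # trail graphs are never periodic
  expect_identical(detect_periodicity(sab_graph()), "no")
})

test_that("reconstruction counts are invariant under simplification", {
  set.seed(43)
  for (i in 1:10) {
    g <- rand_circular_genome(sample(8:13, 1), c("A", "C"))
    kg <- build_kmer_graph(g, 3)
    if (!asmcomplexity:::kg_connected(kg)) next
    if (detect_periodicity(kg) != "no") next
    w0 <- count_circular(kg)$exact_str
    w1 <- count_circular(collapse_trees(path_compress(kg)))$exact_str
    expect_identical(w1, w0)
  }
})

test_that("counts are non-increasing in read length", {
  spec <- sim_spec(400, list(list(length = 30, copies = 2,
                                  type = "interspersed")),
                   unique_k = 12, seed = 5)
  sim <- simulate_genome(spec)
  prev <- Inf
  for (k in c(4, 6, 8, 10)) {
    wc <- count_reconstructions(sim$genome, k, mode = "exact")
    expect_lte(wc$log2_count, prev + 1e-9)
    prev <- wc$log2_count
  }
})

test_that("empty and disconnected graphs are refused", {
  nodes <- data.frame(id = c("n000001", "n000002"), seq = c("AB", "CD"),
                      stringsAsFactors = FALSE)
  edges <- data.frame(from = c("n000001", "n000002"),
                      to = c("n000001", "n000002"),
                      mult = c(1L, 1L), label = NA_character_,
                      stringsAsFactors = FALSE)
  g <- asmcomplexity:::kg_new(3L, "circular", nodes, edges)
  expect_error(count_words(g), "not connected")
  expect_error(count_eulerian_trails(g), "not connected")
})
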