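# Graph transformations: each must preserve the reconstruction word set.

test_that("a simple cycle compresses to a single node with one self-loop", {
  g <- genome("ACGGTA", topology = "circular")
  pc <- path_compress(build_kmer_graph(g, 3))
  expect_identical(nrow(pc$nodes), 1L)
  expect_identical(nrow(pc$edges), 1L)
  expect_identical(pc$edges$from, pc$edges$to)
  expect_identical(pc$edges$mult, 1L)
  # the node spells the genome plus the k - 2 wrap overlap
  expect_identical(nchar(pc$nodes$seq), 6L + 1L)
  res <- enumerate_words(pc)
  expect_identical(res$cyclic_words, asmcomplexity:::canonical_rotation("ACGGTA"))
})

test_that("parallel-edge pairs compress and the wrap edge becomes a self-loop", {
  g <- genome("ATATAT", topology = "circular")
  pc <- path_compress(build_kmer_graph(g, 3))
  expect_identical(nrow(pc$nodes), 1L)
  expect_identical(pc$edges$mult, 3L)
  expect_identical(pc$edges$from, pc$edges$to)
  expect_identical(comparable_words(pc), "ATATAT")
})

test_that("trail-terminal guards keep linear spellings intact", {
  kg <- sab_graph()
  pc <- path_compress(kg)
  expect_identical(comparable_words(pc), "SABABABABAB")
  ct <- collapse_trees(kg)
  expect_identical(comparable_words(ct), "SABABABABAB")
})

test_that("self-loop absorption spells the forced local tour", {
  # trail p -> u (2 self-loops) -> q; the unique traversal spells
  # seq(u) followed by two copies of its k-2-overlap suffix
  nodes <- data.frame(id = c("n000001", "n000002", "n000003"),
                      seq = c("XA", "ABAB", "BY"),
                      stringsAsFactors = FALSE)
  edges <- data.frame(from = c("n000001", "n000002", "n000002"),
                      to = c("n000002", "n000002", "n000003"),
                      mult = c(1L, 2L, 1L), label = NA_character_,
                      stringsAsFactors = FALSE)
  g <- asmcomplexity:::kg_new(3L, "linear", nodes, edges,
                              terminals = c(s = "n000001", t = "n000003"))
  before <- enumerate_words(g)
  ct <- collapse_trees(g)
  expect_identical(ct$nodes$seq[ct$nodes$id == "n000002"], "ABABBABBAB")
  expect_false(any(ct$edges$from == ct$edges$to))
  expect_identical(enumerate_words(ct)$distinct_words, before$distinct_words)
})

test_that("pendant two-node cycles collapse by the leaf rule", {
  # circular-ish core with a pendant excursion u <-> v, u on the main cycle
  nodes <- data.frame(id = sprintf("n%06d", 1:3),
                      seq = c("AB", "BA", "BCA"),  # u = AB, v = BA, rest
                      stringsAsFactors = FALSE)
  edges <- data.frame(from = c("n000001", "n000002", "n000001", "n000003"),
                      to = c("n000002", "n000001", "n000003", "n000001"),
                      mult = c(2L, 2L, 1L, 1L), label = NA_character_,
                      stringsAsFactors = FALSE)
  g <- asmcomplexity:::kg_new(3L, "circular", nodes, edges)
  before <- comparable_words(g)
  ct <- collapse_trees(g)
  expect_identical(nrow(ct$nodes), 1L)
  expect_identical(comparable_words(ct), before)
})

test_that("splitting removes half decisions and preserves words", {
  set.seed(31)
  for (i in 1:20) {
    g <- rand_circular_genome(sample(8:14, 1), c("A", "C", "G"))
    kg <- build_kmer_graph(g, 3)
    if (!asmcomplexity:::kg_connected(kg)) next
    before <- comparable_words(kg)
    sp <- split_half_decisions(kg)
    expect_identical(comparable_words(sp), before)
    # no splittable half decision remains
    for (v in sp$nodes$id) {
      has_self <- any(sp$edges$from == v & sp$edges$to == v)
      if (has_self) next
      np <- length(asmcomplexity:::kg_pred(sp, v))
      ns <- length(asmcomplexity:::kg_succ(sp, v))
      expect_false(xor(np > 1L, ns > 1L),
                   label = sprintf("node %s is still a half decision", v))
    }
  }
})

test_that("splitting bookkeeping conserves multiplicities toward the unique neighbor", {
  # backward decision v: preds x (mult 2) and y (mult 1), successor w
  # (w also has an unrelated predecessor so it cannot pre-merge with v)
  nodes <- data.frame(id = sprintf("n%06d", 1:5),
                      seq = c("AB", "CB", "BD", "DE", "FD"),
                      stringsAsFactors = FALSE)
  edges <- data.frame(from = c("n000001", "n000002", "n000003", "n000005"),
                      to = c("n000003", "n000003", "n000004", "n000004"),
                      mult = c(2L, 1L, 3L, 1L), label = NA_character_,
                      stringsAsFactors = FALSE)
  g <- asmcomplexity:::kg_new(3L, "circular", nodes, edges)
  sp <- asmcomplexity:::kg_split_pass(g, "backward", 10L)
  # v was split per predecessor and compressed into them; total flow into w
  # is unchanged
  din_w <- sum(sp$edges$mult[sp$edges$to == "n000004"])
  expect_identical(din_w, 4L)
  expect_false("n000003" %in% sp$nodes$id)
  expect_identical(sum(grepl("BD$", sp$nodes$seq)), 2L)  # two spelled copies
})

test_that("the pigeonhole rule reroutes exactly the forced traversals", {
  nodes <- data.frame(id = sprintf("n%06d", 1:6),
                      seq = c("XA", "YA", "AB", "BC", "BD", "ZZ"),
                      stringsAsFactors = FALSE)
  # v = AB with in u x3, x x1 and out w x3, y x1: f = 3 + 3 - 4 = 2
  edges <- data.frame(
    from = c("n000001", "n000002", "n000003", "n000003"),
    to = c("n000003", "n000003", "n000004", "n000005"),
    mult = c(3L, 1L, 3L, 1L), label = NA_character_,
    stringsAsFactors = FALSE)
  g <- asmcomplexity:::kg_new(3L, "circular", nodes, edges)
  ph <- infer_pigeonhole_paths(g)
  gete <- function(gr, f, t) sum(gr$edges$mult[gr$edges$from == f & gr$edges$to == t])
  expect_identical(gete(ph, "n000001", "n000003"), 1L)
  expect_identical(gete(ph, "n000003", "n000004"), 1L)
  copies <- setdiff(ph$nodes$id[ph$nodes$seq == "AB"], "n000003")
  expect_length(copies, 1L)
  expect_identical(gete(ph, "n000001", copies), 2L)
  expect_identical(gete(ph, copies, "n000004"), 2L)

  # balanced in/out multiplicities admit no inference
  edges2 <- data.frame(
    from = c("n000001", "n000002", "n000003", "n000003"),
    to = c("n000003", "n000003", "n000004", "n000005"),
    mult = c(2L, 2L, 2L, 2L), label = NA_character_,
    stringsAsFactors = FALSE)
  g2 <- asmcomplexity:::kg_new(3L, "circular", nodes, edges2)
  ph2 <- infer_pigeonhole_paths(g2)
  expect_identical(ph2$edges, g2$edges)
})

test_that("conversion leaves only decision nodes (or a single node)", {
  fix <- interleaved_fixture()
  for (k in c(15, 25)) {
    mc <- maximal_compress(build_kmer_graph(fix$genome, k))$graph
    if (nrow(mc$nodes) > 1L) {
      # after conversion, distinct reconstruction choices at a node are its
      # incoming/outgoing edge instances (labeled records count separately)
      dp <- asmcomplexity:::kg_dplus(mc)
      dm <- asmcomplexity:::kg_dminus(mc)
      expect_true(all(dp > 1L))
      expect_true(all(dm > 1L))
    } else {
      expect_identical(nrow(mc$nodes), 1L)
    }
  }
  # a graph of only full decisions is untouched by conversion
  kg <- build_kmer_graph(fix$genome, 15)
  mc1 <- maximal_compress(kg)$graph
  expect_identical(convert_nondecision_to_edges(mc1)$nodes, mc1$nodes)
})

test_that("maximal compression preserves word sets and reports exact stats", {
  set.seed(33)
  for (i in 1:10) {
    g <- rand_circular_genome(sample(8:14, 1), c("A", "C"))
    kg <- build_kmer_graph(g, 3)
    if (!asmcomplexity:::kg_connected(kg)) next
    before <- comparable_words(kg)
    mc <- maximal_compress(kg)
    expect_identical(comparable_words(mc$graph), before)
    s <- mc$stats
    expect_true(s$edges_after_trees <= s$edges_initial)
    expect_true(s$edges_after_conversion <= s$edges_after_split)
    expect_equal(s$percent_total,
                 100 * (1 - s$edges_after_conversion / s$edges_initial))
    tab <- reduction_stats_table(s)
    expect_identical(tab$edges[[1L]], s$edges_initial)
    expect_identical(tab$edges[[4L]], s$edges_after_conversion)
  }
})

test_that("transformations on labeled graphs are refused", {
  fix <- interleaved_fixture()
  mc <- maximal_compress(build_kmer_graph(fix$genome, 15))$graph
  expect_error(path_compress(mc), "labeled")
  expect_error(collapse_trees(mc), "labeled")
  expect_error(split_half_decisions(mc), "labeled")
})
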