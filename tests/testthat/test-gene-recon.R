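# Gene reconstructibility walks.

test_that("repeat-free genomes have all genes reconstructible at every k", {
  spec <- sim_spec(800, list(),
                   genes = list(list(start = 50, length = 300),
                                list(start = 400, length = 200,
                                     strand = "-")),
                   unique_k = 12, seed = 9)
  sim <- simulate_genome(spec)
  # plus a gene wrapping the circular origin
  genes <- rbind(sim$genes, gene_annotation("gWrap", 700L, 49L, "+", "wrap"))
  expect_true(genes$wraps[[3L]])
  for (k in c(12, 25)) {
    cg <- classify_genes(sim$genome, genes, k)
    expect_identical(cg$summary$fraction_reconstructible, 100)
    expect_true(all(cg$per_gene$reconstructible))
  }
})

test_that("exactly the repeat-bearing genes are non-reconstructible", {
  fix <- interleaved_fixture()
  seg <- fix$seg; rl <- fix$rep_len
  r1 <- fix$r_starts[[1L]]  # 0-based start of the first R copy
  genes <- rbind(
    # contains a full R copy with 30 bp unique flanks on both sides
    gene_annotation("gRep", r1 + 1L - 30L, r1 + rl + 30L, "+", "transposase"),
    # the same gene annotated on the - strand
    gene_annotation("gRepM", r1 + 1L - 30L, r1 + rl + 30L, "-",
                    "IS66 transposase"),
    # wholly inside unique segment A
    gene_annotation("gOkA", 20L, seg - 10L, "+", "DNA polymerase"),
    # wholly inside unique segment B, downstream-adjacent to the repeat
    gene_annotation("gOkB", r1 + rl + 20L, r1 + rl + 130L, "+", "kinase"),
    # minus-strand gene in a unique segment
    gene_annotation("gOkC", 2L * seg + 2L * rl + 20L,
                    2L * seg + 2L * rl + 120L, "-", "ligase"))
  for (k in c(15, 25)) {
    cg <- classify_genes(fix$genome, genes, k)
    got <- stats::setNames(cg$per_gene$reconstructible, cg$per_gene$gene_id)
    expect_identical(got, c(gRep = FALSE, gRepM = FALSE, gOkA = TRUE,
                            gOkB = TRUE, gOkC = TRUE))
    expect_equal(cg$summary$fraction_reconstructible, 100 * 3 / 5)
  }
})

test_that("a gene inside a single node occurrence is reconstructible", {
  fix <- interleaved_fixture()
  pg <- prepare_recon_graph(fix$genome, 15)
  # pick the longest node (a unique segment) and a gene inside one of its
  # occurrences
  i <- which.max(nchar(pg$nodes$seq))
  id <- pg$nodes$id[[i]]
  o <- pg$occ[[id]][[1L]]
  len <- nchar(pg$nodes$seq[[i]])
  gene <- gene_annotation("inNode", o + 5L, o + len - 5L, "+", "x")
  res <- is_reconstructible(pg, fix$genome, gene)
  expect_true(res$reconstructible)
  expect_identical(res$outcome$start_node, id)
})

test_that("the walk passes through a pure backward decision before stopping", {
  # repeat R (2 copies) is always followed by repeat W (3 copies), so after
  # compression R is a pure backward decision (preds A', B'; single
  # successor W) and W is a full decision; the walk from a gene in A passes
  # through R and terminates at W, whose own sequence is still covered
  set.seed(60)
  A <- rnd_seq(120); B <- rnd_seq(120); C <- rnd_seq(120); D <- rnd_seq(120)
  R <- rnd_seq(40); W <- rnd_seq(40); X <- rnd_seq(40)
  g <- genome(paste0(A, R, W, B, R, W, C, X, W, D), topology = "circular")
  pg <- prepare_recon_graph(g, 15)
  cls <- vapply(pg$nodes$id, function(u) classify_node(pg, u), character(1L))
  expect_true("backward_decision" %in% cls)
  # gene from late A through R and into W: reconstructible (R does not stop
  # the walk; the terminating full decision W is included)
  gene_in <- gene_annotation("gIn", 100L, 120L + 40L + 30L, "+", "y")
  expect_true(is_reconstructible(pg, g, gene_in)$reconstructible)
  # gene crossing beyond W into B is ambiguous
  gene_out <- gene_annotation("gOut", 100L, 120L + 40L + 40L + 30L, "+", "y")
  expect_false(is_reconstructible(pg, g, gene_out)$reconstructible)
})

test_that("summaries compute fractions and keyword tallies", {
  ann <- do.call(rbind, lapply(1:10, function(i)
    gene_annotation(sprintf("g%02d", i), i * 10L, i * 10L + 5L, "+",
                    c("transposase", "hypothetical protein", "kinase",
                      "phage integrase")[(i %% 4L) + 1L])))
  flags <- rep(TRUE, 10L); flags[c(4L, 8L)] <- FALSE  # products: transposase
  s <- summarize_reconstructibility(flags, ann)
  expect_identical(s$fraction_reconstructible, 80)  # 8 of 10
  expect_identical(s$n_reconstructible, 8L)
  expect_identical(unname(s$keyword_tallies["transpos"]), 2L)
  expect_identical(unname(s$keyword_tallies["phage"]), 0L)

  # hypothetical products are excluded from tallies
  flags2 <- rep(TRUE, 10L); flags2[c(1L, 2L)] <- FALSE
  # genes 1, 2 products: hypothetical protein, kinase
  s2 <- summarize_reconstructibility(flags2, ann)
  expect_identical(sum(s2$keyword_tallies), 0L)

  # empty annotation set: fraction undefined
  s0 <- summarize_reconstructibility(logical(0L), ann[0L, ])
  expect_true(is.na(s0$fraction_reconstructible))
})

test_that("classification is invariant under genome rotation", {
  fix <- interleaved_fixture()
  rot <- 333L
  seq2 <- paste0(substr(fix$genome$seq, rot + 1L, fix$genome$length),
                 substr(fix$genome$seq, 1L, rot))
  g2 <- genome(seq2, topology = "circular")
  r1 <- fix$r_starts[[1L]]
  shift <- function(p) ((p - 1L - rot) %% fix$genome$length) + 1L
  gene_a <- gene_annotation("a", r1 + 1L - 30L, r1 + fix$rep_len + 30L, "+", "z")
  gene_b <- gene_annotation("b", shift(gene_a$start), shift(gene_a$end), "+", "z")
  k <- 15
  res_a <- is_reconstructible(prepare_recon_graph(fix$genome, k), fix$genome, gene_a)
  res_b <- is_reconstructible(prepare_recon_graph(g2, k), g2, gene_b)
  expect_identical(res_a$reconstructible, res_b$reconstructible)
})
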