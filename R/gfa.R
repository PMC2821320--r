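# Minimal GFA 1.0 serialization of kmer_graph objects.
#
# Segments are node sequences; links are edge records with the multiplicity
# in an RC:i tag (parallel edges emitted once with their count). Spelled
# edge labels, k, topology and trail terminals go in custom two-letter tags
# so that read_gfa() round-trips write_gfa() exactly.

#' Write a k-mer graph to GFA 1.0
#'
#' @param graph A `kmer_graph`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_gfa <- function(graph, path) {
  k <- graph$k
  ov <- sprintf("%dM", k - 2L)
  header <- sprintf("H\tVN:Z:1.0\tKL:i:%d\tTP:Z:%s", k, graph$topology)
  if (!is.null(graph$terminals)) {
    header <- paste0(header, sprintf("\tTS:Z:%s\tTT:Z:%s",
                                     graph$terminals[["s"]],
                                     graph$terminals[["t"]]))
  }
  s_lines <- sprintf("S\t%s\t%s", graph$nodes$id, graph$nodes$seq)
  e <- graph$edges
  l_lines <- character(0L)
  if (nrow(e) > 0L) {
    l_lines <- sprintf("L\t%s\t+\t%s\t+\t%s\tRC:i:%d", e$from, e$to, ov, e$mult)
    lab <- !is.na(e$label)
    l_lines[lab] <- paste0(l_lines[lab], sprintf("\tLB:Z:%s", e$label[lab]))
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(header, s_lines, l_lines), con)
  invisible(path)
}

#' Read a k-mer graph from GFA 1.0 written by [write_gfa()]
#'
#' @param path Path to a GFA file.
#' @return A `kmer_graph`.
#' @export
read_gfa <- function(path) {
  if (!file.exists(path)) stop(sprintf("GFA file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  types <- vapply(fields, `[`, character(1L), 1L)

  tagval <- function(f, tag) {
    hit <- grep(paste0("^", tag, ":"), f, value = TRUE)
    if (length(hit) == 0L) return(NA_character_)
    sub(paste0("^", tag, ":[A-Za-z]:"), "", hit[[1L]])
  }

  hidx <- which(types == "H")
  if (length(hidx) == 0L) stop(sprintf("no GFA header line in %s", path))
  h <- fields[[hidx[[1L]]]]
  k <- as.integer(tagval(h, "KL"))
  topology <- tagval(h, "TP")
  if (is.na(k) || is.na(topology)) {
    stop("GFA header lacks KL/TP tags; not written by write_gfa()")
  }
  s <- tagval(h, "TS")
  t <- tagval(h, "TT")
  terminals <- if (!is.na(s)) c(s = s, t = t) else NULL

  sidx <- which(types == "S")
  nodes <- data.frame(
    id = vapply(fields[sidx], `[`, character(1L), 2L),
    seq = vapply(fields[sidx], `[`, character(1L), 3L),
    stringsAsFactors = FALSE
  )
  lidx <- which(types == "L")
  if (length(lidx) > 0L) {
    edges <- data.frame(
      from = vapply(fields[lidx], `[`, character(1L), 2L),
      to = vapply(fields[lidx], `[`, character(1L), 4L),
      mult = as.integer(vapply(fields[lidx], tagval, character(1L), "RC")),
      label = vapply(fields[lidx], tagval, character(1L), "LB"),
      stringsAsFactors = FALSE
    )
  } else {
    edges <- kg_empty_edges()
  }
  nxt <- suppressWarnings(max(as.integer(sub("^n", "", nodes$id))))
  if (!is.finite(nxt)) nxt <- nrow(nodes)
  kg_new(k, topology, nodes, edges, terminals = terminals, next_id = nxt + 1L)
}
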