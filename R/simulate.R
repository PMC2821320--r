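# Seeded synthetic circular genomes with planted repeat families.
#
# The generator produces the controlled ground truth used throughout the
# test suite: a random background that is rejection-sampled until it is
# repeat-free at the target k, so that the planted repeat copies are the
# only source of reconstruction ambiguity.

#' Specification for a synthetic genome
#'
#' @param genome_length Total length in symbols.
#' @param repeat_families List of families, each a list with `length`
#'   (>= the largest k the genome is meant to exercise), `copies` (>= 2)
#'   and `type` (`"interspersed"` or `"tandem"`).
#' @param genes Optional gene layout: a list of lists with `start` (1-based),
#'   `length`, and optional `strand` / `product`.
#' @param unique_k The k at which the background must be repeat-free: after
#'   generation, every duplicated `unique_k`-mer must lie wholly inside a
#'   planted repeat region.
#' @param alphabet Symbol set.
#' @param seed Mandatory integer seed; generation is deterministic given it.
#' @return A `sim_spec` list.
#' @export
sim_spec <- function(genome_length, repeat_families = list(), genes = list(),
                     unique_k = 15L, alphabet = c("A", "C", "G", "T"),
                     seed) {
  if (missing(seed)) stop("a seed is mandatory for synthetic genomes")
  stopifnot(genome_length >= 2L * unique_k)
  for (f in repeat_families) {
    stopifnot(f$copies >= 2L, f$length >= unique_k)
    span <- if (identical(f$type, "tandem")) f$length * f$copies else f$length
    if (span >= genome_length / max(1L, length(repeat_families) + 1L)) {
      stop("planted repeat family does not fit in the genome")
    }
  }
  for (g in genes) {
    stopifnot(g$start >= 1L, g$length >= 1L,
              g$start + g$length - 1L <= genome_length)
  }
  structure(list(genome_length = as.integer(genome_length),
                 repeat_families = repeat_families, genes = genes,
                 unique_k = as.integer(unique_k), alphabet = alphabet,
                 seed = as.integer(seed)),
            class = "sim_spec")
}

rand_string <- function(n, alphabet) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# 0-based starts of duplicated k-mers of a circular sequence
dup_kmer_starts <- function(seq, k) {
  L <- nchar(seq)
  ext <- paste0(seq, substr(seq, 1L, k - 1L))
  kmers <- substring(ext, seq_len(L), seq_len(L) + k - 1L)
  dup <- kmers %in% kmers[duplicated(kmers)]
  which(dup) - 1L
}

#' Generate a circular genome with planted repeats and toy annotations
#'
#' Deterministic given the spec's seed. The background is redrawn until the
#' only duplicated `unique_k`-mers are those lying wholly inside planted
#' repeat regions (for an empty family list: until all `unique_k`-mers are
#' distinct). A manifest records every planted copy's 0-based position.
#'
#' @param spec A [sim_spec()].
#' @param max_attempts Rejection-sampling cap.
#' @return A list: `genome` (a [genome()]), `genes` (annotation
#'   `data.frame`), `manifest` (list with `repeats` data.frame, `seed`,
#'   `attempts`).
#' @export
simulate_genome <- function(spec, max_attempts = 200L) {
  stopifnot(inherits(spec, "sim_spec"))
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()))
  }
  set.seed(spec$seed)
  L <- spec$genome_length
  uk <- spec$unique_k

  for (attempt in seq_len(max_attempts)) {
    sym <- sample(spec$alphabet, L, replace = TRUE)
    # place repeat blocks without overlap and without wrapping the origin
    blocks <- list()   # (start0, len) regions occupied by planted content
    placements <- list()
    ok <- TRUE
    for (fi in seq_along(spec$repeat_families)) {
      f <- spec$repeat_families[[fi]]
      unit <- rand_string(f$length, spec$alphabet)
      if (identical(f$type, "tandem")) {
        spans <- f$length * f$copies
        starts0 <- place_blocks(1L, spans, L, blocks, gap = uk)
        if (is.null(starts0)) { ok <- FALSE; break }
        blocks[[length(blocks) + 1L]] <- c(starts0, spans)
        copy_starts <- starts0 + f$length * (seq_len(f$copies) - 1L)
      } else {
        starts0 <- place_blocks(f$copies, f$length, L, blocks, gap = uk)
        if (is.null(starts0)) { ok <- FALSE; break }
        for (s0 in starts0) {
          blocks[[length(blocks) + 1L]] <- c(s0, f$length)
        }
        copy_starts <- starts0
      }
      unit_sym <- strsplit(unit, "", fixed = TRUE)[[1L]]
      for (s0 in copy_starts) {
        sym[(s0 + 1L):(s0 + f$length)] <- unit_sym
      }
      placements[[length(placements) + 1L]] <- data.frame(
        family = fi, copy = seq_along(copy_starts),
        start0 = as.integer(copy_starts), length = as.integer(f$length),
        type = f$type, stringsAsFactors = FALSE)
    }
    if (!ok) next
    seq <- paste(sym, collapse = "")
    # accept iff every duplicated unique_k-mer lies wholly inside a block
    dups <- dup_kmer_starts(seq, uk)
    inside <- rep(FALSE, length(dups))
    for (b in blocks) {
      inside <- inside | (dups >= b[[1L]] & dups + uk <= b[[1L]] + b[[2L]])
    }
    if (all(inside)) {
      gen <- genome(seq, id = sprintf("sim%d", spec$seed),
                    topology = "circular", alphabet = spec$alphabet)
      genes <- make_gene_table(spec$genes)
      manifest <- list(
        repeats = if (length(placements) > 0L) do.call(rbind, placements)
                  else data.frame(family = integer(), copy = integer(),
                                  start0 = integer(), length = integer(),
                                  type = character(),
                                  stringsAsFactors = FALSE),
        seed = spec$seed, attempts = attempt, unique_k = uk)
      return(list(genome = gen, genes = genes, manifest = manifest))
    }
  }
  stop(sprintf("could not generate a conforming genome in %d attempts",
               max_attempts))
}

# sample `n` non-overlapping block starts of length `len` in [0, L - len],
# keeping `gap` symbols clear of existing blocks; NULL if a draw fails
place_blocks <- function(n, len, L, blocks, gap, tries = 500L) {
  starts <- integer(0L)
  occupied <- blocks
  for (i in seq_len(n)) {
    placed <- FALSE
    for (t in seq_len(tries)) {
      s0 <- sample.int(L - len + 1L, 1L) - 1L
      clash <- FALSE
      for (b in occupied) {
        if (s0 < b[[1L]] + b[[2L]] + gap && b[[1L]] < s0 + len + gap) {
          clash <- TRUE
          break
        }
      }
      if (!clash) {
        starts <- c(starts, s0)
        occupied[[length(occupied) + 1L]] <- c(s0, len)
        placed <- TRUE
        break
      }
    }
    if (!placed) return(NULL)
  }
  sort(starts)
}

make_gene_table <- function(gene_layout) {
  if (length(gene_layout) == 0L) {
    return(gene_annotation("none", 1L, 1L)[0L, ])
  }
  rows <- lapply(seq_along(gene_layout), function(i) {
    g <- gene_layout[[i]]
    gene_annotation(
      g$id %||% sprintf("g%03d", i),
      g$start, g$start + g$length - 1L,
      g$strand %||% "+",
      g$product %||% "synthetic protein")
  })
  do.call(rbind, rows)
}

#' Write a simulated genome to FASTA + .ptt + JSON manifest
#'
#' @param sim Result of [simulate_genome()].
#' @param prefix Output path prefix (writes `<prefix>.fna`, `<prefix>.ptt`,
#'   `<prefix>.manifest.json`).
#' @return Invisibly, the three paths.
#' @export
write_simulation <- function(sim, prefix) {
  fna <- paste0(prefix, ".fna")
  ptt <- paste0(prefix, ".ptt")
  man <- paste0(prefix, ".manifest.json")
  write_fasta(stats::setNames(sim$genome$seq, sim$genome$id), fna)
  lines <- c(
    sprintf("%s - 1..%d", sim$genome$id, sim$genome$length),
    sprintf("%d proteins", nrow(sim$genes)),
    paste("Location", "Strand", "Length", "PID", "Gene", "Synonym", "Code",
          "COG", "Product", sep = "\t"))
  if (nrow(sim$genes) > 0L) {
    g <- sim$genes
    lines <- c(lines, sprintf("%d..%d\t%s\t%d\t-\t-\t%s\t-\t-\t%s",
                              g$start, g$end, g$strand,
                              pmax(1L, (abs(g$end - g$start) + 1L) %/% 3L),
                              g$gene_id, g$product))
  }
  writeLines(lines, ptt)
  jsonlite::write_json(
    list(seed = sim$manifest$seed, attempts = sim$manifest$attempts,
         unique_k = sim$manifest$unique_k, repeats = sim$manifest$repeats),
    man, auto_unbox = TRUE, digits = NA)
  invisible(c(fna, ptt, man))
}
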