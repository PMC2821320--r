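#' Read genomes from a FASTA file
#'
#' Each FASTA record becomes one [genome()]; records are analyzed
#' independently (no concatenation). Records whose header contains the word
#' "plasmid" (case-insensitive) can be dropped, mirroring the common survey
#' practice of restricting attention to main chromosomes.
#'
#' @param path Path to a FASTA file.
#' @param topology Topology assigned to every record (`"circular"` or
#'   `"linear"`); never inferred silently.
#' @param plasmid_filter Drop records whose header mentions "plasmid".
#' @param alphabet Admitted symbols (default DNA); `NULL` admits any symbol,
#'   which is needed for toy strings over arbitrary alphabets.
#' @return List of `genome` objects.
#' @export
read_fasta <- function(path, topology = c("circular", "linear"),
                       plasmid_filter = FALSE,
                       alphabet = c("A", "C", "G", "T")) {
  topology <- match.arg(topology)
  if (!file.exists(path)) stop(sprintf("FASTA file not found: %s", path))
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) stop(sprintf("malformed FASTA '%s': %s", path,
                                     conditionMessage(e)))
  )
  if (length(set) == 0L) stop(sprintf("no FASTA records in %s", path))
  headers <- names(set)
  seqs <- as.character(set)
  if (any(nchar(seqs) == 0L)) {
    stop(sprintf("empty FASTA record '%s' in %s",
                 headers[which(nchar(seqs) == 0L)[1L]], path))
  }
  if (plasmid_filter) {
    keep <- !grepl("plasmid", headers, ignore.case = TRUE)
    headers <- headers[keep]
    seqs <- seqs[keep]
  }
  ids <- vapply(strsplit(headers, "\\s+"), `[`, character(1L), 1L)
  mapply(function(s, id) genome(s, id = id, topology = topology,
                                alphabet = alphabet),
         seqs, ids, SIMPLIFY = FALSE, USE.NAMES = FALSE)
}

#' Write sequences to FASTA
#'
#' @param sequences Named character vector (names become headers).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(sequences, path) {
  set <- Biostrings::BStringSet(sequences)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read gene annotations from a GenBank .ptt protein table
#'
#' The .ptt dialect is tab-separated with header lines followed by rows
#' whose first column is a location of the form `start..end`. The synonym
#' column (or, failing that, PID / a running index) supplies the gene id;
#' the product description in the last column is retained for keyword
#' tallies.
#'
#' @param path Path to a .ptt file.
#' @return A `data.frame` of gene annotations (see [gene_annotation()]).
#' @export
read_ptt <- function(path) {
  if (!file.exists(path)) stop(sprintf(".ptt file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  out <- list()
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    if (length(fields) == 0L) next
    loc <- fields[[1L]]
    if (!grepl("^[0-9]+\\.\\.[0-9]+$", loc)) {
      # header or column-name line: skip silently, but flag rows that look
      # like data with a broken location column
      if (length(fields) >= 2L && grepl("\\.\\.", loc)) {
        stop(sprintf("unparsable location '%s' at row %d of %s", loc, i, path))
      }
      next
    }
    ends <- as.integer(strsplit(loc, "..", fixed = TRUE)[[1L]])
    strand <- if (length(fields) >= 2L) fields[[2L]] else "+"
    synonym <- if (length(fields) >= 6L && nzchar(fields[[6L]])) fields[[6L]]
               else if (length(fields) >= 4L && nzchar(fields[[4L]])) fields[[4L]]
               else sprintf("gene%04d", length(out) + 1L)
    product <- if (length(fields) >= 9L) fields[[9L]]
               else fields[[length(fields)]]
    out[[length(out) + 1L]] <-
      gene_annotation(synonym, ends[[1L]], ends[[2L]], strand, product)
  }
  if (length(out) == 0L) {
    return(gene_annotation("none", 1L, 1L)[0L, ])
  }
  do.call(rbind, out)
}

#' Read gene annotations from a GFF3 file
#'
#' Thin optional wrapper over `rtracklayer::readGFF` keeping only rows of
#' type `gene` or `CDS`, converted to the same annotation table as
#' [read_ptt()].
#'
#' @param path Path to a GFF3 file.
#' @param feature_types GFF3 `type` values to keep.
#' @return A `data.frame` of gene annotations.
#' @export
read_genes_gff3 <- function(path, feature_types = c("gene", "CDS")) {
  if (!requireNamespace("rtracklayer", quietly = TRUE)) {
    stop("reading GFF3 requires the rtracklayer package")
  }
  gff <- rtracklayer::readGFF(path)
  gff <- gff[gff$type %in% feature_types, , drop = FALSE]
  if (nrow(gff) == 0L) return(gene_annotation("none", 1L, 1L)[0L, ])
  ids <- if (!is.null(gff$ID)) as.character(gff$ID)
         else sprintf("gene%04d", seq_len(nrow(gff)))
  prods <- if (!is.null(gff$product)) as.character(gff$product) else ""
  prods[is.na(prods)] <- ""
  rows <- lapply(seq_len(nrow(gff)), function(i) {
    gene_annotation(ids[[i]], gff$start[[i]], gff$end[[i]],
                    as.character(gff$strand[[i]]), prods[[i]])
  })
  do.call(rbind, rows)
}
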