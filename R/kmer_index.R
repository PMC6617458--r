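#' @title Protein 9-mer LCA index
#' @name kmer_index
#' @description
#' A `kmer_index` maps every length-k amino-acid window of a reference
#' proteome to a single taxon: the lowest common ancestor (LCA) of all
#' reference proteins containing the window. Windows containing stop codons
#' or non-standard residues (B, J, O, U, X, Z) are never indexed: they break
#' windows rather than matching as wildcards. I and L are kept distinct.
NULL

INDEX_MAGIC <- "metapept_kmer_index"
INDEX_VERSION <- 1L

#' Build a k-mer LCA index from reference proteins
#'
#' @param proteins A data frame with a peptide column (`sequence` or
#'   `peptide`) and a `taxid` column, uppercase sequences.
#' @param tree The `taxonomy` the taxids live in.
#' @param k Window length in residues (default 9).
#' @return A `kmer_index` object.
#' @export
build_kmer_index <- function(proteins, tree, k = 9L) {
  proteins <- as_tibble(proteins)
  seq_col <- intersect(c("sequence", "peptide"), names(proteins))[1]
  if (is.na(seq_col)) abort("`proteins` needs a `sequence` or `peptide` column")
  if (nrow(proteins) == 0L) abort("empty protein list")
  stopifnot(k >= 2L)
  pos <- tax_pos(tree, proteins$taxid)
  res <- .build_index_cpp(toupper(proteins[[seq_col]]), pos,
                          tree$parent_pos, as.integer(k))
  structure(
    list(k = as.integer(k),
         kmers = res$kmer,
         taxids = tree$nodes$taxid[res$node_idx]),
    class = "kmer_index"
  )
}

#' @export
print.kmer_index <- function(x, ...) {
  cat(sprintf("<kmer_index> k = %d, %d distinct k-mers\n",
              x$k, length(x$kmers)))
  invisible(x)
}

#' Query a peptide against a k-mer index
#'
#' @param index A `kmer_index`.
#' @param peptide A single peptide string; windows containing `*` or
#'   non-standard residues yield no entry.
#' @return A tibble with columns `offset` (1-based window start) and `taxid`,
#'   one row per indexed window, in offset order.
#' @export
query_kmers <- function(index, peptide) {
  stopifnot(inherits(index, "kmer_index"), length(peptide) == 1L)
  res <- .query_kmers_cpp(toupper(peptide), index$kmers,
                          seq_along(index$kmers), index$k)
  tibble(offset = res$offset, taxid = index$taxids[res$node_idx])
}

#' Save / load a k-mer index
#'
#' The on-disk format is a versioned two-column TSV (`kmer`, `taxid`) with a
#' magic header line; round-trips exactly.
#'
#' @param index A `kmer_index`.
#' @param path File path.
#' @return `save_index` returns `path` invisibly; `load_index` the index.
#' @export
save_index <- function(index, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("#%s\tversion=%d\tk=%d", INDEX_MAGIC, INDEX_VERSION,
                     index$k), con)
  if (length(index$kmers))
    writeLines(paste(index$kmers, index$taxids, sep = "\t"), con)
  invisible(path)
}

#' @rdname save_index
#' @export
load_index <- function(path) {
  header <- readLines(path, n = 1L)
  want <- sprintf("#%s\tversion=%d\t", INDEX_MAGIC, INDEX_VERSION)
  if (!startsWith(header, want))
    abort(sprintf("not a %s version %d file: %s",
                  INDEX_MAGIC, INDEX_VERSION, path))
  k <- as.integer(sub(".*\tk=", "", header))
  body <- readLines(path)[-1L]
  if (length(body)) {
    parts <- strsplit(body, "\t", fixed = TRUE)
    kmers <- vapply(parts, `[[`, "", 1L)
    taxids <- as.integer(vapply(parts, `[[`, "", 2L))
  } else {
    kmers <- character()
    taxids <- integer()
  }
  structure(list(k = k, kmers = kmers, taxids = taxids), class = "kmer_index")
}

#' Read reference proteins from FASTA with taxid-tagged headers
#'
#' Headers must carry a `taxid=<int>` token.
#'
#' @param path FASTA path (gzip transparent).
#' @return Tibble with `name`, `taxid`, `sequence`.
#' @export
read_protein_fasta <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  hdr <- names(aa)
  m <- regmatches(hdr, regexpr("taxid=[0-9]+", hdr))
  if (length(m) != length(hdr))
    abort("every FASTA header must carry a taxid=<int> token")
  tibble(
    name = sub("\\s.*$", "", hdr),
    taxid = as.integer(sub("taxid=", "", m)),
    sequence = as.character(aa)
  )
}
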