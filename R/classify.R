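#' @title Read classification: six-frame translation and consensus taxa
#' @name classify
#' @description
#' Every merged shotgun read is translated in all six reading frames, the
#' amino-acid 9-mers of those peptides are looked up in the reference
#' [kmer_index], and the resulting taxon hits are aggregated into a single
#' consensus taxon per read by a top-down descent of the taxonomy.
NULL

#' Reverse complement
#'
#' @param dna Character vector of IUPAC nucleotide sequences.
#' @return Character vector of reverse complements (uppercase).
#' @export
revcomp <- function(dna) .revcomp_cpp(dna)

#' Translate a read in all six reading frames
#'
#' Frames are ordered `+1, +2, +3` on the forward strand then `-1, -2, -3`
#' on the reverse complement. The standard genetic code is used, stops are
#' rendered `*`, any codon containing `N` (or another ambiguity code)
#' translates to `X`, and trailing partial codons are dropped.
#'
#' @param dna A single nucleotide sequence (`ACGTN`, case-insensitive;
#'   IUPAC ambiguity codes allowed). Non-IUPAC characters are an error.
#' @return Named character vector of the 6 peptides.
#' @export
six_frame_translate <- function(dna) {
  stopifnot(length(dna) == 1L)
  setNames(.six_frame_cpp(dna), c("+1", "+2", "+3", "-1", "-2", "-3"))
}

#' Aggregate taxon hits into a consensus taxon
#'
#' Root-level hits are discarded (the filter step); if nothing remains the
#' read is unclassified. Otherwise the descent starts at the root and
#' repeatedly moves into the child whose subtree carries at least a fraction
#' `f` of the current node's hit weight (hits at internal nodes count toward
#' their own subtree), stopping when no child qualifies. With `f = 1` the
#' result equals the LCA of the surviving hits.
#'
#' @param hits Vector of taxids (a multiset; may be empty).
#' @param tree A `taxonomy`.
#' @param f Descent threshold in (0.5, 1]; values at or below 0.5 would make
#'   the descent ambiguous and are an error.
#' @return A taxid, or [UNCLASSIFIED] (`NA_integer_`).
#' @export
consensus_taxon <- function(hits, tree, f = 0.8) {
  if (f <= 0.5 || f > 1) abort("`f` must lie in (0.5, 1]")
  if (length(hits) == 0L) return(UNCLASSIFIED)
  pos <- tax_pos(tree, hits)
  res <- .consensus_cpp(pos, tree$parent_pos, tree$root_pos, f)
  if (is.na(res)) UNCLASSIFIED else tree$nodes$taxid[res]
}

#' Classify a single read
#'
#' Hits are pooled across all six frames before aggregation; `n_windows`
#' counts every queryable window across frames.
#'
#' @param read A single DNA sequence.
#' @param index A `kmer_index`.
#' @param tree The matching `taxonomy`.
#' @param f Consensus descent threshold, see [consensus_taxon()].
#' @param read_id Identifier carried through to the output.
#' @return One-row tibble: `read_id`, `taxid` (NA if unclassified),
#'   `n_hits`, `n_windows`.
#' @export
classify_read <- function(read, index, tree, f = 0.8, read_id = "read1") {
  classify_reads(setNames(read, read_id), index, tree, f = f)
}

classify_reads <- function(reads, index, tree, f = 0.8) {
  if (f <= 0.5 || f > 1) abort("`f` must lie in (0.5, 1]")
  node_pos <- tax_pos(tree, index$taxids)
  res <- .classify_reads_cpp(as.character(reads), index$kmers, node_pos,
                             tree$parent_pos, tree$root_pos, f, index$k)
  tibble(
    read_id = if (is.null(names(reads)))
      paste0("read", seq_along(reads)) else names(reads),
    taxid = ifelse(is.na(res$node_idx), NA_integer_,
                   tree$nodes$taxid[res$node_idx]),
    n_hits = res$n_hits,
    n_windows = res$n_windows
  )
}

read_sequences <- function(x) {
  if (is.character(x) && length(x) == 1L && file.exists(x)) {
    fmt <- if (grepl("\\.f(ast)?q(\\.gz)?$", x)) "fastq" else "fasta"
    set <- Biostrings::readDNAStringSet(x, format = fmt)
    setNames(as.character(set), sub("\\s.*$", "", names(set)))
  } else {
    if (length(x) && is.null(names(x)))
      names(x) <- paste0("read", seq_along(x))
    x
  }
}

#' Classify all reads of a sample
#'
#' @param reads Either a path to a FASTA/FASTQ file (gzip transparent) or a
#'   (optionally named) character vector of read sequences. Records whose
#'   sequence is not valid IUPAC DNA are skipped with a warning but still
#'   count toward the total.
#' @param index,tree,f As in [classify_read()].
#' @return A tibble of per-read assignments (class `read_assignments`) with
#'   attribute `fraction_assigned` = assigned / total (0 for an empty
#'   stream).
#' @export
classify_sample <- function(reads, index, tree, f = 0.8) {
  seqs <- read_sequences(reads)
  total <- length(seqs)
  ok <- !is.na(seqs) & grepl("^[ACGTUNRYSWKMBDHVacgtunryswkmbdhv]*$", seqs)
  if (any(!ok))
    warn(sprintf("skipped %d unreadable record(s)", sum(!ok)))
  out <- classify_reads(seqs[ok], index, tree, f = f)
  if (any(!ok)) {
    skipped <- tibble(read_id = names(seqs)[!ok], taxid = NA_integer_,
                      n_hits = 0L, n_windows = 0L)
    out <- dplyr::bind_rows(out, skipped)
  }
  frac <- if (total == 0L) 0 else sum(!is.na(out$taxid)) / total
  structure(out, fraction_assigned = frac,
            class = c("read_assignments", class(out)))
}

#' Genus-level (or other rank) count table across samples
#'
#' @param assignments A named list of per-sample assignment tibbles (as from
#'   [classify_sample()]), or one long tibble with a `sample_id` column.
#' @param tree A `taxonomy`.
#' @param rank Reporting rank (default `"genus"`).
#' @param relative If `TRUE`, return relative abundances
#'   (count / library size) instead of counts.
#' @return A wide tibble: `taxid`, `name`, one numeric column per sample;
#'   attribute `library_sizes` holds per-sample totals of assigned reads.
#' @export
build_genus_table <- function(assignments, tree, rank = "genus",
                              relative = FALSE) {
  if (is.data.frame(assignments)) {
    stopifnot("sample_id" %in% names(assignments))
    assignments <- split(assignments, assignments$sample_id)
  }
  if (is.null(names(assignments)) || any(!nzchar(names(assignments))))
    abort("`assignments` must be named by sample")
  per <- purrr::imap(assignments, function(a, sid) {
    r <- roll_up_to_rank(a$taxid, tree, rank)
    r$sample_id <- sid
    r
  })
  libs <- vapply(assignments, function(a) sum(!is.na(a$taxid)), 1L)
  long <- dplyr::bind_rows(per)
  wide <- tidyr::pivot_wider(long, id_cols = c("taxid", "name"),
                             names_from = "sample_id",
                             values_from = "count", values_fill = 0L)
  # preserve sample order
  wide <- wide[, c("taxid", "name", names(assignments))]
  if (relative) {
    for (s in names(assignments)) wide[[s]] <- wide[[s]] / libs[[s]]
  }
  structure(wide, library_sizes = libs,
            class = c("taxon_count_table", class(wide)))
}

#' Write per-read assignments as TSV
#'
#' Columns: read_id, taxid, rank, n_hits, n_windows.
#' @param assignments Tibble from [classify_sample()].
#' @param tree A `taxonomy` (for the rank column).
#' @param path Output path.
#' @export
write_assignments <- function(assignments, tree, path) {
  rank <- rep(NA_character_, nrow(assignments))
  known <- !is.na(assignments$taxid)
  rank[known] <- tree$nodes$rank[tax_pos(tree, assignments$taxid[known])]
  readr::write_tsv(
    tibble(read_id = assignments$read_id,
           taxid = assignments$taxid, rank = rank,
           n_hits = assignments$n_hits, n_windows = assignments$n_windows),
    path)
  invisible(path)
}
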