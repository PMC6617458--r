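#' @title Functional gene profiling and RPKG normalization
#' @name gene_profile
#' @description
#' Reads are matched to profile families (chitin-cycle glycoside hydrolase /
#' carbohydrate-esterase families and nitrogen-cycle gene models). Matches
#' within an e-value and model-coverage threshold are counted per family and
#' sample, then normalized to RPKG: reads per kilobase of model per genome
#' equivalent, where genome equivalents are total sequenced bases divided by
#' the community's average genome size (AGS).
NULL

#' Extract open reading frames
#'
#' All maximal stop-free stretches of at least `min_len_aa` residues across
#' the six reading frames, translated. This is a transparent stop-to-stop
#' ORF finder operating on translated frames.
#'
#' @param dna A single DNA sequence.
#' @param min_len_aa Minimum peptide length to report.
#' @return Character vector of peptides (possibly empty).
#' @export
find_orfs <- function(dna, min_len_aa = 30L) {
  frames <- six_frame_translate(dna)
  orfs <- unlist(strsplit(frames, "*", fixed = TRUE), use.names = FALSE)
  orfs[nchar(orfs) >= min_len_aa]
}

DOMTBL_COLS <- c("target_name", "target_acc", "tlen", "query_name",
                 "query_acc", "qlen", "full_evalue", "full_score",
                 "full_bias", "dom_n", "dom_of", "c_evalue", "i_evalue",
                 "dom_score", "dom_bias", "hmm_from", "hmm_to", "ali_from",
                 "ali_to", "env_from", "env_to", "acc")

#' Read HMMER3 per-domain tabular output (domtblout)
#'
#' Whitespace-delimited; `#` comment lines are skipped. Field mapping:
#' target name is the read/ORF id, query name the family id, the
#' independent e-value (i-Evalue) becomes `e_value`, and the `hmm from/to`
#' pair becomes the model-coordinate span.
#'
#' @param source Path or character vector of lines.
#' @return Tibble of match records: `read_id`, `family_id`, `e_value`,
#'   `hmm_from`, `hmm_to`, `bitscore`.
#' @export
read_domtblout <- function(source) {
  lines <- if (length(source) == 1L && file.exists(source))
    readLines(source) else source
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  if (!length(lines))
    return(tibble(read_id = character(), family_id = character(),
                  e_value = double(), hmm_from = integer(),
                  hmm_to = integer(), bitscore = double()))
  parts <- strsplit(trimws(lines), "[[:space:]]+")
  short <- which(vapply(parts, length, 1L) < 22L)
  if (length(short))
    abort(sprintf("domtblout parse error: line %d has fewer than 22 fields",
                  short[1]))
  fld <- function(i) vapply(parts, `[[`, "", i)
  tibble(
    read_id = fld(1L),
    family_id = fld(4L),
    e_value = as.numeric(fld(13L)),
    hmm_from = as.integer(fld(16L)),
    hmm_to = as.integer(fld(17L)),
    bitscore = as.numeric(fld(14L))
  )
}

#' Write match records in domtblout dialect
#'
#' @param records Tibble as returned by [read_domtblout()].
#' @param path Output path.
#' @param qlen Optional named model lengths per family (fills the qlen
#'   column; defaults to `hmm_to`).
#' @export
write_domtblout <- function(records, path, qlen = NULL) {
  ql <- if (is.null(qlen)) records$hmm_to else
    as.integer(qlen[records$family_id])
  lines <- sprintf(
    "%s - %d %s - %d %.2g %.1f 0.0 1 1 %.2g %.2g %.1f 0.0 %d %d %d %d %d %d 0.90 -",
    records$read_id, 999L, records$family_id, ql,
    records$e_value, records$bitscore, records$e_value, records$e_value,
    records$bitscore, records$hmm_from, records$hmm_to,
    records$hmm_from, records$hmm_to, records$hmm_from, records$hmm_to)
  writeLines(c("# domtblout dialect", lines), path)
  invisible(path)
}

#' Filter profile matches by e-value and model coverage
#'
#' A record is kept iff `e_value <= e_max` and
#' `(hmm_to - hmm_from + 1) / model_length_aa >= cov_min`. Coverage is
#' defined on the profile model (the FunGene convention), both thresholds
#' boundary-inclusive.
#'
#' @param records Match record tibble.
#' @param families Family registry tibble (see [gene_family_registry()]).
#' @param e_max Maximum e-value (default 1e-10).
#' @param cov_min Minimum model coverage fraction (default 0.60).
#' @return The kept records.
#' @export
filter_matches <- function(records, families, e_max = 1e-10,
                           cov_min = 0.60) {
  len <- families$model_length_aa[match(records$family_id,
                                        families$family_id)]
  if (anyNA(len) && nrow(records))
    abort(sprintf("unknown family_id: %s",
                  records$family_id[which(is.na(len))[1]]))
  cov <- (records$hmm_to - records$hmm_from + 1) / len
  records[records$e_value <= e_max & cov >= cov_min, , drop = FALSE]
}

#' Count filtered matches per family
#'
#' A read contributes at most one count per family (duplicate domains are
#' deduplicated, keeping the best e-value); one read may count toward
#' several families.
#'
#' @param records Filtered match records.
#' @param families Family registry.
#' @param sample_id Sample label attached to the output.
#' @return Tibble `family_id`, `sample_id`, `count` covering every registry
#'   family (zero-filled).
#' @export
count_matches <- function(records, families, sample_id = "sample1") {
  unknown <- setdiff(records$family_id, families$family_id)
  if (length(unknown)) abort(sprintf("unknown family_id: %s", unknown[1]))
  dedup <- records %>%
    dplyr::group_by(.data$read_id, .data$family_id) %>%
    dplyr::slice_min(.data$e_value, n = 1, with_ties = FALSE) %>%
    dplyr::ungroup() %>%
    dplyr::count(.data$family_id, name = "count")
  out <- tibble(family_id = families$family_id, sample_id = sample_id)
  out$count <- dedup$count[match(out$family_id, dedup$family_id)]
  out$count[is.na(out$count)] <- 0L
  out$count <- as.integer(out$count)
  out
}

#' Estimate genome equivalents from single-copy marker hit rates
#'
#' For each marker of amino-acid length `L` with `h` read hits out of `R`
#' total reads, the implied average genome size is
#' `AGS_j = 3 L R / h` base pairs (the expected hit rate of a single-copy
#' gene of nucleotide length `3L` in a genome of size AGS). The community
#' AGS is the geometric mean over markers with hits, and genome equivalents
#' are `total_bases / AGS`. A transparent single-copy-marker rate estimator
#' with the `GE = bp / AGS` contract; pass `ags` directly to bypass
#' estimation.
#'
#' @param total_reads,total_bases Library size in reads and bases.
#' @param marker_set Tibble `marker_id`, `length_aa`.
#' @param marker_hits Tibble `marker_id`, `hits` (reads hitting the marker).
#' @param ags Optional known average genome size in bp (skips estimation).
#' @param sample_id Sample label.
#' @return One-row tibble (class `sample_stats`): `sample_id`,
#'   `total_reads`, `total_bases`, `average_genome_size_bp`,
#'   `genome_equivalents`.
#' @export
estimate_genome_equivalents <- function(total_reads, total_bases,
                                        marker_set = NULL,
                                        marker_hits = NULL, ags = NULL,
                                        sample_id = "sample1") {
  if (is.null(ags)) {
    stopifnot(!is.null(marker_set), !is.null(marker_hits))
    h <- marker_hits$hits[match(marker_set$marker_id,
                                marker_hits$marker_id)]
    h[is.na(h)] <- 0
    use <- h > 0
    if (!any(use))
      abort("no marker has hits; supply `ags` directly")
    per <- 3 * marker_set$length_aa[use] * total_reads / h[use]
    ags <- exp(mean(log(per)))
  }
  stopifnot(ags > 0)
  tibble(sample_id = sample_id,
         total_reads = total_reads, total_bases = total_bases,
         average_genome_size_bp = ags,
         genome_equivalents = total_bases / ags)
}

#' RPKG: reads per kilobase of model per genome equivalent
#'
#' `count / (model_length_aa * 3 / 1000) / genome_equivalents`: the model
#' length is converted to kilobases of equivalent nucleotide (aa x 3 /
#' 1000) since the matched reads are nucleotide; set `unit = "aa"` to use
#' kilo-amino-acids instead.
#'
#' @param count Matched read count (>= 0).
#' @param model_length_aa Profile model length in residues.
#' @param genome_equivalents Positive number of genome equivalents.
#' @param unit `"nt"` (default) or `"aa"` model-length unit.
#' @return RPKG value(s); 0 iff `count` is 0.
#' @export
rpkg <- function(count, model_length_aa, genome_equivalents, unit = c("nt", "aa")) {
  unit <- match.arg(unit)
  if (any(genome_equivalents <= 0)) abort("genome_equivalents must be > 0")
  kb <- if (unit == "nt") model_length_aa * 3 / 1000 else model_length_aa / 1000
  count / kb / genome_equivalents
}

#' RPKG table across samples
#'
#' @param counts Long tibble `family_id`, `sample_id`, `count` (as from
#'   [count_matches()], row-bound over samples).
#' @param families Family registry (for model lengths).
#' @param sample_stats Row-bound [estimate_genome_equivalents()] output.
#' @param unit Model-length unit, see [rpkg()].
#' @return Wide tibble `family_id` x samples of RPKG values (class
#'   `rpkg_table`).
#' @export
rpkg_table <- function(counts, families, sample_stats, unit = "nt") {
  len <- families$model_length_aa[match(counts$family_id,
                                        families$family_id)]
  ge <- sample_stats$genome_equivalents[match(counts$sample_id,
                                              sample_stats$sample_id)]
  counts$rpkg <- rpkg(counts$count, len, ge, unit = unit)
  wide <- tidyr::pivot_wider(counts, id_cols = "family_id",
                             names_from = "sample_id",
                             values_from = "rpkg", values_fill = 0)
  structure(wide, class = c("rpkg_table", class(wide)))
}

#' Built-in gene-family registry
#'
#' The ten chitin-cycle carbohydrate-active families (GH18/GH19 chitinases,
#' GH20 N-acetylglucosaminidases, CE4/GH5/GH7/GH8 deacetylase-associated
#' families, GH46/GH75/GH80 chitosanases) and fourteen nitrogen-cycle gene
#' models (amoA split into archaeal AOA and bacterial AOB clades, amoB,
#' napA, nrfA, narG, nirS, nirK, norB, nosZ plus two atypical nosZ clades,
#' nifH, ureC). Model lengths are configurable defaults chosen for this
#' artifact, not published profile lengths. hao, nor, nasA and nir have no
#' usable public profile and are excluded.
#'
#' @param model_lengths Optional named overrides of `model_length_aa`.
#' @return Tibble `family_id`, `category`, `gene_symbol`,
#'   `model_length_aa`.
#' @export
gene_family_registry <- function(model_lengths = NULL) {
  reg <- dplyr::bind_rows(
    tibble(family_id = "GH18", category = "chitinase_GH18",
           gene_symbol = NA_character_, model_length_aa = 308L),
    tibble(family_id = "GH19", category = "chitinase_GH19",
           gene_symbol = NA_character_, model_length_aa = 224L),
    tibble(family_id = "GH20", category = "nacetylglucosaminidase_GH20",
           gene_symbol = NA_character_, model_length_aa = 347L),
    tibble(family_id = "CE4", category = "deacetylase_CE4",
           gene_symbol = NA_character_, model_length_aa = 147L),
    tibble(family_id = "GH5", category = "deacetylase_GH5",
           gene_symbol = NA_character_, model_length_aa = 283L),
    tibble(family_id = "GH7", category = "deacetylase_GH7",
           gene_symbol = NA_character_, model_length_aa = 425L),
    tibble(family_id = "GH8", category = "deacetylase_GH8",
           gene_symbol = NA_character_, model_length_aa = 319L),
    tibble(family_id = "GH46", category = "chitosanase_GH46",
           gene_symbol = NA_character_, model_length_aa = 229L),
    tibble(family_id = "GH75", category = "chitosanase_GH75",
           gene_symbol = NA_character_, model_length_aa = 218L),
    tibble(family_id = "GH80", category = "chitosanase_GH80",
           gene_symbol = NA_character_, model_length_aa = 240L),
    tibble(family_id = c("amoA_AOA", "amoA_AOB", "amoB", "napA", "nrfA",
                         "narG", "nirS", "nirK", "norB", "nosZ",
                         "nosZ_atypical1", "nosZ_atypical2", "nifH",
                         "ureC"),
           category = "ncycle",
           gene_symbol = c("amoA_AOA", "amoA_AOB", "amoB", "napA", "nrfA",
                           "narG", "nirS", "nirK", "norB", "nosZ",
                           "nosZ_atypical1", "nosZ_atypical2", "nifH",
                           "ureC"),
           model_length_aa = c(216L, 247L, 171L, 830L, 478L, 1232L, 548L,
                               470L, 459L, 611L, 600L, 590L, 275L, 569L))
  )
  if (!is.null(model_lengths)) {
    i <- match(names(model_lengths), reg$family_id)
    if (anyNA(i)) abort("model_lengths names must be registry family ids")
    reg$model_length_aa[i] <- as.integer(model_lengths)
  }
  reg
}
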