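#' @title Synthetic two-treatment metagenome communities
#' @name simulate
#' @description
#' Deterministic generators for reference taxonomies, proteomes and
#' genomes, and for two-treatment (peat substrate vs chitin-amended)
#' community read sets and gene-family match tables with full ground truth.
#' Genera are built with pairwise-disjoint 9-mer repertoires so that
#' classifier recovery can be checked exactly; an `overlap` mode shares
#' proteins between sister species to exercise LCA/consensus behavior.
NULL

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N", "P",
          "Q", "R", "S", "T", "V", "W", "Y")

# codons per amino acid (standard code), for reverse translation
codon_table <- function() {
  bases <- c("T", "C", "A", "G")
  codons <- as.vector(outer(outer(bases, bases, paste0), bases, paste0))
  # codon index order must match the translation core: 16*b1 + 4*b2 + b3
  idx <- expand.grid(b3 = 0:3, b2 = 0:3, b1 = 0:3)
  codons <- paste0(bases[idx$b1 + 1], bases[idx$b2 + 1], bases[idx$b3 + 1])
  aa <- strsplit("FFLLSSSSYY**CC*WLLLLPPPPHHQQRRRRIIIMTTTTNNKKSSRRVVVVAAAADDEEGGGG",
                 "")[[1]]
  split(codons, aa)
}

#' Simulation configuration
#'
#' Defaults encode the emulated study design: 2 treatments (`PS`,
#' `Chitin`) x 4 replicates, 10 genera, 10,000 x 200 nt error-free reads
#' per sample, and genus fold changes of the magnitudes reported for the
#' chitin treatment (3.4x and 7.6x spikes on genera of ~0.6-0.8% base
#' abundance). Replicate noise is Dirichlet with concentration 2000 (see
#' the methods vignette for the calibration).
#'
#' @param seed Integer seed; fully determines all generated corpora.
#' @param n_genera,proteins_per_taxon,protein_len_aa Reference shape;
#'   `protein_len_aa` is a `c(min, max)` range.
#' @param intergenic_len Neutral spacer between CDSs in simulated genomes.
#' @param n_replicates_per_group,depth_reads,read_len_nt,error_rate Read-set
#'   design (substitution errors only).
#' @param base_abundances Per-genus simplex weights (length `n_genera`).
#' @param genus_effects Named (by genus label `genus_01`...) fold changes
#'   applied in the `Chitin` group.
#' @param family_effects Named fold changes for gene families (Chitin vs
#'   PS); defaults mirror the reported shifts (bacterial amoA up ~3x, the
#'   three nosZ clades down ~0.75x, GH46/GH75 up).
#' @param family_base_rate Named expected filtered match counts per family
#'   in the PS group (per sample at default depth).
#' @param match_pass_fraction Fraction of emitted match records that pass
#'   the e-value/coverage filters (default 0.9).
#' @param dirichlet_concentration Replicate-noise concentration.
#' @param overlap If `TRUE`, each genus gets two species sharing some
#'   proteins, exercising within-genus LCA.
#' @param n_markers,marker_len_aa The first `n_markers` protein slots of
#'   every genus are universal single-copy markers of common length
#'   `marker_len_aa` (used for average-genome-size estimation).
#' @param k Classifier k-mer length (disjointness is enforced at this k).
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       n_genera = 10L,
                       proteins_per_taxon = 20L,
                       protein_len_aa = c(240L, 360L),
                       intergenic_len = 50L,
                       n_replicates_per_group = 4L,
                       depth_reads = 10000L,
                       read_len_nt = 200L,
                       error_rate = 0,
                       base_abundances = NULL,
                       genus_effects = NULL,
                       family_effects = NULL,
                       family_base_rate = NULL,
                       match_pass_fraction = 0.9,
                       dirichlet_concentration = 2000,
                       overlap = FALSE,
                       n_markers = 5L,
                       marker_len_aa = 300L,
                       k = 9L) {
  # tolerate YAML-sourced lists for the numeric fields
  to_num <- function(x) if (is.list(x)) unlist(x) else x
  base_abundances <- to_num(base_abundances)
  genus_effects <- to_num(genus_effects)
  family_effects <- to_num(family_effects)
  family_base_rate <- to_num(family_base_rate)
  protein_len_aa <- to_num(protein_len_aa)
  if (is.null(base_abundances)) {
    base_abundances <- c(0.29, 0.21, 0.16, 0.11, 0.09, 0.06, 0.04, 0.026,
                         0.008, 0.006)
    if (n_genera != 10L)
      base_abundances <- rep(1 / n_genera, n_genera)
  }
  stopifnot(length(base_abundances) == n_genera,
            abs(sum(base_abundances) - 1) < 1e-8,
            all(base_abundances > 0))
  glab <- sprintf("genus_%02d", seq_len(n_genera))
  if (is.null(genus_effects)) {
    genus_effects <- setNames(rep(1, n_genera), glab)
    if (n_genera >= 10L) { # spikes at the reported 3.4x / 7.6x magnitudes
      genus_effects["genus_10"] <- 3.4
      genus_effects["genus_09"] <- 7.6
    }
  }
  if (is.null(family_effects))
    family_effects <- c(amoA_AOB = 3.1, nosZ = 0.74, nosZ_atypical1 = 0.73,
                        nosZ_atypical2 = 0.75, GH46 = 2.0, GH75 = 1.5)
  structure(
    list(seed = as.integer(seed), n_genera = as.integer(n_genera),
         proteins_per_taxon = as.integer(proteins_per_taxon),
         protein_len_aa = as.integer(protein_len_aa),
         intergenic_len = as.integer(intergenic_len),
         n_replicates_per_group = as.integer(n_replicates_per_group),
         depth_reads = as.integer(depth_reads),
         read_len_nt = as.integer(read_len_nt),
         error_rate = error_rate,
         base_abundances = setNames(base_abundances, glab),
         genus_effects = genus_effects,
         family_effects = family_effects,
         family_base_rate = family_base_rate,
         match_pass_fraction = match_pass_fraction,
         dirichlet_concentration = dirichlet_concentration,
         overlap = isTRUE(overlap),
         n_markers = as.integer(min(n_markers, proteins_per_taxon)),
         marker_len_aa = as.integer(marker_len_aa),
         k = as.integer(k)),
    class = "sim_config")
}

rand_seq <- function(n, alphabet) paste(sample(alphabet, n, replace = TRUE),
                                        collapse = "")

kmer_set <- function(seqs, k) {
  unique(unlist(lapply(seqs, function(s) {
    n <- nchar(s)
    if (n < k) return(character())
    substring(s, 1:(n - k + 1), k:n)
  })))
}

#' Simulate a reference taxonomy, proteome and genomes
#'
#' Each genus sits under its own phylum (distinct lineages root ->
#' superkingdom -> phylum -> class -> order -> family -> genus -> species)
#' and carries `proteins_per_taxon` random proteins attached to its
#' species node. Genera are rejection-resampled until no 9-mer is shared
#' between genera. Genomes concatenate each protein's CDS (random
#' synonymous codons, ATG start, TAA stop) separated by neutral spacer
#' sequence.
#'
#' @param config A [sim_config()].
#' @return List (class `sim_reference`): `tree` (a `taxonomy`), `proteins`
#'   (tibble `protein_id`, `taxid`, `genus_taxid`, `sequence`), `genomes`
#'   (tibble `genus_taxid`, `genus`, `sequence`, `length`), `cds` (CDS
#'   coordinates per protein), `config`.
#' @export
simulate_reference <- function(config = sim_config()) {
  with_seed(config$seed, simulate_reference_impl(config))
}

simulate_reference_impl <- function(config) {
  ng <- config$n_genera
  glab <- names(config$base_abundances)
  # taxids: root 1, superkingdom 2, then 6 per genus lineage
  nodes <- list(tibble(taxid = 1L, parent_taxid = 1L, rank = "root",
                       name = "root"),
                tibble(taxid = 2L, parent_taxid = 1L, rank = "superkingdom",
                       name = "Bacteria"))
  nxt <- 3L
  genus_taxid <- integer(ng)
  species_taxid <- vector("list", ng)
  ranks <- c("phylum", "class", "order", "family", "genus")
  for (g in seq_len(ng)) {
    parent <- 2L
    for (r in ranks) {
      nodes[[length(nodes) + 1L]] <-
        tibble(taxid = nxt, parent_taxid = parent, rank = r,
               name = sprintf("%s_%02d", r, g))
      parent <- nxt
      nxt <- nxt + 1L
    }
    genus_taxid[g] <- parent
    nsp <- if (config$overlap) 2L else 1L
    sp <- integer(nsp)
    for (s in seq_len(nsp)) {
      nodes[[length(nodes) + 1L]] <-
        tibble(taxid = nxt, parent_taxid = parent, rank = "species",
               name = sprintf("species_%02d_%d", g, s))
      sp[s] <- nxt
      nxt <- nxt + 1L
    }
    species_taxid[[g]] <- sp
  }
  tree <- taxonomy(dplyr::bind_rows(nodes))

  # proteomes with genus-disjoint k-mer repertoires
  k <- config$k
  seen <- character() # k-mers claimed by earlier genera
  prot <- vector("list", ng)
  for (g in seq_len(ng)) {
    repeat {
      lens <- sample(config$protein_len_aa[1]:config$protein_len_aa[2],
                     config$proteins_per_taxon, replace = TRUE)
      # the first slots are universal single-copy markers: every genome
      # carries one homolog of common length (sequences stay genus-specific)
      if (config$n_markers > 0)
        lens[seq_len(config$n_markers)] <- config$marker_len_aa
      seqs <- vapply(lens, rand_seq, "", alphabet = AA20)
      km <- kmer_set(seqs, k)
      if (!any(km %in% seen)) { seen <- c(seen, km); break }
    }
    sp <- species_taxid[[g]]
    taxid <- if (length(sp) == 1L) rep(sp, length(seqs)) else {
      # overlap mode: first half shared (assigned to both species in turn),
      # i.e. duplicated entries force the index to the genus LCA
      rep(sp, length.out = length(seqs))
    }
    prot[[g]] <- tibble(
      protein_id = sprintf("%s_p%02d", glab[g], seq_along(seqs)),
      taxid = taxid, genus_taxid = genus_taxid[g], sequence = seqs)
    if (config$overlap) {
      shared <- prot[[g]][seq_len(ceiling(length(seqs) / 4)), ]
      shared$taxid <- sp[2 - (shared$taxid == sp[2])] # the other species
      shared$protein_id <- paste0(shared$protein_id, "b")
      prot[[g]] <- dplyr::bind_rows(prot[[g]], shared)
    }
  }
  proteins <- dplyr::bind_rows(prot)

  # genomes: spacer + CDS per protein (+ trailing spacer)
  ct <- codon_table()
  genomes <- vector("list", ng)
  cds <- vector("list", ng)
  for (g in seq_len(ng)) {
    p <- prot[[g]][!duplicated(sub("b$", "", prot[[g]]$protein_id)), ]
    pieces <- character(0)
    coords <- list()
    pos <- 0L
    for (i in seq_len(nrow(p))) {
      spacer <- rand_seq(config$intergenic_len, c("A", "C", "G", "T"))
      aa <- strsplit(p$sequence[i], "")[[1]]
      codons <- vapply(aa, function(a) sample(ct[[a]], 1L), "")
      cds_seq <- paste0("ATG", paste(codons, collapse = ""), "TAA")
      start <- pos + config$intergenic_len + 1L
      pieces <- c(pieces, spacer, cds_seq)
      coords[[i]] <- tibble(protein_id = p$protein_id[i],
                            genus_taxid = genus_taxid[g],
                            start = start,
                            end = start + nchar(cds_seq) - 1L)
      pos <- start + nchar(cds_seq) - 1L
    }
    seqg <- paste(pieces, collapse = "")
    genomes[[g]] <- tibble(genus_taxid = genus_taxid[g], genus = glab[g],
                           sequence = seqg, length = nchar(seqg))
    cds[[g]] <- dplyr::bind_rows(coords)
  }
  structure(list(tree = tree, proteins = proteins,
                 genomes = dplyr::bind_rows(genomes),
                 cds = dplyr::bind_rows(cds), config = config),
            class = "sim_reference")
}

#' Simulate two-treatment community read sets with ground truth
#'
#' Per replicate, genus proportions are the base abundances (fold changes
#' applied in the `Chitin` group, then renormalized) with Dirichlet
#' replicate noise; reads are drawn uniformly from the source genome on
#' either strand, with substitution errors at `error_rate`.
#'
#' @param reference A `sim_reference`.
#' @param config Defaults to the reference's config.
#' @return List (class `sim_community`): `samples` (tibble `sample_id`,
#'   `group`), `reads` (named list of named character vectors), `truth`
#'   (list: `proportions`, `per_read`, `sample_stats` incl. true AGS).
#' @export
simulate_community_reads <- function(reference,
                                     config = reference$config) {
  with_seed(config$seed + 1L, simulate_reads_impl(reference, config))
}

simulate_reads_impl <- function(reference, config) {
  ng <- config$n_genera
  glab <- names(config$base_abundances)
  nrep <- config$n_replicates_per_group
  samples <- tibble(
    sample_id = c(sprintf("PS%d", seq_len(nrep)),
                  sprintf("CH%d", seq_len(nrep))),
    group = rep(c("PS", "Chitin"), each = nrep))
  fc <- setNames(rep(1, ng), glab)
  fc[names(config$genus_effects)] <- config$genus_effects
  glens <- setNames(reference$genomes$length, reference$genomes$genus)
  reads <- list()
  props_out <- list()
  per_read <- list()
  stats_out <- list()
  for (s in seq_len(nrow(samples))) {
    sid <- samples$sample_id[s]
    base <- config$base_abundances
    if (samples$group[s] == "Chitin") base <- base * fc / sum(base * fc)
    alpha <- config$dirichlet_concentration * base
    gam <- rgamma(ng, shape = alpha)
    prop <- gam / sum(gam)
    counts <- drop(rmultinom(1L, config$depth_reads, prop))
    rl <- config$read_len_nt
    seqs <- character(0); ids <- character(0)
    src <- list()
    for (g in seq_len(ng)) {
      if (counts[g] == 0) next
      gseq <- reference$genomes$sequence[g]
      starts <- sample.int(glens[g] - rl + 1L, counts[g], replace = TRUE)
      rr <- substring(gseq, starts, starts + rl - 1L)
      strand <- sample(c("+", "-"), counts[g], replace = TRUE)
      rr[strand == "-"] <- revcomp(rr[strand == "-"])
      if (config$error_rate > 0) rr <- add_errors(rr, config$error_rate)
      id <- sprintf("%s_%s_r%05d", sid, glab[g], seq_len(counts[g]))
      seqs <- c(seqs, rr); ids <- c(ids, id)
      src[[g]] <- tibble(read_id = id, sample_id = sid,
                         genus = glab[g],
                         genus_taxid = reference$genomes$genus_taxid[g],
                         start = starts, strand = strand)
    }
    ord <- sample.int(length(seqs)) # shuffle read order
    reads[[sid]] <- setNames(seqs[ord], ids[ord])
    props_out[[sid]] <- tibble(sample_id = sid, genus = glab,
                               genus_taxid = reference$genomes$genus_taxid,
                               true_prop = prop,
                               true_count = as.integer(counts))
    per_read[[sid]] <- dplyr::bind_rows(src)
    read_share <- counts / sum(counts)
    true_ags <- 1 / sum(read_share / glens) # read-weighted harmonic mean
    stats_out[[sid]] <- tibble(
      sample_id = sid, group = samples$group[s],
      total_reads = sum(counts),
      total_bases = sum(counts) * rl,
      true_ags = true_ags,
      true_ge = sum(counts) * rl / true_ags)
  }
  structure(list(samples = samples, reads = reads,
                 truth = list(proportions = dplyr::bind_rows(props_out),
                              per_read = dplyr::bind_rows(per_read),
                              sample_stats = dplyr::bind_rows(stats_out)),
                 config = config),
            class = "sim_community")
}

add_errors <- function(reads, rate) {
  vapply(reads, function(r) {
    n <- nchar(r)
    k <- rbinom(1L, n, rate)
    if (k == 0) return(r)
    pos <- sample.int(n, k)
    ch <- strsplit(r, "")[[1]]
    ch[pos] <- vapply(ch[pos], function(b)
      sample(setdiff(c("A", "C", "G", "T"), b), 1L), "")
    paste(ch, collapse = "")
  }, "", USE.NAMES = TRUE)
}

#' Write simulated reads as FASTQ
#'
#' Constant Q30 quality scores.
#' @param community A `sim_community`.
#' @param dir Output directory (one `<sample>.fastq.gz` per sample).
#' @return Named vector of paths.
#' @export
write_community_fastq <- function(community, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(names(community$reads), function(sid) {
    reads <- community$reads[[sid]]
    path <- file.path(dir, paste0(sid, ".fastq.gz"))
    con <- gzfile(path, "w")
    q <- strrep("?", nchar(reads)) # Q30
    writeLines(paste0("@", names(reads), "\n", reads, "\n+\n", q), con)
    close(con)
    path
  }, "")
  invisible(paths)
}

#' Universal single-copy marker set and hit counts of a simulated corpus
#'
#' `sim_marker_set` lists the marker families shared by every simulated
#' genome; `sim_marker_hits` counts, per sample, the reads whose start
#' coordinate falls inside a marker's CDS — the inputs of
#' [estimate_genome_equivalents()].
#'
#' @param reference A `sim_reference`.
#' @return `sim_marker_set`: tibble `marker_id`, `length_aa`.
#' @export
sim_marker_set <- function(reference) {
  cfg <- reference$config
  if (cfg$n_markers < 1) abort("reference was simulated without markers")
  tibble(marker_id = sprintf("marker_%02d", seq_len(cfg$n_markers)),
         length_aa = cfg$marker_len_aa)
}

#' @rdname sim_marker_set
#' @param community A `sim_community` generated from `reference`.
#' @param sample_id One of the community's sample ids.
#' @return `sim_marker_hits`: tibble `marker_id`, `hits`.
#' @export
sim_marker_hits <- function(reference, community, sample_id) {
  cfg <- reference$config
  reads <- community$truth$per_read
  reads <- reads[reads$sample_id == sample_id, ]
  slot <- as.integer(sub(".*_p([0-9]+)b?$", "\\1", reference$cds$protein_id))
  ms <- sim_marker_set(reference)
  hits <- vapply(seq_len(cfg$n_markers), function(m) {
    cds <- reference$cds[slot == m, ]
    i <- match(reads$genus_taxid, cds$genus_taxid)
    sum(reads$start >= cds$start[i] & reads$start <= cds$end[i])
  }, 1L)
  tibble(marker_id = ms$marker_id, hits = hits)
}

#' Simulate gene-family match tables with ground truth
#'
#' Per sample, the true filtered match count of each family is Poisson with
#' mean `base_rate x depth_factor x fold_change` (fold change in the
#' `Chitin` group only). Emitted domtblout records contain exactly those
#' passing records (e-value <= 1e-10, model coverage >= 60%) plus
#' failing decoy records so that a fraction `match_pass_fraction` of all
#' records passes; applying the study filters to the emitted table
#' recovers the truth counts exactly.
#'
#' @param config A [sim_config()].
#' @param families Registry tibble (default [gene_family_registry()]).
#' @param design Optional sample design tibble; defaults to the config's
#'   2 x `n_replicates_per_group` layout.
#' @return List (class `sim_matches`): `records` (named list of match
#'   tibbles per sample), `truth` (tibble `sample_id`, `family_id`,
#'   `true_count`), `sample_stats` (with genome equivalents), `design`.
#' @export
simulate_gene_matches <- function(config = sim_config(),
                                  families = gene_family_registry(),
                                  design = NULL) {
  with_seed(config$seed + 2L, simulate_matches_impl(config, families,
                                                    design))
}

simulate_matches_impl <- function(config, families, design) {
  nrep <- config$n_replicates_per_group
  if (is.null(design))
    design <- tibble(
      sample_id = c(sprintf("PS%d", seq_len(nrep)),
                    sprintf("CH%d", seq_len(nrep))),
      group = rep(c("PS", "Chitin"), each = nrep))
  base <- config$family_base_rate
  if (is.null(base)) {
    # expected filtered counts per sample at default depth: moderate,
    # family-length-weighted spread
    base <- setNames(pmax(5, round(families$model_length_aa / 4)),
                     families$family_id)
  }
  fc <- setNames(rep(1, nrow(families)), families$family_id)
  fc[names(config$family_effects)] <- config$family_effects
  depth_factor <- config$depth_reads / 10000
  records <- list(); truths <- list(); stats_l <- list()
  for (s in seq_len(nrow(design))) {
    sid <- design$sample_id[s]
    lam <- base[families$family_id] * depth_factor
    if (design$group[s] == "Chitin") lam <- lam * fc[families$family_id]
    n_true <- rpois(nrow(families), lam)
    recs <- list()
    for (i in seq_len(nrow(families))) {
      fid <- families$family_id[i]
      L <- families$model_length_aa[i]
      if (n_true[i] > 0) {
        span_len <- pmax(ceiling(0.60 * L),
                         floor(runif(n_true[i], 0.60, 1.0) * L))
        from <- pmax(1L, floor(runif(n_true[i], 1, L - span_len + 1)))
        recs[[length(recs) + 1L]] <- tibble(
          read_id = sprintf("%s_%s_hit%04d", sid, fid, seq_len(n_true[i])),
          family_id = fid,
          e_value = 10^-runif(n_true[i], 10, 40),
          hmm_from = as.integer(from),
          hmm_to = as.integer(from + span_len - 1L),
          bitscore = round(runif(n_true[i], 60, 400), 1))
      }
      n_fail <- rpois(1L, lam[i] * (1 - config$match_pass_fraction) /
                        config$match_pass_fraction)
      if (n_fail > 0) { # decoys: bad e-value or short span
        bad_e <- runif(n_fail) < 0.5
        span_len <- pmax(1L, floor(0.4 * L * runif(n_fail)))
        recs[[length(recs) + 1L]] <- tibble(
          read_id = sprintf("%s_%s_decoy%04d", sid, fid, seq_len(n_fail)),
          family_id = fid,
          e_value = ifelse(bad_e, 10^-runif(n_fail, 2, 9.5),
                           10^-runif(n_fail, 10, 40)),
          hmm_from = 1L,
          hmm_to = as.integer(ifelse(bad_e, L, span_len)),
          bitscore = round(runif(n_fail, 10, 50), 1))
      }
    }
    records[[sid]] <- dplyr::bind_rows(recs)
    truths[[sid]] <- tibble(sample_id = sid,
                            family_id = families$family_id,
                            true_count = as.integer(n_true))
    ags <- 5e6 # nominal community average genome size, bp
    stats_l[[sid]] <- estimate_genome_equivalents(
      total_reads = config$depth_reads,
      total_bases = config$depth_reads * config$read_len_nt,
      ags = ags * exp(stats::rnorm(1, 0, 0.02)), sample_id = sid)
  }
  structure(list(records = records,
                 truth = dplyr::bind_rows(truths),
                 sample_stats = dplyr::bind_rows(stats_l),
                 design = design, families = families, config = config),
            class = "sim_matches")
}
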