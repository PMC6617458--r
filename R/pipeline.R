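#' @title End-to-end analysis pipelines
#' @name pipeline
#' @description
#' Orchestrates the stages — reference/index, read classification, genus
#' tables, differential abundance and community tests; and match filtering,
#' RPKG normalization and quasi-Poisson testing — from a single validated
#' configuration. Every threshold of the workflow is surfaced as a named
#' key defaulting to the study's value. Re-running a pipeline with the
#' same config is deterministic.
NULL

PIPELINE_DEFAULTS <- list(
  out_dir = NULL,
  k = 9L, f = 0.8,                 # classification
  e_max = 1e-10, cov_min = 0.60,   # match filter
  min_cpm = 4, min_samples = 4L,   # abundance filter
  prior_df = 10, tagwise = FALSE,  # dispersion
  n_perm = 9999L, seed = 1L,       # permutation tests
  alpha = 0.05,                    # significance threshold
  sim = list(),                    # sim_config() overrides
  reads = NULL,                    # named FASTA/FASTQ paths (skip simulation)
  index_path = NULL, nodes_path = NULL, names_path = NULL,
  domtblout = NULL,                # named domtblout paths per sample
  design = NULL,                   # sample_id/group data frame
  sample_stats = NULL,             # per-sample GE table
  provenance = list()              # upstream QC settings, recorded only
)

#' Build and validate a pipeline configuration
#'
#' @param ... Named settings (see `metapept:::PIPELINE_DEFAULTS`), or a
#'   single list / YAML file path. Unknown keys are an error.
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(...) {
  args <- list(...)
  if (length(args) == 1L && is.null(names(args))) {
    x <- args[[1L]]
    if (is.character(x) && length(x) == 1L) x <- yaml::read_yaml(x)
    args <- x
  }
  unknown <- setdiff(names(args), names(PIPELINE_DEFAULTS))
  if (length(unknown))
    abort(sprintf("unknown config key(s): %s",
                  paste(unknown, collapse = ", ")))
  cfg <- modifyList(PIPELINE_DEFAULTS, args, keep.null = TRUE)
  if (cfg$f <= 0.5 || cfg$f > 1) abort("config error: f must be in (0.5, 1]")
  if (!is.null(cfg$reads) && length(cfg$reads) == 0L)
    abort("config error: empty sample list")
  if (!is.null(cfg$reads) && is.null(cfg$design))
    abort("config error: `design` required with external reads")
  structure(cfg, class = "pipeline_config")
}

stage_log <- function(log, stage, ...) {
  msg <- sprintf(...)
  message(sprintf("[%s] %s", stage, msg))
  c(log, setNames(list(msg), stage))
}

#' Run the taxonomic analysis end to end
#'
#' Simulates (or loads) reads, classifies them against the 9-mer index,
#' builds the genus count table, and runs the count-based statistics:
#' dispersion homogeneity + PERMANOVA on Bray-Curtis distances, then the
#' CPM filter, TMM normalization, qCML dispersion, NB exact tests and BH
#' correction.
#'
#' @param config A [pipeline_config()] (or arguments for one).
#' @return List: `genus_table`, `assignments` (per-sample tibbles),
#'   `fraction_assigned`, `diff` (feature results with `fdr` and
#'   `significant`), `permanova`, `dispersion_homogeneity`, `summary`.
#'   When `out_dir` is set, TSV/JSON artifacts are written there.
#' @export
run_taxonomic_analysis <- function(config = pipeline_config()) {
  if (!inherits(config, "pipeline_config"))
    config <- pipeline_config(config)
  log <- list()
  if (is.null(config$reads)) {
    sim <- do.call(sim_config, c(list(seed = config$seed), config$sim))
    ref <- simulate_reference(sim)
    tree <- ref$tree
    index <- build_kmer_index(ref$proteins, tree, k = config$k)
    corpus <- simulate_community_reads(ref, sim)
    reads <- corpus$reads
    design <- corpus$samples
    log <- stage_log(log, "simulate", "%d samples x %d reads, %d genera",
                     nrow(design), sim$depth_reads, sim$n_genera)
  } else {
    tree <- load_taxonomy(config$nodes_path, config$names_path)
    index <- load_index(config$index_path)
    reads <- config$reads
    design <- as_tibble(config$design)
  }
  assignments <- purrr::map(reads, classify_sample, index = index,
                            tree = tree, f = config$f)
  frac <- vapply(assignments, attr, 1.0, "fraction_assigned")
  log <- stage_log(log, "classify", "mean fraction assigned %.3f",
                   mean(frac))
  genus_table <- build_genus_table(assignments, tree)
  libs <- attr(genus_table, "library_sizes")

  bc <- bray_curtis(genus_table)
  disp_h <- dispersion_homogeneity(bc, design$group, seed = config$seed)
  pmv <- permanova(bc, design$group, n_perm = config$n_perm,
                   seed = config$seed)
  log <- stage_log(log, "permanova", "pseudo-F %.3f p %.4f (%s)",
                   pmv$pseudo_F, pmv$p_value, pmv$mode)

  kept <- cpm_filter(genus_table, config$min_cpm, config$min_samples,
                     lib_sizes = libs)
  log <- stage_log(log, "cpm_filter", "%d features kept, %d removed",
                   nrow(kept), attr(kept, "n_removed"))
  tmm <- tmm_factors(kept, lib_sizes = libs)
  nf <- setNames(tmm$norm_factor, tmm$sample_id)
  dsp <- estimate_dispersion_qcml(kept, design, tagwise = config$tagwise,
                                  prior_df = config$prior_df,
                                  lib_sizes = libs, norm_factors = nf)
  diff <- nb_exact_test(kept, design, dispersion = dsp,
                        tagwise = config$tagwise)
  diff$fdr <- bh_adjust(diff$p_value)
  diff$significant <- diff$fdr < config$alpha
  diff$name <- kept$name[match(diff$feature_id,
                               as.character(kept$taxid))]
  log <- stage_log(log, "diffstats", "%d/%d features significant at FDR %g",
                   sum(diff$significant), nrow(diff), config$alpha)

  summary <- list(
    n_samples = nrow(design), fraction_assigned = unname(frac),
    mean_fraction_assigned = mean(frac),
    n_features_total = nrow(genus_table), n_features_tested = nrow(diff),
    n_significant = sum(diff$significant),
    permanova_p = pmv$p_value, dispersion_homogeneity_p = disp_h$p_value,
    common_dispersion = dsp$common_phi)
  out <- list(genus_table = genus_table, assignments = assignments,
              fraction_assigned = frac, diff = diff, permanova = pmv,
              dispersion_homogeneity = disp_h, summary = summary,
              log = log)
  if (!is.null(config$out_dir)) write_tax_outputs(out, config$out_dir)
  out
}

write_tax_outputs <- function(out, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_tsv(out$genus_table, file.path(dir, "genus_counts.tsv"))
  readr::write_tsv(out$diff, file.path(dir, "diff_genera.tsv"))
  jsonlite::write_json(out$summary, file.path(dir, "run_summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Run the functional (gene-family) analysis end to end
#'
#' Loads or simulates domtblout match tables, applies the e-value and
#' model-coverage filters, counts matches per family and sample, computes
#' the RPKG table, and tests the treatment effect per family with the
#' quasi-Poisson GLM (offset `log(genome equivalents)`), BH-corrected.
#'
#' @param config A [pipeline_config()].
#' @return List: `counts` (long), `rpkg` (wide RPKG table), `diff`,
#'   `sample_stats`, `summary`.
#' @export
run_functional_analysis <- function(config = pipeline_config()) {
  if (!inherits(config, "pipeline_config"))
    config <- pipeline_config(config)
  log <- list()
  families <- gene_family_registry()
  if (is.null(config$domtblout)) {
    sim <- do.call(sim_config, c(list(seed = config$seed), config$sim))
    matches <- simulate_gene_matches(sim, families)
    records <- matches$records
    design <- matches$design
    sample_stats <- matches$sample_stats
    log <- stage_log(log, "simulate", "%d samples, %d families",
                     nrow(design), nrow(families))
  } else {
    records <- purrr::map(config$domtblout, read_domtblout)
    design <- as_tibble(config$design)
    sample_stats <- as_tibble(config$sample_stats)
  }
  counts <- purrr::imap_dfr(records, function(rec, sid) {
    kept <- filter_matches(rec, families, config$e_max, config$cov_min)
    count_matches(kept, families, sample_id = sid)
  })
  n_in <- sum(vapply(records, nrow, 1L))
  log <- stage_log(log, "filter", "%d records in, %d counted matches",
                   n_in, sum(counts$count))
  rpkg_tbl <- rpkg_table(counts, families, sample_stats)
  wide_counts <- tidyr::pivot_wider(counts, id_cols = "family_id",
                                    names_from = "sample_id",
                                    values_from = "count")
  ge <- setNames(sample_stats$genome_equivalents, sample_stats$sample_id)
  diff <- quasi_poisson_test(wide_counts, design, offset = log(ge))
  diff$fdr <- bh_adjust(diff$p_value)
  diff$significant <- !is.na(diff$fdr) & diff$fdr < config$alpha
  log <- stage_log(log, "quasipoisson", "%d/%d families significant",
                   sum(diff$significant), nrow(diff))
  summary <- list(n_samples = nrow(design), n_families = nrow(families),
                  n_records = n_in, n_counted = sum(counts$count),
                  n_significant = sum(diff$significant))
  out <- list(counts = counts, rpkg = rpkg_tbl, diff = diff,
              sample_stats = sample_stats, summary = summary, log = log)
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    readr::write_tsv(rpkg_tbl, file.path(config$out_dir, "rpkg_table.tsv"))
    readr::write_tsv(diff, file.path(config$out_dir, "diff_families.tsv"))
    jsonlite::write_json(summary,
                         file.path(config$out_dir, "functional_summary.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  out
}
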