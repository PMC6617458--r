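test_that("reference simulation is seed-deterministic and well-formed", {
  cfg <- small_config(seed = 17)
  r1 <- simulate_reference(cfg)
  r2 <- simulate_reference(cfg)
  expect_identical(r1$proteins, r2$proteins)
  expect_identical(r1$genomes, r2$genomes)
  expect_identical(r1$tree$nodes, r2$tree$nodes)

  cfg2 <- sim_config(seed = 3, n_genera = 2, proteins_per_taxon = 3,
                     protein_len_aa = c(50L, 60L),
                     base_abundances = c(0.5, 0.5))
  r <- simulate_reference(cfg2)
  genus_nodes <- r$tree$nodes[r$tree$nodes$rank == "genus", ]
  expect_equal(nrow(genus_nodes), 2L)
  phyla <- r$tree$nodes[r$tree$nodes$rank == "phylum", ]
  expect_equal(nrow(phyla), 2L) # each genus under its own phylum
})

test_that("genera share no 9-mer (brute-force intersection)", {
  ref <- small_reference()
  km <- lapply(split(ref$proteins$sequence, ref$proteins$genus_taxid),
               function(seqs) {
                 unique(unlist(lapply(seqs, function(s) {
                   n <- nchar(s)
                   substring(s, 1:(n - 8), 9:n)
                 })))
               })
  gids <- names(km)
  for (i in seq_along(gids)) for (j in seq_len(i - 1)) {
    expect_length(intersect(km[[i]], km[[j]]), 0)
  }
})

test_that("community reads follow configured proportions with full truth", {
  ref <- small_reference()
  corpus <- simulate_community_reads(ref)
  c2 <- simulate_community_reads(ref)
  expect_identical(corpus$reads, c2$reads) # determinism

  expect_equal(nrow(corpus$samples), 8L)
  expect_equal(sum(lengths(corpus$reads)), 8L * 800L)
  # per-sample truth counts match the emitted reads
  for (sid in names(corpus$reads)) {
    tp <- corpus$truth$proportions
    expect_equal(sum(tp$true_count[tp$sample_id == sid]),
                 length(corpus$reads[[sid]]))
  }
  # binomial bound: observed genus share within 3 sd of the drawn truth
  tp1 <- corpus$truth$proportions[corpus$truth$proportions$sample_id ==
                                    "PS1", ]
  n <- sum(tp1$true_count)
  sd3 <- 3 * sqrt(tp1$true_prop * (1 - tp1$true_prop) / n)
  expect_true(all(abs(tp1$true_count / n - tp1$true_prop) <= sd3 + 1e-9))

  # depth 0: empty FASTQ, valid truth
  cfg0 <- small_config(seed = 2, depth_reads = 0L)
  ref0 <- simulate_reference(cfg0)
  c0 <- simulate_community_reads(ref0, cfg0)
  expect_true(all(lengths(c0$reads) == 0))
  expect_equal(nrow(c0$truth$proportions), 8L * 5L)
})

test_that("error-free single-genus reads classify entirely to that genus", {
  cfg <- sim_config(seed = 6, n_genera = 2, proteins_per_taxon = 5,
                    protein_len_aa = c(80L, 120L), depth_reads = 300L,
                    read_len_nt = 150L, n_replicates_per_group = 1L,
                    base_abundances = c(1 - 1e-9, 1e-9))
  ref <- simulate_reference(cfg)
  corpus <- simulate_community_reads(ref, cfg)
  idx <- build_kmer_index(ref$proteins, ref$tree)
  res <- classify_sample(corpus$reads[[1]], idx, ref$tree)
  expect_equal(attr(res, "fraction_assigned"), 1)
  g <- genus_of(ref$tree, res$taxid)
  expect_true(all(g == ref$genomes$genus_taxid[1]))
})

test_that("classification of the error-free corpus reproduces truth exactly", {
  ref <- small_reference()
  corpus <- simulate_community_reads(ref)
  idx <- build_kmer_index(ref$proteins, ref$tree)
  asg <- lapply(corpus$reads, classify_sample, index = idx,
                tree = ref$tree)
  tab <- build_genus_table(asg, ref$tree)
  truth <- corpus$truth$proportions
  for (sid in names(corpus$reads)) {
    got <- setNames(tab[[sid]], tab$taxid)
    want <- setNames(truth$true_count[truth$sample_id == sid],
                     truth$genus_taxid[truth$sample_id == sid])
    want <- want[want > 0]
    expect_equal(got[names(want)], want[names(want)])
  }
})

test_that("simulated match tables recover truth counts after filtering", {
  cfg <- small_config(seed = 23)
  fam <- gene_family_registry()
  sim <- simulate_gene_matches(cfg, fam)
  sim2 <- simulate_gene_matches(cfg, fam)
  expect_identical(sim$records, sim2$records) # determinism
  for (sid in names(sim$records)) {
    kept <- filter_matches(sim$records[[sid]], fam)
    cnt <- count_matches(kept, fam, sid)
    want <- sim$truth[sim$truth$sample_id == sid, ]
    expect_equal(cnt$count[match(want$family_id, cnt$family_id)],
                 want$true_count)
  }
})

test_that("null families have equal group means within Poisson error", {
  cfg <- small_config(seed = 29)
  cfg$family_effects <- c(GH18 = 1) # all-null configuration
  sim <- simulate_gene_matches(cfg)
  truth <- merge(sim$truth, sim$design, by = "sample_id")
  agg <- tapply(truth$true_count, list(truth$family_id, truth$group), sum)
  # pooled two-sample Poisson z-scores
  z <- (agg[, 1] - agg[, 2]) / sqrt(agg[, 1] + agg[, 2] + 1)
  expect_true(all(abs(z) < 4.5))
})

test_that("zero-rate families emit no matches", {
  cfg <- small_config(seed = 31)
  fam <- gene_family_registry()
  cfg$family_base_rate <- setNames(c(0, rep(20, nrow(fam) - 1)),
                                   fam$family_id)
  sim <- simulate_gene_matches(cfg, fam)
  truth <- sim$truth[sim$truth$family_id == fam$family_id[1], ]
  expect_true(all(truth$true_count == 0))
})

test_that("overlap mode drives shared k-mers to the genus LCA", {
  ref <- simulate_reference(small_config(seed = 37, overlap = TRUE))
  idx <- build_kmer_index(ref$proteins, ref$tree)
  ranks <- ref$tree$nodes$rank[match(idx$taxids, ref$tree$nodes$taxid)]
  expect_true(any(ranks == "genus")) # shared proteins -> genus values
  expect_true(any(ranks == "species"))
})
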