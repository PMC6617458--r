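test_that("ORF finder reports maximal stop-free stretches across frames", {
  dna <- paste0("ATG", strrep("GCT", 40), "TAA")
  orfs <- find_orfs(dna, min_len_aa = 30)
  expect_true(paste0("M", strrep("A", 40)) %in% orfs)

  # stop-rich short sequence yields nothing at the default threshold
  set.seed(8)
  stops <- paste(sample(c("TAA", "TGA", "TAG", "GCT"), 20, replace = TRUE),
                 collapse = "")
  expect_true(all(nchar(find_orfs(stops, 30)) >= 30))

  # reverse-complement invariance of the ORF multiset
  set.seed(9)
  s <- paste(sample(c("A", "C", "G", "T"), 400, replace = TRUE),
             collapse = "")
  expect_equal(sort(find_orfs(s, 15)), sort(find_orfs(revcomp(s), 15)))
})

test_that("domtblout reader parses, errors and round-trips", {
  expect_equal(nrow(read_domtblout(character())), 0L)
  line <- paste("read7 - 999 GH18 - 308 1e-18 88.1 0.0 1 1 2e-19 1e-20",
                "88.1 0.0 10 200 12 202 8 205 0.95 -")
  rec <- read_domtblout(c("# comment", line))
  expect_equal(rec$read_id, "read7")
  expect_equal(rec$family_id, "GH18")
  expect_equal(rec$e_value, 1e-20)
  expect_equal(rec$hmm_from, 10L)
  expect_equal(rec$hmm_to, 200L)
  expect_error(read_domtblout("read7 GH18 1e-20"), "line 1")

  f <- withr::local_tempfile()
  write_domtblout(rec, f)
  back <- read_domtblout(f)
  expect_equal(back[, c("read_id", "family_id", "e_value", "hmm_from",
                        "hmm_to")],
               rec[, c("read_id", "family_id", "e_value", "hmm_from",
                       "hmm_to")])
})

test_that("match filter applies inclusive e-value and model-coverage cuts", {
  fam <- gene_family_registry()
  L <- fam$model_length_aa[fam$family_id == "GH20"] # 347
  span60 <- ceiling(0.60 * L)
  rec <- tibble::tibble(
    read_id = c("a", "b", "c"),
    family_id = "GH20",
    e_value = c(1e-10, 1e-9, 1e-20),
    hmm_from = 1L,
    hmm_to = as.integer(c(span60, L, span60 - 1L)),
    bitscore = 100)
  kept <- filter_matches(rec, fam)
  expect_equal(kept$read_id, "a") # boundary e and boundary coverage kept
  expect_equal(filter_matches(kept, fam), kept) # idempotent
  expect_error(filter_matches(dplyr::mutate(rec, family_id = "nope"), fam),
               "unknown family_id")

  # randomized predicate oracle
  set.seed(14)
  n <- 1000
  fam_ids <- sample(fam$family_id, n, replace = TRUE)
  Ls <- fam$model_length_aa[match(fam_ids, fam$family_id)]
  from <- pmax(1L, as.integer(runif(n, 1, Ls / 2)))
  to <- pmin(Ls, as.integer(from + runif(n, 0, Ls)))
  recs <- tibble::tibble(read_id = paste0("r", 1:n), family_id = fam_ids,
                         e_value = 10^-runif(n, 5, 15),
                         hmm_from = from, hmm_to = to, bitscore = 50)
  kept2 <- filter_matches(recs, fam)
  manual <- recs[recs$e_value <= 1e-10 &
                   (recs$hmm_to - recs$hmm_from + 1) / Ls >= 0.60, ]
  expect_equal(kept2, manual)
})

test_that("match counting deduplicates reads per family", {
  fam <- gene_family_registry()
  rec <- tibble::tibble(
    read_id = c("r1", "r1", "r1", "r2"),
    family_id = c("GH18", "GH18", "GH20", "GH18"),
    e_value = c(1e-20, 1e-30, 1e-15, 1e-12),
    hmm_from = 1L, hmm_to = 300L, bitscore = 100)
  cnt <- count_matches(rec, fam, "s1")
  expect_equal(cnt$count[cnt$family_id == "GH18"], 2L)
  expect_equal(cnt$count[cnt$family_id == "GH20"], 1L)
  expect_equal(sum(cnt$count), 3L)
  # shuffle invariance
  set.seed(2)
  cnt2 <- count_matches(rec[sample(nrow(rec)), ], fam, "s1")
  expect_equal(cnt2, cnt)
})

test_that("genome-equivalents arithmetic and marker estimation behave", {
  # known AGS: 10,000 reads x 200 bp over 2 Mb genomes -> GE = 1
  st <- estimate_genome_equivalents(10000, 10000 * 200, ags = 2e6)
  expect_equal(st$genome_equivalents, 1.0)
  expect_equal(st$average_genome_size_bp, 2e6)

  # single marker at its expected hit rate recovers AGS exactly
  G <- 2e6; L <- 300L; R <- 10000
  hits <- R * (3 * L) / G
  st2 <- estimate_genome_equivalents(
    R, R * 200,
    marker_set = tibble::tibble(marker_id = "m1", length_aa = L),
    marker_hits = tibble::tibble(marker_id = "m1", hits = hits))
  expect_equal(st2$average_genome_size_bp, G)

  # doubling depth doubles GE, AGS unchanged
  st3 <- estimate_genome_equivalents(
    2 * R, 2 * R * 200,
    marker_set = tibble::tibble(marker_id = "m1", length_aa = L),
    marker_hits = tibble::tibble(marker_id = "m1", hits = 2 * hits))
  expect_equal(st3$average_genome_size_bp, st2$average_genome_size_bp)
  expect_equal(st3$genome_equivalents, 2 * st2$genome_equivalents)

  expect_error(estimate_genome_equivalents(
    R, R * 200,
    marker_set = tibble::tibble(marker_id = "m1", length_aa = L),
    marker_hits = tibble::tibble(marker_id = "m1", hits = 0)),
    "no marker has hits")
})

test_that("rpkg arithmetic, zero count and depth invariance", {
  expect_equal(rpkg(30, 1000, 2), 5.0)
  expect_equal(rpkg(0, 500, 3), 0)
  expect_equal(rpkg(60, 1000, 4), rpkg(30, 1000, 2), tolerance = 1e-12)
  expect_error(rpkg(10, 100, 0), "genome_equivalents")
  # aa unit is x3 the nt-unit value
  expect_equal(rpkg(30, 1000, 2, unit = "aa"), 15)
})

test_that("family registry holds the expected families with unique ids", {
  reg <- gene_family_registry()
  expect_equal(reg$category[reg$family_id == "GH19"], "chitinase_GH19")
  expect_true("nosZ_atypical2" %in% reg$family_id)
  expect_equal(anyDuplicated(reg$family_id), 0L)
  expect_equal(sum(reg$category == "ncycle"), 14L)
  expect_equal(sum(reg$category != "ncycle"), 10L)
  expect_true(all(reg$model_length_aa > 0))
  reg2 <- gene_family_registry(model_lengths = c(GH18 = 500L))
  expect_equal(reg2$model_length_aa[reg2$family_id == "GH18"], 500L)
  expect_error(gene_family_registry(model_lengths = c(bogus = 10L)))
})
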