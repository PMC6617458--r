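test_that("six-frame translation matches hand translation and conventions", {
  expect_equal(unname(six_frame_translate("ATGAAA")),
               c("MK", "*", "E", "FH", "F", "S"))
  expect_equal(unname(six_frame_translate("")), rep("", 6))
  expect_equal(unname(six_frame_translate("ATGNAA"))[1], "MX")
  expect_error(six_frame_translate("ATG1AA"), "invalid nucleotide")
})

test_that("translation is strand-symmetric on random sequences", {
  set.seed(21)
  for (i in 1:10) {
    s <- paste(sample(c("A", "C", "G", "T"), 300, replace = TRUE),
               collapse = "")
    fw <- six_frame_translate(s)
    rv <- six_frame_translate(revcomp(s))
    expect_equal(unname(rv[1:3]), unname(fw[4:6]))
    expect_equal(unname(rv[4:6]), unname(fw[1:3]))
  }
})

test_that("consensus descent follows the threshold rule", {
  tr <- toy_tree()
  expect_equal(consensus_taxon(rep(10, 5), tr), 10)     # unanimous
  expect_identical(consensus_taxon(integer(), tr), UNCLASSIFIED)
  expect_identical(consensus_taxon(c(1, 1, 1), tr), UNCLASSIFIED) # root only
  hits <- c(rep(11, 8), rep(12, 2)) # sibling species under genus 10
  expect_equal(consensus_taxon(hits, tr, f = 0.8), 11)
  expect_equal(consensus_taxon(hits, tr, f = 0.9), 10)
  expect_error(consensus_taxon(hits, tr, f = 0.5), "0.5")
})

test_that("consensus with f = 1 equals the LCA of non-root hits", {
  ref <- small_reference()
  tree <- ref$tree
  non_root <- setdiff(tree$nodes$taxid, tree$nodes$taxid[tree$root_pos])
  set.seed(33)
  for (i in 1:200) {
    hits <- sample(non_root, sample(1:6, 1), replace = TRUE)
    expect_equal(consensus_taxon(hits, tree, f = 1.0),
                 lca_bruteforce(tree, unique(hits)))
  }
})

test_that("classify_read recovers the source taxon of CDS fragments", {
  ref <- small_reference()
  idx <- build_kmer_index(ref$proteins, ref$tree)
  p <- ref$proteins[3, ]
  cds <- ref$cds[ref$cds$protein_id == p$protein_id, ]
  g <- ref$genomes$sequence[ref$genomes$genus_taxid == cds$genus_taxid]
  frag <- substr(g, cds$start + 30, cds$start + 230)
  a <- classify_read(frag, idx, ref$tree)
  expect_gt(a$n_hits, 0)
  # assigned to the protein's taxon or one of its ancestors
  expect_equal(lca_bruteforce(ref$tree, c(a$taxid, p$taxid)), a$taxid)
  anc_genus <- genus_of(ref$tree, a$taxid)
  expect_true(is.na(anc_genus) || anc_genus == cds$genus_taxid)

  set.seed(12)
  rnd <- paste(sample(c("A", "C", "G", "T"), 200, replace = TRUE),
               collapse = "")
  r <- classify_read(rnd, idx, ref$tree)
  expect_identical(r$taxid, UNCLASSIFIED)
  expect_equal(r$n_hits, 0L)

  short <- classify_read("ATGCATGCA", idx, ref$tree) # < 3k+2 nt
  expect_identical(short$taxid, UNCLASSIFIED)
})

test_that("classify_sample reports fraction assigned and tolerates junk", {
  ref <- small_reference()
  idx <- build_kmer_index(ref$proteins, ref$tree)
  empty <- classify_sample(character(), idx, ref$tree)
  expect_equal(nrow(empty), 0L)
  expect_equal(attr(empty, "fraction_assigned"), 0)

  # mixed fixture: 4 classifiable CDS fragments + 6 random reads
  cds <- ref$cds[1:4, ]
  frags <- vapply(seq_len(4), function(i) {
    g <- ref$genomes$sequence[ref$genomes$genus_taxid ==
                                cds$genus_taxid[i]]
    substr(g, cds$start[i] + 3, cds$start[i] + 182)
  }, "")
  set.seed(99)
  junk <- vapply(1:6, function(i)
    paste(sample(c("A", "C", "G", "T"), 180, replace = TRUE),
          collapse = ""), "")
  res <- classify_sample(c(frags, junk), idx, ref$tree)
  expect_equal(attr(res, "fraction_assigned"), 0.4)

  # order invariance
  set.seed(100)
  res2 <- classify_sample(sample(c(frags, junk)), idx, ref$tree)
  expect_equal(attr(res2, "fraction_assigned"), 0.4)

  # unreadable record: skipped with warning, still counted in total
  expect_warning(res3 <- classify_sample(c(frags, "ACGT123"), idx,
                                         ref$tree),
                 "unreadable")
  expect_equal(attr(res3, "fraction_assigned"), 4 / 5)
})

test_that("classify_sample reads FASTA and FASTQ files", {
  ref <- small_reference()
  idx <- build_kmer_index(ref$proteins, ref$tree)
  corpus <- simulate_community_reads(ref)
  dir <- withr::local_tempdir()
  paths <- write_community_fastq(corpus, dir)
  res <- classify_sample(file.path(dir, "PS1.fastq.gz"), idx, ref$tree)
  expect_equal(nrow(res), length(corpus$reads$PS1))
  expect_gt(attr(res, "fraction_assigned"), 0.95)
})

test_that("genus table columns follow sample order and library sizes", {
  ref <- small_reference()
  idx <- build_kmer_index(ref$proteins, ref$tree)
  corpus <- simulate_community_reads(ref)
  asg <- lapply(corpus$reads[c("PS1", "CH1")], classify_sample,
                index = idx, tree = ref$tree)
  tab <- build_genus_table(asg, ref$tree)
  expect_equal(names(tab), c("taxid", "name", "PS1", "CH1"))
  libs <- attr(tab, "library_sizes")
  expect_true(all(colSums(tab[, c("PS1", "CH1")]) <= libs))
  rel <- build_genus_table(asg, ref$tree, relative = TRUE)
  expect_true(all(abs(colSums(rel[, c("PS1", "CH1")]) - 1) < 1e-12))
})
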