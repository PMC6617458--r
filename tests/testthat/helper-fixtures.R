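# Shared in-code fixtures: a small hand-built taxonomy and scaled-down
# simulated corpora (full-scale corpora are exercised in the acceptance
# tests only).

toy_tree <- function() {
  taxonomy(data.frame(
    taxid        = c(1, 2, 3, 10, 11, 12, 20, 21),
    parent_taxid = c(1, 1, 2, 3, 10, 10, 3, 20),
    rank = c("root", "superkingdom", "phylum", "genus", "species",
             "species", "genus", "species"),
    name = c("root", "Bacteria", "Proteobacteria", "Cellvibrio",
             "C. sp1", "C. sp2", "Nitrosospira", "N. sp1")))
}

small_config <- function(seed = 1L, ...) {
  defaults <- list(seed = seed, n_genera = 5L, proteins_per_taxon = 6L,
                   protein_len_aa = c(60L, 120L), depth_reads = 800L,
                   read_len_nt = 150L,
                   base_abundances = c(0.4, 0.3, 0.15, 0.1, 0.05),
                   genus_effects = c(genus_04 = 4))
  do.call(sim_config, utils::modifyList(defaults, list(...)))
}

small_reference <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- simulate_reference(small_config())
    cache
  }
})

# genus ancestor taxid (or NA) for each of a vector of taxids
genus_of <- function(tree, taxids) {
  vapply(taxids, function(t) {
    if (is.na(t)) return(NA_integer_)
    p <- match(t, tree$nodes$taxid)
    repeat {
      if (tree$nodes$rank[p] == "genus") return(tree$nodes$taxid[p])
      pp <- tree$parent_pos[p]
      if (pp == p) return(NA_integer_)
      p <- pp
    }
  }, 1L)
}

# brute-force LCA by root-path intersection (independent of lca())
lca_bruteforce <- function(tree, taxa) {
  paths <- lapply(taxa, function(t) {
    p <- match(t, tree$nodes$taxid)
    path <- p
    while (tree$parent_pos[p] != p) {
      p <- tree$parent_pos[p]
      path <- c(path, p)
    }
    tree$nodes$taxid[path]
  })
  common <- Reduce(intersect, paths)
  depths <- tree$depth[match(common, tree$nodes$taxid)]
  common[which.max(depths)]
}
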