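#' @title Ranked taxonomies: load, query, aggregate
#' @name taxonomy
#' @description
#' A `taxonomy` object is a rooted, ranked taxon hierarchy in the NCBI
#' taxdump dialect, the backbone for lowest-common-ancestor (LCA)
#' aggregation of per-9-mer taxon hits and for rolling read assignments up
#' to a reporting rank (typically genus). The rank vocabulary is fixed to
#' eight canonical values; all other ranks map to `no_rank`.
NULL

TAX_RANKS <- c("root", "superkingdom", "phylum", "class", "order",
               "family", "genus", "species", "no_rank")

new_taxonomy <- function(nodes) {
  nodes <- dplyr::arrange(nodes, .data$taxid)
  pos <- match(nodes$parent_taxid, nodes$taxid)
  root <- which(nodes$taxid == nodes$parent_taxid)
  if (length(root) != 1L)
    abort(sprintf("taxonomy must have exactly one root (found %d self-parent nodes)",
                  length(root)))
  if (anyNA(pos))
    abort(sprintf("structural error: parent taxid %d of node %d is absent",
                  nodes$parent_taxid[which(is.na(pos))[1]],
                  nodes$taxid[which(is.na(pos))[1]]))
  if (anyDuplicated(nodes$taxid))
    abort("taxids must be unique")
  depth <- rep(NA_integer_, nrow(nodes))
  depth[root] <- 0L
  # BFS from root; anything unreached sits on a cycle
  frontier <- root
  while (length(frontier)) {
    kids <- which(pos %in% frontier & is.na(depth))
    depth[kids] <- depth[pos[kids]] + 1L
    frontier <- kids
  }
  if (anyNA(depth))
    abort(sprintf("structural error: cycle involving taxid %d",
                  nodes$taxid[which(is.na(depth))[1]]))
  structure(
    list(nodes = nodes, parent_pos = pos, depth = depth, root_pos = root),
    class = "taxonomy"
  )
}

#' Build a taxonomy from a node table
#'
#' @param nodes A data frame with columns `taxid`, `parent_taxid`, `rank`
#'   and optionally `name`. Exactly one node must be its own parent (the
#'   root); every other parent must be present; taxids must be unique.
#' @return A `taxonomy` object.
#' @export
taxonomy <- function(nodes) {
  nodes <- as_tibble(nodes)
  stopifnot(all(c("taxid", "parent_taxid", "rank") %in% names(nodes)))
  if (!"name" %in% names(nodes)) nodes$name <- NA_character_
  nodes$rank <- ifelse(nodes$rank %in% TAX_RANKS, nodes$rank, "no_rank")
  nodes$taxid <- as.integer(nodes$taxid)
  nodes$parent_taxid <- as.integer(nodes$parent_taxid)
  new_taxonomy(nodes[, c("taxid", "parent_taxid", "rank", "name")])
}

#' @export
print.taxonomy <- function(x, ...) {
  cat(sprintf("<taxonomy> %d nodes, %d ranks, root taxid %d\n",
              nrow(x$nodes), length(unique(x$nodes$rank)),
              x$nodes$taxid[x$root_pos]))
  print(utils::head(x$nodes, 5))
  invisible(x)
}

parse_dmp <- function(lines, n_fields, what) {
  lines <- lines[nzchar(lines)]
  stripped <- sub("\t\\|$", "", lines)
  parts <- strsplit(stripped, "\t\\|\t")
  bad <- which(vapply(parts, length, 1L) < n_fields)
  if (length(bad))
    abort(sprintf("malformed %s line %d: fewer than %d fields",
                  what, bad[1], n_fields))
  parts
}

#' Load an NCBI-taxdump-dialect taxonomy
#'
#' Reads pipe-delimited `nodes.dmp` / `names.dmp` files (fields separated by
#' `"\t|\t"`, records terminated `"\t|"`). Only scientific names are
#' attached; ranks outside the canonical eight collapse to `no_rank`.
#'
#' @param nodes_source Path to (or character vector of lines of) a nodes file
#'   with fields taxid, parent taxid, rank.
#' @param names_source Optional path/lines of a names file with fields taxid,
#'   name, unique name, name class.
#' @return A `taxonomy`.
#' @export
load_taxonomy <- function(nodes_source, names_source = NULL) {
  read_lines <- function(x) if (length(x) == 1L && file.exists(x))
    readLines(x) else x
  np <- parse_dmp(read_lines(nodes_source), 3L, "nodes")
  nodes <- tibble(
    taxid = as.integer(vapply(np, `[[`, "", 1L)),
    parent_taxid = as.integer(vapply(np, `[[`, "", 2L)),
    rank = trimws(vapply(np, `[[`, "", 3L))
  )
  if (anyNA(nodes$taxid) || anyNA(nodes$parent_taxid))
    abort("malformed nodes file: non-integer taxid field")
  nodes$name <- NA_character_
  if (!is.null(names_source)) {
    mp <- parse_dmp(read_lines(names_source), 4L, "names")
    nm <- tibble(
      taxid = as.integer(vapply(mp, `[[`, "", 1L)),
      name = vapply(mp, `[[`, "", 2L),
      class = trimws(vapply(mp, `[[`, "", 4L))
    )
    nm <- nm[nm$class == "scientific name", ]
    nodes$name <- nm$name[match(nodes$taxid, nm$taxid)]
  }
  taxonomy(nodes)
}

#' Write a taxonomy in taxdump dialect
#'
#' @param tree A `taxonomy`.
#' @param nodes_path,names_path Output paths.
#' @return Invisibly, the paths written.
#' @export
write_taxonomy <- function(tree, nodes_path, names_path = NULL) {
  n <- tree$nodes
  writeLines(sprintf("%d\t|\t%d\t|\t%s\t|", n$taxid, n$parent_taxid, n$rank),
             nodes_path)
  if (!is.null(names_path)) {
    nm <- n[!is.na(n$name), ]
    writeLines(sprintf("%d\t|\t%s\t|\t\t|\tscientific name\t|",
                       nm$taxid, nm$name), names_path)
  }
  invisible(c(nodes_path, names_path))
}

tax_pos <- function(tree, taxids) {
  pos <- match(taxids, tree$nodes$taxid)
  if (anyNA(pos))
    abort(sprintf("unknown taxid: %d", taxids[which(is.na(pos))[1]]))
  pos
}

root_path_pos <- function(tree, pos) {
  path <- pos
  while (tree$parent_pos[pos] != pos) {
    pos <- tree$parent_pos[pos]
    path <- c(path, pos)
  }
  path
}

#' Lowest common ancestor of a set of taxa
#'
#' @param tree A `taxonomy`.
#' @param taxa Non-empty vector of taxids present in `tree`.
#' @return The taxid of the deepest node that is an ancestor-or-self of every
#'   input taxon.
#' @export
lca <- function(tree, taxa) {
  stopifnot(length(taxa) >= 1)
  pos <- unique(tax_pos(tree, taxa))
  common <- root_path_pos(tree, pos[1])
  for (p in pos[-1]) common <- intersect(common, root_path_pos(tree, p))
  tree$nodes$taxid[common[which.max(tree$depth[common])]]
}

ancestor_at_rank <- function(tree, pos, rank) {
  # position of the `rank` ancestor-or-self, or NA if the node sits above it
  repeat {
    if (tree$nodes$rank[pos] == rank) return(pos)
    parent <- tree$parent_pos[pos]
    if (parent == pos) return(NA_integer_)
    pos <- parent
  }
}

#' Roll taxon assignments up to a rank
#'
#' Each assignment at or below `rank` is counted at its `rank` ancestor;
#' assignments above `rank` (including any lacking a `rank` ancestor) are
#' excluded and reported via the `n_excluded` attribute.
#'
#' @param assignments Vector of taxids (a multiset; `NA` entries, i.e.
#'   unclassified, count as excluded).
#' @param tree A `taxonomy`.
#' @param rank One of the canonical ranks, e.g. `"genus"`.
#' @return A tibble with columns `taxid`, `name`, `count`, ordered by
#'   decreasing count, with attribute `n_excluded`.
#' @export
roll_up_to_rank <- function(assignments, tree, rank = "genus") {
  rank <- match.arg(rank, TAX_RANKS)
  keep <- !is.na(assignments)
  pos <- tax_pos(tree, assignments[keep])
  upos <- unique(pos)
  anc <- vapply(upos, function(p) ancestor_at_rank(tree, p, rank), 1L)
  anc_all <- anc[match(pos, upos)]
  counted <- !is.na(anc_all)
  tab <- table(anc_all[counted])
  out <- tibble(
    taxid = tree$nodes$taxid[as.integer(names(tab))],
    name = tree$nodes$name[as.integer(names(tab))],
    count = as.integer(tab)
  )
  out <- dplyr::arrange(out, dplyr::desc(.data$count))
  attr(out, "n_excluded") <- sum(!keep) + sum(!counted)
  out
}
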