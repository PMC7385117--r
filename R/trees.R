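#' Read a rooted species tree from Newick
#'
#' Thin wrapper around [ape::read.tree()] that validates the result: named
#' tips, unique tip labels, and a usable (rooted) topology. Trees read from
#' a basal trichotomy are accepted; Dollo reconstruction handles polytomies.
#'
#' @param path Path to a Newick file.
#' @return An [ape::phylo] object.
#' @export
read_species_tree <- function(path) {
  tree <- tryCatch(ape::read.tree(path), error = function(e) NULL)
  if (is.null(tree)) abort(sprintf("could not parse Newick file '%s'", path))
  if (inherits(tree, "multiPhylo")) tree <- tree[[1]]
  if (is.null(tree$tip.label) || any(!nzchar(tree$tip.label))) {
    abort("tree has unnamed tips")
  }
  if (anyDuplicated(tree$tip.label)) abort("tree has duplicated tip labels")
  tree
}

#' Reroot a tree on an outgroup
#'
#' Reroots with [ape::root()] (`resolve.root = TRUE`). The tip set and the
#' unrooted bipartition set are preserved; only the root position changes.
#'
#' @param tree An [ape::phylo] object.
#' @param outgroup Character vector of tip labels forming the outgroup.
#' @return The rerooted tree.
#' @export
reroot_tree <- function(tree, outgroup) {
  unknown <- setdiff(outgroup, tree$tip.label)
  if (length(unknown) > 0) {
    abort(sprintf("outgroup tip(s) not in tree: %s", paste(unknown, collapse = ", ")))
  }
  ape::root(tree, outgroup = outgroup, resolve.root = TRUE)
}

#' Canonical unrooted bipartition set of a tree
#'
#' Each internal edge splits the tips in two; a split is represented by the
#' side that does not contain the alphabetically first tip, sorted and
#' collapsed to a string, so representation is rotation- and root-invariant.
#' Trivial splits (single tip / all tips) are excluded.
#'
#' @param tree An [ape::phylo] object.
#' @return Sorted character vector of canonical split strings.
#' @export
tree_bipartitions <- function(tree) {
  tips <- sort(tree$tip.label)
  anchor <- tips[1]
  ntip <- length(tips)
  below <- clade_tip_sets(tree)
  splits <- character(0)
  for (node in seq_along(below)) {
    side <- below[[node]]
    if (length(side) <= 1 || length(side) >= ntip - 1) next
    if (anchor %in% side) side <- setdiff(tips, side)
    splits <- c(splits, paste(sort(side), collapse = "|"))
  }
  sort(unique(splits))
}

# list: for every node id (tips then internals), the tip labels below it
clade_tip_sets <- function(tree) {
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  sets <- vector("list", nnode)
  for (i in seq_len(ntip)) sets[[i]] <- tree$tip.label[i]
  edge <- ape::reorder.phylo(tree, "postorder")$edge
  for (k in seq_len(nrow(edge))) {
    p <- edge[k, 1]; ch <- edge[k, 2]
    sets[[p]] <- c(sets[[p]], sets[[ch]])
  }
  sets
}

#' Check taxon-name agreement between an orthogroup table, tree and panel
#'
#' Taxon names must match exactly (no prefix stripping) between the
#' analysis inputs. Reports the symmetric difference per input so mismatches
#' surface before any analysis runs.
#'
#' @param og Orthogroup count table ([read_orthogroups()]).
#' @param tree Optional [ape::phylo].
#' @param panel Optional habitat panel ([read_habitat_panel()]).
#' @return Tibble with columns `input`, `missing_from_matrix`,
#'   `missing_from_input` (comma-collapsed name lists); zero rows when all
#'   names agree.
#' @export
validate_taxa <- function(og, tree = NULL, panel = NULL) {
  taxa <- og_taxa(og)
  rows <- list()
  cmp <- function(input, other, subset_ok = FALSE) {
    a <- setdiff(other, taxa)
    b <- if (subset_ok) character(0) else setdiff(taxa, other)
    if (length(a) + length(b) == 0) return(NULL)
    tibble(
      input = input,
      missing_from_matrix = paste(a, collapse = ","),
      missing_from_input = paste(b, collapse = ",")
    )
  }
  if (!is.null(tree)) rows$tree <- cmp("tree", tree$tip.label)
  if (!is.null(panel)) {
    # a panel routinely covers a subset of the matrix taxa
    rows$panel <- cmp("panel", c(panel$marine_taxon, panel$freshwater_taxon),
      subset_ok = TRUE)
  }
  out <- bind_rows(rows)
  if (nrow(out) == 0) {
    out <- tibble(
      input = character(), missing_from_matrix = character(),
      missing_from_input = character()
    )
  }
  out
}
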