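# --- tree bookkeeping -------------------------------------------------------

# Precomputed indicator matrices for a rooted tree:
#   D: node x tip, TRUE iff the tip is in the node's clade (tips incl. self)
#   N: node x node, TRUE iff column node is in row node's subtree (incl. self)
tree_tables <- function(tree) {
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  D <- matrix(FALSE, nnode, ntip)
  D[cbind(seq_len(ntip), seq_len(ntip))] <- TRUE
  N <- diag(nnode) > 0
  edge <- ape::reorder.phylo(tree, "postorder")$edge
  for (k in seq_len(nrow(edge))) {
    p <- edge[k, 1]; ch <- edge[k, 2]
    D[p, ] <- D[p, ] | D[ch, ]
    N[p, ] <- N[p, ] | N[ch, ]
  }
  root <- setdiff(edge[, 1], edge[, 2])[1]
  list(ntip = ntip, nnode = nnode, D = D, N = N, edge = tree$edge, root = root)
}

#' Human-readable labels for all nodes of a tree
#'
#' Tips keep their labels; internal nodes use `tree$node.label` when
#' present and non-empty, else `node<N>`.
#'
#' @param tree An [ape::phylo] object.
#' @return Character vector indexed by ape node id.
#' @export
node_labels <- function(tree) {
  ntip <- length(tree$tip.label)
  internal <- tree$node.label
  if (is.null(internal) || !any(nzchar(internal))) {
    internal <- paste0("node", ntip + seq_len(tree$Nnode))
  } else {
    blank <- !nzchar(internal)
    internal[blank] <- paste0("node", ntip + which(blank))
  }
  c(tree$tip.label, internal)
}

# --- single-character Dollo --------------------------------------------------

#' Dollo origin of a presence pattern
#'
#' Under Dollo parsimony (one gain, irreversible loss) the unique
#' most-parsimonious origin of an orthogroup is the most recent common
#' ancestor of the tips that carry it.
#'
#' @param tree An [ape::phylo] object.
#' @param present_tips Non-empty character vector of tip labels.
#' @return The ape node id of the origin (a tip id when only one tip is
#'   present); its label is attached as the `label` attribute.
#' @export
dollo_origin <- function(tree, present_tips) {
  idx <- match_present(tree, present_tips)
  node <- if (length(idx) == 1) {
    idx
  } else {
    ape::getMRCA(tree, idx)
  }
  structure(node, label = node_labels(tree)[node])
}

#' Dollo loss edges of a presence pattern
#'
#' Within the origin's subtree, a node is "live" iff its clade contains at
#' least one present tip; the loss edges of the unique minimal single-gain
#' explanation are exactly the edges from a live parent to a non-live
#' child. Each loss is attributed to the child node of its edge.
#'
#' @inheritParams dollo_origin
#' @return Tibble with columns `parent`, `child` (ape node ids),
#'   `parent_label`, `child_label`; zero rows when no loss is needed.
#' @export
dollo_losses <- function(tree, present_tips) {
  idx <- match_present(tree, present_tips)
  tt <- tree_tables(tree)
  labs <- node_labels(tree)
  live <- rowSums(tt$D[, idx, drop = FALSE]) > 0
  origin <- as.integer(dollo_origin(tree, present_tips))
  keep <- live[tt$edge[, 1]] & !live[tt$edge[, 2]] & tt$N[origin, tt$edge[, 1]]
  e <- tt$edge[keep, , drop = FALSE]
  tibble(
    parent = e[, 1], child = e[, 2],
    parent_label = labs[e[, 1]], child_label = labs[e[, 2]]
  )
}

match_present <- function(tree, present_tips) {
  if (length(present_tips) == 0) abort("present_tips must be non-empty")
  idx <- match(present_tips, tree$tip.label)
  if (anyNA(idx)) {
    abort(sprintf(
      "tip(s) not in tree: %s",
      paste(present_tips[is.na(idx)], collapse = ", ")
    ))
  }
  unique(idx)
}

# --- matrix-level summary ----------------------------------------------------

#' Dollo gain/loss summary over an orthogroup matrix
#'
#' Maps every orthogroup present in at least one taxon onto the tree:
#' its origin is the MRCA of the taxa carrying it, and its losses are the
#' Dollo loss edges of its presence pattern. Orthogroups absent from every
#' analysis taxon are dropped with a warning (count recorded). The matrix
#' taxa must all be tree tips (hard error listing offenders); tree tips
#' without a matrix column are pruned first.
#'
#' Per-tip "gene gain" is reported under two definitions, both emitted:
#' `tip_gain_orthogroups` counts orthogroups whose origin is the terminal
#' edge of that tip, and `tip_gain_genes` counts the member genes of those
#' orthogroups in that tip plus the copy-number excess (`count - 1`) in
#' orthogroups that originated earlier — i.e. all genes attributable to
#' lineage-specific innovation plus duplication.
#'
#' @param og Orthogroup count table ([read_orthogroups()] or simulator).
#' @param tree Rooted [ape::phylo] whose tips cover the matrix taxa.
#' @return An object of class `gain_loss`: list with `nodes` (tibble:
#'   `node`, `label`, `is_tip`, `n_origins`, `n_losses`,
#'   `tip_gain_orthogroups`, `tip_gain_genes`), `origins` (per-orthogroup
#'   origin node), `losses` (per-orthogroup loss edges), `n_dropped`,
#'   `tree`. `sum(nodes$n_origins)` equals the number of retained
#'   orthogroups.
#' @export
summarize_gain_loss <- function(og, tree) {
  taxa <- og_taxa(og)
  offenders <- setdiff(taxa, tree$tip.label)
  if (length(offenders) > 0) {
    abort(sprintf(
      "matrix taxa missing from tree: %s", paste(offenders, collapse = ", ")
    ))
  }
  if (length(setdiff(tree$tip.label, taxa)) > 0) {
    tree <- ape::keep.tip(tree, taxa)
  }
  P <- og_presence_matrix(og)[, tree$tip.label, drop = FALSE]
  counts <- as.matrix(as.data.frame(og[og_taxa(og)]))[, tree$tip.label, drop = FALSE]
  rownames(counts) <- og$orthogroup
  empty <- rowSums(P) == 0
  n_dropped <- sum(empty)
  if (n_dropped > 0) {
    warn(sprintf("%d orthogroup(s) absent from every analysis taxon; dropped", n_dropped))
    P <- P[!empty, , drop = FALSE]
    counts <- counts[!empty, , drop = FALSE]
  }
  tt <- tree_tables(tree)
  labs <- node_labels(tree)
  nog <- nrow(P)
  nodes <- tibble(
    node = seq_len(tt$nnode), label = labs,
    is_tip = seq_len(tt$nnode) <= tt$ntip,
    n_origins = 0L, n_losses = 0L,
    tip_gain_orthogroups = NA_integer_, tip_gain_genes = NA_integer_
  )
  origins_tbl <- tibble(orthogroup = character(), node = integer())
  losses_tbl <- tibble(orthogroup = character(), parent = integer(), child = integer())
  if (nog > 0) {
    B <- (P * 1L) %*% t(tt$D * 1L) # og x node: present tips below node
    tot <- rowSums(P)
    cladesize <- rowSums(tt$D)
    score <- matrix(cladesize, nrow = nog, ncol = tt$nnode, byrow = TRUE)
    score[B != tot] <- Inf
    origin <- max.col(-score, ties.method = "first")
    marked <- B > 0
    loss_rows <- vector("list", nrow(tt$edge))
    n_losses <- integer(tt$nnode)
    for (k in seq_len(nrow(tt$edge))) {
      p <- tt$edge[k, 1]; ch <- tt$edge[k, 2]
      hit <- marked[, p] & !marked[, ch] & tt$N[cbind(origin, rep(p, nog))]
      if (any(hit)) {
        n_losses[ch] <- sum(hit)
        loss_rows[[k]] <- tibble(
          orthogroup = rownames(P)[hit], parent = p, child = ch
        )
      }
    }
    origins_tbl <- tibble(orthogroup = rownames(P), node = origin)
    losses_tbl <- bind_rows(loss_rows)
    nodes$n_origins <- tabulate(origin, nbins = tt$nnode)
    nodes$n_losses <- n_losses
    # tip gains under both definitions
    tip_og <- integer(tt$ntip)
    tip_gene <- integer(tt$ntip)
    for (t in seq_len(tt$ntip)) {
      own <- origin == t
      tip_og[t] <- sum(own)
      tip_gene[t] <- sum(counts[own, t]) + sum(pmax(counts[!own, t] - 1L, 0L))
    }
    nodes$tip_gain_orthogroups[seq_len(tt$ntip)] <- tip_og
    nodes$tip_gain_genes[seq_len(tt$ntip)] <- tip_gene
  }
  structure(
    list(
      nodes = nodes, origins = origins_tbl, losses = losses_tbl,
      n_dropped = n_dropped, tree = tree, criterion = "dollo"
    ),
    class = "gain_loss"
  )
}

#' @export
print.gain_loss <- function(x, ...) {
  cat(sprintf(
    "Dollo gain/loss summary: %d orthogroups mapped on %d tips (%d dropped as all-absent)\n",
    nrow(x$origins), length(x$tree$tip.label), x$n_dropped
  ))
  print(x$nodes, ...)
  invisible(x)
}

#' Contrast Dollo summaries under two root hypotheses
#'
#' Runs [summarize_gain_loss()] under two topologies over the same tip set
#' and aligns their internal nodes by clade tip content: a clade present in
#' both trees gets a row with both counts and their deltas.
#'
#' @param og Orthogroup count table.
#' @param tree_a,tree_b Two rooted trees over the same tip set (hard error
#'   otherwise).
#' @return List with `summary_a`, `summary_b` (class `gain_loss`) and
#'   `shared_clades`: tibble with `clade`, `n_origins_a/b`,
#'   `delta_origins`, `n_losses_a/b`, `delta_losses`.
#' @export
topology_contrast <- function(og, tree_a, tree_b) {
  if (!setequal(tree_a$tip.label, tree_b$tip.label)) {
    abort("tree_a and tree_b must have identical tip sets")
  }
  sa <- summarize_gain_loss(og, tree_a)
  sb <- suppressWarnings(summarize_gain_loss(og, tree_b))
  key <- function(s) {
    sets <- clade_tip_sets(s$tree)
    tibble(
      clade = vapply(sets, function(x) paste(sort(x), collapse = "|"), ""),
      n_origins = s$nodes$n_origins, n_losses = s$nodes$n_losses
    )
  }
  shared <- inner_join(key(sa), key(sb), by = "clade", suffix = c("_a", "_b")) |>
    mutate(
      delta_origins = .data$n_origins_b - .data$n_origins_a,
      delta_losses = .data$n_losses_b - .data$n_losses_a
    ) |>
    select(
      "clade", "n_origins_a", "n_origins_b", "delta_origins",
      "n_losses_a", "n_losses_b", "delta_losses"
    )
  list(summary_a = sa, summary_b = sb, shared_clades = shared)
}
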