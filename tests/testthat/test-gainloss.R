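balanced4 <- ape::read.tree(text = "((A,B),(C,D));")

# clade tip sets per node id, duplicated here to keep the check independent
# of the package's internal helper
syngloss_clade_sets <- function(tree) {
  ntip <- length(tree$tip.label)
  sets <- c(as.list(tree$tip.label), vector("list", tree$Nnode))
  edge <- ape::reorder.phylo(tree, "postorder")$edge
  for (k in seq_len(nrow(edge))) {
    sets[[edge[k, 1]]] <- c(sets[[edge[k, 1]]], sets[[edge[k, 2]]])
  }
  sets
}


test_that("Dollo origin is the MRCA of the present tips", {
  expect_equal(as.integer(dollo_origin(balanced4, c("A", "B", "C", "D"))), 5L) # root
  expect_equal(as.integer(dollo_origin(balanced4, "C")), 3L) # the tip itself
  expect_equal(as.integer(dollo_origin(balanced4, c("A", "C"))), 5L)
  expect_error(dollo_origin(balanced4, character(0)), "non-empty")
  expect_error(dollo_origin(balanced4, "Z"), "Z")
})

test_that("Dollo losses are live-parent to dead-child edges in the origin subtree", {
  expect_equal(nrow(dollo_losses(balanced4, c("A", "B", "C", "D"))), 0)
  l1 <- dollo_losses(balanced4, c("A", "B", "C"))
  expect_equal(l1$child_label, "D")
  l2 <- dollo_losses(balanced4, c("A", "C"))
  expect_setequal(l2$child_label, c("B", "D"))
})

test_that("single-character Dollo matches the exhaustive-assignment oracle", {
  set.seed(71)
  for (i in 1:6) {
    n <- sample(4:7, 1)
    tree <- ape::rtree(n, tip.label = paste0("t", 1:n), br = NULL)
    for (j in 1:8) {
      present <- sample(tree$tip.label, sample(n, 1))
      want <- oracle_dollo(tree, present)
      expect_equal(as.integer(dollo_origin(tree, present)), want$origin)
      expect_equal(sort(dollo_losses(tree, present)$child), want$loss_children)
    }
  }
})

test_that("matrix summary aggregates per-character reconstruction", {
  # all orthogroups everywhere: all origins at root, no losses, no tip gains
  og_all <- make_og(matrix(1L, 5, 4), c("A", "B", "C", "D"))
  s <- summarize_gain_loss(og_all, balanced4)
  expect_equal(s$nodes$n_origins, c(0L, 0L, 0L, 0L, 5L, 0L, 0L))
  expect_equal(sum(s$nodes$n_losses), 0)
  expect_equal(s$nodes$tip_gain_orthogroups[1:4], rep(0L, 4))

  # toy 6-orthogroup matrix: compare each node count to oracle sums
  counts <- rbind(
    c(1L, 1L, 1L, 1L), # root, no loss
    c(1L, 1L, 1L, 0L), # loss in D
    c(1L, 0L, 1L, 0L), # origin root, losses B and D
    c(0L, 0L, 2L, 1L), # origin (C,D) clade
    c(3L, 0L, 0L, 0L), # tip gain A
    c(0L, 1L, 0L, 0L)  # tip gain B
  )
  og <- make_og(counts, c("A", "B", "C", "D"))
  s2 <- summarize_gain_loss(og, balanced4)
  origins <- integer(7); losses <- integer(7)
  for (r in seq_len(nrow(counts))) {
    present <- c("A", "B", "C", "D")[counts[r, ] > 0]
    o <- oracle_dollo(balanced4, present)
    origins[o$origin] <- origins[o$origin] + 1L
    for (ch in o$loss_children) losses[ch] <- losses[ch] + 1L
  }
  expect_equal(s2$nodes$n_origins, origins)
  expect_equal(s2$nodes$n_losses, losses)
  expect_equal(sum(s2$nodes$n_origins), nrow(counts)) # conservation
  # tip gains: orthogroup-level and gene-level definitions
  gains <- s2$nodes$tip_gain_orthogroups[1:4]
  expect_equal(gains, c(1L, 1L, 0L, 0L))
  # A: 3 genes in its own orthogroup + no excess copies elsewhere
  expect_equal(s2$nodes$tip_gain_genes[1], 3L)
  # C: no own orthogroup; one excess copy in row 4
  expect_equal(s2$nodes$tip_gain_genes[3], 1L)
})

test_that("all-absent orthogroups are dropped with a warning", {
  og <- make_og(rbind(c(1L, 1L, 1L, 1L), c(0L, 0L, 0L, 0L)), c("A", "B", "C", "D"))
  expect_warning(s <- summarize_gain_loss(og, balanced4), "absent")
  expect_equal(s$n_dropped, 1L)
  expect_equal(nrow(s$origins), 1)
})

test_that("taxon mismatches error; extra tree tips are pruned", {
  og <- make_og(matrix(1L, 2, 2), c("A", "Z"))
  expect_error(summarize_gain_loss(og, balanced4), "Z")
  og2 <- make_og(matrix(1L, 2, 3), c("A", "B", "C"))
  s <- summarize_gain_loss(og2, balanced4) # D pruned, no phantom losses
  expect_equal(sum(s$nodes$n_losses), 0)
})

test_that("summaries depend on rooted topology, not Newick rotation", {
  set.seed(72)
  og <- make_og(matrix(rbinom(40, 2, 0.6), 10, 4), c("A", "B", "C", "D"))
  rotated <- ape::read.tree(text = "((D,C),(B,A));")
  s1 <- summarize_gain_loss(og, balanced4)
  s2 <- summarize_gain_loss(og, rotated)
  # compare counts keyed by clade tip-content, which is rotation-invariant
  clades <- function(s) {
    D <- syngloss_clade_sets(s$tree)
    tibble::tibble(
      clade = vapply(D, function(x) paste(sort(x), collapse = "|"), ""),
      n_origins = s$nodes$n_origins, n_losses = s$nodes$n_losses
    )
  }
  c1 <- dplyr::arrange(clades(s1), clade)
  c2 <- dplyr::arrange(clades(s2), clade)
  expect_equal(c1, c2)
})

test_that("topology contrast aligns shared clades and reports deltas", {
  og <- make_og(rbind(
    c(1L, 1L, 1L, 1L, 1L), c(1L, 1L, 0L, 0L, 0L), c(0L, 0L, 1L, 1L, 1L)
  ), c("A", "B", "C", "D", "E"))
  tree_a <- ape::read.tree(text = "(((A,B),(C,D)),E);")
  same <- topology_contrast(og, tree_a, tree_a)
  expect_true(all(same$shared_clades$delta_origins == 0))
  expect_true(all(same$shared_clades$delta_losses == 0))

  tree_b <- ape::read.tree(text = "(((C,D),(A,B)),E);") # rotation only
  rot <- topology_contrast(og, tree_a, tree_b)
  expect_true(all(rot$shared_clades$delta_origins == 0))

  tree_c <- ape::read.tree(text = "((A,B),((C,D),E));") # different root split
  swap <- topology_contrast(og, tree_a, tree_c)
  # per-clade counts must equal independent per-character oracle runs
  for (tr in list(tree_a, tree_c)) {
    s <- suppressWarnings(summarize_gain_loss(og, tr))
    for (r in 1:3) {
      present <- c("A", "B", "C", "D", "E")[as.matrix(as.data.frame(og[, -1]))[r, ] > 0]
      o <- oracle_dollo(tr, present)
      expect_true(s$origins$node[s$origins$orthogroup == og$orthogroup[r]] == o$origin)
    }
  }
  expect_error(topology_contrast(og, tree_a, balanced4), "tip sets")
})
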