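pairs_on <- function(genes_a, genes_b) tibble::tibble(gene_a = genes_a, gene_b = genes_b)

test_that("oxford grid counts pairs per scaffold pair with pair-universe margins", {
  annot_a <- make_annotation(list(sA1 = paste0("a", 1:4)), "A")
  annot_b <- make_annotation(list(sB1 = paste0("b", 1:4)), "B")
  dots <- synteny_dots(pairs_on(paste0("a", 1:4), paste0("b", 1:4)), annot_a, annot_b)
  cells <- oxford_grid(dots)
  expect_equal(nrow(cells), 1)
  expect_equal(cells$n_shared, 4L)
  expect_equal(cells$row_margin, 4L)
  expect_equal(cells$col_margin, 4L)
  expect_equal(cells$n_total, 4L)

  annot_a2 <- make_annotation(list(s1 = c("a1", "a2"), s2 = c("a3", "a4")), "A")
  annot_b2 <- make_annotation(list(u1 = c("b1", "b2"), u2 = c("b3", "b4")), "B")
  cells2 <- oxford_grid(synteny_dots(
    pairs_on(paste0("a", 1:4), paste0("b", 1:4)), annot_a2, annot_b2
  ))
  expect_equal(nrow(cells2), 2)
  expect_equal(cells2$n_shared, c(2L, 2L))
  expect_equal(sum(cells2$n_shared), cells2$n_total[1])
})

test_that("oxford grid equals a nested-loop tally on random pairings", {
  set.seed(51)
  for (rep in 1:5) {
    annot_a <- make_annotation(split(paste0("a", 1:30), sample(paste0("sa", 1:3), 30, TRUE)), "A")
    annot_b <- make_annotation(split(paste0("b", 1:30), sample(paste0("sb", 1:3), 30, TRUE)), "B")
    pr <- pairs_on(paste0("a", sample(30)), paste0("b", sample(30)))[1:25, ]
    dots <- synteny_dots(pr, annot_a, annot_b)
    cells <- oxford_grid(dots)
    # oracle: double loop over pairs
    tally <- list()
    for (i in seq_len(nrow(pr))) {
      sa <- annot_a$scaffold_id[annot_a$gene_id == pr$gene_a[i]]
      sb <- annot_b$scaffold_id[annot_b$gene_id == pr$gene_b[i]]
      key <- paste(sa, sb)
      tally[[key]] <- (tally[[key]] %||% 0L) + 1L
    }
    expect_equal(nrow(cells), length(tally))
    for (i in seq_len(nrow(cells))) {
      expect_equal(cells$n_shared[i], tally[[paste(cells$scaffold_a[i], cells$scaffold_b[i])]])
    }
    expect_equal(sum(cells$n_shared), nrow(pr))
  }
})

test_that("pairs with unannotated genes warn-and-drop by default, error on request", {
  annot_a <- make_annotation(list(s1 = "a1"), "A")
  annot_b <- make_annotation(list(u1 = "b1"), "B")
  pr <- pairs_on(c("a1", "aX"), c("b1", "b2"))
  expect_warning(dots <- synteny_dots(pr, annot_a, annot_b), "dropped")
  expect_equal(nrow(dots), 1)
  expect_error(synteny_dots(pr, annot_a, annot_b, missing = "error"), "missing")
})

test_that("hypergeometric enrichment matches exhaustive enumeration", {
  cell <- tibble::tibble(
    scaffold_a = "s", scaffold_b = "u",
    n_shared = 4L, row_margin = 5L, col_margin = 8L, n_total = 20L
  )
  got <- cell_enrichment(cell)
  expect_equal(got$p_hyper, oracle_hyper_tail(4, 5, 8, 20), tolerance = 1e-14)
  expect_equal(got$p_hyper, 7280 / 125970, tolerance = 1e-12)

  zero <- dplyr::mutate(cell, n_shared = 0L)
  expect_equal(cell_enrichment(zero)$p_hyper, 1)

  all_in <- tibble::tibble(
    scaffold_a = "s", scaffold_b = "u",
    n_shared = 9L, row_margin = 9L, col_margin = 9L, n_total = 9L
  )
  expect_equal(cell_enrichment(all_in)$p_hyper, 1)

  bad <- dplyr::mutate(cell, n_shared = 9L) # > min(margins)
  expect_error(cell_enrichment(bad), "margins")
})

test_that("BH q-values dominate p-values over the cell set", {
  set.seed(52)
  cells <- tibble::tibble(
    scaffold_a = paste0("s", 1:6), scaffold_b = paste0("u", 1:6),
    n_shared = c(5L, 1L, 3L, 2L, 4L, 1L), row_margin = 6L, col_margin = 6L,
    n_total = 30L
  )
  got <- cell_enrichment(cells)
  expect_true(all(got$q_value >= got$p_hyper))
  expect_equal(got$q_value, p.adjust(got$p_hyper, "BH"))
})

test_that("co-linearity statistics behave on canonical orders", {
  ident <- colinearity_stats(0:4, 0:4)
  expect_equal(ident$spearman_rho, 1)
  expect_equal(ident$lis_fraction, 1)

  rev <- colinearity_stats(0:4, 4:0)
  expect_equal(rev$spearman_rho, -1)
  expect_equal(rev$lis_fraction, 1) # whole-arm inversion still co-linear

  mixed <- colinearity_stats(0:3, c(1, 3, 2, 4))
  expect_equal(mixed$spearman_rho, 0.8) # 1 - 6*2/(4*15)
  expect_equal(mixed$lis_fraction, 0.75)

  short <- colinearity_stats(0, 3)
  expect_true(is.na(short$spearman_rho) && is.na(short$lis_fraction))
  expect_true(is.na(colinearity_stats(0:1, c(5, 2))$spearman_rho)) # < 3 pairs
})

test_that("lis_length matches exhaustive subsequence enumeration", {
  set.seed(53)
  for (i in 1:20) {
    x <- sample(10, sample(1:9, 1))
    expect_equal(lis_length(x), oracle_lis(x))
  }
})

test_that("lis_fraction is invariant under global reversal of either axis", {
  set.seed(54)
  for (i in 1:10) {
    n <- sample(4:20, 1)
    ra <- sample(n); rb <- sample(n)
    base <- colinearity_stats(ra, rb)$lis_fraction
    expect_equal(colinearity_stats(max(ra) - ra, rb)$lis_fraction, base)
    expect_equal(colinearity_stats(ra, max(rb) - rb)$lis_fraction, base)
  }
})

test_that("cells classify by significance, population, then co-linearity", {
  cells <- tibble::tibble(
    scaffold_a = "s", scaffold_b = "u", n_shared = 10L,
    q_value = c(0.01, 0.01, 0.2), lis_fraction = c(0.95, 0.3, 0.95)
  )
  got <- classify_cells(cells)
  expect_equal(as.character(got$label),
    c("macrosyntenic_colinear", "macrosyntenic_shuffled", "not_syntenic"))
  sparse <- classify_cells(dplyr::mutate(cells[1, ], n_shared = 3L))
  expect_equal(as.character(sparse$label), "not_syntenic")
})

test_that("multi-species scaffold sharing agrees between its two definitions on clean data", {
  annot_a <- make_annotation(list(s1 = c("a1", "a2", "a3")), "A")
  pairings <- list(
    B = tibble::tibble(gene_a = c("a1", "a2"), gene_b = c("b1", "b2")),
    C = tibble::tibble(gene_a = "a1", gene_b = "c1")
  )
  rbh_view <- shared_on_scaffold(annot_a, "s1", pairings = pairings)
  expect_equal(rbh_view$n_shared, c(2L, 1L, 0L))
  expect_equal(rbh_view$shared_all, c(TRUE, FALSE, FALSE))

  members <- tibble::tibble(
    orthogroup = c("OG1", "OG1", "OG1", "OG2", "OG2", "OG3"),
    taxon = c("A", "B", "C", "A", "B", "A"),
    gene_id = c("a1", "b1", "c1", "a2", "b2", "a3")
  )
  og <- make_og(rbind(c(1L, 1L, 1L), c(1L, 1L, 0L), c(1L, 0L, 0L)),
    c("A", "B", "C"), orthogroups = c("OG1", "OG2", "OG3"))
  attr(og, "members") <- members
  og_view <- shared_on_scaffold(annot_a, "s1", og = og, focal_taxon = "A",
    taxa = c("B", "C"), method = "orthogroup")
  expect_equal(og_view$n_shared, rbh_view$n_shared)
  expect_error(shared_on_scaffold(annot_a, "nope", pairings = pairings), "nope")
})
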