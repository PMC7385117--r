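quiet_cfg <- function(...) sim_config("((A:1,B:1):1,(C:1,D:1):1);", ...)

test_that("zero rates leave every tip identical to the root", {
  cfg <- quiet_cfg(root_orthogroups = 30, gain_rate = 0, loss_rate = 0,
    duplication_rate = 0, seed = 2)
  content <- simulate_gene_content(cfg)
  root_state <- content$node_states[[5]]
  for (t in 1:4) expect_equal(content$node_states[[t]], root_state)
  expect_equal(nrow(content$og), 30)
  expect_true(all(as.matrix(as.data.frame(content$og[, -1])) == 1L))
})

test_that("identical config and seed give byte-identical emitted files", {
  cfg <- quiet_cfg(root_orthogroups = 25, seed = 5)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  emit_dataset(simulate_dataset(cfg), d1)
  emit_dataset(simulate_dataset(cfg), d2)
  files <- list.files(d1)
  expect_setequal(files, list.files(d2))
  for (f in files) {
    expect_identical(
      readLines(file.path(d1, f), warn = FALSE),
      readLines(file.path(d2, f), warn = FALSE),
      info = f
    )
  }
  # and a different seed changes the data
  d3 <- withr::local_tempdir()
  emit_dataset(simulate_dataset(quiet_cfg(root_orthogroups = 25, seed = 6)), d3)
  expect_false(identical(
    readLines(file.path(d1, "Orthogroups.tsv"), warn = FALSE),
    readLines(file.path(d3, "Orthogroups.tsv"), warn = FALSE)
  ))
})

test_that("mean gains per branch track the Poisson rate", {
  cfg2 <- sim_config("(A:1,B:1);", root_orthogroups = 0, gain_rate = 4,
    loss_rate = 0, duplication_rate = 0)
  gains <- unlist(lapply(1:200, function(s) {
    content <- simulate_gene_content(
      sim_config("(A:1,B:1);", root_orthogroups = 0, gain_rate = 4,
        loss_rate = 0, duplication_rate = 0, seed = s)
    )
    vapply(content$events[1:2], function(e) length(e$gains), 0L)
  }))
  se <- sqrt(4 / length(gains))
  expect_lt(abs(mean(gains) - 4), 3 * se)
})

test_that("without rearrangements, tip gene order mirrors the root order", {
  cfg <- quiet_cfg(root_orthogroups = 40, gain_rate = 0, loss_rate = 0,
    duplication_rate = 0, inversion_rate = 0, translocation_rate = 0, seed = 8)
  content <- simulate_gene_content(cfg)
  order <- simulate_gene_order(content)
  for (t in 1:4) {
    for (k in seq_along(order$root_genome)) {
      expect_equal(order$genomes[[t]][[k]]$gid, order$root_genome[[k]]$gid)
      expect_equal(order$genomes[[t]][[k]]$strand, order$root_genome[[k]]$strand)
    }
  }
})

test_that("without translocations, chromosome assignment is heritable", {
  cfg <- quiet_cfg(root_orthogroups = 60, gain_rate = 0, loss_rate = 0,
    duplication_rate = 0, inversion_rate = 8, translocation_rate = 0, seed = 9)
  order <- simulate_gene_order(simulate_gene_content(cfg))
  root_chrom <- do.call(rbind, lapply(seq_along(order$root_genome), function(k) {
    data.frame(gid = order$root_genome[[k]]$gid, chrom = k)
  }))
  for (t in 1:4) {
    tip_chrom <- do.call(rbind, lapply(seq_along(order$genomes[[t]]), function(k) {
      data.frame(gid = order$genomes[[t]][[k]]$gid, chrom = k)
    }))
    m <- merge(root_chrom, tip_chrom, by = "gid")
    expect_equal(m$chrom.x, m$chrom.y)
  }
})

test_that("inversion events reverse exactly their logged interval", {
  g <- list(data.frame(gid = 1:6, og = paste0("OG", 1:6),
    strand = c("+", "+", "-", "+", "-", "+")))
  out <- syngloss:::apply_order_event(g, list(type = "inversion", chrom = 1, from = 2, to = 5))
  expect_equal(out[[1]]$gid, c(1L, 5L, 4L, 3L, 2L, 6L))
  # reversed segment order with flipped strands: rows 5,4,3,2 were -,+,-,+
  expect_equal(out[[1]]$strand, c("+", "+", "-", "+", "-", "+"))
})

test_that("the event log replays every tip genome exactly", {
  for (s in c(3, 14)) {
    cfg <- quiet_cfg(root_orthogroups = 40, seed = s)
    order <- simulate_gene_order(simulate_gene_content(cfg))
    expect_true(replay_gene_order(order))
  }
})

test_that("similarity dropout behaves like per-row Bernoulli thinning", {
  base <- simulate_dataset(quiet_cfg(root_orthogroups = 150, gain_rate = 0,
    loss_rate = 0, duplication_rate = 0, similarity_dropout = 0,
    spurious_hit_rate = 0, seed = 10))
  n_full <- nrow(base$similarity[["A__B"]])
  expect_equal(n_full, 150) # one mutual hit per orthogroup pair

  thinned <- simulate_dataset(quiet_cfg(root_orthogroups = 150, gain_rate = 0,
    loss_rate = 0, duplication_rate = 0, similarity_dropout = 0.1,
    spurious_hit_rate = 0, seed = 10))
  kept <- nrow(thinned$similarity[["A__B"]])
  expect_gt(kept, qbinom(0.001, n_full, 0.9)) # binomial tolerance
  expect_lt(kept, qbinom(0.999, n_full, 0.9))

  none <- simulate_dataset(quiet_cfg(root_orthogroups = 20, gain_rate = 0,
    loss_rate = 0, duplication_rate = 0, similarity_dropout = 1,
    spurious_hit_rate = 0, seed = 10))
  expect_equal(nrow(none$similarity[["A__B"]]), 0)
})

test_that("clean similarity tables let RBH recover the planted ortholog map", {
  cfg <- quiet_cfg(root_orthogroups = 80, duplication_rate = 0,
    similarity_dropout = 0, spurious_hit_rate = 0, seed = 11)
  sim <- simulate_dataset(cfg)
  got <- reciprocal_best_hits(sim$similarity[["A__B"]], sim$similarity[["B__A"]])
  want <- dplyr::arrange(sim$truth$ortholog_map[["A__B"]], gene_a)
  expect_equal(as.data.frame(got[, c("gene_a", "gene_b")]), as.data.frame(want))
})

test_that("planting convergent losses edits exactly the sampled orthogroups", {
  panel <- four_pair_panel
  cfg <- sim_config(four_pair_tree_nwk, root_orthogroups = 100, loss_rate = 0.05,
    panel = panel, seed = 12)
  content <- simulate_gene_content(cfg)
  unchanged <- plant_convergent_losses(content$og, panel, L = 0)
  expect_equal(as.data.frame(unchanged$og), as.data.frame(content$og))

  planted <- plant_convergent_losses(content$og, panel, L = 10, seed = 4)
  expect_length(planted$planted, 10)
  P <- as.matrix(as.data.frame(planted$og[, -1])) > 0
  rownames(P) <- planted$og$orthogroup
  expect_true(all(!P[planted$planted, panel$freshwater_taxon]))
  expect_true(all(P[planted$planted, panel$marine_taxon]))
  expect_error(plant_convergent_losses(content$og, panel, L = 1e5), "cannot plant")
})

test_that("planted losses flow through to the shared-loss count", {
  panel <- four_pair_panel
  cfg <- sim_config(four_pair_tree_nwk, root_orthogroups = 120, loss_rate = 0,
    planted_convergent_losses = 10, panel = panel, seed = 13)
  sim <- simulate_dataset(cfg)
  sets <- lapply(seq_len(4), function(i) {
    lineage_loss_set(sim$og, panel$marine_taxon[i], panel$freshwater_taxon[i])
  })
  expect_equal(shared_loss_counts(sets)$count_all_n, 10L)
})
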