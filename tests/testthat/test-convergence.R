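toy_og <- make_og(rbind(
  #      m1  f1  m2  f2
  c(1L, 1L, 1L, 1L), # present everywhere
  c(1L, 0L, 1L, 1L), # lost in f1
  c(1L, 0L, 0L, 0L), # only in m1
  c(0L, 1L, 1L, 0L), # lost in f2 (marine m2 present), also marine m1 loss
  c(2L, 0L, 1L, 0L)  # lost in both freshwater taxa
), c("m1", "f1", "m2", "f2"))

test_that("lineage loss sets follow the directional definition", {
  fw1 <- lineage_loss_set(toy_og, "m1", "f1")
  expect_setequal(fw1, c("OG00002", "OG00003", "OG00005"))
  # with outside-presence required, the pair-private OG00003 drops out
  fw1_strict <- lineage_loss_set(toy_og, "m1", "f1", require_outside_presence = TRUE)
  expect_setequal(fw1_strict, c("OG00002", "OG00005"))
  ma1 <- lineage_loss_set(toy_og, "m1", "f1", direction = "marine")
  expect_equal(ma1, "OG00004")
  expect_error(lineage_loss_set(toy_og, "mX", "f1"), "mX")
})

test_that("shared-loss counts match brute-force intersections", {
  same <- replicate(4, paste0("OG", 1:5), simplify = FALSE)
  sc <- shared_loss_counts(same)
  expect_equal(sc$count_all_n, 5L)
  expect_equal(sc$leave_one_out$count, rep(5L, 4))

  disjoint <- list(a = "OG1", b = "OG2", c = "OG3")
  sc2 <- shared_loss_counts(disjoint)
  expect_equal(sc2$count_all_n, 0L)
  expect_equal(sc2$leave_one_out$count, rep(0L, 3))

  set.seed(81)
  for (i in 1:5) {
    sets <- replicate(4, sample(paste0("OG", 1:12), sample(3:8, 1)), simplify = FALSE)
    names(sets) <- paste0("L", 1:4)
    sc3 <- shared_loss_counts(sets)
    universe <- unique(unlist(sets))
    inall <- sum(vapply(universe, function(o) all(vapply(sets, function(s) o %in% s, TRUE)), TRUE))
    expect_equal(sc3$count_all_n, inall)
    for (k in 1:4) {
      others <- sets[-k]
      want <- sum(vapply(universe, function(o) {
        all(vapply(others, function(s) o %in% s, TRUE))
      }, TRUE))
      expect_equal(sc3$leave_one_out$count[k], want)
    }
    expect_lte(sc3$count_all_n, min(sc3$leave_one_out$count))
  }
})

test_that("background shared absence equals full enumeration", {
  none <- make_og(matrix(1L, 5, 4), paste0("t", 1:4))
  expect_equal(background_shared_absence(none, 2), 0)

  set.seed(82)
  og <- make_og(matrix(rbinom(40, 1, 0.6), 10, 4), paste0("t", 1:4))
  got <- background_shared_absence(og, 2, mode = "exact")
  # oracle: loop over all 6 subsets by hand
  P <- as.matrix(as.data.frame(og[, -1])) > 0
  subs <- combn(4, 2)
  vals <- apply(subs, 2, function(s) {
    sum(rowSums(P[, s, drop = FALSE]) == 0 & rowSums(P[, -s, drop = FALSE]) > 0)
  })
  expect_equal(got, mean(vals))
  # Monte Carlo converges to the exact value
  mc <- background_shared_absence(og, 2, mode = "montecarlo", n_draws = 4000, seed = 9)
  expect_equal(mc, got, tolerance = 0.05)
  expect_error(background_shared_absence(og, 4), "subset_size")
})

test_that("t-test variants match an independently coded oracle", {
  set.seed(83)
  x <- rnorm(6, 10, 3); y <- rnorm(6, 7, 2)
  tt <- tidy(habitat_t_test(x, y))
  for (i in seq_len(nrow(tt))) {
    o <- oracle_t(x, y, pooled = tt$variant[i] == "pooled",
      one_sided = tt$alternative[i] == "greater")
    expect_equal(tt$statistic[i], o$t, tolerance = 1e-10)
    expect_equal(tt$df[i], o$df, tolerance = 1e-10)
    expect_equal(tt$p_value[i], o$p, tolerance = 1e-10)
  }
  ident <- tidy(habitat_t_test(c(3, 3, 3), c(3, 3, 3)))
  expect_true(all(ident$statistic == 0))
  expect_true(all(ident$p_value[ident$alternative == "two.sided"] == 1))
})

test_that("permutation test is exact over within-pair label swaps", {
  # maximally directional: every freshwater taxon loses OG2..OG9, marine none
  n <- 4
  taxa <- c(rbind(paste0("m", 1:n), paste0("f", 1:n)))
  counts <- matrix(1L, 10, 2 * n, dimnames = list(NULL, taxa))
  counts[2:9, paste0("f", 1:n)] <- 0L
  og <- make_og(counts, taxa)
  panel <- four_pair_panel
  res <- habitat_permutation_test(og, panel)
  expect_equal(res$n_assignments, 16L)
  expect_equal(res$p_value, 1 / 16)
  expect_gte(res$p_value, 1 / 2^n) # attainable floor

  # label-invariant data: p = 1
  sym <- make_og(matrix(1L, 5, 2 * n), taxa)
  expect_equal(habitat_permutation_test(sym, panel)$p_value, 1)
})

test_that("swapping all habitat labels swaps the directional blocks", {
  set.seed(84)
  taxa <- c(rbind(paste0("m", 1:4), paste0("f", 1:4)))
  og <- make_og(matrix(rbinom(8 * 60, 1, 0.7), 60, 8, dimnames = list(NULL, taxa)), taxa)
  panel <- four_pair_panel
  flipped <- dplyr::mutate(panel,
    marine_taxon = panel$freshwater_taxon,
    freshwater_taxon = panel$marine_taxon
  )
  a <- convergence_analysis(og, panel)
  b <- convergence_analysis(og, flipped)
  get <- function(x, dir) x$shared$count_all_n[x$shared$direction == dir]
  expect_equal(get(a, "freshwater"), get(b, "marine"))
  expect_equal(get(a, "marine"), get(b, "freshwater"))
  loo <- function(x, dir) sort(x$shared$loo_counts[[which(x$shared$direction == dir)]]$count)
  expect_equal(loo(a, "freshwater"), loo(b, "marine"))
})

test_that("tidy and glance expose the convergence results", {
  res <- convergence_analysis(toy_og, four_pair_panel[1:2, ])
  td <- tidy(res)
  expect_setequal(names(td), c("phylum", "direction", "n_losses", "loo_count"))
  expect_equal(nrow(td), 4) # 2 pairs x 2 directions
  gl <- glance(res)
  expect_equal(gl$n_pairs, 2L)
  expect_true(gl$permutation_p >= 1 / 4)
})
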