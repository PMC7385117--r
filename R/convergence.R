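#' Read or build a habitat-pairing panel
#'
#' A panel pairs, within each phylum, one marine and one freshwater taxon,
#' enabling a paired test of habitat-associated gene loss. `panel.tsv` has
#' columns `phylum`, `marine_taxon`, `freshwater_taxon` (header required).
#'
#' @param path Path to a panel TSV.
#' @return Tibble with those three character columns.
#' @export
read_habitat_panel <- function(path) {
  panel <- readr::read_tsv(path, col_types = "ccc", progress = FALSE)
  check_columns(panel, c("phylum", "marine_taxon", "freshwater_taxon"), "habitat panel")
  validate_panel(panel)
  panel
}

validate_panel <- function(panel) {
  taxa <- c(panel$marine_taxon, panel$freshwater_taxon)
  if (anyDuplicated(taxa)) {
    abort(sprintf(
      "panel taxa must be distinct; duplicated: %s",
      paste(unique(taxa[duplicated(taxa)]), collapse = ", ")
    ))
  }
  invisible(panel)
}

#' Habitat-specific loss set for one lineage pair
#'
#' In the `freshwater` direction, the loss set of a pair is the set of
#' orthogroups present in the marine taxon but absent from its freshwater
#' counterpart (losses specific to the freshwater lineage, with the
#' same-phylum marine genome as the presence reference); the `marine`
#' direction is symmetric. With `require_outside_presence = TRUE` the
#' orthogroup must additionally be present in at least one taxon outside
#' the pair, which guards against pair-private orthogroups.
#'
#' @param og Orthogroup count table.
#' @param marine_taxon,freshwater_taxon Column names in `og`.
#' @param direction `"freshwater"` (default) or `"marine"`.
#' @param require_outside_presence Logical, default `FALSE`.
#' @return Character vector of orthogroup ids.
#' @export
lineage_loss_set <- function(og, marine_taxon, freshwater_taxon,
                             direction = c("freshwater", "marine"),
                             require_outside_presence = FALSE) {
  direction <- match.arg(direction)
  taxa <- og_taxa(og)
  unknown <- setdiff(c(marine_taxon, freshwater_taxon), taxa)
  if (length(unknown) > 0) {
    abort(sprintf("taxon/taxa not in matrix: %s", paste(unknown, collapse = ", ")))
  }
  keep_taxon <- if (direction == "freshwater") marine_taxon else freshwater_taxon
  lose_taxon <- if (direction == "freshwater") freshwater_taxon else marine_taxon
  sel <- og[[keep_taxon]] >= 1L & og[[lose_taxon]] == 0L
  if (require_outside_presence) {
    others <- setdiff(taxa, c(marine_taxon, freshwater_taxon))
    if (length(others) > 0) {
      P <- og_presence_matrix(og)
      sel <- sel & rowSums(P[, others, drop = FALSE]) > 0
    } else {
      sel <- sel & FALSE
    }
  }
  og$orthogroup[sel]
}

#' Shared-loss counts across lineages
#'
#' `count_all_n` is the size of the intersection of all loss sets;
#' `leave_one_out` gives, for each lineage, the size of the intersection
#' of the other `n - 1` sets (the "lost in three of four lineages"
#' vectors). `count_all_n <= min(leave_one_out)` always.
#'
#' @param loss_sets Named list of at least two character vectors.
#' @return List with `count_all_n` (integer) and `leave_one_out` (tibble:
#'   `left_out`, `count`).
#' @export
shared_loss_counts <- function(loss_sets) {
  if (length(loss_sets) < 2) abort("need at least two loss sets")
  if (is.null(names(loss_sets))) names(loss_sets) <- paste0("set", seq_along(loss_sets))
  inter <- function(sets) {
    if (length(sets) == 0) return(character(0))
    Reduce(intersect, sets)
  }
  loo <- purrr::imap(loss_sets, function(s, nm) {
    tibble(left_out = nm, count = length(inter(loss_sets[names(loss_sets) != nm])))
  })
  list(
    count_all_n = length(inter(loss_sets)),
    leave_one_out = bind_rows(loo)
  )
}

#' Background shared-absence rate over random taxon subsets
#'
#' For every taxon subset of the given size, counts the orthogroups absent
#' from all subset members and present in at least one taxon outside the
#' subset, and returns the mean over subsets. This is the expected number
#' of "shared losses" any comparably sized set of taxa shows by chance,
#' the baseline against which a habitat-matched intersection is judged.
#'
#' @param og Orthogroup count table.
#' @param subset_size Subset size, strictly less than the number of taxa.
#' @param mode `"auto"` (exact when `choose(n_taxa, subset_size) <= 10000`,
#'   else Monte Carlo), `"exact"` or `"montecarlo"`.
#' @param n_draws Monte Carlo draws (default 1000).
#' @param seed Seed for Monte Carlo sampling (default 1).
#' @return Mean shared-absence count (double).
#' @export
background_shared_absence <- function(og, subset_size,
                                      mode = c("auto", "exact", "montecarlo"),
                                      n_draws = 1000, seed = 1) {
  mode <- match.arg(mode)
  taxa <- og_taxa(og)
  if (subset_size >= length(taxa)) {
    abort("subset_size must be smaller than the number of taxa")
  }
  P <- og_presence_matrix(og)
  tot <- rowSums(P)
  count_subset <- function(cols) {
    inside <- rowSums(P[, cols, drop = FALSE])
    sum(inside == 0 & tot > 0)
  }
  if (mode == "auto") {
    mode <- if (choose(length(taxa), subset_size) <= 10000) "exact" else "montecarlo"
  }
  if (mode == "exact") {
    subsets <- combn(taxa, subset_size, simplify = FALSE)
    mean(vapply(subsets, count_subset, 0))
  } else {
    with_seed(seed, {
      draws <- replicate(n_draws, sample(taxa, subset_size), simplify = FALSE)
      mean(vapply(draws, count_subset, 0))
    })
  }
}

#' Two-sample t-tests on shared-loss counts, all four variants
#'
#' Computes the two-sample t statistic comparing freshwater against marine
#' shared-loss counts under pooled-variance and Welch forms, each with a
#' one-sided (freshwater greater) and a two-sided p-value. All four are
#' reported; none is silently chosen, because with n = 4 per group the
#' variant changes the p-value substantially and reported "t-tests" in the
#' literature rarely state their form. Use [generics::tidy()] to get the
#' table and `glance()` for the variant closest to a reference p.
#'
#' @param fw_counts,marine_counts Equal-length numeric vectors (length >= 2).
#' @param reference_p Optional reference p-value; `glance()` reports which
#'   variant lands nearest it.
#' @return Object of class `habitat_test` wrapping a tibble with columns
#'   `variant` (`pooled`/`welch`), `alternative` (`greater`/`two.sided`),
#'   `statistic`, `df`, `p_value`.
#' @examples
#' tt <- habitat_t_test(c(73, 22, 52, 37), c(1, 2, 8, 0))
#' generics::tidy(tt)
#' @export
habitat_t_test <- function(fw_counts, marine_counts, reference_p = NULL) {
  if (length(fw_counts) != length(marine_counts)) {
    abort("fw_counts and marine_counts must have equal length")
  }
  if (length(fw_counts) < 2) abort("need at least two lineages per group")
  one <- function(var_equal, alternative) {
    res <- tryCatch(
      stats::t.test(fw_counts, marine_counts,
        var.equal = var_equal, alternative = alternative
      ),
      error = function(e) NULL
    )
    if (is.null(res)) {
      # both groups constant: equal means give t = 0, p = 1 by convention
      df <- if (var_equal) length(fw_counts) + length(marine_counts) - 2 else NA_real_
      delta <- mean(fw_counts) - mean(marine_counts)
      t <- if (delta == 0) 0 else sign(delta) * Inf
      p <- if (delta == 0) 1 else if (alternative == "greater" && delta > 0) 0 else
        if (alternative == "two.sided") 0 else 1
      return(tibble(statistic = t, df = df, p_value = p))
    }
    tibble(
      statistic = unname(res$statistic), df = unname(res$parameter),
      p_value = res$p.value
    )
  }
  grid <- tidyr::expand_grid(
    variant = c("pooled", "welch"), alternative = c("greater", "two.sided")
  )
  rows <- purrr::pmap(grid, function(variant, alternative) {
    one(variant == "pooled", alternative)
  })
  out <- dplyr::bind_cols(grid, bind_rows(rows))
  structure(
    list(
      table = out, fw_counts = fw_counts, marine_counts = marine_counts,
      reference_p = reference_p
    ),
    class = "habitat_test"
  )
}

#' @export
print.habitat_test <- function(x, ...) {
  cat("Two-sample t-tests, freshwater vs marine shared-loss counts\n")
  print(x$table, ...)
  invisible(x)
}

#' Exact within-pair permutation test of habitat-directed shared loss
#'
#' Under the null of no habitat effect, the marine/freshwater labels
#' within each lineage pair are exchangeable. The test enumerates all
#' `2^n` within-pair label swaps (or samples them), recomputes the
#' statistic for each assignment, and reports the proportion of
#' assignments with a statistic at least as large as the observed one
#' (the identity assignment counts, so the exact p is at least `1 / 2^n`).
#'
#' Statistics: `"loo_mean_diff"` (default) is the difference in mean
#' leave-one-out shared-loss counts, freshwater minus marine;
#' `"all_n_diff"` is the difference in all-`n` intersection counts.
#'
#' @param og Orthogroup count table.
#' @param panel Habitat panel ([read_habitat_panel()]).
#' @param statistic `"loo_mean_diff"` or `"all_n_diff"`.
#' @param exact `TRUE` (default) enumerates all `2^n` assignments; `FALSE`
#'   samples `n_draws` assignments (identity always included).
#' @param n_draws Number of sampled assignments when `exact = FALSE`.
#' @param seed Seed for sampling.
#' @param require_outside_presence Passed to [lineage_loss_set()].
#' @return List of class `habitat_perm`: `p_value`, `observed`,
#'   `null_statistics` (vector over assignments, identity first),
#'   `statistic`, `n_assignments`.
#' @export
habitat_permutation_test <- function(og, panel,
                                     statistic = c("loo_mean_diff", "all_n_diff"),
                                     exact = TRUE, n_draws = 1000, seed = 1,
                                     require_outside_presence = FALSE) {
  statistic <- match.arg(statistic)
  validate_panel(panel)
  n <- nrow(panel)
  # per pair, the two directed loss sets as presence columns
  fw_sets <- purrr::map2(
    panel$marine_taxon, panel$freshwater_taxon,
    function(m, f) {
      lineage_loss_set(og, m, f,
        direction = "freshwater",
        require_outside_presence = require_outside_presence
      )
    }
  )
  ma_sets <- purrr::map2(
    panel$marine_taxon, panel$freshwater_taxon,
    function(m, f) {
      lineage_loss_set(og, m, f,
        direction = "marine",
        require_outside_presence = require_outside_presence
      )
    }
  )
  universe <- og$orthogroup
  Fm <- vapply(fw_sets, function(s) universe %in% s, logical(length(universe)))
  Mm <- vapply(ma_sets, function(s) universe %in% s, logical(length(universe)))
  if (length(universe) == 0) {
    Fm <- matrix(FALSE, 0, n); Mm <- matrix(FALSE, 0, n)
  }
  assignments <- if (exact) {
    purrr::map(seq_len(2^n) - 1L, function(code) {
      as.logical(bitwAnd(bitwShiftR(code, seq_len(n) - 1L), 1L))
    })
  } else {
    with_seed(seed, c(
      list(rep(FALSE, n)),
      purrr::map(seq_len(n_draws - 1), function(i) sample(c(TRUE, FALSE), n, replace = TRUE))
    ))
  }
  # Swapping pair i's habitat labels exchanges its two directed loss sets,
  # so for assignment s the freshwater-direction row sums are
  # S = rowSums(F) + (M - F) %*% s and the marine-direction ones are
  # rowSums(F + M) - S. The all-n intersection count is #{S == n}; the sum
  # of the n leave-one-out intersection counts is n * #{S == n} + #{S == n-1}
  # (rows present in all n sets lie in every (n-1)-intersection; rows
  # present in exactly n-1 lie in exactly one). One matrix product covers
  # every assignment at once.
  grid <- vapply(assignments, as.numeric, numeric(n))
  S <- as.vector(rowSums(Fm)) + (Mm - Fm) %*% grid
  Sm <- as.vector(rowSums(Fm) + rowSums(Mm)) - S
  stats_vec <- if (statistic == "all_n_diff") {
    colSums(S == n) - colSums(Sm == n)
  } else {
    (n * colSums(S == n) + colSums(S == n - 1) -
      n * colSums(Sm == n) - colSums(Sm == n - 1)) / n
  }
  observed <- stats_vec[[1]]
  structure(
    list(
      p_value = mean(stats_vec >= observed),
      observed = observed,
      null_statistics = stats_vec,
      statistic = statistic,
      n_assignments = length(stats_vec)
    ),
    class = "habitat_perm"
  )
}

#' @export
print.habitat_perm <- function(x, ...) {
  cat(sprintf(
    "Within-pair permutation test (%s): observed %.3f, p = %.4g over %d assignments\n",
    x$statistic, x$observed, x$p_value, x$n_assignments
  ))
  invisible(x)
}

#' Full convergent-loss analysis for a habitat panel
#'
#' Runs the complete habitat-paired contrast: per-lineage loss sets in both
#' directions, all-`n` and leave-one-out shared-loss counts, the background
#' shared-absence rate for subsets of the panel size, all four t-test
#' variants on the leave-one-out counts, and the exact within-pair
#' permutation test.
#'
#' @inheritParams habitat_permutation_test
#' @param background_mode Passed to [background_shared_absence()].
#' @param reference_p Optional reference p forwarded to [habitat_t_test()].
#' @return Object of class `convergence_result`: list with `panel`,
#'   `loss_sets` (tibble: `phylum`, `direction`, `n_losses`, `orthogroups`
#'   list-column), `shared` (tibble: `direction`, `count_all_n`,
#'   `loo_counts` list-column), `background_mean`, `t_tests`
#'   (`habitat_test`), `permutation` (`habitat_perm`).
#' @export
convergence_analysis <- function(og, panel, require_outside_presence = FALSE,
                                 background_mode = "auto", seed = 1,
                                 reference_p = NULL,
                                 statistic = "loo_mean_diff") {
  validate_panel(panel)
  unknown <- setdiff(c(panel$marine_taxon, panel$freshwater_taxon), og_taxa(og))
  if (length(unknown) > 0) {
    abort(sprintf("panel taxa not in matrix: %s", paste(unknown, collapse = ", ")))
  }
  directions <- c("freshwater", "marine")
  sets <- purrr::map(directions, function(dir) {
    purrr::map2(
      panel$marine_taxon, panel$freshwater_taxon,
      function(m, f) {
        lineage_loss_set(og, m, f,
          direction = dir,
          require_outside_presence = require_outside_presence
        )
      }
    ) |> setNames(panel$phylum)
  }) |> setNames(directions)
  loss_tbl <- purrr::imap(sets, function(by_phylum, dir) {
    tibble(
      phylum = names(by_phylum), direction = dir,
      n_losses = lengths(by_phylum), orthogroups = unname(by_phylum)
    )
  }) |> bind_rows()
  shared <- purrr::imap(sets, function(by_phylum, dir) {
    sc <- shared_loss_counts(by_phylum)
    tibble(
      direction = dir, count_all_n = sc$count_all_n,
      loo_counts = list(sc$leave_one_out)
    )
  }) |> bind_rows()
  fw_loo <- shared$loo_counts[[which(shared$direction == "freshwater")]]$count
  ma_loo <- shared$loo_counts[[which(shared$direction == "marine")]]$count
  structure(
    list(
      panel = panel,
      loss_sets = loss_tbl,
      shared = shared,
      background_mean = background_shared_absence(og, nrow(panel),
        mode = background_mode, seed = seed
      ),
      t_tests = habitat_t_test(fw_loo, ma_loo, reference_p = reference_p),
      permutation = habitat_permutation_test(og, panel,
        statistic = statistic, exact = nrow(panel) <= 12, seed = seed,
        require_outside_presence = require_outside_presence
      )
    ),
    class = "convergence_result"
  )
}

#' @export
print.convergence_result <- function(x, ...) {
  fw <- x$shared$count_all_n[x$shared$direction == "freshwater"]
  ma <- x$shared$count_all_n[x$shared$direction == "marine"]
  cat(sprintf(
    paste0(
      "Convergent-loss analysis over %d lineage pairs\n",
      "  shared losses in all pairs: freshwater %d vs marine %d\n",
      "  background shared-absence mean for %d random taxa: %.1f\n",
      "  permutation p (%s): %.4g\n"
    ),
    nrow(x$panel), fw, ma, nrow(x$panel), x$background_mean,
    x$permutation$statistic, x$permutation$p_value
  ))
  invisible(x)
}
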