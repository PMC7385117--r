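#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a Dollo gain/loss summary
#'
#' @param x A `gain_loss` from [summarize_gain_loss()].
#' @param ... Unused.
#' @return The per-node tibble (`node`, `label`, `is_tip`, `n_origins`,
#'   `n_losses`, tip gain columns).
#' @method tidy gain_loss
#' @export
tidy.gain_loss <- function(x, ...) x$nodes

#' @rdname tidy.gain_loss
#' @return For `glance()`: one row with `n_orthogroups`, `n_dropped`,
#'   `total_losses`, `root_origins`.
#' @method glance gain_loss
#' @export
glance.gain_loss <- function(x, ...) {
  root <- length(x$tree$tip.label) + 1L
  tibble(
    n_orthogroups = nrow(x$origins),
    n_dropped = x$n_dropped,
    total_losses = sum(x$nodes$n_losses),
    root_origins = x$nodes$n_origins[x$nodes$node == root]
  )
}

#' Tidy the four t-test variants of a habitat contrast
#'
#' @param x A `habitat_test` from [habitat_t_test()].
#' @param ... Unused.
#' @return Tibble with one row per (variant, alternative) combination.
#' @method tidy habitat_test
#' @export
tidy.habitat_test <- function(x, ...) x$table

#' @rdname tidy.habitat_test
#' @return For `glance()`: one row with group means and, when a
#'   `reference_p` was supplied, the variant whose p lands nearest it.
#' @method glance habitat_test
#' @export
glance.habitat_test <- function(x, ...) {
  out <- tibble(
    mean_freshwater = mean(x$fw_counts),
    mean_marine = mean(x$marine_counts),
    n = length(x$fw_counts)
  )
  if (!is.null(x$reference_p)) {
    i <- which.min(abs(x$table$p_value - x$reference_p))
    out$reference_p <- x$reference_p
    out$nearest_variant <- paste(x$table$variant[i], x$table$alternative[i], sep = "/")
    out$nearest_p <- x$table$p_value[i]
  }
  out
}

#' Tidy a convergence analysis
#'
#' @param x A `convergence_result` from [convergence_analysis()].
#' @param ... Unused.
#' @return Per-lineage loss counts with leave-one-out intersections: one
#'   row per (phylum, direction).
#' @method tidy convergence_result
#' @export
tidy.convergence_result <- function(x, ...) {
  loo <- x$shared |>
    mutate(loo = purrr::map(.data$loo_counts, function(t) {
      rename(t, phylum = "left_out", loo_count = "count")
    })) |>
    select("direction", "loo") |>
    tidyr::unnest("loo")
  x$loss_sets |>
    select("phylum", "direction", "n_losses") |>
    left_join(loo, by = c("phylum", "direction"))
}

#' @rdname tidy.convergence_result
#' @return For `glance()`: one row with the all-`n` counts in both
#'   directions, the background mean, the smallest t-test p and the
#'   permutation p.
#' @method glance convergence_result
#' @export
glance.convergence_result <- function(x, ...) {
  tibble(
    n_pairs = nrow(x$panel),
    shared_all_freshwater = x$shared$count_all_n[x$shared$direction == "freshwater"],
    shared_all_marine = x$shared$count_all_n[x$shared$direction == "marine"],
    background_mean = x$background_mean,
    min_t_test_p = min(x$t_tests$table$p_value),
    permutation_p = x$permutation$p_value
  )
}
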