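#' Place ortholog pairs on the Oxford grid
#'
#' Joins a one-to-one ortholog pairing against the two genome annotations
#' and returns one dot per pair: the scaffolds and within-scaffold ordinal
#' ranks of the two genes. This is the raw material for both the
#' scaffold-pair enrichment test and the co-linearity statistics.
#'
#' @param pairs Pairing tibble ([reciprocal_best_hits()]): columns `gene_a`,
#'   `gene_b`.
#' @param annot_a,annot_b Annotations ([read_gene_annotation()]).
#' @param missing What to do with pairs whose gene is absent from its
#'   annotation: `"drop"` (default; one warning with the count) or
#'   `"error"`.
#' @return Tibble with columns `gene_a`, `gene_b`, `scaffold_a`, `rank_a`,
#'   `scaffold_b`, `rank_b`.
#' @export
synteny_dots <- function(pairs, annot_a, annot_b, missing = c("drop", "error")) {
  missing <- match.arg(missing)
  check_columns(pairs, c("gene_a", "gene_b"), "pairing")
  loc_a <- select(annot_a, gene_a = "gene_id", scaffold_a = "scaffold_id", rank_a = "rank")
  loc_b <- select(annot_b, gene_b = "gene_id", scaffold_b = "scaffold_id", rank_b = "rank")
  dots <- pairs |>
    left_join(loc_a, by = "gene_a") |>
    left_join(loc_b, by = "gene_b")
  bad <- is.na(dots$scaffold_a) | is.na(dots$scaffold_b)
  if (any(bad)) {
    msg <- sprintf("%d ortholog pair(s) with a gene missing from its annotation", sum(bad))
    if (missing == "error") abort(msg)
    warn(paste0(msg, "; dropped"))
    dots <- dots[!bad, ]
  }
  select(dots, "gene_a", "gene_b", "scaffold_a", "rank_a", "scaffold_b", "rank_b")
}

#' Scaffold-pair counts and margins of the Oxford grid
#'
#' Counts homologous gene pairs per scaffold pair. The counting universe is
#' ortholog pairs, not genes: `n_total` is the number of pairs with both
#' genes annotated, and the margins are pair counts per scaffold over that
#' same universe. Cells with zero shared pairs are omitted.
#'
#' @param dots Dot table from [synteny_dots()], or a pairing plus
#'   annotations via `...` forwarded to [synteny_dots()].
#' @return Tibble with columns `scaffold_a`, `scaffold_b`, `n_shared`,
#'   `row_margin`, `col_margin`, `n_total`; `sum(n_shared) == n_total`.
#' @export
oxford_grid <- function(dots) {
  check_columns(dots, c("scaffold_a", "scaffold_b"), "dot table")
  cells <- dots |>
    count(.data$scaffold_a, .data$scaffold_b, name = "n_shared")
  rows <- dots |> count(.data$scaffold_a, name = "row_margin")
  cols <- dots |> count(.data$scaffold_b, name = "col_margin")
  cells |>
    left_join(rows, by = "scaffold_a") |>
    left_join(cols, by = "scaffold_b") |>
    mutate(n_total = nrow(dots)) |>
    arrange(.data$scaffold_a, .data$scaffold_b)
}

#' Hypergeometric enrichment of Oxford-grid cells
#'
#' For each scaffold pair, tests whether it holds more homologous gene
#' pairs than expected if pairs fell on scaffolds independently:
#' `p_hyper = P[X >= n_shared]` with `X ~ Hypergeometric(n_total,
#' row_margin, col_margin)`. Benjamini-Hochberg `q_value` is computed
#' across all non-empty cells of the species pair (the set passed in).
#'
#' @param cells Cell table from [oxford_grid()].
#' @return `cells` with `p_hyper` and `q_value` columns added.
#' @export
cell_enrichment <- function(cells) {
  check_columns(cells, c("n_shared", "row_margin", "col_margin", "n_total"), "cell table")
  if (nrow(cells) == 0) return(mutate(cells, p_hyper = double(), q_value = double()))
  with(cells, {
    if (any(n_shared > pmin(row_margin, col_margin)) ||
      any(row_margin > n_total) || any(col_margin > n_total)) {
      abort("inconsistent margins: n_shared > min(margins) or margin > n_total")
    }
  })
  cells |>
    mutate(
      p_hyper = phyper(.data$n_shared - 1, .data$row_margin,
        .data$n_total - .data$row_margin, .data$col_margin,
        lower.tail = FALSE
      ),
      q_value = p.adjust(.data$p_hyper, method = "BH")
    )
}

#' Co-linearity statistics for one scaffold pair
#'
#' Given the within-scaffold ranks of the shared gene pairs, computes the
#' Spearman rank correlation and the longest-monotone-subsequence fraction:
#' `lis_fraction = max(LIS, LDS) / n`, where LIS/LDS are the longest
#' strictly increasing/decreasing subsequences of `rank_b` taken in
#' `rank_a` order. A perfectly co-linear segment scores 1 under either
#' orientation, so a whole-arm inversion still scores 1; within-chromosome
#' shuffling drives the fraction towards `2 sqrt(n) / n`.
#'
#' `spearman_rho` is reported as `NA` for fewer than 3 pairs; both
#' statistics are `NA` for fewer than 2 pairs (flagged, not an error).
#'
#' @param rank_a,rank_b Integer rank vectors of equal length.
#' @return Tibble with one row: `n_pairs`, `spearman_rho`, `lis_fraction`.
#' @examples
#' colinearity_stats(0:3, c(1, 3, 2, 4))  # rho 0.8, lis_fraction 0.75
#' @export
colinearity_stats <- function(rank_a, rank_b) {
  stopifnot(length(rank_a) == length(rank_b))
  n <- length(rank_a)
  if (n < 2) {
    return(tibble(n_pairs = n, spearman_rho = NA_real_, lis_fraction = NA_real_))
  }
  ord <- order(rank_a)
  b <- rank_b[ord]
  lis <- max(lis_length(b), lis_length(-b))
  rho <- if (n >= 3) suppressWarnings(cor(rank_a, rank_b, method = "spearman")) else NA_real_
  tibble(n_pairs = n, spearman_rho = rho, lis_fraction = lis / n)
}

#' Add per-cell co-linearity statistics to an Oxford grid
#'
#' @param cells Cell table ([oxford_grid()] or [cell_enrichment()]).
#' @param dots Dot table ([synteny_dots()]) over the same pair universe.
#' @return `cells` with `spearman_rho` and `lis_fraction` columns.
#' @export
add_colinearity <- function(cells, dots) {
  stats <- dots |>
    group_by(.data$scaffold_a, .data$scaffold_b) |>
    summarise(colinearity_stats(.data$rank_a, .data$rank_b), .groups = "drop") |>
    select(-"n_pairs")
  left_join(cells, stats, by = c("scaffold_a", "scaffold_b"))
}

#' Classify Oxford-grid cells
#'
#' A cell is `not_syntenic` unless it is both significantly enriched
#' (`q_value <= q_max`) and adequately populated (`n_shared >= min_pairs`).
#' Significant cells are `macrosyntenic_colinear` when
#' `lis_fraction >= colinear_min` and `macrosyntenic_shuffled` otherwise —
#' the shuffled class is the signature of gene content held on a
#' chromosome while local order is scrambled by within-chromosome
#' rearrangement (the DCJ-DS regime). Classification uses `lis_fraction`
#' only; `spearman_rho` is descriptive (and undefined below 3 pairs).
#'
#' @param cells Cell table with `q_value` and `lis_fraction` columns.
#' @param q_max Significance cutoff on BH q (default 0.05).
#' @param min_pairs Minimum shared pairs for a syntenic call (default 5).
#' @param colinear_min Minimum `lis_fraction` for the co-linear class
#'   (default 0.8).
#' @return `cells` with a `label` factor column.
#' @export
classify_cells <- function(cells, q_max = 0.05, min_pairs = 5, colinear_min = 0.8) {
  check_columns(cells, c("q_value", "n_shared", "lis_fraction"), "cell table")
  cells |>
    mutate(label = factor(
      dplyr::case_when(
        .data$q_value > q_max | .data$n_shared < min_pairs ~ "not_syntenic",
        !is.na(.data$lis_fraction) & .data$lis_fraction >= colinear_min ~
          "macrosyntenic_colinear",
        TRUE ~ "macrosyntenic_shuffled"
      ),
      levels = c("macrosyntenic_colinear", "macrosyntenic_shuffled", "not_syntenic")
    ))
}

#' Full macrosynteny analysis for one species pair
#'
#' Convenience wrapper: [synteny_dots()] -> [oxford_grid()] ->
#' [cell_enrichment()] -> [add_colinearity()] -> [classify_cells()].
#'
#' @inheritParams synteny_dots
#' @inheritParams classify_cells
#' @return List with `cells` (classified cell tibble) and `dots`.
#' @export
synteny_analysis <- function(pairs, annot_a, annot_b, q_max = 0.05,
                             min_pairs = 5, colinear_min = 0.8,
                             missing = "drop") {
  dots <- synteny_dots(pairs, annot_a, annot_b, missing = missing)
  cells <- oxford_grid(dots) |>
    cell_enrichment() |>
    add_colinearity(dots) |>
    classify_cells(q_max = q_max, min_pairs = min_pairs, colinear_min = colinear_min)
  list(cells = cells, dots = dots)
}

#' Genes of one scaffold shared across several species
#'
#' For a focal scaffold, reports which of its genes have homologues in
#' every one of a set of other species, under two definitions of
#' "shared": chained one-to-one pairings (`method = "rbh"`, a gene must
#' appear in the pairing with each species) or orthogroup membership
#' (`method = "orthogroup"`, the gene's orthogroup must be present in
#' every listed taxon). The two rules disagree whenever an orthogroup
#' survives in a species without a reciprocal best hit, so both are
#' exposed rather than silently picking one.
#'
#' @param annot Focal species' annotation.
#' @param scaffold Scaffold id in `annot`.
#' @param pairings Named list of pairing tibbles (`gene_a` = focal gene),
#'   one per other species; required for `method = "rbh"`.
#' @param og,focal_taxon,taxa Orthogroup table, the focal taxon column and
#'   the other taxon columns; required for `method = "orthogroup"`.
#' @param method `"rbh"` or `"orthogroup"`.
#' @return Tibble with `gene_id`, `rank`, `n_shared` (species with a
#'   homologue) and `shared_all` (logical).
#' @export
shared_on_scaffold <- function(annot, scaffold, pairings = NULL, og = NULL,
                               focal_taxon = NULL, taxa = NULL,
                               method = c("rbh", "orthogroup")) {
  method <- match.arg(method)
  genes <- filter(annot, .data$scaffold_id == scaffold)
  if (nrow(genes) == 0 && !scaffold %in% annot$scaffold_id) {
    abort(sprintf("unknown scaffold '%s'", scaffold))
  }
  if (method == "rbh") {
    if (is.null(pairings)) abort("method 'rbh' needs `pairings`")
    hit <- vapply(pairings, function(p) genes$gene_id %in% p$gene_a,
      logical(nrow(genes)))
    n_shared <- if (nrow(genes) == 0) integer(0) else rowSums(as.matrix(hit))
    n_species <- length(pairings)
  } else {
    if (is.null(og) || is.null(focal_taxon) || is.null(taxa)) {
      abort("method 'orthogroup' needs `og`, `focal_taxon` and `taxa`")
    }
    members <- og_members(og)
    if (is.null(members)) abort("orthogroup table has no gene-level members")
    P <- og_presence_matrix(og)
    og_of <- members$orthogroup[match(genes$gene_id, members$gene_id)]
    n_shared <- rowSums(P[, taxa, drop = FALSE])[match(og_of, og$orthogroup)]
    n_shared[is.na(n_shared)] <- 0
    n_species <- length(taxa)
  }
  tibble(
    gene_id = genes$gene_id, rank = genes$rank,
    n_shared = as.integer(n_shared),
    shared_all = as.integer(n_shared) == n_species
  ) |>
    arrange(.data$rank)
}
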