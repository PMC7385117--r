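#' Detect tandem gene arrays
#'
#' Finds maximal runs of same-family genes along one scaffold: consecutive
#' members may be separated by at most `max_gap` intervening genes (rank
#' difference at most `max_gap + 1`). Runs of at least two genes are
#' reported. Tandem arrays are the footprint of local duplication by
#' unequal crossing-over or replication slippage.
#'
#' @param annot Annotation tibble ([read_gene_annotation()]).
#' @param families Family assignment ([cluster_self_hits()]): columns
#'   `gene_id`, `family_id`.
#' @param max_gap Maximum number of intervening non-family genes between
#'   consecutive array members (default 1).
#' @return Tibble with one row per array: `species_id`, `scaffold_id`,
#'   `family_id`, `size`, `first_rank`, `last_rank`, `member_ranks`
#'   (list-column), `member_genes` (list-column).
#' @export
detect_tandem_arrays <- function(annot, families, max_gap = 1) {
  check_columns(families, c("gene_id", "family_id"), "family assignment")
  x <- annot |>
    inner_join(families, by = "gene_id") |>
    arrange(.data$species_id, .data$scaffold_id, .data$family_id, .data$rank)
  if (nrow(x) == 0) {
    return(tibble(
      species_id = character(), scaffold_id = character(), family_id = character(),
      size = integer(), first_rank = integer(), last_rank = integer(),
      member_ranks = list(), member_genes = list()
    ))
  }
  x |>
    group_by(.data$species_id, .data$scaffold_id, .data$family_id) |>
    mutate(run = cumsum(c(0L, diff(.data$rank) > max_gap + 1L))) |>
    group_by(.data$species_id, .data$scaffold_id, .data$family_id, .data$run) |>
    summarise(
      size = n(),
      first_rank = min(.data$rank),
      last_rank = max(.data$rank),
      member_ranks = list(.data$rank),
      member_genes = list(.data$gene_id),
      .groups = "drop"
    ) |>
    filter(.data$size >= 2L) |>
    select(-"run") |>
    arrange(.data$species_id, .data$scaffold_id, .data$first_rank)
}

#' Self-similarity dotplot for one scaffold
#'
#' Projects within-species similarity hits onto the rank coordinates of a
#' single scaffold: one point per kept hit plus its mirror image across the
#' diagonal. Orientation is `"forward"` when the two genes lie on the same
#' strand and `"reverse"` otherwise; a band of reverse-orientation points
#' marks an inverted segmental duplication.
#'
#' @param annot Annotation tibble.
#' @param self_hits Within-species similarity tibble; self rows ignored.
#' @param scaffold Scaffold id to plot; unknown scaffold is a hard error.
#' @param min_bitscore Drop hits below this bitscore (default 0, keep all).
#' @return Tibble with columns `rank_q`, `rank_s`, `orientation`,
#'   `gene_q`, `gene_s`; empty when there are no qualifying hits.
#' @export
self_dotplot <- function(annot, self_hits, scaffold, min_bitscore = 0) {
  onscaf <- filter(annot, .data$scaffold_id == scaffold)
  if (nrow(onscaf) == 0 && !scaffold %in% annot$scaffold_id) {
    abort(sprintf("unknown scaffold '%s'", scaffold))
  }
  loc <- select(onscaf, "gene_id", "rank", "strand")
  pts <- self_hits |>
    filter(.data$query_id != .data$subject_id, .data$bitscore >= min_bitscore) |>
    inner_join(select(loc, query_id = "gene_id", rank_q = "rank", strand_q = "strand"),
      by = "query_id") |>
    inner_join(select(loc, subject_id = "gene_id", rank_s = "rank", strand_s = "strand"),
      by = "subject_id") |>
    mutate(orientation = ifelse(.data$strand_q == .data$strand_s, "forward", "reverse")) |>
    select(gene_q = "query_id", gene_s = "subject_id", "rank_q", "rank_s", "orientation") |>
    distinct()
  mirror <- pts |>
    select(gene_q = "gene_s", gene_s = "gene_q", rank_q = "rank_s",
      rank_s = "rank_q", "orientation")
  bind_rows(pts, mirror) |>
    distinct() |>
    arrange(.data$rank_q, .data$rank_s) |>
    select("rank_q", "rank_s", "orientation", "gene_q", "gene_s")
}
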