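#' One-to-one orthologs by reciprocal best hits
#'
#' Builds a one-to-one ortholog pairing from two similarity tables oriented
#' A->B and B->A. Multiple HSP rows for the same (query, subject) are
#' collapsed to the best-scoring row first. A pair (a, b) is emitted iff b
#' is a's best subject and a is b's best subject.
#'
#' Best-hit ranking: maximum `bitscore` (or minimum `evalue` when
#' `rank_by = "evalue"`), then minimum `evalue` (respectively maximum
#' `bitscore`), then lexicographically smallest subject id. With
#' `ambiguous = "exclude"`, a query whose two top subjects are still tied
#' on both score keys is dropped from the pairing instead of resolved
#' lexicographically, since such genes have no defensible single ortholog
#' and pollute downstream synteny counts.
#'
#' The two species' gene namespaces must be disjoint; a shared id makes the
#' table orientation ambiguous and is a hard error. Self hits
#' (query == subject) are ignored.
#'
#' @param hits_ab,hits_ba Similarity tibbles ([read_similarity()]; only
#'   `query_id`, `subject_id`, `evalue`, `bitscore` are used).
#' @param rank_by Primary best-hit key, `"bitscore"` (default) or `"evalue"`.
#' @param ambiguous `"lexicographic"` (default; resolve score ties by
#'   subject id) or `"exclude"`.
#' @return Tibble with columns `gene_a`, `gene_b`, `bitscore_ab`,
#'   `bitscore_ba`, sorted by `gene_a`. Each gene appears at most once.
#' @examples
#' ab <- tibble::tibble(query_id = "a1", subject_id = "b1", evalue = 1e-50, bitscore = 100)
#' ba <- tibble::tibble(query_id = "b1", subject_id = "a1", evalue = 1e-48, bitscore = 95)
#' reciprocal_best_hits(ab, ba)
#' @export
reciprocal_best_hits <- function(hits_ab, hits_ba,
                                 rank_by = c("bitscore", "evalue"),
                                 ambiguous = c("lexicographic", "exclude")) {
  rank_by <- match.arg(rank_by)
  ambiguous <- match.arg(ambiguous)
  for (h in list(hits_ab, hits_ba)) {
    check_columns(h, c("query_id", "subject_id", "evalue", "bitscore"), "hit table")
  }
  hits_ab <- filter(hits_ab, .data$query_id != .data$subject_id)
  hits_ba <- filter(hits_ba, .data$query_id != .data$subject_id)
  genes_a <- unique(c(hits_ab$query_id, hits_ba$subject_id))
  genes_b <- unique(c(hits_ba$query_id, hits_ab$subject_id))
  shared <- intersect(genes_a, genes_b)
  if (length(shared) > 0) {
    abort(sprintf(
      "gene id(s) present in both species' namespaces (ambiguous orientation): %s",
      paste(head(shared, 5), collapse = ", ")
    ))
  }
  best_ab <- best_hits(hits_ab, rank_by, ambiguous)
  best_ba <- best_hits(hits_ba, rank_by, ambiguous)
  inner_join(
    best_ab |> select(gene_a = "query_id", gene_b = "subject_id", bitscore_ab = "bitscore"),
    best_ba |> select(gene_b = "query_id", gene_a = "subject_id", bitscore_ba = "bitscore"),
    by = c("gene_a", "gene_b")
  ) |>
    select("gene_a", "gene_b", "bitscore_ab", "bitscore_ba") |>
    arrange(.data$gene_a)
}

# collapse HSPs, then keep each query's single best subject under the tie policy
best_hits <- function(hits, rank_by, ambiguous) {
  if (nrow(hits) == 0) {
    return(tibble(query_id = character(), subject_id = character(), bitscore = double()))
  }
  collapsed <- hits |>
    group_by(.data$query_id, .data$subject_id) |>
    summarise(
      bitscore = max(.data$bitscore),
      evalue = min(.data$evalue[.data$bitscore == max(.data$bitscore)]),
      .groups = "drop"
    )
  if (rank_by == "bitscore") {
    collapsed <- arrange(collapsed, .data$query_id, dplyr::desc(.data$bitscore),
      .data$evalue, .data$subject_id)
  } else {
    collapsed <- arrange(collapsed, .data$query_id, .data$evalue,
      dplyr::desc(.data$bitscore), .data$subject_id)
  }
  top <- collapsed |>
    group_by(.data$query_id) |>
    mutate(
      .pos = row_number(),
      .tied = n() > 1 & .data$bitscore[1] == .data$bitscore[min(2, n())] &
        .data$evalue[1] == .data$evalue[min(2, n())]
    ) |>
    ungroup()
  if (ambiguous == "exclude") top <- filter(top, !.data$.tied)
  top |>
    filter(.data$.pos == 1L) |>
    select("query_id", "subject_id", "bitscore")
}

#' Within-genome gene families by single-linkage clustering of self hits
#'
#' Builds connected components over within-species similarity hits with
#' `bitscore >= min_bitscore` (single linkage); every gene of `genes` with
#' no qualifying hit becomes a singleton family. Family ids are
#' `FAM000001, ...`, assigned in order of each family's lexicographically
#' smallest member, so output is deterministic.
#'
#' @param self_hits Similarity tibble of within-species hits; self rows
#'   (query == subject) are ignored.
#' @param genes Character vector of all gene ids to cover (e.g. an
#'   annotation's `gene_id` column). Hit genes absent from `genes` are kept.
#' @param min_bitscore Minimum bitscore for an edge (default 50).
#' @return Tibble with columns `gene_id`, `family_id`, one row per gene.
#' @export
cluster_self_hits <- function(self_hits, genes = character(0), min_bitscore = 50) {
  check_columns(self_hits, c("query_id", "subject_id", "bitscore"), "hit table")
  edges <- self_hits |>
    filter(.data$query_id != .data$subject_id, .data$bitscore >= min_bitscore)
  all_genes <- sort(unique(c(genes, edges$query_id, edges$subject_id)))
  if (length(all_genes) == 0) {
    return(tibble(gene_id = character(), family_id = character()))
  }
  g <- igraph::graph_from_data_frame(
    edges[, c("query_id", "subject_id")],
    directed = FALSE,
    vertices = data.frame(name = all_genes)
  )
  comp <- igraph::components(g)$membership
  fam <- tibble(gene_id = names(comp), component = as.integer(comp)) |>
    group_by(.data$component) |>
    mutate(.anchor = min(.data$gene_id)) |>
    ungroup() |>
    arrange(.data$.anchor, .data$gene_id)
  ids <- sprintf("FAM%06d", match(fam$.anchor, unique(fam$.anchor)))
  tibble(gene_id = fam$gene_id, family_id = ids)
}
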