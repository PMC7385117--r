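# genuine within-orthogroup hit rows between two gene tables (one direction)
pair_hits <- function(genes_q, genes_s) {
  inner_join(
    select(genes_q, query_id = "gene_id", "og", gid_q = "gid"),
    select(genes_s, subject_id = "gene_id", "og", gid_s = "gid"),
    by = "og", relationship = "many-to-many"
  )
}

fill_blast_cols <- function(df) {
  n <- nrow(df)
  mutate(df,
    pident = round(runif(n, 60, 99), 1), length = 200L, mismatch = 10L,
    gapopen = 1L, qstart = 1L, qend = 200L, sstart = 1L, send = 200L,
    evalue = 10^(-.data$bitscore / 10)
  )[, BLAST6_COLS]
}

# one direction of a between-species table: score, degrade, contaminate
emit_direction <- function(genes_q, genes_s, config) {
  hits <- pair_hits(genes_q, genes_s)
  n <- nrow(hits)
  if (n > 0) {
    base <- ifelse(hits$gid_q == hits$gid_s, 500, 300)
    hits$bitscore <- base - runif(n, 0, 10)
    keep <- runif(n) >= config$similarity_dropout
    hits <- hits[keep, , drop = FALSE]
  } else {
    hits$bitscore <- double(0)
  }
  n_sp <- rpois(1, config$spurious_hit_rate * n)
  if (n_sp > 0 && nrow(genes_q) > 0 && nrow(genes_s) > 0) {
    sp <- tibble(
      query_id = sample(genes_q$gene_id, n_sp, replace = TRUE),
      subject_id = sample(genes_s$gene_id, n_sp, replace = TRUE),
      bitscore = runif(n_sp, 40, 60)
    )
    hits <- bind_rows(hits[, c("query_id", "subject_id", "bitscore")], sp)
  } else {
    hits <- hits[, c("query_id", "subject_id", "bitscore")]
  }
  fill_blast_cols(hits)
}

# within-species table (both row directions), used for families/dotplots
emit_self <- function(genes, config) {
  hits <- pair_hits(genes, genes) |>
    filter(.data$query_id != .data$subject_id)
  n <- nrow(hits)
  hits$bitscore <- 300 - runif(n, 0, 10)
  if (n > 0) hits <- hits[runif(n) >= config$similarity_dropout, , drop = FALSE]
  fill_blast_cols(hits[, c("query_id", "subject_id", "bitscore")])
}

#' Simulate a complete analysis-ready dataset
#'
#' Runs content simulation, optional convergent-loss planting, gene-order
#' simulation and similarity-table emission under one config. The result
#' holds every input the analysis modules consume, plus the ground truth.
#'
#' @param config A [sim_config()].
#' @return List of class `sim_dataset`: `config`, `tree`, `og` (an
#'   `og_tbl` with gene-level members), `annotations` (named list of
#'   annotation tibbles per tip, with truth columns `gid`, `og`),
#'   `similarity` (named list, `"<A>__<B>"` per ordered tip pair),
#'   `self_similarity` (named list per tip), `truth` (list: `planted`,
#'   `content_events`, `order`, `ortholog_map` per tip pair).
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  content <- simulate_gene_content(config)
  if (config$planted_convergent_losses > 0) {
    content <- plant_convergent_losses(content, L = config$planted_convergent_losses)
  }
  order <- simulate_gene_order(content)
  tips <- config$tree$tip.label
  annotations <- setNames(
    purrr::map(seq_along(tips), function(t) {
      genome_to_annotation(order$genomes[[t]], tips[t])
    }),
    tips
  )
  members <- bind_rows(annotations) |>
    select(orthogroup = "og", taxon = "species_id", "gene_id")
  og <- new_og_tbl(as_tibble(content$og), members)
  sims <- with_seed(config$seed + 2L, {
    out <- list()
    for (i in seq_along(tips)) {
      for (j in seq_along(tips)) {
        if (i == j) next
        out[[paste0(tips[i], "__", tips[j])]] <-
          emit_direction(annotations[[i]], annotations[[j]], config)
      }
    }
    selfs <- purrr::map(annotations, emit_self, config = config)
    list(between = out, self = selfs)
  })
  maps <- list()
  for (i in seq_along(tips)) {
    for (j in seq_along(tips)) {
      if (i >= j) next
      maps[[paste0(tips[i], "__", tips[j])]] <- inner_join(
        select(annotations[[i]], gene_a = "gene_id", "gid"),
        select(annotations[[j]], gene_b = "gene_id", "gid"),
        by = "gid"
      ) |> select("gene_a", "gene_b")
    }
  }
  structure(
    list(
      config = config, tree = config$tree, og = og,
      annotations = annotations, similarity = sims$between,
      self_similarity = sims$self,
      truth = list(
        planted = content$planted,
        content_events = content$events,
        node_states = content$node_states,
        order = order,
        ortholog_map = maps
      )
    ),
    class = "sim_dataset"
  )
}

#' Write a simulated dataset to disk
#'
#' Emits the standard-format fixture directory: one BED per tip, one
#' 12-column similarity table per ordered tip pair (`hits_<A>__<B>.tsv`)
#' and per tip (`self_<A>.tsv`), `Orthogroups.tsv`, `tree.nwk`,
#' `panel.tsv` when a panel is configured, and `truth.json` (seed, planted
#' losses, per-branch event counts). Identical config and seed give
#' byte-identical files.
#'
#' @param sim A `sim_dataset`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
emit_dataset <- function(sim, dir) {
  stopifnot(inherits(sim, "sim_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (tip in names(sim$annotations)) {
    write_gene_annotation(sim$annotations[[tip]], file.path(dir, paste0(tip, ".bed")))
    write_similarity(sim$self_similarity[[tip]], file.path(dir, paste0("self_", tip, ".tsv")))
  }
  for (nm in names(sim$similarity)) {
    write_similarity(sim$similarity[[nm]], file.path(dir, paste0("hits_", nm, ".tsv")))
  }
  write_orthogroups(sim$og, file.path(dir, "Orthogroups.tsv"))
  ape::write.tree(sim$tree, file.path(dir, "tree.nwk"))
  if (!is.null(sim$config$panel)) {
    readr::write_tsv(sim$config$panel, file.path(dir, "panel.tsv"))
  }
  ev <- sim$truth$content_events
  ev_counts <- purrr::imap(ev, function(e, node) {
    if (is.null(e)) return(NULL)
    list(node = as.integer(node), gains = length(e$gains),
      losses = length(e$losses), duplications = length(e$dups))
  })
  jsonlite::write_json(
    list(
      seed = sim$config$seed,
      planted_convergent_losses = sim$truth$planted,
      branch_event_counts = purrr::compact(ev_counts)
    ),
    file.path(dir, "truth.json"),
    auto_unbox = TRUE, pretty = TRUE
  )
  invisible(dir)
}
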