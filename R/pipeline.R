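default_run_params <- function() {
  list(
    rank_by = "bitscore", ambiguous = "lexicographic",
    q_max = 0.05, min_pairs = 5, colinear_min = 0.8,
    min_bitscore = 50, max_gap = 1,
    require_outside_presence = FALSE, background_mode = "auto",
    permutation_statistic = "loo_mean_diff"
  )
}

#' Run the full analysis pipeline
#'
#' Orchestrates the stages in dependency order — input loading, then
#' reciprocal best hits, macrosynteny and tandem arrays for the configured
#' species pair, Dollo gain/loss on the tree, and the habitat convergence
#' analysis — writing TSV/JSON outputs and a machine-readable run report.
#' A failing stage aborts only its dependents; independent stages still
#' run. Every parameter that affected a result (including untouched
#' defaults) is echoed into the report, so no silent defaults exist.
#'
#' Config is a YAML file or an equivalent nested list:
#' \preformatted{
#' seed: 1
#' inputs:
#'   annotation_a: a.bed      # BED or GFF3
#'   annotation_b: b.bed
#'   hits_ab: hits_A__B.tsv   # similarity tables, outfmt-6 dialect
#'   hits_ba: hits_B__A.tsv
#'   self_a: self_A.tsv       # optional, enables tandem stage
#'   orthogroups: Orthogroups.tsv
#'   tree: tree.nwk           # optional, enables gainloss stage
#'   alt_tree: alt.nwk        # optional second root hypothesis
#'   panel: panel.tsv         # optional, enables convergence stage
#' params:                    # optional overrides of the defaults
#'   q_max: 0.05
#' }
#'
#' @param config Path to a YAML config or a list.
#' @param out_dir Output directory.
#' @return The run report (list), invisibly; also written as
#'   `report.json` in `out_dir`. Stage outputs: `pairs.tsv`, `cells.tsv`,
#'   `dots.tsv`, `tandem.tsv`, `gainloss.tsv`, `convergence.json`.
#' @export
run_all <- function(config, out_dir) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  params <- utils::modifyList(default_run_params(), config$params %||% list())
  seed <- config$seed %||% 1L
  inputs <- config$inputs %||% list()
  existing <- purrr::keep(inputs, is.character)
  missing <- existing[!purrr::map_lgl(existing, file.exists)]
  if (length(missing) > 0) {
    abort(sprintf(
      "missing input file(s): %s",
      paste(sprintf("%s (%s)", names(missing), unlist(missing)), collapse = ", ")
    ))
  }
  report <- list(
    tool = "syngloss",
    version = as.character(utils::packageVersion("syngloss")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed,
    params = params,
    inputs = lapply(existing, function(p) {
      list(path = p, md5 = unname(tools::md5sum(p)))
    }),
    stages = list(),
    warnings = character(0)
  )
  note_warning <- function(w) {
    report$warnings <<- c(report$warnings, conditionMessage(w))
    invokeRestart("muffleWarning")
  }
  run_stage <- function(name, deps_ok, fn) {
    if (!deps_ok) {
      report$stages[[name]] <<- list(status = "skipped")
      inform(sprintf("stage %s skipped (unmet dependency or missing input)", name))
      return(NULL)
    }
    res <- tryCatch(
      withCallingHandlers(fn(), warning = note_warning),
      error = function(e) e
    )
    if (inherits(res, "error")) {
      report$stages[[name]] <<- list(status = "error", message = conditionMessage(res))
      warning(sprintf("stage %s failed: %s", name, conditionMessage(res)), call. = FALSE)
      return(NULL)
    }
    report$stages[[name]] <<- list(status = "ok")
    res
  }

  loaded <- run_stage("io", TRUE, function() {
    out <- list()
    if (!is.null(inputs$annotation_a)) out$annot_a <- read_gene_annotation(inputs$annotation_a)
    if (!is.null(inputs$annotation_b)) out$annot_b <- read_gene_annotation(inputs$annotation_b)
    if (!is.null(inputs$hits_ab)) out$hits_ab <- read_similarity(inputs$hits_ab)
    if (!is.null(inputs$hits_ba)) out$hits_ba <- read_similarity(inputs$hits_ba)
    if (!is.null(inputs$self_a)) out$self_a <- read_similarity(inputs$self_a)
    if (!is.null(inputs$orthogroups)) out$og <- read_orthogroups(inputs$orthogroups)
    if (!is.null(inputs$tree)) out$tree <- read_species_tree(inputs$tree)
    if (!is.null(inputs$alt_tree)) out$alt_tree <- read_species_tree(inputs$alt_tree)
    if (!is.null(inputs$panel)) out$panel <- read_habitat_panel(inputs$panel)
    if (!is.null(out$og)) {
      v <- validate_taxa(out$og, tree = out$tree, panel = out$panel)
      if (nrow(v) > 0) {
        abort(paste(
          "taxon names disagree between inputs:",
          paste(sprintf(
            "%s (missing from matrix: %s; missing from input: %s)",
            v$input, v$missing_from_matrix, v$missing_from_input
          ), collapse = "; ")
        ))
      }
    }
    out
  })
  if (is.null(loaded)) loaded <- list()

  pairs <- run_stage(
    "rbh", !is.null(loaded$hits_ab) && !is.null(loaded$hits_ba),
    function() {
      p <- reciprocal_best_hits(loaded$hits_ab, loaded$hits_ba,
        rank_by = params$rank_by, ambiguous = params$ambiguous
      )
      readr::write_tsv(p, file.path(out_dir, "pairs.tsv"))
      p
    }
  )

  run_stage(
    "synteny",
    !is.null(pairs) && !is.null(loaded$annot_a) && !is.null(loaded$annot_b),
    function() {
      res <- synteny_analysis(pairs, loaded$annot_a, loaded$annot_b,
        q_max = params$q_max, min_pairs = params$min_pairs,
        colinear_min = params$colinear_min
      )
      readr::write_tsv(
        select(res$cells, !dplyr::any_of("label")) |>
          mutate(label = as.character(res$cells$label)),
        file.path(out_dir, "cells.tsv")
      )
      readr::write_tsv(
        select(res$dots, "scaffold_a", "rank_a", "scaffold_b", "rank_b"),
        file.path(out_dir, "dots.tsv")
      )
      res
    }
  )

  run_stage(
    "tandem", !is.null(loaded$self_a) && !is.null(loaded$annot_a),
    function() {
      fams <- cluster_self_hits(loaded$self_a, loaded$annot_a$gene_id,
        min_bitscore = params$min_bitscore
      )
      arrays <- detect_tandem_arrays(loaded$annot_a, fams, max_gap = params$max_gap)
      readr::write_tsv(
        arrays |>
          mutate(
            member_ranks = purrr::map_chr(.data$member_ranks, paste, collapse = ","),
            member_genes = purrr::map_chr(.data$member_genes, paste, collapse = ",")
          ),
        file.path(out_dir, "tandem.tsv")
      )
      arrays
    }
  )

  run_stage(
    "gainloss", !is.null(loaded$og) && !is.null(loaded$tree),
    function() {
      gl <- summarize_gain_loss(loaded$og, loaded$tree)
      out <- gl$nodes
      if (!is.null(loaded$alt_tree)) {
        contrast <- topology_contrast(loaded$og, loaded$tree, loaded$alt_tree)
        readr::write_tsv(contrast$shared_clades, file.path(out_dir, "gainloss_contrast.tsv"))
      }
      readr::write_tsv(out, file.path(out_dir, "gainloss.tsv"))
      gl
    }
  )

  run_stage(
    "convergence", !is.null(loaded$og) && !is.null(loaded$panel),
    function() {
      conv <- convergence_analysis(loaded$og, loaded$panel,
        require_outside_presence = params$require_outside_presence,
        background_mode = params$background_mode, seed = seed,
        statistic = params$permutation_statistic
      )
      jsonlite::write_json(
        list(
          shared = conv$shared |>
            mutate(loo_counts = purrr::map(.data$loo_counts, as.list)),
          background_mean = conv$background_mean,
          t_tests = conv$t_tests$table,
          permutation = conv$permutation[c("p_value", "observed", "statistic", "n_assignments")]
        ),
        file.path(out_dir, "convergence.json"),
        auto_unbox = TRUE, digits = NA, pretty = TRUE
      )
      conv
    }
  )

  report$n_warnings <- length(report$warnings)
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
    auto_unbox = TRUE, pretty = TRUE, digits = NA
  )
  invisible(report)
}
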