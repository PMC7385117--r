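BLAST6_COLS <- c(
  "query_id", "subject_id", "pident", "length", "mismatch", "gapopen",
  "qstart", "qend", "sstart", "send", "evalue", "bitscore"
)

#' Read a 12-column tabular similarity table (BLAST outfmt 6 dialect)
#'
#' Columns are the standard `qseqid sseqid pident length mismatch gapopen
#' qstart qend sstart send evalue bitscore`, renamed to `query_id`,
#' `subject_id`, ..., `evalue`, `bitscore`. Row order is preserved.
#' Malformed rows (wrong column count, non-numeric score fields) are hard
#' errors reported with their line number.
#'
#' @param path Path to a tab-separated similarity table.
#' @return A tibble with the 12 columns above; zero rows for an empty file.
#' @export
read_similarity <- function(path) {
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(lines, "#")]
  if (length(lines) == 0) {
    out <- tibble(
      query_id = character(), subject_id = character(), pident = double(),
      length = integer(), mismatch = integer(), gapopen = integer(),
      qstart = integer(), qend = integer(), sstart = integer(),
      send = integer(), evalue = double(), bitscore = double()
    )
    return(out)
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncols <- lengths(fields)
  if (any(ncols != 12L)) {
    bad <- which(ncols != 12L)[1]
    abort(sprintf(
      "similarity table line %d has %d columns; 12 expected", bad, ncols[bad]
    ))
  }
  m <- matrix(unlist(fields), ncol = 12L, byrow = TRUE)
  num <- function(j, what) {
    v <- suppressWarnings(as.numeric(m[, j]))
    if (anyNA(v)) {
      abort(sprintf(
        "non-numeric %s on similarity table line %d", what, which(is.na(v))[1]
      ))
    }
    v
  }
  bit <- num(12, "bitscore")
  ev <- num(11, "evalue")
  if (any(ev < 0)) abort("negative e-value in similarity table")
  if (any(!is.finite(bit) | bit < 0)) abort("bitscore must be finite and non-negative")
  tibble(
    query_id = m[, 1], subject_id = m[, 2],
    pident = num(3, "pident"), length = as.integer(num(4, "length")),
    mismatch = as.integer(num(5, "mismatch")), gapopen = as.integer(num(6, "gapopen")),
    qstart = as.integer(num(7, "qstart")), qend = as.integer(num(8, "qend")),
    sstart = as.integer(num(9, "sstart")), send = as.integer(num(10, "send")),
    evalue = ev, bitscore = bit
  )
}

#' Write a similarity table in the 12-column tabular dialect
#'
#' @param hits Tibble as returned by [read_similarity()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_similarity <- function(hits, path) {
  check_columns(hits, BLAST6_COLS, "similarity table")
  readr::write_tsv(hits[, BLAST6_COLS], path, col_names = FALSE)
  invisible(path)
}

#' Read an orthogroup membership table
#'
#' Reads the OrthoFinder-style `Orthogroups.tsv` dialect: a TSV whose header
#' is `Orthogroup` followed by one column per taxon, and whose cells are
#' comma-separated gene lists (possibly empty). Returns a copy-number
#' table: one row per orthogroup, one integer column per taxon, with the
#' per-gene membership kept in the `members` attribute (see [og_members()]).
#'
#' A duplicated orthogroup id is a hard error; a gene id listed under two
#' taxa is kept but triggers a warning.
#'
#' @param path Path to an orthogroups TSV.
#' @return A tibble of class `og_tbl`: column `orthogroup`, then one integer
#'   count column per taxon.
#' @seealso [og_members()], [og_presence()], [write_orthogroups()]
#' @export
read_orthogroups <- function(path) {
  df <- readr::read_tsv(path,
    col_types = readr::cols(.default = readr::col_character()),
    na = character(), progress = FALSE
  )
  if (names(df)[1] != "Orthogroup") {
    abort("orthogroups table must have 'Orthogroup' as its first header field")
  }
  taxa <- names(df)[-1]
  dup <- unique(df$Orthogroup[duplicated(df$Orthogroup)])
  if (length(dup) > 0) {
    abort(sprintf("duplicated orthogroup id(s): %s", paste(head(dup, 5), collapse = ", ")))
  }
  members <- df |>
    rename(orthogroup = "Orthogroup") |>
    tidyr::pivot_longer(-"orthogroup", names_to = "taxon", values_to = "genes") |>
    mutate(genes = strsplit(.data$genes, ",[ ]*")) |>
    tidyr::unnest_longer("genes", values_to = "gene_id") |>
    filter(!is.na(.data$gene_id), nzchar(.data$gene_id)) |>
    select("orthogroup", "taxon", "gene_id")
  cross <- members |>
    distinct(.data$gene_id, .data$taxon) |>
    count(.data$gene_id) |>
    filter(.data$n > 1)
  if (nrow(cross) > 0) {
    warn(sprintf(
      "%d gene id(s) listed under more than one taxon (kept): %s",
      nrow(cross), paste(head(cross$gene_id, 3), collapse = ", ")
    ))
  }
  counts <- members |>
    count(.data$orthogroup, .data$taxon) |>
    tidyr::pivot_wider(names_from = "taxon", values_from = "n", values_fill = 0L)
  # keep original row and column order, including all-empty rows
  out <- tibble(orthogroup = df$Orthogroup) |>
    left_join(counts, by = "orthogroup")
  for (t in taxa) {
    if (!t %in% names(out)) out[[t]] <- 0L
    out[[t]][is.na(out[[t]])] <- 0L
    out[[t]] <- as.integer(out[[t]])
  }
  out <- out[, c("orthogroup", taxa)]
  new_og_tbl(out, members)
}

new_og_tbl <- function(counts, members = NULL) {
  attr(counts, "members") <- members
  class(counts) <- unique(c("og_tbl", class(counts)))
  counts
}

#' Per-gene orthogroup membership
#'
#' @param og An `og_tbl` from [read_orthogroups()] or the simulator.
#' @return Tibble with columns `orthogroup`, `taxon`, `gene_id`, or `NULL`
#'   when membership was not recorded. Note that dplyr transformations of
#'   the count table drop this attribute.
#' @export
og_members <- function(og) attr(og, "members", exact = TRUE)

#' Taxa of an orthogroup table
#' @param og An orthogroup count tibble (`orthogroup` column plus one
#'   column per taxon).
#' @return Character vector of taxon names.
#' @export
og_taxa <- function(og) setdiff(names(og), "orthogroup")

#' Binary presence view of an orthogroup table
#'
#' `presence[o, t]` is `TRUE` iff taxon `t` has at least one gene in
#' orthogroup `o`.
#'
#' @inheritParams og_taxa
#' @return Tibble with the same shape, taxon columns logical.
#' @export
og_presence <- function(og) {
  check_columns(og, "orthogroup", "orthogroup table")
  out <- og
  for (t in og_taxa(og)) out[[t]] <- og[[t]] >= 1L
  attr(out, "members") <- NULL
  class(out) <- setdiff(class(out), "og_tbl")
  out
}

# internal: presence as a logical matrix (rows = orthogroups)
og_presence_matrix <- function(og) {
  taxa <- og_taxa(og)
  m <- as.matrix(as.data.frame(og[taxa])) >= 1L
  rownames(m) <- og$orthogroup
  m
}

#' Write an orthogroup table in the Orthogroups.tsv dialect
#'
#' Uses the `members` attribute when present; otherwise placeholder gene
#' ids `<taxon>_<orthogroup>_<i>` are written so counts round-trip.
#'
#' @inheritParams og_members
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_orthogroups <- function(og, path) {
  taxa <- og_taxa(og)
  members <- og_members(og)
  if (is.null(members)) {
    members <- og |>
      tidyr::pivot_longer(-"orthogroup", names_to = "taxon", values_to = "n") |>
      filter(.data$n > 0) |>
      mutate(gene_id = purrr::map2(
        paste(.data$taxon, .data$orthogroup, sep = "_"), .data$n,
        function(p, k) paste0(p, "_", seq_len(k))
      )) |>
      tidyr::unnest_longer("gene_id") |>
      select("orthogroup", "taxon", "gene_id")
  }
  cells <- members |>
    group_by(.data$orthogroup, .data$taxon) |>
    summarise(genes = paste(.data$gene_id, collapse = ", "), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "taxon", values_from = "genes", values_fill = "")
  out <- tibble(Orthogroup = og$orthogroup) |>
    left_join(cells, by = c(Orthogroup = "orthogroup"))
  for (t in taxa) {
    if (!t %in% names(out)) out[[t]] <- ""
    out[[t]][is.na(out[[t]])] <- ""
  }
  readr::write_tsv(out[, c("Orthogroup", taxa)], path)
  invisible(path)
}
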