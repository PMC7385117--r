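#' Read a genome annotation as an ordered gene table
#'
#' Loads gene positions from BED (0-based half-open) or GFF3 (1-based
#' inclusive, converted to 0-based half-open internally) and assigns each
#' gene an ordinal `rank` along its scaffold: genes are sorted by ascending
#' `start`, with ties broken by (`end`, `gene_id`) so rank assignment is
#' deterministic. Ranks within a scaffold are exactly `0..n-1`.
#'
#' For GFF3 only features of type `gene` are used and the `ID` attribute is
#' the gene identifier. For BED the fourth column (name) is the gene
#' identifier; a sixth column, when present, supplies the strand.
#'
#' @param path Path to a BED4+ or GFF3 file.
#' @param format `"auto"` (by file extension), `"bed"` or `"gff3"`.
#' @param species_id Species label stored with every gene; defaults to the
#'   file name without extension.
#' @return A tibble with columns `gene_id`, `species_id`, `scaffold_id`,
#'   `rank` (0-based), `start`, `end` (0-based half-open), `strand`
#'   (`"+"`, `"-"` or `"*"` for unknown).
#' @seealso [write_gene_annotation()]
#' @export
read_gene_annotation <- function(path, format = c("auto", "bed", "gff3"),
                                 species_id = NULL) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.gff3?(\\.gz)?$", path, ignore.case = TRUE)) "gff3" else "bed"
  }
  if (is.null(species_id)) {
    species_id <- sub("\\.[^.]*$", "", basename(path))
  }
  raw <- if (format == "bed") read_bed_genes(path) else read_gff3_genes(path)
  rank_annotation(raw, species_id)
}

read_bed_genes <- function(path) {
  lines <- readr::read_lines(path)
  lines <- lines[!grepl("^(#|track|browser)", lines) & nzchar(trimws(lines))]
  if (length(lines) == 0) {
    return(tibble(
      scaffold_id = character(), start = integer(), end = integer(),
      gene_id = character(), strand = character()
    ))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncols <- lengths(fields)
  if (any(ncols < 4)) {
    abort(sprintf(
      "BED line %d has %d column(s); at least 4 (chrom, start, end, name) are required",
      which(ncols < 4)[1], ncols[which(ncols < 4)[1]]
    ))
  }
  tibble(
    scaffold_id = vapply(fields, `[[`, "", 1L),
    start = as.integer(vapply(fields, `[[`, "", 2L)),
    end = as.integer(vapply(fields, `[[`, "", 3L)),
    gene_id = vapply(fields, `[[`, "", 4L),
    strand = vapply(fields, function(f) {
      if (length(f) >= 6 && f[[6]] %in% c("+", "-")) f[[6]] else "*"
    }, "")
  )
}

read_gff3_genes <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[gr$type == "gene"]
  if (length(gr) == 0) {
    return(tibble(
      scaffold_id = character(), start = integer(), end = integer(),
      gene_id = character(), strand = character()
    ))
  }
  ids <- gr$ID
  if (is.null(ids) || anyNA(ids)) {
    abort("GFF3 gene feature without an ID attribute")
  }
  tibble(
    scaffold_id = as.character(GenomicRanges::seqnames(gr)),
    # GFF3 is 1-based inclusive; internal convention is 0-based half-open
    start = as.integer(GenomicRanges::start(gr)) - 1L,
    end = as.integer(GenomicRanges::end(gr)),
    gene_id = as.character(ids),
    strand = ifelse(as.character(GenomicRanges::strand(gr)) %in% c("+", "-"),
      as.character(GenomicRanges::strand(gr)), "*"
    )
  )
}

# sort by (scaffold, start, end, gene_id) and assign 0-based ranks
rank_annotation <- function(raw, species_id) {
  if (anyNA(raw$scaffold_id) | any(!nzchar(raw$scaffold_id))) {
    abort("gene feature without a scaffold")
  }
  dup <- unique(raw$gene_id[duplicated(raw$gene_id)])
  if (length(dup) > 0) {
    abort(sprintf(
      "duplicate gene ID(s): %s",
      paste(head(dup, 5), collapse = ", ")
    ))
  }
  raw |>
    mutate(species_id = species_id) |>
    arrange(.data$scaffold_id, .data$start, .data$end, .data$gene_id) |>
    group_by(.data$scaffold_id) |>
    mutate(rank = row_number() - 1L) |>
    ungroup() |>
    select("gene_id", "species_id", "scaffold_id", "rank", "start", "end", "strand")
}

#' Write a gene annotation to BED6
#'
#' Inverse of [read_gene_annotation()] for the BED path: writing then
#' re-reading reproduces the same table (score column is a placeholder 0).
#'
#' @param annot Annotation tibble as returned by [read_gene_annotation()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_annotation <- function(annot, path) {
  check_columns(annot, c("gene_id", "scaffold_id", "rank", "start", "end", "strand"),
    "annotation")
  bed <- annot |>
    arrange(.data$scaffold_id, .data$start, .data$end, .data$gene_id) |>
    mutate(score = 0L, strand = ifelse(.data$strand %in% c("+", "-"), .data$strand, ".")) |>
    select("scaffold_id", "start", "end", "gene_id", "score", "strand")
  readr::write_tsv(bed, path, col_names = FALSE)
  invisible(path)
}
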