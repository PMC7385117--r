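# small in-code fixture builders shared across test files

make_og <- function(counts, taxa, orthogroups = NULL) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "integer"
  if (is.null(orthogroups)) orthogroups <- sprintf("OG%05d", seq_len(nrow(counts)))
  df <- tibble::as_tibble(as.data.frame(counts))
  names(df) <- taxa
  df <- dplyr::mutate(df, orthogroup = orthogroups, .before = 1)
  class(df) <- c("og_tbl", class(df))
  df
}

make_annotation <- function(scaffolds, species = "sp") {
  # scaffolds: named list scaffold_id -> character vector of gene ids in order
  rows <- purrr::imap(scaffolds, function(genes, scaf) {
    tibble::tibble(
      gene_id = genes, species_id = species, scaffold_id = scaf,
      rank = seq_along(genes) - 1L,
      start = (seq_along(genes) - 1L) * 100L,
      end = (seq_along(genes) - 1L) * 100L + 50L,
      strand = "+"
    )
  })
  dplyr::bind_rows(rows)
}

make_hits <- function(query, subject, bitscore, evalue = 10^(-bitscore / 10)) {
  tibble::tibble(
    query_id = query, subject_id = subject, pident = 90, length = 100L,
    mismatch = 5L, gapopen = 1L, qstart = 1L, qend = 100L, sstart = 1L,
    send = 100L, evalue = evalue, bitscore = bitscore
  )
}

four_pair_panel <- tibble::tibble(
  phylum = paste0("P", 1:4),
  marine_taxon = paste0("m", 1:4),
  freshwater_taxon = paste0("f", 1:4)
)

# four marine/freshwater sister pairs, unit branch lengths
four_pair_tree_nwk <- paste0(
  "((m1:1,f1:1):1,((m2:1,f2:1):1,((m3:1,f3:1):1,(m4:1,f4:1):1):1):1);"
)
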