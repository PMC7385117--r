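#' Configuration for the genome-evolution simulator
#'
#' Bundles and validates every simulator parameter. The generative model:
#' orthogroup content evolves along the tree by gain (new orthogroups,
#' Poisson with rate `gain_rate` per unit branch length), strict Dollo loss
#' (each orthogroup lost with probability `1 - exp(-loss_rate * len)`,
#' irreversibly — re-gain is disallowed so reconstruction equality can be
#' exact), and duplication (extra copies, Poisson `duplication_rate` per
#' retained orthogroup). Gene order evolves by within-chromosome
#' inversions (`inversion_rate`) that reverse a uniform interval and flip
#' strands, and rarer between-chromosome translocations
#' (`translocation_rate`) that move a segment. New gene copies insert
#' adjacent to their parent with probability `p_tandem` (tandem arrays),
#' else at a uniform position. Emitted similarity tables contain a mutual
#' hit for every within-orthogroup gene pair, degraded by per-row
#' `similarity_dropout` and contaminated by `spurious_hit_rate` random
#' low-score hits per genuine row.
#'
#' All randomness flows from `seed` through fixed per-stage substreams
#' (`seed`, `seed + 1`, ...), so an identical config yields byte-identical
#' emitted files.
#'
#' @param tree An [ape::phylo] or a Newick string. Branch lengths are taken
#'   from the tree; unit lengths are substituted with a warning if absent.
#' @param root_orthogroups Orthogroups present at the root (default 200).
#' @param gain_rate,loss_rate,duplication_rate Content event rates per unit
#'   branch length (defaults 5, 0.3, 0.2).
#' @param n_chromosomes Chromosomes at the root (default 3).
#' @param inversion_rate,translocation_rate Rearrangement rates per unit
#'   branch length (defaults 5, 0.2).
#' @param p_tandem Probability a duplicate inserts adjacent to its parent
#'   (default 0.6).
#' @param similarity_dropout Per-row drop probability for emitted hits
#'   (default 0.05).
#' @param spurious_hit_rate Expected spurious hits per genuine row
#'   (default 0.02).
#' @param planted_convergent_losses Number of orthogroups forced absent in
#'   every freshwater panel taxon (default 0; requires `panel`).
#' @param panel Optional habitat panel whose taxa are tree tips.
#' @param seed Integer seed (default 1).
#' @return Validated list of class `sim_config`.
#' @export
sim_config <- function(tree, root_orthogroups = 200, gain_rate = 5,
                       loss_rate = 0.3, duplication_rate = 0.2,
                       n_chromosomes = 3, inversion_rate = 5,
                       translocation_rate = 0.2, p_tandem = 0.6,
                       similarity_dropout = 0.05, spurious_hit_rate = 0.02,
                       planted_convergent_losses = 0, panel = NULL, seed = 1) {
  if (is.character(tree)) tree <- ape::read.tree(text = tree)
  if (!inherits(tree, "phylo")) abort("tree must be a phylo object or Newick string")
  if (is.null(tree$edge.length)) {
    warn("tree has no branch lengths; substituting unit lengths")
    tree$edge.length <- rep(1, nrow(tree$edge))
  }
  rates <- c(
    gain_rate = gain_rate, loss_rate = loss_rate,
    duplication_rate = duplication_rate, inversion_rate = inversion_rate,
    translocation_rate = translocation_rate
  )
  if (any(rates < 0)) abort("rates must be non-negative")
  probs <- c(
    p_tandem = p_tandem, similarity_dropout = similarity_dropout
  )
  if (any(probs < 0 | probs > 1)) abort("probabilities must be in [0, 1]")
  if (spurious_hit_rate < 0) abort("spurious_hit_rate must be non-negative")
  if (planted_convergent_losses > 0 && is.null(panel)) {
    abort("planted_convergent_losses > 0 requires a panel")
  }
  if (!is.null(panel)) {
    validate_panel(panel)
    missing_tips <- setdiff(
      c(panel$marine_taxon, panel$freshwater_taxon), tree$tip.label
    )
    if (length(missing_tips) > 0) {
      abort(sprintf("panel taxa not in tree: %s", paste(missing_tips, collapse = ", ")))
    }
  }
  structure(
    list(
      tree = tree, root_orthogroups = as.integer(root_orthogroups),
      gain_rate = gain_rate, loss_rate = loss_rate,
      duplication_rate = duplication_rate,
      n_chromosomes = as.integer(n_chromosomes),
      inversion_rate = inversion_rate, translocation_rate = translocation_rate,
      p_tandem = p_tandem, similarity_dropout = similarity_dropout,
      spurious_hit_rate = spurious_hit_rate,
      planted_convergent_losses = as.integer(planted_convergent_losses),
      panel = panel, seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

# preorder edge table: parent, child, length (parents always before children)
preorder_edges <- function(tree) {
  tr <- ape::reorder.phylo(tree, "cladewise")
  tibble(parent = tr$edge[, 1], child = tr$edge[, 2], len = tr$edge.length)
}

#' Simulate orthogroup content evolution on the tree
#'
#' Strict Dollo content model: see [sim_config()]. Returns the tip
#' copy-number matrix together with the full per-branch event log and
#' per-node states, the ground truth for recovery tests.
#'
#' @param config A [sim_config()].
#' @return List of class `sim_content`: `og` (an `og_tbl` over the tips,
#'   restricted to orthogroups present in at least one tip), `node_states`
#'   (per ape node id, named count vectors), `events` (per child node id:
#'   `gains`, `losses`, `dups` orthogroup id vectors), `planted`
#'   (character vector, filled by planting), `tree`, `config`.
#' @export
simulate_gene_content <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  tree <- config$tree
  with_seed(config$seed, {
    counter <- new.env()
    counter$og <- 0L
    new_ogs <- function(k) {
      if (k == 0) return(character(0))
      ids <- sprintf("OG%06d", counter$og + seq_len(k))
      counter$og <- counter$og + k
      ids
    }
    ntip <- length(tree$tip.label)
    root <- ntip + 1L
    states <- vector("list", ntip + tree$Nnode)
    states[[root]] <- setNames(
      rep(1L, config$root_orthogroups), new_ogs(config$root_orthogroups)
    )
    events <- vector("list", ntip + tree$Nnode)
    edges <- preorder_edges(tree)
    for (k in seq_len(nrow(edges))) {
      p <- edges$parent[k]; ch <- edges$child[k]; len <- edges$len[k]
      cur <- states[[p]]
      p_loss <- 1 - exp(-config$loss_rate * len)
      lost <- names(cur)[runif(length(cur)) < p_loss]
      cur <- cur[!names(cur) %in% lost]
      gained <- new_ogs(rpois(1, config$gain_rate * len))
      cur <- c(cur, setNames(rep(1L, length(gained)), gained))
      dup_counts <- if (length(cur) > 0) {
        rpois(length(cur), config$duplication_rate * len)
      } else {
        integer(0)
      }
      dups <- rep(names(cur), dup_counts)
      cur <- cur + setNames(
        tabulate(match(dups, names(cur)), nbins = length(cur)), NULL
      )
      states[[ch]] <- cur
      events[[ch]] <- list(gains = gained, losses = lost, dups = dups)
    }
    all_ogs <- sprintf("OG%06d", seq_len(counter$og))
    tips <- seq_len(ntip)
    counts <- vapply(tips, function(t) {
      s <- states[[t]]
      out <- setNames(rep(0L, length(all_ogs)), all_ogs)
      out[names(s)] <- s
      out
    }, integer(length(all_ogs)))
    colnames(counts) <- tree$tip.label
    keep <- rowSums(counts) > 0
    og <- as_tibble(counts[keep, , drop = FALSE]) |>
      mutate(orthogroup = all_ogs[keep], .before = 1)
    structure(
      list(
        og = new_og_tbl(og), node_states = states, events = events,
        planted = character(0), tree = tree, config = config
      ),
      class = "sim_content"
    )
  })
}

#' Plant convergent losses in freshwater panel taxa
#'
#' Samples `L` orthogroups present in every marine panel taxon and sets
#' them absent in every freshwater panel taxon (marine copies untouched).
#' Works on a bare orthogroup count table or on a `sim_content` object; in
#' the latter case tip states and the terminal-branch event logs are
#' updated so downstream gene-order simulation stays consistent.
#'
#' @param x An `og_tbl` or a `sim_content`.
#' @param panel Habitat panel; for `sim_content`, defaults to the config's.
#' @param L Number of losses to plant; a hard error if fewer than `L`
#'   orthogroups are present in all marine taxa.
#' @param seed Seed for sampling (default: config seed + 3 for
#'   `sim_content`, 1 otherwise).
#' @return For an `og_tbl`: list with `og` (modified) and `planted`
#'   (orthogroup ids). For `sim_content`: the modified `sim_content` with
#'   its `planted` field filled.
#' @export
plant_convergent_losses <- function(x, panel = NULL, L, seed = NULL) {
  if (inherits(x, "sim_content")) {
    panel <- panel %||% x$config$panel
    seed <- seed %||% (x$config$seed + 3L)
    if (is.null(panel)) abort("no panel available for planting")
    planted <- with_seed(seed, sample_plantable(x$og, panel, L))
    tipidx <- match(c(panel$freshwater_taxon), x$tree$tip.label)
    for (t in tipidx) {
      s <- x$node_states[[t]]
      x$node_states[[t]] <- s[!names(s) %in% planted]
      x$events[[t]]$losses <- union(x$events[[t]]$losses, planted)
    }
    for (tx in panel$freshwater_taxon) {
      x$og[[tx]][x$og$orthogroup %in% planted] <- 0L
    }
    keep <- rowSums(og_presence_matrix(x$og)) > 0
    x$og <- new_og_tbl(x$og[keep, ])
    x$planted <- planted
    return(x)
  }
  if (is.null(panel)) abort("panel is required")
  seed <- seed %||% 1L
  planted <- with_seed(seed, sample_plantable(x, panel, L))
  out <- x
  for (tx in panel$freshwater_taxon) {
    out[[tx]][out$orthogroup %in% planted] <- 0L
  }
  list(og = out, planted = planted)
}

sample_plantable <- function(og, panel, L) {
  if (L == 0) return(character(0))
  P <- og_presence_matrix(og)
  eligible <- og$orthogroup[
    rowSums(P[, panel$marine_taxon, drop = FALSE]) == nrow(panel)
  ]
  if (length(eligible) < L) {
    abort(sprintf(
      "cannot plant %d losses: only %d orthogroups present in all marine taxa",
      L, length(eligible)
    ))
  }
  sort(sample(eligible, L))
}

# --- gene order --------------------------------------------------------------

# genome = list of data.frames (gid, og, strand) per chromosome
apply_order_event <- function(genome, ev) {
  switch(ev$type,
    loss = lapply(genome, function(g) g[!g$og %in% ev$ogs, , drop = FALSE]),
    gain = ,
    dup = {
      g <- genome[[ev$chrom]]
      row <- data.frame(gid = ev$gid, og = ev$og, strand = ev$strand)
      genome[[ev$chrom]] <- insert_rows(g, row, ev$pos)
      genome
    },
    inversion = {
      g <- genome[[ev$chrom]]
      idx <- ev$from:ev$to
      seg <- g[rev(idx), , drop = FALSE]
      seg$strand <- ifelse(seg$strand == "+", "-", "+")
      g[idx, ] <- seg
      genome[[ev$chrom]] <- g
      genome
    },
    translocation = {
      src <- genome[[ev$src]]
      idx <- ev$from:(ev$from + ev$len - 1L)
      seg <- src[idx, , drop = FALSE]
      genome[[ev$src]] <- src[-idx, , drop = FALSE]
      genome[[ev$dest]] <- insert_rows(genome[[ev$dest]], seg, ev$pos)
      genome
    },
    abort(sprintf("unknown event type '%s'", ev$type))
  )
}

insert_rows <- function(g, rows, pos) {
  # pos = 1-based index the inserted block will occupy
  n <- nrow(g)
  if (pos <= 1) {
    rbind(rows, g)
  } else if (pos > n) {
    rbind(g, rows)
  } else {
    rbind(g[seq_len(pos - 1L), , drop = FALSE], rows, g[pos:n, , drop = FALSE])
  }
}

#' Simulate gene order evolution given simulated content
#'
#' Distributes the root orthogroups over chromosomes, then walks the tree
#' applying the content events (loss, gain, duplication) and the
#' rearrangement events (inversions, then translocations) drawn for each
#' branch. Every applied event is logged with concrete coordinates so the
#' log replays exactly (see [replay_gene_order()]).
#'
#' @param content A `sim_content` (after planting, if any).
#' @return List of class `sim_order`: `genomes` (per node id, list of
#'   per-chromosome data frames `gid`, `og`, `strand`), `order_events`
#'   (per child node id, list of event records in application order),
#'   `root_genome`, `tree`, `config`.
#' @export
simulate_gene_order <- function(content) {
  stopifnot(inherits(content, "sim_content"))
  config <- content$config
  tree <- content$tree
  with_seed(config$seed + 1L, {
    counter <- new.env()
    counter$gid <- 0L
    new_gid <- function() {
      counter$gid <- counter$gid + 1L
      counter$gid
    }
    ntip <- length(tree$tip.label)
    root <- ntip + 1L
    root_state <- content$node_states[[root]]
    n0 <- length(root_state)
    chrom_of <- sample(rep(seq_len(config$n_chromosomes), length.out = n0))
    ord <- sample(n0)
    root_genome <- lapply(seq_len(config$n_chromosomes), function(k) {
      sel <- ord[chrom_of[ord] == k]
      data.frame(
        gid = vapply(sel, function(i) new_gid(), 0L),
        og = names(root_state)[sel],
        strand = sample(c("+", "-"), sum(chrom_of == k), replace = TRUE)
      )
    })
    genomes <- vector("list", ntip + tree$Nnode)
    genomes[[root]] <- root_genome
    order_events <- vector("list", ntip + tree$Nnode)
    edges <- preorder_edges(tree)
    for (k in seq_len(nrow(edges))) {
      p <- edges$parent[k]; ch <- edges$child[k]; len <- edges$len[k]
      g <- genomes[[p]]
      ev_list <- list()
      emit <- function(ev) {
        ev_list[[length(ev_list) + 1L]] <<- ev
        g <<- apply_order_event(g, ev)
      }
      cev <- content$events[[ch]]
      if (length(cev$losses) > 0) emit(list(type = "loss", ogs = cev$losses))
      for (og in cev$gains) {
        chrom <- sample.int(config$n_chromosomes, 1)
        emit(list(
          type = "gain", og = og, gid = new_gid(), chrom = chrom,
          pos = sample.int(nrow(g[[chrom]]) + 1L, 1),
          strand = sample(c("+", "-"), 1)
        ))
      }
      for (og in cev$dups) {
        hits <- purrr::map(g, function(x) which(x$og == og))
        chroms <- rep(seq_along(g), lengths(hits))
        rows <- unlist(hits)
        if (length(rows) == 0) next # orthogroup removed by planted loss
        pick <- sample.int(length(rows), 1)
        c0 <- chroms[pick]; i0 <- rows[pick]
        if (runif(1) < config$p_tandem) {
          emit(list(
            type = "dup", og = og, gid = new_gid(), chrom = c0,
            pos = i0 + 1L, strand = g[[c0]]$strand[i0], tandem = TRUE
          ))
        } else {
          chrom <- sample.int(config$n_chromosomes, 1)
          emit(list(
            type = "dup", og = og, gid = new_gid(), chrom = chrom,
            pos = sample.int(nrow(g[[chrom]]) + 1L, 1),
            strand = sample(c("+", "-"), 1), tandem = FALSE
          ))
        }
      }
      n_inv <- rpois(1, config$inversion_rate * len)
      for (i in seq_len(n_inv)) {
        sizes <- vapply(g, nrow, 0L)
        ok <- which(sizes >= 2)
        if (length(ok) == 0) break
        chrom <- ok[sample.int(length(ok), 1)]
        bounds <- sort(sample.int(sizes[chrom], 2))
        emit(list(type = "inversion", chrom = chrom, from = bounds[1], to = bounds[2]))
      }
      n_tr <- rpois(1, config$translocation_rate * len)
      for (i in seq_len(n_tr)) {
        sizes <- vapply(g, nrow, 0L)
        ok <- which(sizes >= 1)
        if (length(ok) == 0 || length(g) < 2) break
        src <- ok[sample.int(length(ok), 1)]
        from <- sample.int(sizes[src], 1)
        seg_len <- min(1L + rpois(1, 4), sizes[src] - from + 1L)
        dest <- sample(setdiff(seq_along(g), src), 1)
        emit(list(
          type = "translocation", src = src, from = from, len = seg_len,
          dest = dest, pos = sample.int(sizes[dest] + 1L, 1)
        ))
      }
      genomes[[ch]] <- g
      order_events[[ch]] <- ev_list
    }
    structure(
      list(
        genomes = genomes, order_events = order_events,
        root_genome = root_genome, tree = tree, config = config
      ),
      class = "sim_order"
    )
  })
}

#' Replay an order event log from the root
#'
#' Applies each branch's logged events to the parent genome and checks the
#' result against the stored child genome. Used to assert that the event
#' log fully determines every tip genome.
#'
#' @param order A `sim_order`.
#' @return `TRUE` invisibly if every node replays exactly; otherwise a
#'   hard error naming the first mismatching node.
#' @export
replay_gene_order <- function(order) {
  edges <- preorder_edges(order$tree)
  genomes <- vector("list", length(order$genomes))
  root <- length(order$tree$tip.label) + 1L
  genomes[[root]] <- order$root_genome
  for (k in seq_len(nrow(edges))) {
    p <- edges$parent[k]; ch <- edges$child[k]
    g <- genomes[[p]]
    for (ev in order$order_events[[ch]]) g <- apply_order_event(g, ev)
    genomes[[ch]] <- g
    stored <- order$genomes[[ch]]
    same <- all(vapply(seq_along(g), function(i) {
      identical(g[[i]]$gid, stored[[i]]$gid) &&
        identical(g[[i]]$og, stored[[i]]$og) &&
        identical(g[[i]]$strand, stored[[i]]$strand)
    }, TRUE))
    if (!same) abort(sprintf("event-log replay mismatch at node %d", ch))
  }
  invisible(TRUE)
}

# tip genome -> annotation tibble (+ truth columns gid, og)
genome_to_annotation <- function(genome, tip) {
  rows <- purrr::imap(genome, function(g, k) {
    n <- nrow(g)
    if (n == 0) return(NULL)
    tibble(
      gene_id = sprintf("%s_g%05d", tip, g$gid),
      species_id = tip,
      scaffold_id = sprintf("chr%02d", as.integer(k)),
      rank = seq_len(n) - 1L,
      start = (seq_len(n) - 1L) * 1000L,
      end = (seq_len(n) - 1L) * 1000L + 900L,
      strand = g$strand,
      gid = g$gid,
      og = g$og
    )
  })
  bind_rows(rows)
}
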