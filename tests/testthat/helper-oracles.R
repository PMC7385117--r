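# Independent brute-force oracles. These deliberately share no code with
# the package implementations they check.

# --- reciprocal best hits ----------------------------------------------------

# plain-loop RBH with the bitscore > evalue > subject-id tie policy
oracle_rbh <- function(hits_ab, hits_ba) {
  collapse <- function(h) {
    out <- list()
    for (i in seq_len(nrow(h))) {
      key <- paste(h$query_id[i], h$subject_id[i], sep = "\r")
      cur <- out[[key]]
      if (is.null(cur) ||
        h$bitscore[i] > cur$bitscore ||
        (h$bitscore[i] == cur$bitscore && h$evalue[i] < cur$evalue)) {
        out[[key]] <- list(
          query = h$query_id[i], subject = h$subject_id[i],
          bitscore = h$bitscore[i], evalue = h$evalue[i]
        )
      }
    }
    out
  }
  best <- function(rows) {
    per_query <- list()
    for (r in rows) {
      b <- per_query[[r$query]]
      if (is.null(b) ||
        r$bitscore > b$bitscore ||
        (r$bitscore == b$bitscore && r$evalue < b$evalue) ||
        (r$bitscore == b$bitscore && r$evalue == b$evalue && r$subject < b$subject)) {
        per_query[[r$query]] <- r
      }
    }
    per_query
  }
  best_ab <- best(collapse(hits_ab))
  best_ba <- best(collapse(hits_ba))
  pairs <- list()
  for (a in names(best_ab)) {
    b <- best_ab[[a]]$subject
    if (!is.null(best_ba[[b]]) && best_ba[[b]]$subject == a) {
      pairs[[length(pairs) + 1]] <- c(a, b)
    }
  }
  if (length(pairs) == 0) {
    return(data.frame(gene_a = character(), gene_b = character()))
  }
  m <- do.call(rbind, pairs)
  df <- data.frame(gene_a = m[, 1], gene_b = m[, 2])
  df[order(df$gene_a), , drop = FALSE]
}

random_hit_table <- function(genes_q, genes_s, p_hit = 0.15,
                             scores = seq(40, 80, by = 5)) {
  rows <- expand.grid(query_id = genes_q, subject_id = genes_s,
    stringsAsFactors = FALSE)
  rows <- rows[runif(nrow(rows)) < p_hit, , drop = FALSE]
  n <- nrow(rows)
  # coarse score/evalue grids on purpose: ties must occur
  rows$bitscore <- sample(scores, n, replace = TRUE)
  rows$evalue <- sample(c(1e-10, 1e-8, 1e-6), n, replace = TRUE)
  tibble::as_tibble(rows)
}

# --- hypergeometric upper tail ----------------------------------------------

oracle_hyper_tail <- function(k, row_margin, col_margin, n_total) {
  upper <- min(row_margin, col_margin)
  if (k > upper) return(0)
  i <- k:upper
  sum(choose(row_margin, i) * choose(n_total - row_margin, col_margin - i)) /
    choose(n_total, col_margin)
}

# --- Dollo: exhaustive minimal single-gain assignment ------------------------

# Enumerates every 0/1 assignment to internal nodes (tips fixed by
# presence), keeps assignments with exactly one gain (a 0->1 edge, or
# presence at the root), and among those minimizes the number of 1->0
# edges. Returns the unique minimum: origin node and loss-edge child ids.
oracle_dollo <- function(tree, present_tips) {
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  root <- ntip + 1L
  tip_state <- as.integer(tree$tip.label %in% present_tips)
  internals <- (ntip + 1L):nnode
  best <- NULL
  for (code in 0:(2^length(internals) - 1)) {
    state <- integer(nnode)
    state[seq_len(ntip)] <- tip_state
    state[internals] <- bitwAnd(bitwShiftR(code, seq_along(internals) - 1L), 1L)
    gains <- sum(state[tree$edge[, 1]] == 0 & state[tree$edge[, 2]] == 1) +
      state[root]
    if (gains != 1) next
    losses <- which(state[tree$edge[, 1]] == 1 & state[tree$edge[, 2]] == 0)
    if (is.null(best) || length(losses) < length(best$n_losses)) {
      origin <- if (state[root] == 1) {
        root
      } else {
        tree$edge[state[tree$edge[, 1]] == 0 & state[tree$edge[, 2]] == 1, 2]
      }
      best <- list(
        origin = origin,
        loss_children = sort(tree$edge[losses, 2]),
        n_losses = losses
      )
    }
  }
  best
}

# all rooted binary tree shapes with n tips, as Newick strings labelled
# t1..tn left to right
all_tree_shapes <- function(n) {
  shapes <- function(k) {
    if (k == 1) return("x")
    out <- character(0)
    for (i in seq_len(k %/% 2)) {
      left <- shapes(i); right <- shapes(k - i)
      for (l in left) {
        for (r in right) {
          if (i == k - i && l > r) next # unordered pair: dedupe
          out <- c(out, paste0("(", l, ",", r, ")"))
        }
      }
    }
    unique(out)
  }
  vapply(shapes(n), function(s) {
    for (i in seq_len(n)) s <- sub("x", paste0("t", i), s, fixed = TRUE)
    paste0(s, ";")
  }, "", USE.NAMES = FALSE)
}

# --- misc small oracles ------------------------------------------------------

# longest strictly increasing subsequence by exhaustive subset enumeration
oracle_lis <- function(x) {
  n <- length(x)
  if (n == 0) return(0L)
  best <- 0L
  for (code in 1:(2^n - 1)) {
    idx <- which(bitwAnd(bitwShiftR(code, 0:(n - 1)), 1L) == 1L)
    v <- x[idx]
    if (all(diff(v) > 0) && length(v) > best) best <- length(v)
  }
  best
}

# connected components by hand-rolled BFS over an edge list
oracle_components <- function(edges, vertices) {
  adj <- setNames(vector("list", length(vertices)), vertices)
  for (i in seq_len(nrow(edges))) {
    a <- edges[i, 1]; b <- edges[i, 2]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  comp <- setNames(rep(NA_integer_, length(vertices)), vertices)
  k <- 0L
  for (v in vertices) {
    if (!is.na(comp[[v]])) next
    k <- k + 1L
    queue <- v
    while (length(queue) > 0) {
      u <- queue[[1]]; queue <- queue[-1]
      if (!is.na(comp[[u]])) next
      comp[[u]] <- k
      queue <- c(queue, adj[[u]])
    }
  }
  comp
}

# Welch / pooled t-test from first principles
oracle_t <- function(x, y, pooled, one_sided) {
  nx <- length(x); ny <- length(y)
  vx <- var(x); vy <- var(y)
  if (pooled) {
    sp2 <- ((nx - 1) * vx + (ny - 1) * vy) / (nx + ny - 2)
    se <- sqrt(sp2 * (1 / nx + 1 / ny))
    df <- nx + ny - 2
  } else {
    se <- sqrt(vx / nx + vy / ny)
    df <- (vx / nx + vy / ny)^2 /
      ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  }
  t <- (mean(x) - mean(y)) / se
  p <- if (one_sided) pt(t, df, lower.tail = FALSE) else 2 * pt(-abs(t), df)
  list(t = t, df = df, p = p)
}
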