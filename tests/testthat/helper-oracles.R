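# Independent oracles used across the suite. Each is a deliberately naive
# re-statement of the operation it checks (enumeration, counting, direct
# formulas) and shares no code with the implementation.

AA <- c("A","R","N","D","C","Q","E","G","H","I",
        "L","K","M","F","P","S","T","W","Y","V")

rand_protein <- function(L, alphabet = AA) {
  paste(sample(alphabet, L, replace = TRUE), collapse = "")
}

# exhaustive global alignment score with affine gaps: memoized recursion
# over (position, position, gap state) enumerating every alignment
# (feasible for sequences <= 8-10 aa)
oracle_align_score <- function(a, b, B, open = 10, ext = 0.5) {
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  memo <- new.env()
  # state: 0 = no open gap, 1 = gap in b open, 2 = gap in a open
  rec <- function(i, j, state) {
    key <- paste(i, j, state)
    if (!is.null(memo[[key]])) return(memo[[key]])
    if (i > length(ca) && j > length(cb)) {
      v <- 0
    } else {
      v <- -Inf
      if (i <= length(ca) && j <= length(cb))
        v <- max(v, B[ca[i], cb[j]] + rec(i + 1, j + 1, 0))
      if (i <= length(ca))
        v <- max(v, -(if (state == 1) ext else open + ext) +
                   rec(i + 1, j, 1))
      if (j <= length(cb))
        v <- max(v, -(if (state == 2) ext else open + ext) +
                   rec(i, j + 1, 2))
    }
    memo[[key]] <- v
    v
  }
  rec(1, 1, 0)
}

# brute-force PROSITE matcher: expand the pattern into all concrete
# fixed-length element vectors, then test every window position-by-position
oracle_prosite_matches <- function(pattern, sequence) {
  el <- pattern$elements
  chars <- strsplit(sequence, "")[[1]]
  expansions <- list(list())
  for (k in seq_len(nrow(el))) {
    reps <- el$min[[k]]:el$max[[k]]
    expansions <- unlist(lapply(expansions, function(pref) {
      lapply(reps, function(r) {
        c(pref, rep(list(list(kind = el$kind[[k]],
                              residues = el$residues[[k]])), r))
      })
    }), recursive = FALSE)
  }
  hits <- list()
  for (exp in expansions) {
    wlen <- length(exp)
    starts <- if (pattern$n_anchor) 1 else seq_len(max(length(chars), 0))
    for (s in starts) {
      e <- s + wlen - 1
      if (wlen > 0 && e > length(chars)) next
      if (pattern$c_anchor && e != length(chars)) next
      ok <- TRUE
      for (k in seq_len(wlen)) {
        ch <- chars[s + k - 1]
        el_k <- exp[[k]]
        m <- switch(el_k$kind,
                    any = TRUE,
                    exact = ch == el_k$residues[[1]],
                    `one-of` = ch %in% el_k$residues,
                    `none-of` = !(ch %in% el_k$residues))
        if (!m) { ok <- FALSE; break }
      }
      if (ok) hits[[length(hits) + 1]] <- c(s, e)
    }
  }
  if (!length(hits)) return(tibble::tibble(start = integer(),
                                           end = integer()))
  m <- unique(do.call(rbind, hits))
  out <- tibble::tibble(start = m[, 1], end = m[, 2])
  dplyr::arrange(out, start, end)
}

# direct BH step-up: find largest k with p_(k) <= k/m * q; here we return
# adjusted values by the defining minimum
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  for (i in seq_len(m)) {
    k <- which(o == i)  # rank of p[i]
    adj[i] <- min(1, min(m * p[o][k:m] / (k:m)))
  }
  adj
}

# least-squares tree fit over all 3 topologies of 4 taxa or enumerated
# topologies of n taxa via ape::allTrees is overkill; for NJ consistency we
# instead compare against the true generating tree (additive case).

random_additive_matrix <- function(n_taxa) {
  tr <- ape::rtree(n_taxa)
  tr$edge.length <- runif(nrow(tr$edge), 0.05, 1)
  d <- ape::cophenetic.phylo(tr)
  ord <- sort(rownames(d))
  list(tree = tr, d = d[ord, ord])
}

# exhaustive tandem-cluster scan: for every maximal window of same-family
# genes check the gap rule directly
oracle_tandem <- function(layout, assignments, max_intervening) {
  pos <- merge(layout[!is.na(layout$gene_id), ], assignments,
               by = "gene_id")
  out <- list()
  for (chr in unique(pos$chromosome)) {
    for (f in unique(pos$family)) {
      g <- pos[pos$chromosome == chr & pos$family == f, ]
      g <- g[order(g$rank), ]
      if (nrow(g) < 2) next
      grp <- cumsum(c(1, diff(g$rank) - 1 > max_intervening))
      for (k in unique(grp)) {
        mem <- g$gene_id[grp == k]
        if (length(mem) >= 2)
          out[[length(out) + 1]] <- list(family = f, members = sort(mem))
      }
    }
  }
  out
}

# optimal 3-way sum-of-pairs alignment score with linear gaps: full 3D DP
# over the 7 non-empty move subsets (feasible for sequences <= 8 aa)
oracle_msa3_sp <- function(a, b, c, match = 1, mismatch = -1, gap = -2) {
  sa <- strsplit(a, "")[[1]]; sb <- strsplit(b, "")[[1]]
  sc <- strsplit(c, "")[[1]]
  pair <- function(x, y) {
    if (is.na(x) && is.na(y)) 0
    else if (is.na(x) || is.na(y)) gap
    else if (x == y) match else mismatch
  }
  col_score <- function(x, y, z) pair(x, y) + pair(x, z) + pair(y, z)
  na <- length(sa); nb <- length(sb); nc <- length(sc)
  D <- array(-Inf, dim = c(na + 1, nb + 1, nc + 1))
  D[1, 1, 1] <- 0
  moves <- expand.grid(di = 0:1, dj = 0:1, dk = 0:1)
  moves <- moves[rowSums(moves) > 0, ]
  for (i in 0:na) for (j in 0:nb) for (k in 0:nc) {
    if (i + j + k == 0) next
    best <- -Inf
    for (m in seq_len(nrow(moves))) {
      di <- moves$di[m]; dj <- moves$dj[m]; dk <- moves$dk[m]
      pi <- i - di; pj <- j - dj; pk <- k - dk
      if (pi < 0 || pj < 0 || pk < 0) next
      prev <- D[pi + 1, pj + 1, pk + 1]
      if (!is.finite(prev)) next
      sc_col <- col_score(if (di) sa[i] else NA, if (dj) sb[j] else NA,
                          if (dk) sc[k] else NA)
      best <- max(best, prev + sc_col)
    }
    D[i + 1, j + 1, k + 1] <- best
  }
  D[na + 1, nb + 1, nc + 1]
}

# sum-of-pairs score of a given alignment under the same linear-gap scheme
sp_score_of_msa <- function(msa, match = 1, mismatch = -1, gap = -2) {
  m <- do.call(rbind, strsplit(msa, ""))
  total <- 0
  for (col in seq_len(ncol(m))) {
    for (i in seq_len(nrow(m) - 1)) for (j in (i + 1):nrow(m)) {
      x <- m[i, col]; y <- m[j, col]
      total <- total +
        if (x == "-" && y == "-") 0
        else if (x == "-" || y == "-") gap
        else if (x == y) match else mismatch
    }
  }
  total
}

# random well-formed PROSITE pattern over a small alphabet
rand_pattern <- function(n_el = sample(2:4, 1), alphabet = c("A","C","D","E")) {
  toks <- vapply(seq_len(n_el), function(i) {
    kind <- sample(c("exact", "any", "one-of", "none-of"), 1)
    core <- switch(kind,
      exact = sample(alphabet, 1),
      any = "x",
      `one-of` = paste0("[", paste(sample(alphabet, sample(1:3, 1)),
                                   collapse = ""), "]"),
      `none-of` = paste0("{", sample(alphabet, 1), "}"))
    if (runif(1) < 0.3) {
      r1 <- sample(0:2, 1); r2 <- r1 + sample(0:2, 1)
      core <- paste0(core, if (r1 == r2) sprintf("(%d)", r1)
                     else sprintf("(%d,%d)", r1, r2))
    }
    core
  }, "")
  paste(toks, collapse = "-")
}
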