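#' Pairwise p-distance matrix from a multiple alignment
#'
#' The p-distance between two rows is the proportion of differing
#' positions over columns where neither row has a gap (pairwise deletion).
#'
#' @param msa Named character vector of equal-length gapped sequences.
#' @param allow_missing If `TRUE`, a pair with zero comparable columns is
#'   assigned the maximal distance 1 instead of erroring (used by the
#'   bootstrap resampler, where rare replicates can drop all shared
#'   columns of a sparse pair).
#' @return Symmetric distance matrix with zero diagonal, taxa as dimnames.
#' @export
msa_pdistance <- function(msa, allow_missing = FALSE) {
  m <- msa_matrix(msa)
  n <- nrow(m)
  if (n < 2) stop("need at least two sequences")
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    ok <- m[i, ] != "-" & m[j, ] != "-"
    if (!any(ok)) {
      if (!allow_missing)
        stop("no comparable columns between ", rownames(m)[i], " and ",
             rownames(m)[j], call. = FALSE)
      d[i, j] <- d[j, i] <- 1
    } else {
      d[i, j] <- d[j, i] <- mean(m[i, ok] != m[j, ok])
    }
  }
  d
}

msa_matrix <- function(msa) {
  stopifnot(is.character(msa), !is.null(names(msa)))
  L <- unique(nchar(msa))
  if (length(L) != 1) stop("alignment rows differ in length", call. = FALSE)
  m <- do.call(rbind, strsplit(msa, ""))
  rownames(m) <- names(msa)
  m
}

check_distance_matrix <- function(d) {
  if (!is.matrix(d) || nrow(d) != ncol(d))
    stop("distance matrix must be square", call. = FALSE)
  if (is.null(rownames(d))) stop("distance matrix needs taxon names")
  if (!isTRUE(all.equal(d, t(d), tolerance = 1e-8)))
    stop("distance matrix must be symmetric", call. = FALSE)
  if (any(!is.finite(d)) || any(d < -1e-12))
    stop("distances must be finite and non-negative", call. = FALSE)
  if (any(abs(diag(d)) > 1e-12)) stop("diagonal must be zero", call. = FALSE)
  invisible(d)
}

# core NJ loop; returns newick string, the join order (cluster member index
# sets, used as an MSA merge schedule) and the count of clamped negative
# branch lengths
nj_core <- function(d) {
  labs <- rownames(d)
  n <- nrow(d)
  cl_newick <- labs                 # newick fragment per active cluster
  cl_members <- as.list(seq_len(n)) # original indices per active cluster
  cl_rep <- labs                    # representative label for tie-breaks
  joins <- list()
  clamped <- 0L
  fmt <- function(x) format(x, digits = 15, scientific = FALSE, trim = TRUE)

  while (nrow(d) > 3) {
    m <- nrow(d)
    r <- rowSums(d)
    Q <- (m - 2) * d - outer(r, r, "+")
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q <= qmin + 1e-12, arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    key <- apply(cand, 1, function(ij) {
      p <- sort(c(cl_rep[ij[1]], cl_rep[ij[2]]))
      paste(p, collapse = "\r")
    })
    pick <- cand[order(key)[1], ]
    i <- pick[[1]]; j <- pick[[2]]
    li <- d[i, j] / 2 + (r[i] - r[j]) / (2 * (m - 2))
    lj <- d[i, j] - li
    if (li < 0) { clamped <- clamped + 1L; li <- 0 }
    if (lj < 0) { clamped <- clamped + 1L; lj <- 0 }
    joins[[length(joins) + 1]] <- list(a = cl_members[[i]],
                                       b = cl_members[[j]])
    new_nw <- paste0("(", cl_newick[i], ":", fmt(li), ",",
                     cl_newick[j], ":", fmt(lj), ")")
    dnew <- (d[i, ] + d[j, ] - d[i, j]) / 2
    keep <- setdiff(seq_len(m), c(i, j))
    d2 <- rbind(cbind(d[keep, keep, drop = FALSE], dnew[keep]),
                c(dnew[keep], 0))
    nm <- c(rownames(d)[keep], paste0("u", length(joins)))
    dimnames(d2) <- list(nm, nm)
    d <- d2
    cl_newick <- c(cl_newick[keep], new_nw)
    cl_members <- c(cl_members[keep],
                    list(sort(c(joins[[length(joins)]]$a,
                                joins[[length(joins)]]$b))))
    cl_rep <- c(cl_rep[keep], min(cl_rep[c(i, j)]))
  }

  if (nrow(d) == 3) {
    l1 <- (d[1, 2] + d[1, 3] - d[2, 3]) / 2
    l2 <- (d[1, 2] + d[2, 3] - d[1, 3]) / 2
    l3 <- (d[1, 3] + d[2, 3] - d[1, 2]) / 2
    ls <- pmax(c(l1, l2, l3), 0)
    clamped <- clamped + sum(c(l1, l2, l3) < 0)
    # merge schedule: closest pair first, then the third
    pair <- which.min(c(d[1, 2], d[1, 3], d[2, 3]))
    ij <- list(c(1, 2), c(1, 3), c(2, 3))[[pair]]
    k <- setdiff(1:3, ij)
    joins[[length(joins) + 1]] <- list(a = cl_members[[ij[1]]],
                                       b = cl_members[[ij[2]]])
    joins[[length(joins) + 1]] <- list(
      a = sort(c(cl_members[[ij[1]]], cl_members[[ij[2]]])),
      b = cl_members[[k]])
    newick <- paste0("(", cl_newick[1], ":", fmt(ls[1]), ",",
                     cl_newick[2], ":", fmt(ls[2]), ",",
                     cl_newick[3], ":", fmt(ls[3]), ");")
  } else { # exactly 2 clusters
    joins[[length(joins) + 1]] <- list(a = cl_members[[1]],
                                       b = cl_members[[2]])
    newick <- paste0("(", cl_newick[1], ":", fmt(d[1, 2] / 2), ",",
                     cl_newick[2], ":", fmt(d[1, 2] / 2), ");")
  }
  list(newick = newick, joins = joins, clamped = clamped)
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard NJ with the Q-criterion; when several pairs minimize Q the
#' lexicographically lowest taxon pair is joined, so results are
#' reproducible. Negative branch lengths are clamped to zero; the number
#' of clamped branches is recorded in attribute `"clamped"`.
#'
#' @param d Symmetric distance matrix (>= 3 taxa) with taxon dimnames.
#' @return An unrooted [ape::phylo] tree.
#' @export
nj_tree <- function(d) {
  check_distance_matrix(d)
  if (nrow(d) < 3) stop("need at least 3 taxa", call. = FALSE)
  core <- nj_core(d)
  tr <- ape::read.tree(text = core$newick)
  attr(tr, "clamped") <- core$clamped
  tr
}

#' Bootstrap support for a neighbor-joining tree
#'
#' Resamples alignment columns with replacement; each replicate gets a
#' p-distance NJ tree, and the support of each internal edge of the
#' full-data tree is the percentage of replicate trees containing the
#' same bipartition (the convention of mainstream phylogenetics GUIs:
#' support is mapped onto the full-data tree, not a consensus tree).
#'
#' @param msa Named character vector of gapped sequences.
#' @param n_reps Number of bootstrap replicates (>= 1; 1000 is the
#'   conventional default for publication trees).
#' @param seed Integer seed; the same seed always yields the same
#'   supports.
#' @return The full-data NJ tree with node labels holding percentage
#'   supports in \[0, 100\] (root label empty).
#' @export
bootstrap_support <- function(msa, n_reps = 1000, seed = 1) {
  stopifnot(n_reps >= 1)
  m <- msa_matrix(msa)
  if (ncol(m) < 2) stop("alignment must have at least 2 columns",
                        call. = FALSE)
  main <- nj_tree(msa_pdistance(msa, allow_missing = TRUE))
  reps <- with_local_seed(seed, {
    purrr::map(seq_len(n_reps), function(r) {
      cols <- sample.int(ncol(m), ncol(m), replace = TRUE)
      mm <- m[, cols, drop = FALSE]
      msar <- setNames(apply(mm, 1, paste, collapse = ""), rownames(m))
      nj_tree(msa_pdistance(msar, allow_missing = TRUE))
    })
  })
  counts <- ape::prop.clades(main, reps, rooted = FALSE)
  counts[is.na(counts)] <- 0
  support <- round(100 * counts / n_reps, 1)
  main$node.label <- as.character(support)
  main$node.label[1] <- ""  # root of the stored representation
  attr(main, "n_reps") <- n_reps
  main
}

with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  force(code)
}

profile_of <- function(alnmat) {
  L <- ncol(alnmat)
  f <- matrix(0, length(AA20), L, dimnames = list(AA20, NULL))
  for (a in AA20) f[a, ] <- colSums(alnmat == a)
  f / nrow(alnmat)
}

merge_alignments <- function(A, B, scoring) {
  Bsub <- scoring$matrix[AA20, AA20]
  S <- t(profile_of(A)) %*% Bsub %*% profile_of(B)
  res <- .dp_affine(S, scoring$gap_open, scoring$gap_extend)
  expand <- function(M, idx) {
    out <- matrix("-", nrow(M), length(idx), dimnames = list(rownames(M)))
    out[, idx != 0] <- M[, idx[idx != 0], drop = FALSE]
    out
  }
  rbind(expand(A, res$a), expand(B, res$b))
}

#' Progressive multiple sequence alignment
#'
#' Guide-tree progressive alignment: pairwise global-alignment identities
#' give a distance matrix, an NJ guide tree fixes the merge order, and
#' clusters are merged by profile--profile affine alignment in which a
#' column pair is scored by the mean substitution score over residue
#' frequencies.
#'
#' @param seqs Named character vector of protein sequences (>= 2; a
#'   single sequence is returned unchanged with a warning).
#' @param scoring Scoring scheme, see [aa_scoring()].
#' @return Named character vector of equal-length gapped sequences, in
#'   input order.
#' @export
progressive_msa <- function(seqs, scoring = aa_scoring()) {
  stopifnot(is.character(seqs), !is.null(names(seqs)))
  if (length(seqs) == 1) {
    warning("single sequence: nothing to align", call. = FALSE)
    return(seqs)
  }
  for (s in seqs) check_protein(s)
  if (length(seqs) == 2) {
    aln <- global_align(seqs[[1]], seqs[[2]], scoring)
    return(setNames(c(aln$a, aln$b), names(seqs)))
  }
  d <- 1 - identity_matrix(seqs, scoring)
  diag(d) <- 0
  joins <- nj_core(d)$joins
  clusters <- purrr::imap(seqs, function(s, id) {
    matrix(strsplit(s, "")[[1]], 1, dimnames = list(id))
  })
  names(clusters) <- NULL
  membership <- as.list(seq_along(seqs))
  for (jn in joins) {
    ia <- which(purrr::map_lgl(membership, ~ setequal(.x, jn$a)))
    ib <- which(purrr::map_lgl(membership, ~ setequal(.x, jn$b)))
    merged <- merge_alignments(clusters[[ia]], clusters[[ib]], scoring)
    keep <- setdiff(seq_along(clusters), c(ia, ib))
    clusters <- c(clusters[keep], list(merged))
    membership <- c(membership[keep], list(sort(c(jn$a, jn$b))))
  }
  final <- clusters[[1]]
  out <- setNames(apply(final, 1, paste, collapse = ""), rownames(final))
  out[names(seqs)]
}
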