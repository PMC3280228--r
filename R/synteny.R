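#' Detect tandemly duplicated family members
#'
#' Tandem duplicates are same-family genes lying adjacent on a
#' chromosome with at most `max_intervening` annotated loci between
#' successive members (the classic "no more than one intervening gene"
#' rule corresponds to the default 1). Intervening loci are counted
#' regardless of their own family. Reported clusters are maximal and
#' singletons are excluded.
#'
#' @param layout Genome layout tibble: `chromosome`, `rank` (consecutive
#'   from 1 within each chromosome), `locus_id`, `gene_id` (`NA` for
#'   background loci); an optional `genome` column is carried through.
#' @param assignments Tibble `gene_id`, `family` for the genes of
#'   interest; every assigned gene must appear in the layout.
#' @param max_intervening Maximum number of intervening loci (default 1).
#' @return Tibble with one row per cluster member: `cluster`, `family`,
#'   `chromosome`, `gene_id`, `rank`, `intervening_before` (`NA` for the
#'   first member of each cluster).
#' @export
find_tandem_clusters <- function(layout, assignments, max_intervening = 1) {
  missing <- setdiff(assignments$gene_id,
                     layout$gene_id[!is.na(layout$gene_id)])
  if (length(missing))
    stop("genes missing from layout: ", paste(missing, collapse = ", "),
         call. = FALSE)
  pos <- dplyr::inner_join(
    layout[!is.na(layout$gene_id), ], assignments, by = "gene_id")
  out <- list()
  cluster_id <- 0L
  groups <- dplyr::group_split(dplyr::group_by(pos, .data$chromosome,
                                               .data$family))
  # deterministic cluster numbering: by chromosome then first rank
  groups <- groups[order(purrr::map_chr(groups, ~ .x$chromosome[1]),
                         purrr::map_int(groups, ~ min(.x$rank)))]
  for (g in groups) {
    g <- g[order(g$rank), ]
    if (nrow(g) < 2) next
    gaps <- diff(g$rank) - 1L
    brk <- c(0L, which(gaps > max_intervening), nrow(g))
    for (k in seq_len(length(brk) - 1)) {
      idx <- (brk[k] + 1L):brk[k + 1L]
      if (length(idx) < 2) next
      cluster_id <- cluster_id + 1L
      out[[cluster_id]] <- tibble::tibble(
        cluster = cluster_id, family = g$family[idx][1],
        chromosome = g$chromosome[idx][1], gene_id = g$gene_id[idx],
        rank = g$rank[idx],
        intervening_before = c(NA_integer_, gaps[idx[-length(idx)]]))
    }
  }
  if (!length(out))
    return(tibble::tibble(cluster = integer(), family = character(),
                          chromosome = character(), gene_id = character(),
                          rank = integer(), intervening_before = integer()))
  dplyr::bind_rows(out)
}

#' Map genes into synteny blocks
#'
#' Assigns each annotated gene to every synteny block side containing
#' it. Blocks carry a dialect: `"rank"` blocks bound an interval of
#' layout ranks, `"coord"` blocks bound genomic coordinates (the gene's
#' `start`/`end` columns in the layout are then required and membership
#' is by overlap).
#'
#' @param layout Genome layout tibble (see [find_tandem_clusters()]) with
#'   a `genome` column; for the `"coord"` dialect also `start`, `end`.
#' @param blocks Block tibble: `block_id`, `genome_a`, `chr_a`,
#'   `start_a`, `end_a`, `genome_b`, `chr_b`, `start_b`, `end_b`,
#'   `orientation`; attribute or column `dialect` of `"rank"` or
#'   `"coord"`.
#' @return Tibble `gene_id`, `genome`, `chromosome`, `rank`, `block_id`,
#'   `side`; genes lying in no block appear once with `block_id = NA`
#'   (flagged unmapped).
#' @export
map_genes_to_blocks <- function(layout, blocks) {
  dialect <- attr(blocks, "dialect") %||%
    (if ("dialect" %in% names(blocks)) blocks$dialect[1] else "rank")
  if (!dialect %in% c("rank", "coord"))
    stop("unknown block dialect: ", dialect, call. = FALSE)
  if (any(blocks$end_a < blocks$start_a) || any(blocks$end_b < blocks$start_b))
    stop("malformed block intervals", call. = FALSE)
  if (!"genome" %in% names(layout)) layout$genome <- "genome"
  genes <- layout[!is.na(layout$gene_id), ]
  hits <- list()
  for (side in c("a", "b")) {
    gcol <- paste0("genome_", side); ccol <- paste0("chr_", side)
    scol <- paste0("start_", side); ecol <- paste0("end_", side)
    for (b in seq_len(nrow(blocks))) {
      cand <- genes[genes$genome == blocks[[gcol]][b] &
                    genes$chromosome == blocks[[ccol]][b], ]
      if (!nrow(cand)) next
      inb <- if (dialect == "rank") {
        cand$rank >= blocks[[scol]][b] & cand$rank <= blocks[[ecol]][b]
      } else {
        cand$start <= blocks[[ecol]][b] & cand$end >= blocks[[scol]][b]
      }
      if (any(inb))
        hits[[length(hits) + 1]] <- tibble::tibble(
          gene_id = cand$gene_id[inb], genome = cand$genome[inb],
          chromosome = cand$chromosome[inb], rank = cand$rank[inb],
          block_id = blocks$block_id[b], side = toupper(side))
    }
  }
  mapped <- dplyr::bind_rows(hits)
  if (!nrow(mapped))
    mapped <- tibble::tibble(gene_id = character(), genome = character(),
                             chromosome = character(), rank = integer(),
                             block_id = character(), side = character())
  unmapped <- genes[!genes$gene_id %in% mapped$gene_id, ]
  dplyr::bind_rows(
    mapped,
    tibble::tibble(gene_id = unmapped$gene_id, genome = unmapped$genome,
                   chromosome = unmapped$chromosome, rank = unmapped$rank,
                   block_id = NA_character_, side = NA_character_))
}

#' Syntenic gene pairs from block membership
#'
#' Pairs same-family genes lying on opposite sides of a synteny block:
#' segmental duplicates in `"within"` mode (both sides one genome),
#' syntenic orthologs in `"cross"` mode. After collecting candidate pairs
#' over all blocks, a pair is `"unambiguous"` when both of its genes
#' occur in exactly one pair of their family (a 1:1 correspondence) and
#' `"ambiguous"` otherwise (duplicated genes corresponding to several
#' counterparts, possibly via several overlapping blocks). A block whose
#' family members all lie on one side yields a `"counterpart_lost"` row
#' (the other-side gene is `NA`).
#'
#' @param membership Output of [map_genes_to_blocks()].
#' @param assignments Tibble `gene_id`, `family` covering the genes of
#'   both genomes.
#' @param mode `"within"` or `"cross"`.
#' @return Tibble `block_id` (all supporting blocks, comma separated),
#'   `family`, `gene_a`, `gene_b`, `status`.
#' @export
syntenic_pairs <- function(membership, assignments,
                           mode = c("within", "cross")) {
  mode <- match.arg(mode)
  mem <- membership[!is.na(membership$block_id), ]
  mem <- dplyr::inner_join(mem, assignments, by = "gene_id")
  empty <- tibble::tibble(block_id = character(), family = character(),
                          gene_a = character(), gene_b = character(),
                          status = character())
  if (!nrow(mem)) return(empty)
  pairs <- list()
  lost <- list()
  for (b in unique(mem$block_id)) {
    mb <- mem[mem$block_id == b, ]
    for (f in unique(mb$family)) {
      a_genes <- sort(mb$gene_id[mb$family == f & mb$side == "A"])
      b_genes <- sort(mb$gene_id[mb$family == f & mb$side == "B"])
      if (length(a_genes) && length(b_genes)) {
        grid <- expand.grid(gene_a = a_genes, gene_b = b_genes,
                            stringsAsFactors = FALSE)
        grid <- grid[grid$gene_a != grid$gene_b, , drop = FALSE]
        if (nrow(grid))
          pairs[[length(pairs) + 1]] <- tibble::tibble(
            block_id = b, family = f, gene_a = grid$gene_a,
            gene_b = grid$gene_b)
      } else {
        lone <- if (length(a_genes)) a_genes else b_genes
        lost[[length(lost) + 1]] <- tibble::tibble(
          block_id = b, family = f,
          gene_a = if (length(a_genes)) lone else NA_character_,
          gene_b = if (length(b_genes)) lone else NA_character_,
          status = "counterpart_lost")
      }
    }
  }
  pt <- dplyr::bind_rows(pairs)
  if (nrow(pt)) {
    pt <- pt |>
      dplyr::group_by(.data$family, .data$gene_a, .data$gene_b) |>
      dplyr::summarise(block_id = paste(sort(unique(.data$block_id)),
                                        collapse = ","),
                       .groups = "drop")
    deg_a <- table(pt$gene_a)
    deg_b <- table(pt$gene_b)
    pt$status <- as.character(
      ifelse(deg_a[pt$gene_a] == 1 & deg_b[pt$gene_b] == 1,
             "unambiguous", "ambiguous"))
    pt <- pt[, c("block_id", "family", "gene_a", "gene_b", "status")]
  } else pt <- empty
  dplyr::bind_rows(pt, dplyr::bind_rows(lost)) |>
    dplyr::arrange(.data$family, .data$gene_a)
}
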