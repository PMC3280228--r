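#' Construct and validate a gene model
#'
#' A gene model is a tibble with one row per coding exon: `gene_id`,
#' `chromosome`, `strand`, `exon` (1-based index in transcription order),
#' `start`, `end` in 1-based inclusive genomic coordinates. Exons must be
#' non-overlapping with positive lengths and sorted 5' to 3' on the
#' coding strand (minus-strand models store exons in transcription order,
#' i.e. decreasing genomic coordinates).
#'
#' @param gene_id,chromosome,strand Scalars describing the gene.
#' @param exons Two-column data frame or matrix of `start`, `end`.
#' @return A validated gene-model tibble.
#' @export
gene_model <- function(gene_id, chromosome, strand, exons) {
  exons <- as.data.frame(exons)
  names(exons)[1:2] <- c("start", "end")
  gm <- tibble::tibble(
    gene_id = gene_id, chromosome = chromosome, strand = strand,
    exon = seq_len(nrow(exons)),
    start = as.integer(exons$start), end = as.integer(exons$end))
  validate_gene_model(gm)
}

validate_gene_model <- function(gm) {
  stopifnot(all(c("gene_id", "chromosome", "strand", "exon", "start",
                  "end") %in% names(gm)))
  if (any(gm$end < gm$start)) stop("exon with non-positive length")
  for (g in unique(gm$gene_id)) {
    e <- gm[gm$gene_id == g, ]
    s <- unique(e$strand)
    if (length(s) != 1) stop("mixed strands within gene ", g)
    o <- if (s == "+") order(e$start) else order(-e$start)
    if (!identical(o, seq_len(nrow(e))) ||
        !identical(e$exon, seq_len(nrow(e))))
      stop("exons of ", g, " not in transcription order")
    srt <- sort(e$start)
    ends <- e$end[order(e$start)]
    if (nrow(e) > 1 && any(srt[-1] <= ends[-nrow(e)]))
      stop("overlapping exons in ", g)
  }
  gm
}

gm_introns <- function(gm) {
  gm <- gm[order(gm$start), ]
  n <- nrow(gm)
  if (n < 2)
    return(tibble::tibble(intron = integer(), start = integer(),
                          end = integer()))
  tx_order <- if (gm$strand[1] == "+") seq_len(n - 1) else rev(seq_len(n - 1))
  tibble::tibble(intron = tx_order,
                 start = gm$end[-n] + 1L, end = gm$start[-1] - 1L) |>
    dplyr::arrange(.data$intron)
}

#' Exon--intron structure from a spliced CDS-to-genome alignment
#'
#' Aligns a coding sequence onto its genomic sequence with a dynamic
#' program in which introns are free-length gaps of at least `min_intron`
#' bases, and canonical GT...AG intron boundaries earn a score bonus
#' (scored, not required). Every CDS base must align; if the best
#' alignment still contains mismatches the CDS is not derivable from the
#' genomic sequence and an error is raised.
#'
#' @param cds,genomic Nucleotide strings over A/C/G/T (the CDS must be a
#'   substring of the genomic sequence after intron removal).
#' @param gene_id,chromosome,strand Metadata for the returned model.
#' @param min_intron Minimum intron length in bp (default 20).
#' @param splice_bonus Score bonus for a canonical GT...AG intron.
#' @return A gene-model tibble (see [gene_model()]); the concatenated
#'   exon lengths always equal `nchar(cds)`.
#' @export
structure_from_alignment <- function(cds, genomic, gene_id = "gene",
                                     chromosome = "chr1", strand = "+",
                                     min_intron = 20, splice_bonus = 4) {
  stopifnot(is.character(cds), is.character(genomic))
  cds <- toupper(cds); genomic <- toupper(genomic)
  if (grepl("[^ACGT]", cds) || grepl("[^ACGT]", genomic))
    stop("sequences must be over A/C/G/T", call. = FALSE)
  res <- .dp_spliced(cds, genomic, as.integer(min_intron),
                     match = 2, mismatch = -8, intron_open = 6,
                     splice_bonus = splice_bonus)
  path <- res$path
  gchars <- strsplit(genomic, "")[[1]]
  cchars <- strsplit(cds, "")[[1]]
  if (any(gchars[path] != cchars))
    stop("CDS cannot be derived from the genomic sequence ",
         "(spliced alignment contains mismatches)", call. = FALSE)
  brk <- which(diff(path) != 1L)
  starts <- path[c(1L, brk + 1L)]
  ends <- path[c(brk, length(path))]
  gene_model(gene_id, chromosome, strand, cbind(starts, ends))
}

#' Compare exon--intron structures across gene models
#'
#' Pairwise structural comparison: exon counts, per-exon length equality,
#' and named differences such as a lost first exon or an additional
#' terminal exon -- the vocabulary in which family-level structural
#' conservation is usually described.
#'
#' @param models A gene-model tibble covering >= 2 genes (rows grouped by
#'   `gene_id`), or a list of gene-model tibbles.
#' @return Tibble with one row per gene pair: `gene_a`, `gene_b`,
#'   `n_exons_a`, `n_exons_b`, `same_exon_count`, `n_equal_length`
#'   (matching exon lengths, 5'-aligned), and `differences` (semicolon
#'   separated descriptions, `"identical"` when none).
#' @export
compare_structures <- function(models) {
  if (is.list(models) && !is.data.frame(models))
    models <- dplyr::bind_rows(models)
  genes <- unique(models$gene_id)
  if (length(genes) < 2) stop("need at least two gene models")
  lens <- purrr::map(setNames(genes, genes), function(g) {
    e <- models[models$gene_id == g, ]
    e <- e[order(e$exon), ]
    e$end - e$start + 1L
  })
  pairs <- utils::combn(genes, 2, simplify = FALSE)
  purrr::map_dfr(pairs, function(p) {
    la <- lens[[p[1]]]; lb <- lens[[p[2]]]
    na <- length(la); nb <- length(lb)
    diffs <- character()
    if (na == nb) {
      neq <- sum(la == lb)
      bad <- which(la != lb)
      if (length(bad))
        diffs <- paste0("exon ", bad, " length differs (", la[bad], " vs ",
                        lb[bad], ")")
    } else {
      long <- if (na > nb) la else lb
      short <- if (na > nb) lb else la
      long_id <- if (na > nb) p[1] else p[2]
      short_id <- if (na > nb) p[2] else p[1]
      k <- length(long) - length(short)
      if (identical(long[(k + 1):length(long)], short)) {
        diffs <- sprintf("first %s lost in %s",
                         if (k == 1) "exon" else paste(k, "exons"), short_id)
      } else if (identical(long[seq_along(short)], short)) {
        diffs <- sprintf("%s additional exon%s in 3'-end of %s",
                         if (k == 1) "one" else k, if (k == 1) "" else "s",
                         long_id)
      } else {
        diffs <- sprintf("exon count differs (%d vs %d)", na, nb)
      }
      neq <- sum(la[seq_len(min(na, nb))] == lb[seq_len(min(na, nb))])
    }
    tibble::tibble(
      gene_a = p[1], gene_b = p[2], n_exons_a = na, n_exons_b = nb,
      same_exon_count = na == nb, n_equal_length = neq,
      differences = if (length(diffs)) paste(diffs, collapse = "; ")
                    else "identical")
  })
}

#' Classify alternative-splicing events between two gene models
#'
#' Compares a splice variant against a reference model of the same locus
#' and returns the minimal event list explaining the coordinate
#' differences: retained introns (`intron_retention`, with the retained
#' length), shifted acceptor/donor sites (`alt_3prime_acceptor`,
#' `alt_5prime_donor`, with the length change), and skipped exons
#' (`exon_skip`). Outermost transcript ends are not splice events and are
#' ignored.
#'
#' @param variant,reference Gene-model tibbles on the same chromosome and
#'   strand.
#' @return Tibble `kind`, `location` (affected reference intron/exon
#'   index), `length_delta` (bp; 0 only for `exon_skip` rows where the
#'   full exon length is reported instead).
#' @export
detect_splice_events <- function(variant, reference) {
  if (unique(variant$chromosome) != unique(reference$chromosome))
    stop("variant and reference are on different chromosomes",
         call. = FALSE)
  if (unique(variant$strand) != unique(reference$strand))
    stop("variant and reference are on different strands", call. = FALSE)
  minus <- unique(reference$strand) == "-"
  ev <- list()

  vex <- variant[order(variant$start), ]
  rex <- reference[order(reference$start), ]
  rint <- gm_introns(reference)

  # intron retention: a reference intron fully inside one variant exon
  retained <- integer()
  if (nrow(rint)) {
    for (k in seq_len(nrow(rint))) {
      inside <- vex$start <= rint$start[k] & vex$end >= rint$end[k]
      if (any(inside)) {
        retained <- c(retained, k)
        ev[[length(ev) + 1]] <- tibble::tibble(
          kind = "intron_retention", location = rint$intron[k],
          length_delta = rint$end[k] - rint$start[k] + 1L)
      }
    }
  }

  # exon-by-exon boundary comparison (overlap pairing)
  overlaps <- function(a1, a2, b1, b2) a1 <= b2 & b1 <= a2
  n_r <- nrow(rex)
  tx_idx <- if (minus) rev(seq_len(n_r)) else seq_len(n_r)
  for (i in seq_len(n_r)) {
    hit <- which(overlaps(vex$start, vex$end, rex$start[i], rex$end[i]))
    tx <- tx_idx[i]  # exon index in transcription order
    if (!length(hit)) {
      ev[[length(ev) + 1]] <- tibble::tibble(
        kind = "exon_skip", location = tx,
        length_delta = rex$end[i] - rex$start[i] + 1L)
      next
    }
    if (length(hit) > 1) next  # merged across a retained intron
    v <- hit[1]
    # skip boundaries adjacent to a retained intron (already explained)
    left_int <- i - 1L; right_int <- i
    left_retained <- left_int >= 1 && left_int %in% retained
    right_retained <- right_int <= nrow(rint) && right_int %in% retained
    merged_span <- vex$start[v] < rex$start[i] - 1L && left_retained ||
      vex$end[v] > rex$end[i] + 1L && right_retained
    if (merged_span) next
    start_diff <- vex$start[v] != rex$start[i]
    end_diff <- vex$end[v] != rex$end[i]
    # outermost transcript boundaries are not splice sites
    first_gx <- i == 1; last_gx <- i == n_r
    if (start_diff && !first_gx && !left_retained) {
      kind <- if (minus) "alt_5prime_donor" else "alt_3prime_acceptor"
      ev[[length(ev) + 1]] <- tibble::tibble(
        kind = kind, location = tx,
        length_delta = rex$start[i] - vex$start[v])
    }
    if (end_diff && !last_gx && !right_retained) {
      kind <- if (minus) "alt_3prime_acceptor" else "alt_5prime_donor"
      ev[[length(ev) + 1]] <- tibble::tibble(
        kind = kind, location = tx,
        length_delta = vex$end[v] - rex$end[i])
    }
  }
  out <- dplyr::bind_rows(ev)
  if (!nrow(out))
    return(tibble::tibble(kind = character(), location = integer(),
                          length_delta = integer()))
  dplyr::arrange(out, .data$location, .data$kind)
}

#' Longest ATG-initiated open reading frame and its translation
#'
#' Scans all three forward frames for the longest ORF that starts at ATG
#' and ends at an in-frame stop. The longest-ORF policy (rather than
#' first-ATG) reflects transcripts in which a frameshifting retained
#' intron moves the functional initiation site downstream. The protein
#' excludes the stop, so a valid CDS of length `3(n+1)` encodes `n`
#' residues.
#'
#' @param transcript Nucleotide string over A/C/G/T.
#' @param min_aa Minimum protein length to report (default 50); if no ORF
#'   reaches it, a not-found result is returned rather than an error.
#' @return List: `found`, `start`, `end` (1-based inclusive interval of
#'   the ORF including the stop codon), `protein`.
#' @export
find_orf_and_translate <- function(transcript, min_aa = 50) {
  stopifnot(is.character(transcript), length(transcript) == 1)
  transcript <- toupper(transcript)
  if (grepl("[^ACGT]", transcript))
    stop("transcript must be over A/C/G/T", call. = FALSE)
  n <- nchar(transcript)
  best <- NULL
  stops <- c("TAA", "TAG", "TGA")
  for (frame in 0:2) {
    starts <- seq(1 + frame, n - 2, by = 3)
    if (!length(starts)) next
    codons <- substring(transcript, starts, starts + 2)
    is_atg <- codons == "ATG"
    is_stop <- codons %in% stops
    stop_idx <- which(is_stop)
    for (a in which(is_atg)) {
      s_after <- stop_idx[stop_idx > a]
      if (!length(s_after)) next
      s <- s_after[1]
      aa_len <- s - a  # codons between ATG and stop, inclusive of ATG
      if (is.null(best) || aa_len > best$aa_len)
        best <- list(aa_len = aa_len, from = starts[a], to = starts[s] + 2)
    }
  }
  if (is.null(best) || best$aa_len < min_aa)
    return(list(found = FALSE, start = NA_integer_, end = NA_integer_,
                protein = NA_character_))
  orf <- substr(transcript, best$from, best$to)
  prot <- as.character(Biostrings::translate(Biostrings::DNAString(orf)))
  prot <- sub("\\*$", "", prot)
  list(found = TRUE, start = best$from, end = best$to, protein = prot)
}

#' Write / read gene models as GFF3
#'
#' Serializes gene models as nested gene/mRNA/CDS features via
#' rtracklayer; `read_gene_models()` inverts it.
#'
#' @param models Gene-model tibble.
#' @param path File path.
#' @return `write_gene_models()` returns `path` invisibly;
#'   `read_gene_models()` returns a gene-model tibble.
#' @export
write_gene_models <- function(models, path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE))
    stop("rtracklayer is required for GFF3 output")
  rows <- list()
  for (g in unique(models$gene_id)) {
    e <- models[models$gene_id == g, ]
    rows[[length(rows) + 1]] <- tibble::tibble(
      seqnames = e$chromosome[1], start = min(e$start), end = max(e$end),
      strand = e$strand[1], type = c("gene", "mRNA"),
      ID = c(g, paste0(g, ".t1")), Parent = c(NA, g))
    lens <- e$end - e$start + 1L
    phase <- c(0L, cumsum(lens)[-length(lens)]) %% 3L
    phase <- (3L - phase) %% 3L
    rows[[length(rows) + 1]] <- tibble::tibble(
      seqnames = e$chromosome, start = e$start, end = e$end,
      strand = e$strand, type = "CDS", phase = phase,
      ID = paste0(g, ".cds", e$exon), Parent = paste0(g, ".t1"))
  }
  df <- dplyr::bind_rows(rows)
  gr <- GenomicRanges::GRanges(
    seqnames = df$seqnames,
    ranges = IRanges::IRanges(df$start, df$end),
    strand = df$strand, type = df$type, ID = df$ID,
    phase = df$phase,
    Parent = ifelse(is.na(df$Parent), "", df$Parent))
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' @rdname write_gene_models
#' @export
read_gene_models <- function(path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE))
    stop("rtracklayer is required for GFF3 input")
  gr <- rtracklayer::import(path, format = "gff3")
  df <- tibble::as_tibble(as.data.frame(gr))
  cds <- df[df$type == "CDS", ]
  parent <- vapply(cds$Parent, function(p) sub("\\.t1$", "", p[[1]]),
                   character(1))
  out <- purrr::map_dfr(unique(parent), function(g) {
    e <- cds[parent == g, ]
    minus <- as.character(e$strand[1]) == "-"
    e <- e[order(e$start, decreasing = minus), ]
    gene_model(g, as.character(e$seqnames[1]), as.character(e$strand[1]),
               cbind(e$start, e$end))
  })
  out
}
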