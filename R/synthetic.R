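#' Specification for the synthetic-data generator
#'
#' Collects the parameters of the synthetic genome and expression
#' experiment in one validated object. The defaults are the conditions
#' the downstream analyses are tested under: five protein families of
#' three members with ~0.70 pairwise identity within families and ~0.30
#' between (straddling the 0.60/0.40 nomenclature thresholds), 150-aa
#' proteins, and a two-condition expression experiment of 2000 genes with
#' 200 planted effects of log2 fold change 2, noise SD 1, and 3 arrays
#' per group.
#'
#' @param n_families,members_per_family Family structure of the synthetic
#'   proteome.
#' @param within_family_identity Target pairwise identity within a family
#'   (fraction in (0.6, 1]).
#' @param between_family_identity Target pairwise identity between family
#'   seed sequences (fraction in \[0, 0.4)).
#' @param seq_len Protein length in aa (>= 50).
#' @param seed Integer seed; fully determines all generator output.
#' @param tandem_arrays List of `list(family =, size =, intervening =)`
#'   entries: tandem arrays to plant in the genome layout.
#' @param n_genes_background Number of background (non-family) loci.
#' @param exons_per_gene Integer range (length 2) of exon counts per gene.
#' @param expression List with `n_genes`, `n_planted`, `log2fc`, `sigma`,
#'   `n_per_group`, `frac_absent`.
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_families = 5, members_per_family = 3,
                           within_family_identity = 0.7,
                           between_family_identity = 0.3,
                           seq_len = 150, seed = 1,
                           tandem_arrays = list(),
                           n_genes_background = 40,
                           exons_per_gene = c(2, 8),
                           expression = list()) {
  stopifnot(n_families >= 1, members_per_family >= 1, seq_len >= 50)
  if (within_family_identity <= 0.6 || within_family_identity > 1)
    stop("within_family_identity must be in (0.6, 1]", call. = FALSE)
  if (between_family_identity < 0 || between_family_identity >= 0.4)
    stop("between_family_identity must be in [0, 0.4)", call. = FALSE)
  expr <- utils::modifyList(
    list(n_genes = 2000, n_planted = 200, log2fc = 2, sigma = 1,
         n_per_group = 3, frac_absent = 0.05), expression)
  if (expr$sigma <= 0) stop("sigma must be positive", call. = FALSE)
  if (expr$n_planted > expr$n_genes)
    stop("n_planted exceeds n_genes", call. = FALSE)
  if (expr$n_per_group < 2) stop("need n_per_group >= 2", call. = FALSE)
  for (arr in tandem_arrays) {
    stopifnot(all(c("family", "size", "intervening") %in% names(arr)))
    if (arr$size > members_per_family)
      stop("tandem array larger than its family", call. = FALSE)
  }
  structure(list(
    n_families = n_families, members_per_family = members_per_family,
    within_family_identity = within_family_identity,
    between_family_identity = between_family_identity,
    seq_len = seq_len, seed = seed, tandem_arrays = tandem_arrays,
    n_genes_background = n_genes_background,
    exons_per_gene = exons_per_gene, expression = expr),
    class = "synthetic_spec")
}

random_protein <- function(L) paste(c("M", sample(AA20, L - 1, replace = TRUE)),
                                    collapse = "")

# per-site ancestral retention probability that yields expected pairwise
# identity q between two sequences independently mutated from one ancestor
# (uniform substitution over the 19 other residues):
# q = p^2 + (1 - p)^2 / 19
retention_for_identity <- function(q) {
  disc <- 1 - 20 * (1 - 19 * q)
  if (disc < 0) return(0)
  min(1, (1 + sqrt(disc)) / 20)
}

# protect_first keeps an initiator methionine intact (generator use)
substitute_sites <- function(seq, k, protect_first = FALSE) {
  chars <- strsplit(seq, "")[[1]]
  if (k == 0) return(seq)
  pool <- if (protect_first) seq_along(chars)[-1] else seq_along(chars)
  pos <- pool[sample.int(length(pool), min(k, length(pool)))]
  chars[pos] <- vapply(chars[pos],
                       function(a) sample(setdiff(AA20, a), 1), "")
  paste(chars, collapse = "")
}

pick1 <- function(v) v[sample.int(length(v), 1)]

#' Mutate a protein towards a target identity
#'
#' Substitutes a deterministic number of uniformly sampled positions
#' (each to a different residue) so that the Hamming identity to the seed
#' is `round(target * L) / L`; no indels are introduced by default, which
#' keeps the realized identity analytically controllable. With
#' `indel_rate > 0` a Poisson number of single-residue indels is added.
#' The realized global-alignment identity is within +/- 0.05 of the
#' target for targets above ~0.2; below that, chance residue sharing in
#' gapped alignments of unrelated proteins puts a floor of roughly
#' 0.1-0.15 under the alignment identity even though the substitution
#' (Hamming) identity is exact.
#'
#' @param seed_seq Protein sequence (length >= 50).
#' @param target Target identity fraction in \[0, 1\].
#' @param rng_seed Integer seed.
#' @param indel_rate Expected indels per sequence (default 0).
#' @return Mutated protein sequence.
#' @export
mutate_to_identity <- function(seed_seq, target, rng_seed, indel_rate = 0) {
  check_protein(seed_seq, "seed_seq")
  L <- nchar(seed_seq)
  if (L < 50) stop("seed sequence shorter than 50 aa", call. = FALSE)
  if (target < 0 || target > 1)
    stop("target identity must be in [0, 1]", call. = FALSE)
  with_local_seed(rng_seed, {
    out <- substitute_sites(seed_seq, round((1 - target) * L))

    if (indel_rate > 0) {
      for (i in seq_len(stats::rpois(1, indel_rate))) {
        chars <- strsplit(out, "")[[1]]
        if (runif(1) < 0.5 && length(chars) > 50) {
          chars <- chars[-sample(length(chars), 1)]
        } else {
          at <- sample(length(chars) + 1, 1)
          chars <- append(chars, sample(AA20, 1), after = at - 1)
        }
        out <- paste(chars, collapse = "")
      }
    }
    out
  })
}

codon_table <- function() {
  gc <- Biostrings::GENETIC_CODE
  split(names(gc), unname(gc))
}

reverse_translate <- function(protein, codons) {
  aa <- strsplit(protein, "")[[1]]
  picks <- vapply(aa, function(a) {
    cand <- codons[[a]]
    cand[sample.int(length(cand), 1)]
  }, "")
  paste0(paste(picks, collapse = ""), "TAA")
}

random_intron <- function(min_len = 20, max_len = 80) {
  interior <- pick1(seq(min_len - 4, max_len - 4))
  paste0("GT", paste(sample(c("C", "A"), interior, replace = TRUE),
                     collapse = ""), "AG")
}

#' Generate a synthetic genome layout with planted family structure
#'
#' Builds a deterministic synthetic genome for end-to-end testing: family
#' seed proteins are derived from a common ancestor at the
#' between-family identity target, members from their family seed at the
#' within-family target (a star topology, so pairwise member identities
#' match the target directly); CDSs are sampled by reverse translation;
#' gene models split each CDS into exons separated by GT...AG introns
#' whose interiors avoid G/T, making planted boundaries uniquely
#' recoverable; and a genome layout places genes with at least two
#' intervening background loci except inside requested tandem arrays.
#'
#' @param spec A [synthetic_spec()].
#' @return List: `proteins`, `cds`, `genomic` (named character vectors),
#'   `gene_models` (tibble), `layout` (tibble), `truth` (tibble
#'   `gene_id`, `family`, `member`), `spec`.
#' @export
make_genome_layout <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  with_local_seed(spec$seed, {
    L <- spec$seq_len
    p_b <- retention_for_identity(spec$between_family_identity)
    r_w <- retention_for_identity(spec$within_family_identity)
    ancestor <- random_protein(L)
    codons <- codon_table()

    proteins <- character(); truth <- list()
    for (f in seq_len(spec$n_families)) {
      fseed <- substitute_sites(ancestor, round((1 - p_b) * L),
                                protect_first = TRUE)
      for (m in seq_len(spec$members_per_family)) {
        id <- sprintf("fam%d_m%d", f, m)
        proteins[[id]] <- if (m == 1) fseed
          else substitute_sites(fseed, round((1 - r_w) * L),
                                protect_first = TRUE)
        truth[[length(truth) + 1]] <- tibble::tibble(
          gene_id = id, family = f, member = m)
      }
    }
    truth <- dplyr::bind_rows(truth)

    cds <- vapply(proteins, reverse_translate, "", codons = codons)
    gene_models <- list(); genomic <- character()
    for (id in names(cds)) {
      nt <- cds[[id]]
      n_ex <- pick1(seq(spec$exons_per_gene[1], spec$exons_per_gene[2]))
      n_ex <- min(n_ex, nchar(nt) - 1)
      cuts <- sort(sample(nchar(nt) - 1L, n_ex - 1L))
      bounds <- cbind(c(1, cuts + 1), c(cuts, nchar(nt)))
      exon_seqs <- substring(nt, bounds[, 1], bounds[, 2])
      introns <- if (n_ex > 1)
        replicate(n_ex - 1, random_intron()) else character()
      flank5 <- paste(sample(c("C", "A"), 30, replace = TRUE),
                      collapse = "")
      flank3 <- paste(sample(c("C", "A"), 30, replace = TRUE),
                      collapse = "")
      pieces <- character(); pos <- nchar(flank5)
      starts <- integer(n_ex); ends <- integer(n_ex)
      for (e in seq_len(n_ex)) {
        starts[e] <- pos + 1L
        ends[e] <- pos + nchar(exon_seqs[e])
        pieces <- c(pieces, exon_seqs[e])
        pos <- ends[e]
        if (e < n_ex) {
          pieces <- c(pieces, introns[e])
          pos <- pos + nchar(introns[e])
        }
      }
      genomic[[id]] <- paste0(flank5, paste(pieces, collapse = ""), flank3)
      gene_models[[id]] <- gene_model(id, paste0("scaf_", id), "+",
                                      cbind(starts, ends))
    }
    gene_models <- dplyr::bind_rows(gene_models)

    # layout: arrays on chrA, remaining genes on chrB, background between
    in_array <- character()
    rowsA <- list(); rankA <- 0L; bg <- 0L
    add_bg <- function(rows, rank, chr, n) {
      for (i in seq_len(n)) {
        bg <<- bg + 1L; rank <- rank + 1L
        rows[[length(rows) + 1]] <- tibble::tibble(
          genome = "synthetic", chromosome = chr, rank = rank,
          locus_id = sprintf("bg%04d", bg), gene_id = NA_character_)
      }
      list(rows = rows, rank = rank)
    }
    for (arr in spec$tandem_arrays) {
      members <- truth$gene_id[truth$family == arr$family][seq_len(arr$size)]
      st <- add_bg(rowsA, rankA, "chrA", 2); rowsA <- st$rows; rankA <- st$rank
      for (k in seq_along(members)) {
        if (k > 1) {
          st <- add_bg(rowsA, rankA, "chrA", arr$intervening)
          rowsA <- st$rows; rankA <- st$rank
        }
        rankA <- rankA + 1L
        rowsA[[length(rowsA) + 1]] <- tibble::tibble(
          genome = "synthetic", chromosome = "chrA", rank = rankA,
          locus_id = paste0("locus_", members[k]), gene_id = members[k])
      }
      in_array <- c(in_array, members)
    }
    st <- add_bg(rowsA, rankA, "chrA", 2); rowsA <- st$rows

    rowsB <- list(); rankB <- 0L
    rest <- setdiff(truth$gene_id, in_array)
    n_between <- max(2L, ceiling(spec$n_genes_background /
                                   max(1, length(rest))))
    for (g in rest) {
      st <- add_bg(rowsB, rankB, "chrB", n_between)
      rowsB <- st$rows; rankB <- st$rank
      rankB <- rankB + 1L
      rowsB[[length(rowsB) + 1]] <- tibble::tibble(
        genome = "synthetic", chromosome = "chrB", rank = rankB,
        locus_id = paste0("locus_", g), gene_id = g)
    }
    st <- add_bg(rowsB, rankB, "chrB", 2); rowsB <- st$rows

    list(proteins = proteins, cds = cds, genomic = genomic,
         gene_models = gene_models,
         layout = dplyr::bind_rows(c(rowsA, rowsB)),
         truth = truth, spec = spec)
  })
}

#' Write a synthetic genome layout to disk
#'
#' Serializes a [make_genome_layout()] result: protein and CDS FASTA,
#' genomic FASTA, gene models as GFF3, layout as TSV, truth as JSON-like
#' TSV. Output is byte-deterministic for a fixed spec seed.
#'
#' @param gl A [make_genome_layout()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_genome_layout <- function(gl, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(x, file) {
    Biostrings::writeXStringSet(
      if (grepl("protein", file)) Biostrings::AAStringSet(x)
      else Biostrings::DNAStringSet(x),
      file.path(dir, file))
  }
  wr(gl$proteins, "proteins.fasta")
  wr(gl$cds, "cds.fasta")
  wr(gl$genomic, "genomic.fasta")
  readr::write_tsv(gl$layout, file.path(dir, "layout.tsv"))
  readr::write_tsv(gl$truth, file.path(dir, "truth.tsv"))
  if (requireNamespace("rtracklayer", quietly = TRUE))
    write_gene_models(gl$gene_models, file.path(dir, "models.gff3"))
  invisible(dir)
}

#' Simulate a two-condition expression experiment
#'
#' Emits already-normalized log2 intensities (the statistics downstream
#' of array normalization are what the screen tests): baseline levels
#' ~N(8, 2) per gene, i.i.d. N(0, sigma^2) noise per cell, a planted
#' additive `log2fc` on the treatment arrays of `n_planted` randomly
#' chosen genes, and a `frac_absent` fraction of non-planted probes
#' flagged absent on every array (these should be removed by
#' [filter_absent()]).
#'
#' @param spec A [synthetic_spec()]; its `expression` entry holds the
#'   simulation parameters.
#' @return List: `es` (an [expression_set()]; conditions `"treatment"`
#'   and `"control"`), `truth` (tibble `probe_id`, `gene_id`, `planted`,
#'   `true_lfc`).
#' @export
make_expression <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  ex <- spec$expression
  with_local_seed(spec$seed, {
    n <- ex$n_genes; k <- ex$n_planted; npg <- ex$n_per_group
    probes <- sprintf("probe%05d", seq_len(n))
    genes <- sprintf("gene%05d", seq_len(n))
    planted <- sort(sample(n, k))
    base <- rnorm(n, 8, 2)
    lfc <- numeric(n); lfc[planted] <- ex$log2fc
    arrays <- c(paste0("T", seq_len(npg)), paste0("C", seq_len(npg)))
    m <- matrix(rnorm(n * 2 * npg, sd = ex$sigma), n, 2 * npg,
                dimnames = list(probes, arrays)) + base
    m[, seq_len(npg)] <- m[, seq_len(npg)] + lfc
    calls <- matrix("P", n, 2 * npg, dimnames = dimnames(m))
    n_abs <- round(ex$frac_absent * n)
    if (n_abs > 0) {
      absent <- sample(setdiff(seq_len(n), planted), n_abs)
      calls[absent, ] <- "A"
    }
    design <- tibble::tibble(
      array = arrays,
      condition = rep(c("treatment", "control"), each = npg))
    es <- expression_set(m, design, calls,
                         tibble::tibble(probe_id = probes, gene_id = genes))
    truth <- tibble::tibble(probe_id = probes, gene_id = genes,
                            planted = seq_len(n) %in% planted,
                            true_lfc = lfc)
    list(es = es, truth = truth)
  })
}
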