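# Packaged fixtures: machine-readable transcriptions of the in-text gene
# and family tables plus the layout/block scaffolding built from them.
# Loaders verify an MD5 checksum so silent fixture corruption fails loudly.

fixture_md5 <- c(
  table1.tsv = "188e8b795458dc6d8c72d462a1ca5e9c",
  table2.tsv = "4d20fa7458628f4a67b019be50e9472e",
  layout_vitis.tsv = "fde46fb0a6df85167e9b2d5274819bcc",
  layout_arabidopsis_synthetic.tsv = "8bf2bac9bd8d2267a54bcbc1dbc3b7b1",
  blocks_within.tsv = "a2da6b59e95bea81bd6a1a733d57c278",
  blocks_cross.tsv = "b9637bae923154bf9fe5007b4c462c43")

fixture_path <- function(file) {
  p <- system.file("extdata", file, package = "aldhcensus")
  if (p == "" || !file.exists(p))
    stop("fixture ", file, " is missing from the installation",
         call. = FALSE)
  sum <- unname(tools::md5sum(p))
  if (!identical(sum, unname(fixture_md5[[file]])))
    stop("fixture ", file, " is corrupt (checksum mismatch)", call. = FALSE)
  p
}

#' The packaged grape ALDH gene table
#'
#' A transcription of the published grape ALDH gene catalog: 25 rows (23
#' gene loci; the three ALDH2B4 splice variants share one locus) with
#' family label, gene / locus / accession identifiers, putative function,
#' CDS length in bp and ORF length in aa. Every row satisfies
#' `orf_len == cds_len / 3 - 1`.
#'
#' @return A tibble with columns `family_label`, `family` (integer),
#'   `gene_id`, `locus_id`, `accession`, `putative_function`, `cds_len`,
#'   `orf_len`.
#' @export
load_table1 <- function() {
  tb <- readr::read_tsv(fixture_path("table1.tsv"), comment = "#",
                        show_col_types = FALSE)
  tb$family <- as.integer(sub("Family ", "", tb$family_label))
  dplyr::relocate(tb, "family", .after = "family_label")
}

#' The packaged cross-organism family-count matrix
#'
#' Family membership counts for eleven organisms across the 24 recognized
#' ALDH families, in long form. For fungi only presence/absence is
#' recorded (`count` is `NA`), mirroring the source.
#'
#' @return A tibble `organism`, `group`, `family` (integer 1-24), `count`
#'   (integer or `NA`), `present` (logical).
#' @export
load_table2 <- function() {
  wide <- readr::read_tsv(fixture_path("table2.tsv"), comment = "#",
                          col_types = readr::cols(.default = "c"))
  long <- tidyr::pivot_longer(wide, dplyr::starts_with("f"),
                              names_to = "family", values_to = "value")
  long$family <- as.integer(sub("^f", "", long$family))
  long$present <- long$value != "-"
  long$count <- suppressWarnings(as.integer(long$value))
  long[long$present, c("organism", "group", "family", "count", "present")]
}

#' Packaged genome layouts and synteny blocks
#'
#' `load_layout()` returns the ordered gene-locus catalog of the grape
#' fixture (or the synthetic Arabidopsis stand-in); `load_synteny_blocks()`
#' returns the within-grape or grape-Arabidopsis block tables. Block
#' files declare their coordinate dialect in a header comment; the
#' packaged fixtures use rank intervals.
#'
#' @param genome `"vitis"` or `"arabidopsis"`.
#' @return A layout tibble (`genome`, `chromosome`, `rank`, `locus_id`,
#'   `gene_id`).
#' @export
load_layout <- function(genome = c("vitis", "arabidopsis")) {
  genome <- match.arg(genome)
  file <- if (genome == "vitis") "layout_vitis.tsv"
          else "layout_arabidopsis_synthetic.tsv"
  readr::read_tsv(fixture_path(file), comment = "#",
                  na = "NA", show_col_types = FALSE)
}

#' @rdname load_layout
#' @param set `"within"` (grape duplicated regions) or `"cross"`
#'   (grape-Arabidopsis).
#' @export
load_synteny_blocks <- function(set = c("within", "cross")) {
  set <- match.arg(set)
  path <- fixture_path(paste0("blocks_", set, ".tsv"))
  header <- readLines(path, n = 1)
  dialect <- if (grepl("dialect:\\s*coord", header)) "coord" else "rank"
  b <- readr::read_tsv(path, comment = "#", show_col_types = FALSE)
  attr(b, "dialect") <- dialect
  b
}

#' Family assignments implied by systematic ALDH gene names
#'
#' Parses the family number out of names like `VvALDH10A9` or
#' `AthALDH3H1`. Convenient for turning a layout or census into the
#' `gene_id`/`family` table the duplication analyses consume.
#'
#' @param gene_ids Character vector of systematic gene names.
#' @return Tibble `gene_id`, `family` (family as character, e.g. `"10"`).
#' @export
aldh_family_from_name <- function(gene_ids) {
  gene_ids <- gene_ids[!is.na(gene_ids)]
  fam <- stringr::str_match(gene_ids, "ALDH(\\d+)")[, 2]
  if (any(is.na(fam)))
    stop("not systematic ALDH names: ",
         paste(gene_ids[is.na(fam)], collapse = ", "), call. = FALSE)
  tibble::tibble(gene_id = gene_ids, family = fam)
}
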