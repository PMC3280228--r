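#' Parse a PROSITE-style pattern
#'
#' Supports the PROSITE grammar the package uses for motif evidence:
#' residues joined by `-`; `x` for any residue; `[ABC]` one-of; `{ABC}`
#' none-of; repeat counts `(n)` or `(n,m)`; `<` and `>` as N-/C-terminal
#' anchors; an optional trailing `.`. Pattern content (e.g. the PS00070
#' and PS00687 active-site patterns) is supplied as configuration, never
#' hard-coded.
#'
#' @param raw Pattern string, e.g. `"[LIVM]-x(2)-{P}-C"`.
#' @param id Optional pattern identifier carried through to scan output.
#' @return A `prosite_pattern`: list with `raw`, `id`, `n_anchor`,
#'   `c_anchor` and an `elements` tibble (`kind`, `residues`, `min`,
#'   `max`).
#' @export
parse_prosite <- function(raw, id = NULL) {
  stopifnot(is.character(raw), length(raw) == 1, nchar(raw) > 0)
  pat <- sub("\\.$", "", raw)
  n_anchor <- startsWith(pat, "<")
  if (n_anchor) pat <- substring(pat, 2)
  c_anchor <- endsWith(pat, ">")
  if (c_anchor) pat <- substring(pat, 1, nchar(pat) - 1)
  if (!nchar(pat)) stop("empty pattern", call. = FALSE)
  toks <- strsplit(pat, "-", fixed = TRUE)[[1]]
  rx <- "^(?:([A-WYZa-wyz])|x|\\[([A-Z]+)\\]|\\{([A-Z]+)\\})(?:\\((\\d+)(?:,(\\d+))?\\))?$"
  els <- purrr::imap(toks, function(tok, pos) {
    m <- regmatches(tok, regexec(rx, tok))[[1]]
    if (!length(m))
      stop("malformed PROSITE token '", tok, "' at element ", pos,
           call. = FALSE)
    kind <- if (m[2] != "") "exact"
      else if (m[3] != "") "one-of"
      else if (m[4] != "") "none-of"
      else "any"
    residues <- switch(kind,
      exact = toupper(m[2]),
      `one-of` = strsplit(m[3], "")[[1]],
      `none-of` = strsplit(m[4], "")[[1]],
      any = character())
    rmin <- if (m[5] != "") as.integer(m[5]) else 1L
    rmax <- if (m[6] != "") as.integer(m[6]) else rmin
    if (rmin > rmax) stop("repeat min > max in '", tok, "'", call. = FALSE)
    tibble::tibble(kind = kind, residues = list(residues),
                   min = rmin, max = rmax)
  })
  structure(list(raw = raw, id = id %||% raw,
                 n_anchor = n_anchor, c_anchor = c_anchor,
                 elements = dplyr::bind_rows(els)),
            class = "prosite_pattern")
}

#' @export
print.prosite_pattern <- function(x, ...) {
  cat("<prosite_pattern>", x$id, ":", format(x), "\n")
  invisible(x)
}

#' @export
format.prosite_pattern <- function(x, ...) {
  el <- x$elements
  toks <- purrr::pmap_chr(el, function(kind, residues, min, max) {
    core <- switch(kind,
      exact = residues[[1]],
      any = "x",
      `one-of` = paste0("[", paste(residues, collapse = ""), "]"),
      `none-of` = paste0("{", paste(residues, collapse = ""), "}"))
    rep <- if (min == 1 && max == 1) ""
      else if (min == max) paste0("(", min, ")")
      else paste0("(", min, ",", max, ")")
    paste0(core, rep)
  })
  paste0(if (x$n_anchor) "<" else "", paste(toks, collapse = "-"),
         if (x$c_anchor) ">" else "")
}

element_matches <- function(kind, residues, ch) {
  switch(kind,
    any = TRUE,
    exact = ch == residues[[1]],
    `one-of` = ch %in% residues,
    `none-of` = !(ch %in% residues))
}

#' Scan a sequence for PROSITE pattern matches
#'
#' Reports every leftmost-anchored match: for each start position, every
#' span over which the full pattern can be laid (variable repeats can
#' yield several ends per start). Matches may overlap.
#'
#' @param pattern A [parse_prosite()] result (a raw string is parsed on
#'   the fly).
#' @param sequence Protein sequence string.
#' @return Tibble of 1-based inclusive `start`, `end` intervals (zero rows
#'   when nothing matches).
#' @export
scan_prosite <- function(pattern, sequence) {
  if (is.character(pattern)) pattern <- parse_prosite(pattern)
  stopifnot(inherits(pattern, "prosite_pattern"), is.character(sequence),
            length(sequence) == 1)
  chars <- strsplit(sequence, "")[[1]]
  L <- length(chars)
  el <- pattern$elements
  nel <- nrow(el)

  # ends(pos, k): all end positions of a match of elements k..nel starting
  # at sequence position pos
  ends <- function(pos, k) {
    if (k > nel) return(pos - 1L)
    out <- integer()
    kind <- el$kind[[k]]; res <- el$residues[[k]]
    rmin <- el$min[[k]]; rmax <- el$max[[k]]
    # consume r copies of this element
    r <- 0L
    p <- pos
    while (r < rmax) {
      if (p > L || !element_matches(kind, res, chars[p])) break
      r <- r + 1L; p <- p + 1L
      if (r >= rmin) out <- c(out, ends(p, k + 1L))
    }
    if (rmin == 0L) out <- c(out, ends(pos, k + 1L))
    unique(out)
  }

  starts <- if (pattern$n_anchor) 1L else seq_len(max(L, 0L))
  hits <- purrr::map(starts, function(s) {
    e <- ends(s, 1L)
    if (pattern$c_anchor) e <- e[e == L]
    e <- e[e >= s - 1L]
    if (!length(e)) return(NULL)
    tibble::tibble(start = s, end = e)
  })
  out <- dplyr::bind_rows(hits)
  if (!nrow(out)) tibble::tibble(start = integer(), end = integer())
  else dplyr::arrange(out, .data$start, .data$end)
}

#' Flag candidate family members in a proteome
#'
#' A protein passes if it matches at least one motif pattern OR its best
#' global-alignment identity to the curated query panel reaches
#' `identity_floor` (the two evidence channels are combined with OR;
#' both are recorded). This emulates a database search stage: motif hits
#' play the role of domain-model evidence, panel identity the role of
#' homology-search evidence.
#'
#' @param proteome Named character vector of protein sequences.
#' @param panel Named character vector of curated query proteins (may be
#'   empty if `patterns` is non-empty).
#' @param patterns List of [parse_prosite()] patterns or raw strings (may
#'   be empty if `panel` is non-empty).
#' @param identity_floor Identity threshold for the homology channel
#'   (default 0.4).
#' @param scoring Alignment scoring, see [aa_scoring()].
#' @return Tibble: `gene_id`, `n_motif_hits`, `best_hit`,
#'   `best_identity`, `passed`; attribute `evidence_mode = "OR"`.
#' @export
find_candidates <- function(proteome, panel = character(),
                            patterns = list(), identity_floor = 0.4,
                            scoring = aa_scoring()) {
  if (!length(panel) && !length(patterns))
    stop("need a non-empty panel or at least one pattern", call. = FALSE)
  if (!length(proteome))
    return(structure(tibble::tibble(
      gene_id = character(), n_motif_hits = integer(),
      best_hit = character(), best_identity = double(), passed = logical()),
      evidence_mode = "OR"))
  stopifnot(is.character(proteome), !is.null(names(proteome)))
  patterns <- purrr::map(patterns, function(p)
    if (is.character(p)) parse_prosite(p) else p)

  rows <- purrr::imap(proteome, function(s, id) {
    nhits <- sum(purrr::map_int(patterns, ~ nrow(scan_prosite(.x, s))))
    if (length(panel)) {
      ids <- purrr::map_dbl(panel, ~ pair_identity(s, .x, scoring))
      bi <- max(ids); bh <- names(panel)[which.max(ids)]
    } else {
      bi <- NA_real_; bh <- NA_character_
    }
    tibble::tibble(gene_id = id, n_motif_hits = nhits, best_hit = bh,
                   best_identity = bi,
                   passed = nhits > 0 || (!is.na(bi) && bi >= identity_floor))
  })
  structure(dplyr::bind_rows(rows), evidence_mode = "OR")
}
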