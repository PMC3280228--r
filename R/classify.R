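#' AGNC family/subfamily assignment for one query protein
#'
#' Implements the ALDH Gene Nomenclature Committee percent-identity rule:
#' a query more than 40% identical to a previously named ALDH belongs to
#' that family, more than 60% to that subfamily, and less than 40%
#' identical to everything founds a new family. Boundary handling (the
#' committee rule quotes strict inequalities on both sides of 40%): a
#' query at exactly 0.40 joins the family (a new family requires identity
#' strictly below 0.40 everywhere); a query at exactly 0.60 joins the
#' family but founds a new subfamily (subfamily membership requires
#' strictly more than 0.60).
#'
#' @param query Named length-1 character vector (or a string plus `id`)
#'   holding the query protein sequence.
#' @param panel A tibble of classified panel proteins with columns
#'   `gene_id`, `family` (integer), `subfamily` (letter), `member_no`
#'   (integer), `sequence`.
#' @param id Query identifier (defaults to the name of `query`).
#' @param family_threshold,subfamily_threshold Identity thresholds
#'   (defaults 0.4 and 0.6, the committee values).
#' @param scoring Alignment scoring scheme, see [aa_scoring()].
#' @param denominator Identity denominator, see [percent_identity()].
#' @return One-row tibble: `gene_id`, `family`, `subfamily`, `member_no`,
#'   `is_new_family`, `is_new_subfamily`, `best_hit`, `best_identity`.
#' @export
classify_protein <- function(query, panel = NULL, id = NULL,
                             family_threshold = 0.4,
                             subfamily_threshold = 0.6,
                             scoring = aa_scoring(),
                             denominator = c("alignment", "shorter")) {
  denominator <- match.arg(denominator)
  if (is.null(id)) id <- names(query) %||% "query"
  query <- unname(query)
  check_protein(query, "query")

  if (is.null(panel) || nrow(panel) == 0) {
    warning("empty panel: query founds family 1", call. = FALSE)
    return(tibble::tibble(
      gene_id = id, family = 1L, subfamily = "A", member_no = 1L,
      is_new_family = TRUE, is_new_subfamily = TRUE,
      best_hit = NA_character_, best_identity = NA_real_))
  }
  check_panel(panel)

  ids <- purrr::map_dbl(panel$sequence, ~ pair_identity(query, .x, scoring,
                                                        denominator))
  best <- which.max(ids)
  best_id <- ids[best]

  if (best_id < family_threshold) {
    fam <- max(panel$family) + 1L
    return(tibble::tibble(
      gene_id = id, family = fam, subfamily = "A", member_no = 1L,
      is_new_family = TRUE, is_new_subfamily = TRUE,
      best_hit = panel$gene_id[best], best_identity = best_id))
  }
  fam <- panel$family[best]
  fam_rows <- panel[panel$family == fam, ]
  fam_ids <- ids[panel$family == fam]
  if (max(fam_ids) > subfamily_threshold) {
    sub <- fam_rows$subfamily[which.max(fam_ids)]
    member <- max(fam_rows$member_no[fam_rows$subfamily == sub]) + 1L
    new_sub <- FALSE
  } else {
    sub <- next_letter(fam_rows$subfamily)
    member <- 1L
    new_sub <- TRUE
  }
  tibble::tibble(
    gene_id = id, family = fam, subfamily = sub, member_no = member,
    is_new_family = FALSE, is_new_subfamily = new_sub,
    best_hit = panel$gene_id[best], best_identity = best_id)
}

check_panel <- function(panel) {
  need <- c("gene_id", "family", "subfamily", "member_no", "sequence")
  miss <- setdiff(need, names(panel))
  if (length(miss))
    stop("panel lacks columns: ", paste(miss, collapse = ", "), call. = FALSE)
  invisible(panel)
}

next_letter <- function(used) {
  pool <- c(LETTERS, paste0(rep(LETTERS, each = 26), LETTERS))
  cand <- setdiff(pool, used)
  if (!length(cand)) stop("subfamily letters exhausted")
  cand[[1]]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# single-linkage components of an identity matrix at a strict/non-strict cutoff
identity_components <- function(m, cutoff, strict = FALSE) {
  n <- nrow(m)
  comp <- seq_len(n)
  link <- if (strict) m > cutoff else m >= cutoff
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) {
      nb <- which(link[i, ])
      if (length(nb)) {
        newc <- min(comp[c(i, nb)])
        if (any(comp[c(i, nb)] != newc)) {
          comp[c(i, nb)] <- newc
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  match(comp, unique(comp))
}

#' Name every candidate in a proteome: the family census
#'
#' Runs the AGNC rule over a whole set of candidate proteins. Queries that
#' attach to the panel (best identity at or above the family threshold)
#' inherit its family; mutually novel queries are grouped by
#' single-linkage on pairwise identity before new family numbers are
#' assigned, so one new family never splinters into several. All
#' numbering (new family numbers, subfamily letters, member numbers) is
#' assigned in a canonical query order -- queries sorted by sequence, then
#' id -- which makes the census invariant to input order.
#'
#' @param queries Named character vector of candidate protein sequences,
#'   or a [find_candidates()] result tibble (its passing rows are used, in
#'   which case `sequences` must supply the proteome).
#' @param sequences Named character vector of sequences (required when
#'   `queries` is a hit tibble).
#' @param panel Optional classified panel tibble (see
#'   [classify_protein()]); `NULL` founds families from scratch.
#' @param prefix Prefix for systematic gene names (default `"ALDH"`).
#' @inheritParams classify_protein
#' @return An `aldh_census` tibble: one row per query with `gene_id`,
#'   `name`, `family`, `subfamily`, `member_no`, novelty flags, best-hit
#'   evidence. Per-family member counts are available via [glance()].
#' @examples
#' \donttest{
#' gl <- make_genome_layout(synthetic_spec(n_families = 3, seed = 1))
#' cs <- family_census(gl$proteins)
#' glance(cs)
#' }
#' @export
family_census <- function(queries, sequences = NULL, panel = NULL,
                          family_threshold = 0.4, subfamily_threshold = 0.6,
                          scoring = aa_scoring(), prefix = "ALDH",
                          denominator = c("alignment", "shorter")) {
  denominator <- match.arg(denominator)
  if (is.data.frame(queries)) {
    if (is.null(sequences))
      stop("supply `sequences` when `queries` is a hit table")
    ids <- queries$gene_id[queries$passed]
    queries <- sequences[ids]
  }
  if (!length(queries)) {
    return(new_census(tibble::tibble(
      gene_id = character(), name = character(), family = integer(),
      subfamily = character(), member_no = integer(),
      is_new_family = logical(), is_new_subfamily = logical(),
      best_hit = character(), best_identity = double())))
  }
  stopifnot(is.character(queries), !is.null(names(queries)))
  if (anyDuplicated(names(queries)))
    stop("duplicate gene_ids in queries", call. = FALSE)

  # canonical processing order: by sequence string, then id
  ord <- order(unname(queries), names(queries))
  queries <- queries[ord]
  n <- length(queries)

  if (!is.null(panel)) check_panel(panel)
  pan <- panel %||% tibble::tibble(
    gene_id = character(), family = integer(), subfamily = character(),
    member_no = integer(), sequence = character())

  # query-vs-panel identities
  qp <- matrix(0, n, nrow(pan))
  if (nrow(pan))
    for (i in seq_len(n)) for (j in seq_len(nrow(pan)))
      qp[i, j] <- pair_identity(queries[[i]], pan$sequence[[j]],
                                scoring, denominator)
  best_j <- if (nrow(pan)) apply(qp, 1, which.max) else rep(NA_integer_, n)
  best_id <- if (nrow(pan)) apply(qp, 1, max) else rep(NA_real_, n)
  attached <- if (nrow(pan)) best_id >= family_threshold else rep(FALSE, n)

  res <- tibble::tibble(
    gene_id = names(queries), name = NA_character_, family = NA_integer_,
    subfamily = NA_character_, member_no = NA_integer_,
    is_new_family = !attached, is_new_subfamily = FALSE,
    best_hit = if (nrow(pan)) pan$gene_id[best_j] else NA_character_,
    best_identity = best_id)

  # working panel grows as queries are named, so member numbering and
  # subfamily inheritance see earlier (canonically ordered) queries
  work <- pan

  # novel queries: group before numbering
  if (any(!attached)) {
    novel <- which(!attached)
    qq <- identity_matrix(queries[novel], scoring)
    comp <- identity_components(qq, family_threshold, strict = FALSE)
    base_fam <- if (nrow(pan)) max(pan$family) else 0L
    for (k in sort(unique(comp))) {
      fam <- base_fam + k
      members <- novel[comp == k]
      sub_comp <- identity_components(
        qq[comp == k, comp == k, drop = FALSE],
        subfamily_threshold, strict = TRUE)
      for (s in sort(unique(sub_comp))) {
        letter <- LETTERS[s]
        in_sub <- members[sub_comp == s]
        res$family[in_sub] <- fam
        res$subfamily[in_sub] <- letter
        res$member_no[in_sub] <- seq_along(in_sub)
        res$is_new_subfamily[in_sub] <- TRUE
      }
    }
  }

  # attached queries: sequential assignment in canonical order
  for (i in which(attached)) {
    fam <- pan$family[best_j[i]]
    fam_rows <- work[work$family == fam, ]
    ids_fam <- purrr::map_dbl(fam_rows$sequence,
                              ~ pair_identity(queries[[i]], .x, scoring,
                                              denominator))
    if (length(ids_fam) && max(ids_fam) > subfamily_threshold) {
      sub <- fam_rows$subfamily[which.max(ids_fam)]
      member <- max(fam_rows$member_no[fam_rows$subfamily == sub]) + 1L
    } else {
      sub <- next_letter(fam_rows$subfamily)
      member <- 1L
      res$is_new_subfamily[i] <- TRUE
    }
    res$family[i] <- fam
    res$subfamily[i] <- sub
    res$member_no[i] <- member
    work <- dplyr::bind_rows(work, tibble::tibble(
      gene_id = res$gene_id[i], family = fam, subfamily = sub,
      member_no = member, sequence = unname(queries[[i]])))
  }

  res$name <- paste0(prefix, res$family, res$subfamily, res$member_no)
  new_census(dplyr::arrange(res, .data$family, .data$subfamily,
                            .data$member_no))
}

new_census <- function(tbl) {
  class(tbl) <- c("aldh_census", class(tbl))
  tbl
}

#' @exportS3Method generics::glance
glance.aldh_census <- function(x, ...) {
  counts <- dplyr::count(tibble::as_tibble(x), .data$family, name = "members")
  tibble::tibble(
    n_genes = nrow(x),
    n_families = nrow(counts),
    n_multimember = sum(counts$members > 1),
    n_new_families = length(unique(x$family[x$is_new_family])))
}

#' @exportS3Method generics::tidy
tidy.aldh_census <- function(x, ...) {
  dplyr::count(tibble::as_tibble(x), .data$family, name = "members")
}
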