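#' Core families shared by a set of organisms
#'
#' A family is core to a set of organisms when it is present in every
#' one of them; adding organisms can therefore only shrink the core.
#'
#' @param fm Long family matrix as returned by [load_table2()]
#'   (`organism`, `family`, `present`).
#' @param organisms Character vector of organism names (must all be rows
#'   of the matrix).
#' @return Sorted integer vector of family numbers.
#' @export
core_families <- function(fm, organisms) {
  unknown <- setdiff(organisms, unique(fm$organism))
  if (length(unknown))
    stop("unknown organisms: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  per <- lapply(organisms, function(o)
    sort(unique(fm$family[fm$organism == o & fm$present])))
  if (!length(per)) return(integer())
  sort(Reduce(intersect, per))
}

#' Core families shared with further organisms
#'
#' Restricts a core family set to those families present in any (or all)
#' of a second organism list -- e.g. which core vascular-plant families
#' are also found in at least one alga.
#'
#' @inheritParams core_families
#' @param core Family set (from [core_families()]).
#' @param mode `"any"` (default) or `"all"`.
#' @return Sorted integer vector of family numbers.
#' @export
shared_with <- function(fm, core, organisms, mode = c("any", "all")) {
  mode <- match.arg(mode)
  if (!length(organisms)) return(integer())
  per <- lapply(organisms, function(o)
    unique(fm$family[fm$organism == o & fm$present]))
  pool <- if (mode == "any") Reduce(union, per) else Reduce(intersect, per)
  sort(intersect(core, pool))
}

#' Per-organism gene totals
#'
#' Row sums of the family matrix. Organisms recorded with presence flags
#' only (the fungal row) have no defined total and return `NA`.
#'
#' @inheritParams core_families
#' @return Tibble `organism`, `total` (integer or `NA`).
#' @export
organism_totals <- function(fm) {
  fm |>
    dplyr::group_by(.data$organism) |>
    dplyr::summarise(total = if (any(is.na(.data$count[.data$present])))
      NA_integer_ else sum(.data$count[.data$present]), .groups = "drop")
}
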