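#' Build an expression set
#'
#' Container for a probe-set by array matrix of log2 intensities with
#' per-cell detection calls (P/M/A), an array-to-condition design, and a
#' many-to-one probe-to-gene map.
#'
#' @param expr Numeric matrix (probes x arrays) of log2 intensities with
#'   dimnames.
#' @param design Tibble `array`, `condition` covering every column of
#'   `expr`.
#' @param calls Character matrix congruent to `expr` with values in
#'   P/M/A; defaults to all-present.
#' @param probe_map Tibble `probe_id`, `gene_id`; defaults to
#'   probe == gene.
#' @return An `expr_set` list.
#' @export
expression_set <- function(expr, design, calls = NULL, probe_map = NULL) {
  stopifnot(is.matrix(expr), is.numeric(expr), !is.null(rownames(expr)),
            !is.null(colnames(expr)))
  if (any(!is.finite(expr))) stop("expression values must be finite")
  if (is.null(calls)) {
    calls <- matrix("P", nrow(expr), ncol(expr), dimnames = dimnames(expr))
  }
  stopifnot(identical(dim(calls), dim(expr)), all(calls %in% c("P", "M", "A")))
  if (!all(colnames(expr) %in% design$array))
    stop("every array must be mapped to a condition", call. = FALSE)
  if (is.null(probe_map))
    probe_map <- tibble::tibble(probe_id = rownames(expr),
                                gene_id = rownames(expr))
  structure(list(expr = expr, calls = calls,
                 design = tibble::as_tibble(design),
                 probe_map = tibble::as_tibble(probe_map)),
            class = "expr_set")
}

#' @export
print.expr_set <- function(x, ...) {
  cat("<expr_set>", nrow(x$expr), "probes x", ncol(x$expr), "arrays;",
      length(unique(x$design$condition)), "conditions\n")
  invisible(x)
}

#' Quantile normalization across arrays
#'
#' Forces every array column onto the common distribution of mean order
#' statistics; within-array ranks are preserved, and ties receive the
#' average of the corresponding order statistics.
#'
#' @param es An [expression_set()] (>= 2 arrays).
#' @return The expression set with normalized intensities.
#' @export
quantile_normalize <- function(es) {
  stopifnot(inherits(es, "expr_set"))
  m <- es$expr
  if (ncol(m) < 2) stop("need at least 2 arrays", call. = FALSE)
  sorted <- apply(m, 2, sort)
  target <- rowMeans(sorted)
  out <- apply(m, 2, function(col) {
    r <- rank(col, ties.method = "average")
    lo <- target[floor(r)]; hi <- target[ceiling(r)]
    (lo + hi) / 2
  })
  dimnames(out) <- dimnames(m)
  es$expr <- out
  es
}

#' Drop probes absent or marginal on every array
#'
#' A probe set is removed iff its detection call is A or M on all arrays
#' of the experiment (i.e., it is never called present); the identities
#' of dropped probes are kept in attribute `"dropped"`.
#'
#' @param es An [expression_set()].
#' @return Filtered expression set.
#' @export
filter_absent <- function(es) {
  stopifnot(inherits(es, "expr_set"))
  keep <- apply(es$calls == "P", 1, any)
  dropped <- rownames(es$expr)[!keep]
  es$expr <- es$expr[keep, , drop = FALSE]
  es$calls <- es$calls[keep, , drop = FALSE]
  attr(es, "dropped") <- dropped
  es
}

# Newton inversion of the trigamma function (y > 0)
trigamma_inverse <- function(y) {
  if (y > 1e7) return(1 / sqrt(y))
  if (y < 1e-6) return(1 / y)
  x <- 0.5 + 1 / y
  for (i in 1:50) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, deriv = 2)
    x <- x + dif
    if (abs(dif / x) < 1e-10) break
  }
  x
}

#' Empirical-Bayes moderated t-test for one contrast
#'
#' Two-group comparison with variance shrinkage: per-probe pooled sample
#' variances are squeezed towards a common prior variance `s0^2` with
#' prior degrees of freedom `d0`, both estimated by the method of moments
#' on the log sample variances (log variances of scaled-F distributed
#' variances have closed-form digamma/trigamma moments; a non-finite
#' moment estimate of `d0` means the variances are consistent with full
#' pooling and `d0 = Inf` is used). The moderated t has `d + d0` degrees
#' of freedom.
#'
#' @param es An [expression_set()].
#' @param contrast Length-2 character vector `c(treatment, control)`
#'   naming design conditions; the log2 fold change is treatment minus
#'   control.
#' @param d0_override Optional fixed prior df (0 recovers the ordinary
#'   equal-variance t; `Inf` fully pools variances).
#' @return A `contrast_result` tibble: `probe_id`, `lfc`, `s2`,
#'   `s2_post`, `t`, `df_total`, `p_value`; estimated `d0` and `s0sq` are
#'   attributes and reported by [glance()].
#' @export
moderated_t <- function(es, contrast, d0_override = NULL) {
  stopifnot(inherits(es, "expr_set"), length(contrast) == 2)
  arr <- function(cond) es$design$array[es$design$condition == cond]
  a1 <- intersect(colnames(es$expr), arr(contrast[1]))
  a2 <- intersect(colnames(es$expr), arr(contrast[2]))
  n1 <- length(a1); n2 <- length(a2)
  if (n1 < 2 || n2 < 2)
    stop("each condition needs >= 2 arrays for a variance estimate; ",
         "use descriptive summaries for single-array conditions",
         call. = FALSE)
  x1 <- es$expr[, a1, drop = FALSE]; x2 <- es$expr[, a2, drop = FALSE]
  lfc <- unname(rowMeans(x1) - rowMeans(x2))
  rss <- unname(rowSums((x1 - rowMeans(x1))^2) +
                  rowSums((x2 - rowMeans(x2))^2))
  d <- n1 + n2 - 2
  s2 <- rss / d
  s2 <- pmax(s2, 1e-12)

  if (is.null(d0_override)) {
    z <- log(s2)
    evar <- var(z) - trigamma(d / 2)
    emean <- mean(z) - digamma(d / 2) + log(d / 2)
    if (is.finite(evar) && evar > 0) {
      d0 <- 2 * trigamma_inverse(evar)
      s0sq <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
    } else {
      d0 <- Inf
      s0sq <- mean(s2)  # MLE under full pooling
    }
  } else {
    d0 <- d0_override
    z <- log(s2)
    emean <- mean(z) - digamma(d / 2) + log(d / 2)
    s0sq <- if (is.finite(d0) && d0 > 0)
      exp(emean + digamma(d0 / 2) - log(d0 / 2)) else mean(s2)
  }
  s2_post <- if (is.infinite(d0)) rep(s0sq, length(s2))
    else if (d0 == 0) s2
    else (d0 * s0sq + d * s2) / (d0 + d)
  se <- sqrt(s2_post * (1 / n1 + 1 / n2))
  tt <- lfc / se
  # total df capped at the pooled df of the whole experiment
  df_total <- min(d + d0, length(s2) * d)
  p <- 2 * pt(-abs(tt), df = df_total)
  structure(tibble::tibble(
    probe_id = rownames(es$expr), lfc = lfc, s2 = s2, s2_post = s2_post,
    t = tt, df_total = df_total, p_value = p),
    class = c("contrast_result", class(tibble::tibble())),
    d0 = d0, s0sq = s0sq, contrast = contrast, n = c(n1, n2))
}

#' @exportS3Method generics::glance
glance.contrast_result <- function(x, ...) {
  tibble::tibble(d0 = attr(x, "d0"), s0sq = attr(x, "s0sq"),
                 treatment = attr(x, "contrast")[1],
                 control = attr(x, "contrast")[2],
                 n_treatment = attr(x, "n")[1], n_control = attr(x, "n")[2],
                 n_probes = nrow(x))
}

#' @exportS3Method generics::tidy
tidy.contrast_result <- function(x, alpha = 0.05, ...) {
  out <- tibble::as_tibble(x)
  out$adj_p <- bh_fdr(out$p_value)
  out$de <- out$adj_p < alpha
  out
}

#' Benjamini--Hochberg adjusted p-values
#'
#' Step-up false discovery rate adjustment (monotone, capped at 1).
#'
#' @param pvals Numeric vector of p-values in \[0, 1\]; `NA`/`NaN` is an
#'   error.
#' @return Adjusted p-values in the input order.
#' @export
bh_fdr <- function(pvals) {
  if (any(is.na(pvals))) stop("NA/NaN p-values", call. = FALSE)
  if (any(pvals < 0 | pvals > 1)) stop("p-values outside [0, 1]",
                                       call. = FALSE)
  stats::p.adjust(pvals, method = "BH")
}

#' Gene-level responsiveness across contrasts
#'
#' Aggregates probe-level results to genes: a gene is responsive in a
#' contrast iff any of its probe sets is differentially expressed at
#' BH-adjusted p below `alpha` (mode `"any"`; `"all"` requires every
#' surviving probe). Direction comes from the most significant DE probe.
#' Genes whose probes were all filtered out are reported `not_assayed`,
#' distinct from `not_de`. The log2 fold-change matrix (most significant
#' probe per gene) is ordered by average-linkage hierarchical clustering
#' on correlation distance; reordering never alters the stored values.
#'
#' @param results Named list of [moderated_t()] results (one per
#'   contrast), or a single result.
#' @param probe_map Tibble `probe_id`, `gene_id` covering all probes
#'   (including filtered ones, so not-assayed genes can be identified).
#' @param alpha FDR threshold (default 0.05).
#' @param mode `"any"` (default) or `"all"` probe aggregation.
#' @return A `responsiveness_report`: list with `report` (tibble
#'   `gene_id`, `contrast`, `status`, `lfc`, `min_adj_p`), `lfc_matrix`,
#'   `row_order`, `alpha`.
#' @export
responsiveness_report <- function(results, probe_map, alpha = 0.05,
                                  mode = c("any", "all")) {
  mode <- match.arg(mode)
  if (inherits(results, "contrast_result")) results <- list(contrast = results)
  stopifnot(length(results) >= 1, !is.null(names(results)))
  genes <- sort(unique(probe_map$gene_id))
  rows <- list()
  for (ct in names(results)) {
    res <- tibble::as_tibble(results[[ct]])
    res$adj_p <- bh_fdr(res$p_value)
    res <- dplyr::inner_join(res, probe_map, by = "probe_id")
    for (g in genes) {
      rg <- res[res$gene_id == g, ]
      if (!nrow(rg)) {
        rows[[length(rows) + 1]] <- tibble::tibble(
          gene_id = g, contrast = ct, status = "not_assayed",
          lfc = NA_real_, min_adj_p = NA_real_)
        next
      }
      de <- rg$adj_p < alpha
      responsive <- if (mode == "any") any(de) else all(de)
      top <- which.min(rg$adj_p)
      status <- if (!responsive) "not_de"
        else if (rg$lfc[top] > 0) "up" else "down"
      rows[[length(rows) + 1]] <- tibble::tibble(
        gene_id = g, contrast = ct, status = status,
        lfc = unname(rg$lfc[top]), min_adj_p = min(rg$adj_p))
    }
  }
  report <- dplyr::bind_rows(rows)
  lfc_matrix <- tidyr::pivot_wider(report[, c("gene_id", "contrast", "lfc")],
                                   names_from = "contrast",
                                   values_from = "lfc")
  mat <- as.matrix(lfc_matrix[, -1, drop = FALSE])
  rownames(mat) <- lfc_matrix$gene_id
  row_order <- seq_len(nrow(mat))
  ok <- rowSums(!is.na(mat)) == ncol(mat) & apply(mat, 1, sd) > 0
  if (ncol(mat) >= 2 && sum(ok) >= 3) {
    cc <- suppressWarnings(cor(t(mat[ok, , drop = FALSE])))
    cc[!is.finite(cc)] <- 0
    hc <- hclust(as.dist(1 - cc), method = "average")
    row_order <- c(which(ok)[hc$order], which(!ok))
  }
  structure(list(report = report, lfc_matrix = mat, row_order = row_order,
                 alpha = alpha, mode = mode),
            class = "responsiveness_report")
}

#' @export
print.responsiveness_report <- function(x, ...) {
  cat("<responsiveness_report>", nrow(x$lfc_matrix), "genes x",
      ncol(x$lfc_matrix), "contrasts; alpha", x$alpha, "\n")
  print(dplyr::count(x$report, .data$contrast, .data$status))
  invisible(x)
}

#' Heatmap of a responsiveness report
#'
#' Log2 fold-change heatmap with rows in clustering order, the usual
#' display for a stress-response screen.
#'
#' @param object A [responsiveness_report()].
#' @param ... Ignored.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.responsiveness_report <- function(object, ...) {
  mat <- object$lfc_matrix[object$row_order, , drop = FALSE]
  df <- tibble::as_tibble(mat, rownames = "gene_id") |>
    tidyr::pivot_longer(-"gene_id", names_to = "contrast",
                        values_to = "lfc")
  df$gene_id <- factor(df$gene_id, levels = rev(rownames(mat)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$contrast, y = .data$gene_id,
                                   fill = .data$lfc)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "white",
                                  high = "red", na.value = "grey85") +
    ggplot2::labs(x = NULL, y = NULL, fill = "log2 FC") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}
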