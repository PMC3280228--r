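make_toy_es <- function(m, conds = rep(c("treatment", "control"), each = 3),
                        calls = NULL, probe_map = NULL) {
  colnames(m) <- paste0("a", seq_len(ncol(m)))
  if (is.null(rownames(m))) rownames(m) <- paste0("p", seq_len(nrow(m)))
  expression_set(m, tibble::tibble(array = colnames(m), condition = conds),
                 calls = calls, probe_map = probe_map)
}

test_that("quantile normalization equalizes column distributions", {
  m <- cbind(c(2, 4, 6, 8), c(2, 4, 6, 8))
  es <- make_toy_es(m, conds = c("t", "c"))
  expect_equal(quantile_normalize(es)$expr, es$expr)

  # permuted columns: both become the mean order statistics
  m2 <- cbind(c(5, 2, 3, 4), c(4, 3, 2, 5))
  es2 <- quantile_normalize(make_toy_es(m2, conds = c("t", "c")))
  expect_equal(sort(unname(es2$expr[, 1])), sort(unname(es2$expr[, 2])))
  expect_equal(unname(es2$expr[, 1]), c(5, 2, 3, 4))  # ranks preserved

  # hand-computed case with distinct values
  m3 <- cbind(c(1, 3, 5, 7), c(2, 4, 6, 100))
  es3 <- quantile_normalize(make_toy_es(m3, conds = c("t", "c")))
  expect_equal(unname(es3$expr[, 1]), c(1.5, 3.5, 5.5, 53.5))

  # a monotone transform of a column leaves its post-normalization ranks
  m4 <- matrix(rnorm(40), 10, 4)
  es4 <- make_toy_es(m4, conds = rep(c("t", "c"), each = 2))
  es4b <- es4; es4b$expr[, 2] <- exp(es4b$expr[, 2])
  expect_equal(rank(quantile_normalize(es4)$expr[, 2]),
               rank(quantile_normalize(es4b)$expr[, 2]))

  # cross-check against the established implementation
  q <- quantile_normalize(es4)$expr
  ref <- limma::normalizeQuantiles(es4$expr)
  expect_equal(unname(q), unname(ref), tolerance = 1e-12)
})

test_that("all-absent probes are dropped, partially-present kept", {
  m <- matrix(rnorm(18, 8), 3, 6)
  calls <- matrix("A", 3, 6)
  calls[1, 2] <- "P"          # present on one array: retained
  calls[3, ] <- "M"           # marginal everywhere: dropped
  rownames(m) <- paste0("p", 1:3)
  dimnames(calls) <- dimnames(m) <- list(paste0("p", 1:3),
                                         paste0("a", 1:6))
  es <- filter_absent(make_toy_es(m, calls = calls))
  expect_equal(rownames(es$expr), "p1")
  expect_setequal(attr(es, "dropped"), c("p2", "p3"))

  me <- make_expression(synthetic_spec(seed = 88, expression = list(
    n_genes = 400, n_planted = 40, frac_absent = 0.1)))
  expect_equal(length(attr(filter_absent(me$es), "dropped")), 40)
})

test_that("moderated t matches limma and its stated limits", {
  me <- make_expression(synthetic_spec(seed = 90, expression = list(
    n_genes = 300, n_planted = 30)))
  es <- filter_absent(me$es)
  res <- moderated_t(es, c("treatment", "control"))

  design <- cbind(1, es$design$condition[match(
    colnames(es$expr), es$design$array)] == "treatment")
  fit <- limma::eBayes(limma::lmFit(es$expr, design))
  expect_equal(attr(res, "d0"), fit$df.prior, tolerance = 1e-6)
  expect_equal(attr(res, "s0sq"), fit$s2.prior, tolerance = 1e-6)
  expect_equal(res$t, unname(fit$t[, 2]), tolerance = 1e-9)
  expect_equal(res$p_value, unname(fit$p.value[, 2]), tolerance = 1e-9)

  # d0 -> 0 is the ordinary equal-variance two-sample t
  r0 <- moderated_t(es, c("treatment", "control"), d0_override = 0)
  i <- which.max(abs(r0$lfc))
  tt <- t.test(es$expr[i, 1:3], es$expr[i, 4:6], var.equal = TRUE)
  expect_equal(r0$t[i], unname(tt$statistic), tolerance = 1e-9)
  expect_equal(r0$p_value[i], tt$p.value, tolerance = 1e-9)

  # shrinkage direction: posterior variance between s2 and s0^2
  s0 <- attr(res, "s0sq")
  expect_true(all(res$s2_post >= pmin(res$s2, s0) - 1e-12 &
                    res$s2_post <= pmax(res$s2, s0) + 1e-12))

  # equal true variances, many probes: posterior df is large, t ~ z
  expect_gt(attr(res, "d0"), 4)

  # single-array condition is rejected with advice
  bad <- es; bad$design$condition[5:6] <- "other"
  expect_error(moderated_t(bad, c("treatment", "control")), "descriptive")
})

test_that("null p-values are approximately uniform", {
  me <- make_expression(synthetic_spec(seed = 11, expression = list(
    n_genes = 5000, n_planted = 0, frac_absent = 0)))
  res <- moderated_t(me$es, c("treatment", "control"))
  ks <- suppressWarnings(ks.test(res$p_value, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("BH adjustment equals the direct step-up", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_fdr(0.2), 0.2)
  expect_error(bh_fdr(c(0.1, NA)), "NA")
  expect_error(bh_fdr(c(0.1, 1.2)), "outside")

  withr::with_seed(91, {
    for (i in 1:20) {
      p <- runif(sample(1:50, 1))
      expect_equal(bh_fdr(p), oracle_bh(p))
    }
    # exhaustive short vectors over a p-grid
    grid <- c(0.001, 0.01, 0.04, 0.2, 0.5, 1)
    for (i in 1:30) {
      p <- sample(grid, sample(1:6, 1), replace = TRUE)
      expect_equal(bh_fdr(p), oracle_bh(p))
    }
  })
})

test_that("gene-level report aggregates probes and flags not-assayed", {
  withr::with_seed(92, {
    m <- matrix(rnorm(5 * 6, 8, 0.2), 5, 6)
    m[1, 1:3] <- m[1, 1:3] + 5     # probe 1 strongly up
    rownames(m) <- paste0("p", 1:5)
    pm <- tibble::tibble(probe_id = paste0("p", 1:6),
                         gene_id = c("gA", "gA", "gB", "gB", "gC", "gD"))
    es <- make_toy_es(m, probe_map = pm)
    res <- moderated_t(es, c("treatment", "control"))
    rep <- responsiveness_report(list(salt = res), pm, alpha = 0.05)
    r <- rep$report
    expect_equal(r$status[r$gene_id == "gA"], "up")   # any-probe rule
    expect_equal(r$status[r$gene_id == "gD"], "not_assayed")
    expect_true(all(r$status[r$gene_id %in% c("gB", "gC")] == "not_de"))
    # stored fold changes do not depend on clustering order
    expect_equal(sort(rownames(rep$lfc_matrix)), sort(unique(pm$gene_id)))
    expect_equal(rep$lfc_matrix["gA", "salt"],
                 r$lfc[r$gene_id == "gA"])
    p <- ggplot2::autoplot(rep)
    expect_s3_class(p, "ggplot")
  })
})

test_that("clustering order never alters stored fold changes", {
  me <- make_expression(synthetic_spec(seed = 93, expression = list(
    n_genes = 60, n_planted = 15, frac_absent = 0)))
  res1 <- moderated_t(me$es, c("treatment", "control"))
  me2 <- make_expression(synthetic_spec(seed = 94, expression = list(
    n_genes = 60, n_planted = 10, frac_absent = 0)))
  es2 <- me2$es; es2$expr <- es2$expr[rownames(me$es$expr), ]
  res2 <- moderated_t(es2, c("treatment", "control"))
  rep <- responsiveness_report(list(c1 = res1, c2 = res2),
                               me$es$probe_map)
  ord <- rep$row_order
  expect_setequal(ord, seq_len(nrow(rep$lfc_matrix)))
  got <- rep$lfc_matrix[rep$report$gene_id[1], "c1"]
  expect_equal(got, rep$report$lfc[rep$report$contrast == "c1"][1])
})
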