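test_that("alignment scores are optimal (exhaustive oracle, short pairs)", {
  withr::with_seed(31, {
    for (i in 1:25) {
      a <- rand_protein(sample(2:8, 1))
      b <- rand_protein(sample(2:8, 1))
      my <- global_align(a, b)
      expect_equal(my$score, oracle_align_score(a, b, blosum62),
                   info = paste(a, b))
    }
  })
})

test_that("alignment scores match an independent implementation", {
  withr::with_seed(32, {
    for (i in 1:10) {
      a <- rand_protein(sample(20, 1) + 30)
      b <- rand_protein(sample(20, 1) + 30)
      ref <- Biostrings::pairwiseAlignment(
        a, b, substitutionMatrix = blosum62,
        gapOpening = 10, gapExtension = 0.5)
      expect_equal(global_align(a, b)$score, Biostrings::score(ref))
    }
  })
})

test_that("percent identity follows its definition", {
  s <- with_seed_protein(60, 1)
  expect_equal(global_align(s, s)$identity, 1)
  expect_equal(global_align(s, s)$aligned_columns, 60)

  aln <- global_align("ACDEFGHIK", "ACDEFGHIR")
  expect_false(grepl("-", aln$a))
  expect_equal(aln$identity, 8 / 9)

  expect_equal(global_align("AAAA", "CCCC")$identity, 0)

  # constructed gapped pair: 50 matches over 100 non-terminal-gap columns
  a <- paste(rep(c("A", "C"), 50), collapse = "")
  b <- paste(c(rep(c("A", "G"), 50)), collapse = "")
  expect_equal(percent_identity(list(a, b)), 0.5)
  # terminal gaps are excluded from the denominator
  expect_equal(percent_identity(list(paste0("--", a), paste0(b, "--"))), 0.5)
  # symmetry
  expect_equal(percent_identity(list(b, a)), percent_identity(list(a, b)))
  # alternative denominator: shorter ungapped sequence
  expect_equal(percent_identity(list("AC-D", "ACAD"), "shorter"), 1)
  expect_error(global_align("AC1D", "ACD"), "non-amino-acid")
})

test_that("the nomenclature rule assigns families and subfamilies", {
  base <- with_seed_protein(100, 9)
  panel <- tibble::tibble(
    gene_id = c("ALDH2B1", "ALDH9A1"),
    family = c(2L, 9L), subfamily = c("B", "A"), member_no = c(1L, 1L),
    sequence = c(base, with_seed_protein(100, 10)))

  q65 <- flip_to_identity(base, 0.65)
  expect_equal(pair_identity(q65, base), 0.65)
  r <- classify_protein(q65, panel, id = "q")
  expect_equal(r$family, 2L)
  expect_equal(r$subfamily, "B")
  expect_equal(r$member_no, 2L)
  expect_false(r$is_new_subfamily)

  q45 <- flip_to_identity(base, 0.45)
  r <- classify_protein(q45, panel, id = "q")
  expect_equal(r$family, 2L)
  expect_true(r$is_new_subfamily)
  expect_equal(r$subfamily, "A")  # next free letter in family 2
  expect_equal(r$member_no, 1L)

  q35 <- flip_to_identity(base, 0.35)
  r <- classify_protein(q35, panel, id = "q")
  expect_true(r$is_new_family)
  expect_equal(r$family, 10L)  # max existing + 1

  expect_warning(r0 <- classify_protein(q35, NULL, id = "q"), "empty panel")
  expect_equal(r0$family, 1L)
})

test_that("threshold boundaries follow the strict-inequality reading", {
  base <- with_seed_protein(100, 19)
  panel <- tibble::tibble(gene_id = "ALDH2B1", family = 2L,
                          subfamily = "B", member_no = 1L, sequence = base)
  q40 <- flip_to_identity(base, 0.40)
  expect_equal(pair_identity(q40, base), 0.40)  # construction check
  r40 <- classify_protein(q40, panel)
  expect_false(r40$is_new_family)   # exactly 0.40 does NOT found a family
  expect_equal(r40$family, 2L)
  expect_true(r40$is_new_subfamily)

  q60 <- flip_to_identity(base, 0.60)
  expect_equal(pair_identity(q60, base), 0.60)
  r60 <- classify_protein(q60, panel)
  expect_equal(r60$family, 2L)
  expect_true(r60$is_new_subfamily)  # exactly 0.60 is not subfamily member
})

test_that("census recovers planted families exactly", {
  for (seed in c(3, 8, 15)) {
    gl <- make_genome_layout(synthetic_spec(
      n_families = 5, members_per_family = 3, seq_len = 120, seed = seed))
    cs <- family_census(gl$proteins)
    expect_equal(glance(cs)$n_families, 5)
    joined <- dplyr::inner_join(tibble::as_tibble(cs)[, c("gene_id", "family")],
                                gl$truth, by = "gene_id")
    # recovered partition equals planted partition
    expect_equal(length(unique(paste(joined$family.x, joined$family.y))), 5)
    expect_equal(sort(tidy(cs)$members), rep(3L, 5))
  }
})

test_that("census is invariant to query input order", {
  gl <- make_genome_layout(synthetic_spec(
    n_families = 3, members_per_family = 3, seq_len = 100, seed = 27))
  cs1 <- family_census(gl$proteins)
  cs2 <- family_census(gl$proteins[withr::with_seed(1, sample(9))])
  expect_identical(tibble::as_tibble(cs1), tibble::as_tibble(cs2))
})

test_that("census mirrors the published family-size profile", {
  sizes <- c(3, 4, 3, 3, 2, 2, 2, 1, 2, 1)  # ten families, 23 genes
  gl <- make_genome_layout(synthetic_spec(
    n_families = 10, members_per_family = 4, seq_len = 120, seed = 33))
  keep <- unlist(purrr::imap(sizes, function(k, f)
    gl$truth$gene_id[gl$truth$family == f][seq_len(k)]))
  cs <- family_census(gl$proteins[keep])
  g <- glance(cs)
  expect_equal(g$n_genes, 23)
  expect_equal(g$n_families, 10)
  expect_equal(g$n_multimember, 8)
  expect_equal(sort(tidy(cs)$members), sort(sizes))
})

test_that("census handles degenerate inputs", {
  expect_equal(nrow(family_census(character())), 0)
  s <- c(a = with_seed_protein(60, 2), a = with_seed_protein(60, 3))
  expect_error(family_census(s), "duplicate")
})
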