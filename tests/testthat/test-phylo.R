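test_that("p-distance implements pairwise deletion", {
  msa <- c(s1 = "ACDEF", s2 = "ACDEF", s3 = "ACDEW")
  d <- msa_pdistance(msa)
  expect_equal(d["s1", "s2"], 0)
  expect_equal(d["s1", "s3"], 0.2)

  # rows differing at 3 of 10 comparable columns (2 columns gap-masked)
  a <- "ACDEFGHIKLMN"
  b <- "ACWEFGHIKWM-"  # diffs at 3,10; col 12 gapped; plus one more
  b <- "ACWEFGAIKWM-"  # diffs at 3,7,10 among 11 comparable
  msa2 <- c(x = a, y = b)
  d2 <- msa_pdistance(msa2)
  expect_equal(d2["x", "y"], 3 / 11)

  expect_error(msa_pdistance(c(p = "AA--", q = "--AA")), "no comparable")

  # random alignments agree with direct column counting
  withr::with_seed(41, {
    for (i in 1:10) {
      m <- replicate(3, paste(sample(c("A", "C", "-"), 20, TRUE),
                              collapse = ""))
      names(m) <- paste0("t", 1:3)
      ok <- !grepl("^-*$", m)
      if (!all(ok)) next
      d <- try(msa_pdistance(m), silent = TRUE)
      if (inherits(d, "try-error")) next
      ch <- do.call(rbind, strsplit(m, ""))
      for (p in 1:2) for (q in (p + 1):3) {
        cmp <- ch[p, ] != "-" & ch[q, ] != "-"
        expect_equal(d[p, q], mean(ch[p, cmp] != ch[q, cmp]))
      }
    }
  })
})

test_that("three-taxon NJ has the closed-form branch lengths", {
  d <- matrix(c(0, 2, 3,
                2, 0, 5,
                3, 5, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- nj_tree(d)
  # l_A = (2 + 3 - 5)/2 = 0, l_B = (2 + 5 - 3)/2 = 2, l_C = 3
  len <- setNames(tr$edge.length[match(seq_len(3), tr$edge[, 2])],
                  tr$tip.label)
  expect_equal(unname(len[c("A", "B", "C")]), c(0, 2, 3))
  expect_error(nj_tree(d[1:2, 1:2]), "3 taxa")
  d2 <- d; d2[1, 2] <- 99
  expect_error(nj_tree(d2), "symmetric")
})

test_that("NJ recovers additive trees exactly", {
  withr::with_seed(50, {
    hits <- 0
    for (i in 1:50) {
      gen <- random_additive_matrix(6)
      my <- nj_tree(gen$d)
      hits <- hits + (ape::dist.topo(ape::unroot(my),
                                     ape::unroot(gen$tree)) == 0)
    }
    expect_equal(hits, 50)
    # and branch lengths reproduce the additive distances (4-taxon case)
    gen4 <- random_additive_matrix(4)
    my4 <- nj_tree(gen4$d)
    co <- ape::cophenetic.phylo(my4)[rownames(gen4$d), colnames(gen4$d)]
    expect_equal(co, gen4$d, tolerance = 1e-9)
  })
})

test_that("NJ agrees with an independent implementation on topology", {
  withr::with_seed(51, {
    for (i in 1:10) {
      n <- sample(5:9, 1)
      d <- as.matrix(dist(matrix(runif(n * 4), n)))
      dimnames(d) <- list(paste0("t", 1:n), paste0("t", 1:n))
      expect_true(ape::dist.topo(ape::unroot(nj_tree(d)),
                                 ape::unroot(ape::nj(d))) == 0)
    }
  })
})

test_that("newick round trip preserves topology, lengths and supports", {
  gl <- make_genome_layout(synthetic_spec(n_families = 2,
                                          members_per_family = 3,
                                          seq_len = 80, seed = 6))
  msa <- progressive_msa(gl$proteins)
  tr <- bootstrap_support(msa, n_reps = 50, seed = 3)
  nwk <- ape::write.tree(tr, digits = 12)
  tr2 <- ape::read.tree(text = nwk)
  expect_true(ape::dist.topo(ape::unroot(tr), ape::unroot(tr2)) == 0)
  expect_equal(sort(tr$edge.length), sort(tr2$edge.length),
               tolerance = 1e-9)
  expect_identical(tr$node.label, tr2$node.label)
})

test_that("bootstrap behaves at the extremes and is seed-deterministic", {
  s <- with_seed_protein(40, 44)
  msa <- setNames(rep(s, 4), paste0("t", 1:4))
  tr <- bootstrap_support(msa, n_reps = 30, seed = 1)
  expect_true(all(as.numeric(tr$node.label[-1]) == 100))

  # a deep split supported by many columns gets near-100 support
  a <- with_seed_protein(60, 45)
  b <- mutate_to_identity(a, 0.4, 1)
  msa2 <- c(g1a = a, g1b = mutate_to_identity(a, 0.9, 2),
            g2a = b, g2b = mutate_to_identity(b, 0.9, 3))
  msa2 <- progressive_msa(msa2)
  tr2 <- bootstrap_support(msa2, n_reps = 200, seed = 9)
  expect_gte(max(as.numeric(tr2$node.label[-1])), 99)

  tr3 <- bootstrap_support(msa2, n_reps = 200, seed = 9)
  expect_identical(tr2$node.label, tr3$node.label)
  expect_error(bootstrap_support(c(a = "A", b = "C"), 10, 1), "2 columns")
})

test_that("progressive alignment reduces to the pairwise aligner", {
  a <- with_seed_protein(50, 61); b <- mutate_to_identity(a, 0.6, 5)
  aln <- global_align(a, b)
  msa <- progressive_msa(c(x = a, y = b))
  expect_identical(unname(msa), c(aln$a, aln$b))

  s <- with_seed_protein(30, 62)
  msa3 <- progressive_msa(setNames(rep(s, 3), c("a", "b", "c")))
  expect_true(all(!grepl("-", msa3)))
  expect_warning(progressive_msa(c(only = s)), "single")
})

test_that("an easy planted indel is aligned optimally (3-way oracle)", {
  a <- "MACDEFGH"
  b <- "MACDFGH"   # E deleted
  c3 <- "MACDEFGH"
  msa <- progressive_msa(c(a = a, b = b, c = c3))
  expect_equal(gsub("-", "", msa), c(a = a, b = b, c = c3))
  got <- sp_score_of_msa(msa)
  opt <- oracle_msa3_sp(a, b, c3)
  expect_equal(got, opt)
})

test_that("members of one planted family form a clade", {
  ok <- 0
  for (seed in 1:10) {
    gl <- make_genome_layout(synthetic_spec(
      n_families = 3, members_per_family = 3, seq_len = 100, seed = seed))
    tr <- nj_tree(msa_pdistance(progressive_msa(gl$proteins)))
    mono <- all(vapply(1:3, function(f) {
      ape::is.monophyletic(tr, gl$truth$gene_id[gl$truth$family == f])
    }, TRUE))
    ok <- ok + mono
  }
  expect_gte(ok, 9)
})
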