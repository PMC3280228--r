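vit_layout <- load_layout("vitis")
vit_asg <- aldh_family_from_name(vit_layout$gene_id)

test_that("the adjacency rule finds the two published tandem clusters", {
  tc <- find_tandem_clusters(vit_layout, vit_asg, max_intervening = 1)
  expect_equal(length(unique(tc$cluster)), 2)
  cl <- split(tc$gene_id, tc$cluster)
  expect_setequal(cl[[1]], c("VvALDH5F1", "VvALDH5F2", "VvALDH5F3"))
  expect_setequal(cl[[2]], c("VvALDH6B3", "VvALDH6B5"))
  expect_equal(tc$intervening_before[tc$gene_id == "VvALDH6B5"], 1)
})

test_that("two intervening loci break a cluster; missing genes error", {
  layout <- tibble::tibble(
    genome = "g", chromosome = "c1", rank = 1:5,
    locus_id = paste0("l", 1:5),
    gene_id = c("a1", NA, NA, "a2", NA))
  asg <- tibble::tibble(gene_id = c("a1", "a2"), family = "9")
  expect_equal(nrow(find_tandem_clusters(layout, asg, 1)), 0)
  expect_equal(length(unique(
    find_tandem_clusters(layout, asg, 2)$cluster)), 1)
  asg2 <- rbind(asg, tibble::tibble(gene_id = "ghost", family = "9"))
  expect_error(find_tandem_clusters(layout, asg2, 1), "ghost")
})

test_that("tandem clusters match the exhaustive scan on random layouts", {
  withr::with_seed(81, {
    for (i in 1:30) {
      n <- sample(6:12, 1)
      fams <- sample(1:3, n, replace = TRUE)
      is_gene <- runif(n) < 0.6
      layout <- tibble::tibble(
        genome = "g", chromosome = sample(c("c1", "c2"), n, TRUE),
        rank = NA_integer_, locus_id = paste0("l", 1:n),
        gene_id = ifelse(is_gene, paste0("g", 1:n), NA))
      layout <- layout |>
        dplyr::group_by(chromosome) |>
        dplyr::mutate(rank = dplyr::row_number()) |>
        dplyr::ungroup()
      asg <- tibble::tibble(gene_id = layout$gene_id[is_gene],
                            family = as.character(fams[is_gene]))
      k <- sample(0:2, 1)
      got <- find_tandem_clusters(layout, asg, k)
      want <- oracle_tandem(layout, asg, k)
      got_sets <- unname(lapply(split(got$gene_id, got$cluster), sort))
      want_sets <- unname(lapply(want, `[[`, "members"))
      expect_setequal(got_sets, want_sets)
    }
  })
})

test_that("raising max_intervening never splits or shrinks clusters", {
  for (k in 0:2) {
    lo <- find_tandem_clusters(vit_layout, vit_asg, k)
    hi <- find_tandem_clusters(vit_layout, vit_asg, k + 1)
    lo_sets <- lapply(split(lo$gene_id, lo$cluster), sort)
    hi_sets <- lapply(split(hi$gene_id, hi$cluster), sort)
    for (s in lo_sets)
      expect_true(any(vapply(hi_sets, function(h) all(s %in% h), TRUE)))
  }
})

test_that("the six published block pairs hold eleven family genes", {
  blocks <- load_synteny_blocks("within")
  expect_equal(nrow(blocks), 6)
  mem <- map_genes_to_blocks(vit_layout, blocks)
  inside <- unique(mem$gene_id[!is.na(mem$block_id)])
  expect_equal(length(inside), 11)
  expect_setequal(inside, c(
    "VvALDH2B4", "VvALDH2B9", "VvALDH2B8", "VvALDH3H1", "VvALDH3H5",
    "VvALDH7B5", "VvALDH7D1", "VvALDH10A9", "VvALDH10B1",
    "VvALDH18B1", "VvALDH18B3"))
  # five families, six block pairs, six anchor pairs
  sp <- syntenic_pairs(mem, vit_asg, "within")
  expect_equal(nrow(sp), 6)
  expect_equal(length(unique(sp$family)), 5)
  # genes outside every block are flagged unmapped
  expect_true("VvALDH12A1" %in% mem$gene_id[is.na(mem$block_id)])
  bad <- blocks; bad$end_a[1] <- bad$start_a[1] - 1
  expect_error(map_genes_to_blocks(vit_layout, bad), "malformed")
})

test_that("planted synthetic blocks give planted membership", {
  layout <- tibble::tibble(
    genome = "s", chromosome = "c1", rank = 1:8,
    locus_id = paste0("l", 1:8),
    gene_id = c("x1", NA, "x2", NA, "x3", NA, "x4", NA))
  blocks <- tibble::tibble(
    block_id = "p1", genome_a = "s", chr_a = "c1", start_a = 1,
    end_a = 3, genome_b = "s", chr_b = "c1", start_b = 5, end_b = 8,
    orientation = "same")
  attr(blocks, "dialect") <- "rank"
  mem <- map_genes_to_blocks(layout, blocks)
  expect_setequal(mem$gene_id[mem$side %in% "A"], c("x1", "x2"))
  expect_setequal(mem$gene_id[mem$side %in% "B"], c("x3", "x4"))
})

test_that("cross-genome pairs reproduce the ortholog table", {
  lay <- rbind(vit_layout, load_layout("arabidopsis"))
  asg <- aldh_family_from_name(lay$gene_id)
  mem <- map_genes_to_blocks(lay, load_synteny_blocks("cross"))
  sp <- syntenic_pairs(mem, asg, "cross")

  unamb <- sp[sp$status == "unambiguous", ]
  expect_equal(nrow(unamb), 6)
  expect_true(all(paste(unamb$gene_a, unamb$gene_b) %in% paste(
    c("VvALDH3H1", "VvALDH7D1", "VvALDH3F1", "VvALDH11B1", "VvALDH5F3",
      "VvALDH22A1"),
    c("AthALDH3H1", "AthALDH7B4", "AthALDH3F1", "AthALDH11A3",
      "AthALDH5F1", "AthALDH22A1"))))
  # duplicated families are flagged ambiguous
  expect_true(all(sp$status[sp$family %in% c("2", "18")] == "ambiguous"))
  # the family-6 gene sits in a block whose counterpart was lost
  lost <- sp[sp$status == "counterpart_lost", ]
  expect_equal(lost$gene_a, "VvALDH6B3")
  expect_true(is.na(lost$gene_b))
  # families 10 and 12 map to no cross block
  expect_false(any(sp$family %in% c("10", "12")))
})

test_that("swapping block sides transposes the pair table", {
  lay <- rbind(vit_layout, load_layout("arabidopsis"))
  asg <- aldh_family_from_name(lay$gene_id)
  blocks <- load_synteny_blocks("cross")
  swapped <- blocks
  names(swapped) <- sub("_a$", "_tmp", names(swapped))
  names(swapped) <- sub("_b$", "_a", names(swapped))
  names(swapped) <- sub("_tmp$", "_b", names(swapped))
  attr(swapped, "dialect") <- "rank"
  sp <- syntenic_pairs(map_genes_to_blocks(lay, blocks), asg, "cross")
  sp2 <- syntenic_pairs(map_genes_to_blocks(lay, swapped), asg, "cross")
  expect_setequal(paste(sp$gene_a, sp$gene_b, sp$status),
                  paste(sp2$gene_b, sp2$gene_a, sp2$status))
  expect_equal(nrow(syntenic_pairs(
    map_genes_to_blocks(lay, blocks[0, ]), asg, "cross")), 0)
})
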