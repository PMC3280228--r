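# small shared utilities for building test inputs

with_seed_protein <- function(L, seed) {
  withr::with_seed(seed, rand_protein(L))
}

hamming_identity <- function(a, b) {
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  stopifnot(length(ca) == length(cb))
  mean(ca == cb)
}

# a protein at an exact Hamming identity to `base`: flip the first k
# positions (after position 1) each to a fixed different residue
flip_to_identity <- function(base, identity) {
  chars <- strsplit(base, "")[[1]]
  k <- round((1 - identity) * length(chars))
  idx <- withr::with_seed(424242, sample(2:length(chars), k))
  aa <- c("A","R","N","D","C","Q","E","G","H","I",
          "L","K","M","F","P","S","T","W","Y","V")
  # derangement: each residue to the next in a fixed cycle, so flips stay
  # diverse and the gapless alignment remains optimal
  chars[idx] <- aa[(match(chars[idx], aa) %% 20) + 1]
  paste(chars, collapse = "")
}

# random CDS: ATG + (n_codons - 2) random non-stop codons + TAA
random_cds <- function(cds_len) {
  stopifnot(cds_len %% 3 == 0, cds_len >= 6)
  codons <- names(Biostrings::GENETIC_CODE)
  sense <- codons[!Biostrings::GENETIC_CODE %in% "*" &
                    codons != "ATG"]
  body <- sample(sense, cds_len / 3 - 2, replace = TRUE)
  paste0("ATG", paste(body, collapse = ""), "TAA")
}

blosum62 <- local({
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
})

random_cds_seeded <- function(L, seed) withr::with_seed(seed, random_cds(L))
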