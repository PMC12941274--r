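make_promoter_genome <- function() {
  # chr1: 6000 bp; gA on + at 3001..3300, gB on - at 5001..5300
  set.seed(99)
  seq <- random_dna_string(6000)
  c(chr1 = seq)
}

test_that("upstream extraction follows the strand-aware coordinate contract", {
  models <- tiny_models()
  genome <- make_promoter_genome()
  prom <- extract_upstream(models, genome, window = 2000)
  pa <- prom[prom$gene_id == "gA", ]
  expect_identical(c(pa$start, pa$end), c(1001L, 3000L))
  expect_identical(pa$length, 2000L)
  expect_false(pa$truncated)
  expect_identical(pa$sequence, substr(genome[["chr1"]], 1001, 3000))

  # minus strand: interval right of the gene end, reverse-complemented
  pb <- prom[prom$gene_id == "gB", ]
  expect_identical(c(pb$start, pb$end), c(5301L, 6000L))
  expect_identical(pb$length, 700L)
  expect_true(pb$truncated)
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(substr(genome[["chr1"]], 5301, 6000))
  ))
  expect_identical(pb$sequence, rc)
})

test_that("a start codon near the chromosome edge truncates, at the edge is empty", {
  genes <- data.frame(gene_id = "g", chrom = "c", start = 500L, end = 799L,
                      strand = "+", stringsAsFactors = FALSE)
  cds <- data.frame(gene_id = "g", transcript_id = "t", protein_id = "p",
                    start = 500L, end = 799L, stringsAsFactors = FALSE)
  models <- gene_models(genes, cds)
  genome <- c(c = random_dna_string(1000))
  prom <- extract_upstream(models, genome)
  expect_identical(c(prom$start, prom$end), c(1L, 499L))
  expect_identical(prom$length, 499L)
  expect_true(prom$truncated)

  genes$start <- 1L; genes$end <- 300L; cds$start <- 1L; cds$end <- 300L
  prom0 <- extract_upstream(gene_models(genes, cds), genome)
  expect_identical(prom0$length, 0L)
  expect_error(extract_upstream(models, genome, window = 0), "window")
})

test_that("degenerate consensus follows the single/two/three-base rules", {
  mk <- function(a, c, g, t) matrix(c(a, c, g, t), nrow = 4, byrow = TRUE,
                                    dimnames = list(c("A", "C", "G", "T"), NULL))
  expect_identical(pfm_to_degenerate_consensus(mk(97, 1, 1, 1)), "A")
  expect_identical(pfm_to_degenerate_consensus(mk(50, 0, 50, 0)), "R")
  expect_identical(pfm_to_degenerate_consensus(mk(2, 1, 1, 0)), "V")
  # a flat column with all four present falls through to N
  expect_identical(pfm_to_degenerate_consensus(mk(1, 1, 1, 1)), "N")
  expect_error(pfm_to_degenerate_consensus(mk(0, 0, 0, 0)), "all-zero")
})

test_that("consensus length equals matrix width for random PFMs", {
  set.seed(5)
  for (i in 1:25) {
    L <- sample(4:15, 1)
    counts <- matrix(rpois(4 * L, 10), nrow = 4,
                     dimnames = list(c("A", "C", "G", "T"), NULL))
    counts[1, colSums(counts) == 0] <- 1
    expect_identical(nchar(pfm_to_degenerate_consensus(counts)), L)
  }
})

test_that("IUPAC words compile to the printed character-class patterns", {
  expect_identical(iupac_to_pattern("RTAAACA")$pattern, "[AG]TAAACA")
  expect_identical(iupac_to_pattern("GTAAACAC")$pattern, "GTAAACAC")
  expect_identical(iupac_to_pattern("N")$pattern, "[ACGT]")
  expect_error(iupac_to_pattern("ACX"), "position 3")
  expect_error(iupac_to_pattern(""), "non-empty")
})

test_that("occurrence counting is greedy non-overlapping with an overlapping option", {
  expect_identical(count_occurrences("GGATTAGGATTA", "GGATTA"), 2L)
  expect_identical(count_occurrences("ATATA", "ATA"), 1L)
  expect_identical(count_occurrences("ATATA", "ATA", overlapping = TRUE), 2L)
  expect_identical(count_occurrences("ACG", "ACGTACGT"), 0L)
  # N in the sequence never matches
  expect_identical(count_occurrences("GGNTTA", "GGATTA"), 0L)
  expect_identical(count_occurrences("GGNTTA", "GGNTTA"), 0L)  # pattern N = [ACGT]
})

test_that("regex scanner agrees with the naive membership scanner", {
  set.seed(123)
  words <- c("GGATTA", "RTAAACA", "TTCYAGAA", "WTACGTG", "GAACRC", "N", "ATA")
  for (i in 1:300) {
    seqlen <- sample(50:400, 1)
    s <- random_dna_string(seqlen)
    w <- sample(words, 1)
    expect_identical(count_occurrences(s, w), naive_motif_count(s, w),
                     label = paste(w, "in", substr(s, 1, 20)))
    expect_identical(count_occurrences(s, w, overlapping = TRUE),
                     naive_motif_count(s, w, overlapping = TRUE))
  }
})

test_that("scan_all recovers planted counts exactly and ignores pattern order", {
  cfg <- list(n_chrom = 2L, genes_per_chrom = 4L)
  sim <- simulate_genome(cfg, seed = 17)
  genes <- sim$models$genes$gene_id[1:4]
  elements <- nematode_elements()[c(1, 3, 20), ]   # daf-16, fkh-2, ceh-36
  set.seed(4)
  instances <- do.call(rbind, lapply(genes, function(g) {
    data.frame(gene_id = g, motif_id = elements$element, iupac = elements$iupac,
               count = sample(0:4, nrow(elements), replace = TRUE),
               stringsAsFactors = FALSE)
  }))
  instances <- harmonize_motif_targets(instances)
  sim <- plant_promoter_motifs(sim, instances, seed = 8)
  prom <- extract_upstream(sim$models, sim$seqs)
  prom <- prom[prom$gene_id %in% genes, ]
  patterns <- lapply(seq_len(nrow(elements)), function(i) {
    iupac_to_pattern(elements$iupac[i], motif_id = elements$element[i])
  })
  counts <- scan_all(prom, patterns)
  led <- sim$ledger$planted_motif_counts
  for (r in seq_len(nrow(led))) {
    expect_identical(counts[led$gene_id[r], led$motif_id[r]],
                     led$count[r],
                     label = paste(led$gene_id[r], led$motif_id[r]))
  }
  # row sums invariant under pattern order
  counts_rev <- scan_all(prom, rev(patterns))
  expect_equal(rowSums(counts), rowSums(counts_rev))
  expect_identical(attr(counts, "has_any_element"),
                   attr(counts_rev, "has_any_element"))
})

test_that("the packaged element set has twenty named IUPAC words", {
  el <- nematode_elements()
  expect_identical(nrow(el), 20L)
  expect_true(all(c("daf-16", "fkh-2", "hsf-1", "ceh-36") %in% el$element))
  for (w in el$iupac) expect_s3_class(iupac_to_pattern(w), "motif_pattern")
})
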