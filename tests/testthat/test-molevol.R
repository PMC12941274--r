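test_that("site counting matches literal enumeration and the worked codons", {
  expect_equal(count_sites("TTT"), c(s = 1 / 3, n = 8 / 3))
  expect_equal(count_sites("ATG"), c(s = 0, n = 3))
  expect_gte(count_sites("GGG")[["s"]], 1)

  # independent enumeration oracle (seqinr genetic code) over all codons,
  # both stop conventions
  for (codon in oracle_sense_codons()) {
    expect_equal(unname(count_sites(codon)), oracle_count_sites(codon),
                 tolerance = 1e-12, label = codon)
    expect_equal(unname(count_sites(codon, stops_as_nonsyn = TRUE)),
                 oracle_count_sites(codon, stops_as_nonsyn = TRUE),
                 tolerance = 1e-12, label = paste(codon, "orig"))
  }
  expect_error(count_sites("TAA"), "stop")
  expect_error(count_sites("ANG"), "invalid")
})

test_that("site counts conserve s + n = 3 for every sense codon", {
  for (codon in zfam:::SENSE_CODONS) {
    expect_equal(sum(count_sites(codon)), 3, tolerance = 1e-12)
  }
})

test_that("pathway-averaged differences match the worked examples", {
  expect_equal(count_differences("TTT", "TTA"), c(sd = 0, nd = 1))
  expect_equal(count_differences("TTT", "GTA"), c(sd = 0.5, nd = 1.5))
  expect_equal(count_differences("AAA", "AAA"), c(sd = 0, nd = 0))
  expect_error(count_differences("TAA", "TTT"), "stop")
})

test_that("pathway averaging equals recursive enumeration on random codon pairs", {
  set.seed(42)
  sense <- oracle_sense_codons()
  for (rep in 1:150) {
    a <- sample(sense, 1)
    b <- sample(sense, 1)
    expect_equal(unname(count_differences(a, b)), oracle_count_differences(a, b),
                 tolerance = 1e-12, label = paste(a, b))
  }
})

test_that("difference counting is symmetric and sums to the Hamming distance", {
  set.seed(7)
  sense <- zfam:::SENSE_CODONS
  for (rep in 1:100) {
    a <- sample(sense, 1)
    b <- sample(sense, 1)
    d_ab <- count_differences(a, b)
    d_ba <- count_differences(b, a)
    expect_equal(d_ab, d_ba)
    hamming <- sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
    expect_equal(sum(d_ab), hamming, tolerance = 1e-12)
  }
})

test_that("Jukes-Cantor correction has the right closed form and inflation", {
  expect_equal(zfam:::jc_correct(0.5), -0.75 * log(1 / 3), tolerance = 1e-12)
  expect_equal(zfam:::jc_correct(0.5), 0.8239, tolerance = 1e-4)
  for (p in c(0.01, 0.1, 0.3, 0.5, 0.7)) {
    expect_gte(zfam:::jc_correct(p), p)
  }
  expect_true(is.na(zfam:::jc_correct(0.75)))
  expect_true(is.na(zfam:::jc_correct(0.9)))
  # small-p limit: d/p -> 1
  expect_equal(zfam:::jc_correct(1e-4) / 1e-4, 1, tolerance = 1e-3)
})

test_that("nei_gojobori composes counting, correction and omega correctly", {
  # identical sequences
  res <- nei_gojobori(codon_alignment("ATGAAA", "ATGAAA"))
  expect_equal(res$dN, 0)
  expect_equal(res$dS, 0)
  expect_true(is.na(res$omega))

  # one nonsynonymous change only: dS = 0 so omega undefined
  res <- nei_gojobori(codon_alignment("ATGAAATTT", "ATGAAATTA"))
  expect_equal(res$Nd, 1)
  expect_equal(res$Sd, 0)
  expect_equal(res$dS, 0)
  expect_true(is.na(res$omega))

  # symmetry in the pair order
  a <- "ATGGCTAGAAAGTTTGGG"
  b <- "ATGGCAAGAAAATTCGGA"
  r1 <- nei_gojobori(codon_alignment(a, b))
  r2 <- nei_gojobori(codon_alignment(b, a))
  for (col in c("S", "N", "Sd", "Nd", "pS", "pN", "dS", "dN", "omega")) {
    expect_identical(r1[[col]], r2[[col]])
  }
})

test_that("gap and stop columns are dropped pairwise", {
  aln <- codon_alignment(c("ATG", "---", "TTT", "TAA"), c("ATG", "AAA", "TTC", "AAA"))
  expect_identical(aln$L_used, 2L)
  expect_identical(aln$used, c(TRUE, FALSE, TRUE, FALSE))
})

test_that("back-translation maps residues to codons and validates translation", {
  aln <- backtranslate("M-K", "MLK", "ATGAAA", "ATGCTGAAG")
  expect_identical(aln$codons_a, c("ATG", "---", "AAA"))
  expect_identical(aln$codons_b, c("ATG", "CTG", "AAG"))
  expect_identical(aln$L_used, 2L)

  # identical peptides give identical codon columns
  aln2 <- backtranslate("MK", "MK", "ATGAAA", "ATGAAA")
  expect_identical(aln2$codons_a, aln2$codons_b)

  expect_error(backtranslate("MK", "MK", "ATGTAAAAA", "ATGAAA"), "stop")
  expect_error(backtranslate("MK", "MK", "ATGGGG", "ATGAAA"), "mismatch")
  expect_error(backtranslate("MKR", "MKR", "ATGAAA", "ATGAAACGA"), "inconsistent")
})

test_that("bootstrap is deterministic under a fixed seed and zero for identical pairs", {
  pair <- simulate_codon_pair(60, 25, omega = 0.5, seed = 11)
  aln <- codon_alignment(pair$cds_a, pair$cds_b)
  b1 <- bootstrap_kaks(aln, reps = 200, seed = 5)
  b2 <- bootstrap_kaks(aln, reps = 200, seed = 5)
  expect_identical(b1, b2)
  b3 <- bootstrap_kaks(aln, reps = 200, seed = 6)
  expect_false(identical(b1$se_dN, b3$se_dN))

  same <- codon_alignment("ATGAAATTTGGG", "ATGAAATTTGGG")
  b0 <- bootstrap_kaks(same, reps = 50, seed = 1)
  expect_equal(b0$se_dN, 0)
  expect_equal(b0$se_dS, 0)
})

test_that("bootstrap SE shrinks with alignment length", {
  ses <- vapply(c(100L, 400L), function(L) {
    pair <- simulate_codon_pair(L, as.integer(L * 0.3), omega = 0.5, seed = 21)
    aln <- codon_alignment(pair$cds_a, pair$cds_b)
    bootstrap_kaks(aln, reps = 150, seed = 3)$se_dN
  }, numeric(1))
  expect_lt(ses[2], ses[1])
})

test_that("batch Ka/Ks summarises omega fractions over defined pairs", {
  pairs <- list(
    codon_alignment("ATGAAATTT", "ATGAAATTT", pair_id = "ident"),
    {
      p <- simulate_codon_pair(200, 60, omega = 0.2, seed = 31)
      codon_alignment(p$cds_a, p$cds_b, pair_id = "purifying")
    }
  )
  res <- batch_kaks(pairs, labels = c("paralogous", "paralogous"))
  expect_identical(nrow(res$table), 2L)
  expect_true(is.na(res$table$omega[res$table$pair_id == "ident"]))
  expect_identical(res$summary$n_defined, 1L)
  expect_error(batch_kaks(list()), "empty")
})

test_that("planted omega below one is recovered as omega-hat below one", {
  vals <- vapply(1:6, function(i) {
    p <- simulate_codon_pair(300, 90, omega = 0.2, seed = 100 + i)
    nei_gojobori(codon_alignment(p$cds_a, p$cds_b))$omega
  }, numeric(1))
  expect_true(all(vals < 1))
})
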