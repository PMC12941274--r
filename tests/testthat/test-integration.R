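test_that("the DE filter applies strict thresholds and directions", {
  tab <- data.frame(
    gene_id = c("up", "weak", "insig", "down", "edge"),
    log2fc = c(2, 0.9, 3, -2.5, 1),
    p = c(0.001, 0.001, 0.2, 0.01, 0.001), stringsAsFactors = FALSE
  )
  out <- filter_de(tab)
  expect_identical(out$significant, c(TRUE, FALSE, FALSE, TRUE, FALSE))
  expect_identical(out$direction, c("up", "ns", "ns", "down", "ns"))
  expect_error(filter_de(transform(tab, p = c(0, 0.5, 0.5, 0.5, 0.5))), "0, 1")
})

test_that("group DE summaries flag monotone directions and NA for empty groups", {
  de <- filter_de(data.frame(
    gene_id = paste0("g", 1:6),
    log2fc = c(-2, -3, -2.2, 2, -2, 0.1),
    p = c(0.01, 0.01, 0.01, 0.01, 0.01, 0.9), stringsAsFactors = FALSE
  ))
  groups <- data.frame(
    leaf = paste0("g", 1:6),
    group = c("G5", "G5", "G5", "G2", "G2", "G3"), stringsAsFactors = FALSE
  )
  summ <- group_de_summary(de, groups)
  g5 <- summ[summ$group == "G5", ]
  expect_true(g5$monotone)
  expect_identical(g5$direction, "down")
  g2 <- summ[summ$group == "G2", ]
  expect_false(g2$monotone)
  g3 <- summ[summ$group == "G3", ]
  expect_true(is.na(g3$monotone))
})

test_that("the upregulated cis-element fraction behaves and validates", {
  de <- filter_de(data.frame(
    gene_id = c("u1", "u2", "d1"), log2fc = c(2, 3, -2), p = 0.01,
    stringsAsFactors = FALSE
  ))
  mat <- matrix(c(1L, 1L, 0L, 0L, 2L, 5L), nrow = 3,
                dimnames = list(c("u1", "u2", "d1"), c("m1", "m2")))
  expect_equal(upregulated_cis_check(de, mat), 1)
  # column order never matters
  expect_equal(upregulated_cis_check(de, mat[, c(2, 1)]), 1)
  mat["u2", ] <- 0L
  expect_equal(upregulated_cis_check(de, mat), 0.5)
  no_up <- filter_de(data.frame(gene_id = "d1", log2fc = -2, p = 0.01))
  expect_error(upregulated_cis_check(no_up, mat), "no upregulated")
})

test_that("localisation reconciliation prefers the primary predictor and flags conflicts", {
  res <- reconcile_localisation("p1", "nucleus", "mitochondrial transfer peptide")
  expect_identical(res$final, "nucleus")
  expect_true(res$conflict)
  res2 <- reconcile_localisation("p2", "nucleus", "nucleus")
  expect_false(res2$conflict)
  res3 <- reconcile_localisation("p3", "cytoplasm", NA)
  expect_identical(res3$final, "cytoplasm")
  expect_false(res3$conflict)
  expect_error(reconcile_localisation("p4", NA, "nucleus"), "missing primary")
})

test_that("the chromosome table lists each family gene once, ordered, with classes", {
  sim <- simulate_genome(list(n_chrom = 2L, genes_per_chrom = 8L), seed = 19)
  sim <- plant_family(sim, 4, c("tandem", "proximal", "dispersed"), seed = 2)
  fam <- sim$ledger$planted_families[[1]]
  calls <- classify_duplicates(sim$hits, gene_rank_index(sim$models))
  tab <- chromosome_table(fam, sim$models, calls)
  expect_identical(sort(tab$gene_id), sort(fam))
  expect_identical(anyDuplicated(tab$gene_id), 0L)
  for (ch in unique(tab$chrom)) {
    expect_true(all(diff(tab$start[tab$chrom == ch]) > 0))
  }
  expect_identical(
    tab$class,
    calls$class[match(tab$gene_id, calls$gene_id)]
  )
  expect_error(chromosome_table(c(fam, "ghost"), sim$models, calls), "absent")
})

test_that("a reduced end-to-end run is deterministic and internally consistent", {
  cfg <- list(n_chrom = 3L, genes_per_chrom = 10L, gene_len_bp = 150L)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  r1 <- run_pipeline(d1, seed = 5, config = cfg, n_families = 2L,
                     kaks_bootstrap = 50L)
  r2 <- run_pipeline(d2, seed = 5, config = cfg, n_families = 2L,
                     kaks_bootstrap = 50L)
  expect_identical(r1$manifest$md5, r2$manifest$md5)

  # ledger closure on the reduced run
  led <- r1$sim$ledger
  truth <- ledger_duplication_classes(r1$sim)
  expect_identical(unname(truth[r1$duplication$gene_id]), r1$duplication$class)
  for (r in seq_len(nrow(led$planted_motif_counts))) {
    row <- led$planted_motif_counts[r, ]
    expect_identical(r1$element_counts[row$gene_id, row$motif_id], row$count)
  }
  sig_truth <- sort(names(led$planted_de)[led$planted_de != "ns"])
  expect_identical(sort(r1$de$gene_id[r1$de$significant]), sig_truth)
  ages <- stats::setNames(r1$ages$stratum, r1$ages$gene_id)
  expect_identical(ages[names(led$planted_strata)], led$planted_strata)

  # every stage's table landed in the report directory
  expect_true(all(file.exists(file.path(d1, c(
    "family.tsv", "element_counts.tsv", "duplication_calls.tsv",
    "tandem_enrichment.tsv", "kaks.tsv", "gene_ages.tsv",
    "protein_properties.tsv", "groups.tsv", "de_filtered.tsv",
    "chromosome_table.tsv", "manifest.tsv"
  )))))
})
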