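small_cfg <- list(n_chrom = 2L, genes_per_chrom = 5L, gene_len_bp = 120L,
                  intergenic_bp = 4200L, gc_fraction = 0.45)

test_that("genome simulation is deterministic and validates its config", {
  s1 <- simulate_genome(small_cfg, seed = 7)
  s2 <- simulate_genome(small_cfg, seed = 7)
  expect_identical(s1$seqs, s2$seqs)
  expect_identical(s1$models, s2$models)
  s3 <- simulate_genome(small_cfg, seed = 8)
  expect_false(identical(s1$seqs, s3$seqs))

  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  p1 <- write_sim(s1, d1); p2 <- write_sim(s2, d2)
  expect_identical(readLines(p1["genome"]), readLines(p2["genome"]))
  expect_identical(readLines(p1["gff"]), readLines(p2["gff"]))

  expect_error(simulate_genome(utils::modifyList(small_cfg, list(genes_per_chrom = 0L))),
               ">= 1")
  expect_error(simulate_genome(utils::modifyList(small_cfg, list(gc_fraction = 1))),
               "gc_fraction")
  expect_error(simulate_genome(utils::modifyList(small_cfg, list(chrom_len_bp = 100L))),
               "too short")
})

test_that("every emitted CDS starts with ATG, ends with a stop, has no internal stop", {
  sim <- simulate_genome(small_cfg, seed = 3)
  for (g in sim$models$genes$gene_id) {
    cds <- cds_sequence(sim, g)
    expect_identical(substr(cds, 1, 3), "ATG")
    last <- substr(cds, nchar(cds) - 2, nchar(cds))
    expect_true(last %in% c("TAA", "TAG", "TGA"))
    expect_silent(translate_cds(cds))  # errors on internal stops
  }
})

test_that("planted family layouts produce the promised rank geometry", {
  sim <- simulate_genome(small_cfg, seed = 5)
  sim <- plant_family(sim, 2, "tandem", mutation_rate = 0, seed = 2)
  fam <- sim$ledger$planted_families[[1]]
  idx <- gene_rank_index(sim$models)
  ranks <- idx$rank[match(fam, idx$gene_id)]
  chroms <- idx$chrom[match(fam, idx$gene_id)]
  expect_identical(length(unique(chroms)), 1L)
  expect_identical(abs(diff(ranks)), 1L)
  expect_true(all(sim$ledger$planted_duplication[fam] == "tandem"))

  # no-mutation copies are byte-identical to the founder CDS
  expect_identical(cds_sequence(sim, fam[1]), cds_sequence(sim, fam[2]))

  one_chrom <- simulate_genome(utils::modifyList(small_cfg, list(n_chrom = 1L)), seed = 5)
  expect_error(plant_family(one_chrom, 2, "dispersed", seed = 2), "single chromosome")
  expect_error(plant_family(sim, 3, "tandem", seed = 2), "layout length")
  expect_error(plant_family(sim, 2, "tandem", mutation_rate = 0.5, seed = 2), "mutation_rate")
})

test_that("the emitted hit table connects exactly the family plus self-hits", {
  sim <- simulate_genome(small_cfg, seed = 9)
  sim <- plant_family(sim, 3, c("tandem", "dispersed"), mutation_rate = 0.01, seed = 4)
  fam <- sim$ledger$planted_families[[1]]
  expect_identical(nrow(sim$hits), as.integer(length(fam)^2))
  expect_setequal(unique(sim$hits$query_id), fam)
  expect_identical(sum(sim$hits$self_hit), as.integer(length(fam)))
  expect_true(all(sim$hits$e_value < 1e-5))
})

test_that("motif planting updates only the requested windows and bookkeeping", {
  sim <- simulate_genome(small_cfg, seed = 11)
  g <- sim$models$genes$gene_id[2]   # a minus-strand gene
  before <- sim$seqs
  ins0 <- data.frame(gene_id = g, motif_id = "ceh-36", iupac = "GGATTA",
                     count = 0L, stringsAsFactors = FALSE)
  sim0 <- plant_promoter_motifs(sim, ins0, seed = 1)
  # planting zero occurrences still normalizes the window; ledger says 0
  expect_identical(sim0$ledger$planted_motif_counts$count, 0L)

  ins2 <- data.frame(gene_id = g, motif_id = "ceh-36", iupac = "GGATTA",
                     count = 2L, stringsAsFactors = FALSE)
  sim2 <- plant_promoter_motifs(sim, ins2, seed = 1)
  prom <- extract_upstream(sim2$models, sim2$seqs)
  expect_identical(naive_motif_count(prom$sequence[prom$gene_id == g], "GGATTA"), 2L)
  # untouched chromosome stays untouched
  expect_identical(sim2$seqs[["chr2"]], before[["chr2"]])

  # degenerate positions realize to members of the IUPAC class
  insr <- data.frame(gene_id = g, motif_id = "fkh-2", iupac = "RTAAACA",
                     count = 1L, stringsAsFactors = FALSE)
  simr <- plant_promoter_motifs(sim, insr, seed = 2)
  promr <- extract_upstream(simr$models, simr$seqs)
  expect_identical(naive_motif_count(promr$sequence[promr$gene_id == g], "RTAAACA"), 1L)

  # an impossible request errors
  big <- data.frame(gene_id = g, motif_id = "x", iupac = strrep("A", 600),
                    count = 4L, stringsAsFactors = FALSE)
  expect_error(plant_promoter_motifs(sim, big, seed = 1), "fit|not placeable|attempts")
})

test_that("codon-pair simulation honours limits, determinism and omega=0", {
  p0 <- simulate_codon_pair(40, 0, omega = 0.5, seed = 1)
  expect_identical(p0$cds_a, p0$cds_b)

  p1 <- simulate_codon_pair(50, 30, omega = 0, seed = 2)
  # omega = 0: every accepted event is synonymous
  expect_identical(p1$truth$n_nonsyn_events, 0L)
  expect_identical(translate_cds(paste0(p1$cds_a, "TAA")),
                   translate_cds(paste0(p1$cds_b, "TAA")))

  pa <- simulate_codon_pair(30, 10, omega = 0.5, seed = 3)
  pb <- simulate_codon_pair(30, 10, omega = 0.5, seed = 3)
  expect_identical(pa, pb)
  expect_error(simulate_codon_pair(0, 5, 1), "n_codons")
})

test_that("homolog evidence respects planted strata and the reciprocal rule", {
  ladder <- lineage_ladder(
    DEFAULT_LADDER,
    c(bac1 = "Cellular organisms", yeast = "Eukaryota",
      worm = "Metazoa", tardi = "Tardigrada-specific")
  )
  strata <- c(gA = "Metazoa", gB = "Tardigrada-specific", gC = "Cellular organisms")
  ev <- simulate_homolog_evidence(strata, ladder, seed = 6)
  ev2 <- simulate_homolog_evidence(strata, ladder, seed = 6)
  expect_identical(ev, ev2)

  # Metazoa-planted gene: no bacterial species passes the reciprocal rule
  bacterial <- ev[ev$gene_id == "gA" & ev$species_id == "bac1", ]
  expect_false(call_homolog(bacterial$e_forward, bacterial$e_reverse))
  # species-specific gene: only the youngest-stratum species passes
  gb <- ev[ev$gene_id == "gB", ]
  pass <- gb$species_id[call_homolog(gb$e_forward, gb$e_reverse)]
  expect_identical(pass, "tardi")
  # oldest-planted gene: everything passes
  gc_ <- ev[ev$gene_id == "gC", ]
  expect_true(all(call_homolog(gc_$e_forward, gc_$e_reverse)))
})

test_that("DE simulation plants exactly the significant set the filter recovers", {
  genes <- paste0("g", 1:60)
  de <- simulate_de_table(genes, frac_signif = 0.3, seed = 13)
  filtered <- filter_de(de$table)
  expect_identical(sort(filtered$gene_id[filtered$significant]),
                   sort(names(de$planted)[de$planted != "ns"]))
  downs <- names(de$planted)[de$planted == "down"]
  expect_true(all(filtered$log2fc[match(downs, filtered$gene_id)] < 0))

  none <- simulate_de_table(genes, frac_signif = 0, seed = 13)
  f0 <- filter_de(none$table)
  expect_identical(sum(f0$significant), 0L)
})

test_that("ledger round-trips through its JSON text form", {
  sim <- simulate_genome(small_cfg, seed = 21)
  sim <- plant_family(sim, 3, c("tandem", "dispersed"), seed = 1)
  f <- withr::local_tempfile(fileext = ".json")
  write_ledger(sim$ledger, f)
  led <- read_ledger(f)
  expect_identical(led$seed, sim$ledger$seed)
  expect_identical(sort(unlist(led$planted_families)),
                   sort(unlist(sim$ledger$planted_families)))
  expect_identical(led$planted_duplication[sort(names(led$planted_duplication))],
                   sim$ledger$planted_duplication[sort(names(sim$ledger$planted_duplication))])
})
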