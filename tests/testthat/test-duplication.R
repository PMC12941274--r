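toy_index <- function() {
  genes <- data.frame(
    gene_id = c(paste0("a", 1:12), paste0("b", 1:3)),
    chrom = c(rep("chr1", 12), rep("chr2", 3)),
    start = c(seq(1000, by = 1000, length.out = 12),
              seq(1000, by = 1000, length.out = 3)),
    stringsAsFactors = FALSE
  )
  gene_rank_index(genes)
}

hit_rows <- function(pairs) {
  do.call(rbind, lapply(pairs, function(pr) {
    data.frame(query_id = pr[1], subject_id = pr[2], percent_identity = 99,
               alignment_length = 100, mismatches = 1, gap_opens = 0,
               q_start = 1, q_end = 100, s_start = 1, s_end = 100,
               e_value = 1e-20, bit_score = 200, stringsAsFactors = FALSE)
  }))
}

test_that("rank index gives consecutive per-chromosome ranks regardless of row order", {
  genes <- data.frame(
    gene_id = c("x3", "x1", "x2"), chrom = "c",
    start = c(300, 100, 200), stringsAsFactors = FALSE
  )
  idx <- gene_rank_index(genes)
  expect_identical(idx$gene_id, c("x1", "x2", "x3"))
  expect_identical(idx$rank, c(1L, 2L, 3L))
  shuffled <- gene_rank_index(genes[c(2, 3, 1), ])
  expect_identical(idx, shuffled)
})

test_that("the four classes follow the rank-distance rules", {
  idx <- toy_index()
  hits <- hit_rows(list(c("a1", "a2"),      # adjacent: tandem
                        c("a4", "a7"),      # distance 3: proximal
                        c("a9", "b1")))     # cross-chromosome: dispersed
  calls <- classify_duplicates(hits, idx)
  cls <- stats::setNames(calls$class, calls$gene_id)
  expect_identical(unname(cls[c("a1", "a2")]), c("tandem", "tandem"))
  expect_identical(unname(cls[c("a4", "a7")]), c("proximal", "proximal"))
  expect_identical(unname(cls[c("a9", "b1")]), c("dispersed", "dispersed"))
  expect_identical(unname(cls["a3"]), "singleton")
  # witnesses only for non-singletons
  expect_true(is.na(calls$witness[calls$gene_id == "a3"]))
  expect_identical(calls$witness[calls$gene_id == "a1"], "a2")
})

test_that("proximal_max_rank bounds the proximal call", {
  idx <- toy_index()
  hits <- hit_rows(list(c("a1", "a12")))   # distance 11 on one chromosome
  calls <- classify_duplicates(hits, idx)
  expect_identical(calls$class[calls$gene_id == "a1"], "dispersed")
  calls2 <- classify_duplicates(hits, idx, proximal_max_rank = 11)
  expect_identical(calls2$class[calls2$gene_id == "a1"], "proximal")
})

test_that("tandem outranks proximal which outranks dispersed", {
  idx <- toy_index()
  # a4 has a proximal partner (a7) and a cross-chromosome partner
  base <- hit_rows(list(c("a4", "a7"), c("a4", "b2")))
  expect_identical(
    classify_duplicates(base, idx)$class[idx$gene_id == "a4"], "proximal"
  )
  # adding an adjacent homolog promotes to tandem, never the reverse
  promoted <- rbind(base, hit_rows(list(c("a4", "a5"))))
  expect_identical(
    classify_duplicates(promoted, idx)$class[idx$gene_id == "a4"], "tandem"
  )
})

test_that("classification is invariant to row permutation and query/subject swap", {
  idx <- toy_index()
  hits <- hit_rows(list(c("a1", "a2"), c("a4", "a7"), c("a9", "b1"), c("b1", "b3")))
  base <- classify_duplicates(hits, idx)
  swapped <- hits
  swapped[, c("query_id", "subject_id")] <- swapped[, c("subject_id", "query_id")]
  expect_identical(classify_duplicates(swapped, idx), base)
  expect_identical(classify_duplicates(hits[sample(nrow(hits)), ], idx), base)
})

test_that("self-hits and weak hits are ignored; unknown genes are an error", {
  idx <- toy_index()
  hits <- rbind(hit_rows(list(c("a1", "a1"))),             # self-hit
                within(hit_rows(list(c("a1", "a2"))), e_value <- 1e-3))
  calls <- classify_duplicates(hits, idx)
  expect_true(all(calls$class == "singleton"))
  expect_error(classify_duplicates(hit_rows(list(c("a1", "ghost"))), idx),
               "absent from rank index")
})

test_that("summary counts sum to the subset size and fractions to one", {
  idx <- toy_index()
  hits <- hit_rows(list(c("a1", "a2"), c("a9", "b1")))
  calls <- classify_duplicates(hits, idx)
  summ <- duplication_summary(calls)
  expect_identical(sum(summ$n), nrow(idx))
  expect_equal(sum(summ$fraction), 1)
  sub <- duplication_summary(calls, subset = c("a1", "a2", "a3"))
  expect_identical(sum(sub$n), 3L)
  expect_error(duplication_summary(calls, subset = character(0)), "empty")
})

test_that("planted duplication structure is recovered exactly at zero mutation", {
  sim <- simulate_genome(list(n_chrom = 3L, genes_per_chrom = 14L), seed = 31)
  sim <- plant_family(sim, 5, c("tandem", "tandem", "proximal", "dispersed"),
                      mutation_rate = 0, seed = 1, family_id = "famA")
  sim <- plant_family(sim, 3, c("proximal", "dispersed"),
                      mutation_rate = 0, seed = 2, family_id = "famB")
  idx <- gene_rank_index(sim$models)
  calls <- classify_duplicates(sim$hits, idx)
  truth <- ledger_duplication_classes(sim)
  expect_identical(unname(truth[calls$gene_id]), calls$class)
})
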