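# Independent oracles used across the suite. Each deliberately takes a
# different computational route than the implementation it checks.

# seqinr's genetic code (independent of the Biostrings table the package
# uses), tabulated once for all 64 codons.
ORACLE_CODE <- local({
  bases <- c("A", "C", "G", "T")
  all64 <- as.vector(outer(outer(bases, bases, paste0), bases, paste0))
  stats::setNames(
    vapply(all64, function(cd) seqinr::translate(strsplit(cd, "")[[1]]), character(1)),
    all64
  )
})

oracle_translate <- function(codon) unname(ORACLE_CODE[codon])

oracle_sense_codons <- function() names(ORACLE_CODE)[ORACLE_CODE != "*"]

# NG86 site counts by literal enumeration of the 9 single-base changes.
oracle_count_sites <- function(codon, stops_as_nonsyn = FALSE) {
  bases <- c("A", "C", "G", "T")
  aa <- oracle_translate(codon)
  s <- 0
  for (pos in 1:3) {
    syn <- 0
    nonstop <- 0
    for (b in setdiff(bases, substr(codon, pos, pos))) {
      mut <- codon
      substr(mut, pos, pos) <- b
      if (oracle_translate(mut) == "*") {
        if (stops_as_nonsyn) nonstop <- nonstop + 1
        next
      }
      nonstop <- nonstop + 1
      if (oracle_translate(mut) == aa) syn <- syn + 1
    }
    s <- s + syn / (if (stops_as_nonsyn) 3 else nonstop)
  }
  c(s, 3 - s)
}

# Literal d! pathway enumeration via recursion (not the permutation list
# used in the implementation).
oracle_count_differences <- function(a, b) {
  walk <- function(cur, remaining) {
    if (length(remaining) == 0L) {
      return(list(list(sd = 0, nd = 0, stop = FALSE)))
    }
    out <- list()
    for (i in seq_along(remaining)) {
      pos <- remaining[i]
      nxt <- cur
      substr(nxt, pos, pos) <- substr(b, pos, pos)
      step_stop <- oracle_translate(nxt) == "*" || oracle_translate(cur) == "*"
      step_syn <- !step_stop && oracle_translate(nxt) == oracle_translate(cur)
      rest <- walk(nxt, remaining[-i])
      for (r in rest) {
        out[[length(out) + 1L]] <- list(
          sd = r$sd + as.numeric(step_syn),
          nd = r$nd + as.numeric(!step_syn && !step_stop) + as.numeric(step_stop),
          stop = r$stop || step_stop
        )
      }
    }
    out
  }
  diff_pos <- which(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  if (length(diff_pos) == 0L) return(c(0, 0))
  paths <- walk(a, diff_pos)
  keep <- Filter(function(p) !p$stop, paths)
  if (length(keep) == 0L) keep <- paths
  c(mean(vapply(keep, `[[`, numeric(1), "sd")),
    mean(vapply(keep, `[[`, numeric(1), "nd")))
}

# Hypergeometric tails by exhaustive subset enumeration (N <= 12).
oracle_hyper_tails <- function(N, K, n, k) {
  pop <- c(rep(1, K), rep(0, N - K))
  subsets <- utils::combn(N, n)
  draws <- apply(subsets, 2, function(idx) sum(pop[idx]))
  c(upper = mean(draws >= k), lower = mean(draws <= k))
}

# BH step-up by the explicit formula.
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  q <- numeric(m)
  sorted <- p[ord]
  for (i in seq_len(m)) {
    q[i] <- min(pmin(1, m * sorted[i:m] / (i:m)))
  }
  out <- numeric(m)
  out[ord] <- q
  out
}

random_dna_string <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# A tiny two-gene genome fixture built in code (plus- and minus-strand
# genes with known coordinates), used by I/O and promoter tests.
tiny_models <- function() {
  genes <- data.frame(
    gene_id = c("gA", "gB"), chrom = c("chr1", "chr1"),
    start = c(3001L, 5001L), end = c(3300L, 5300L), strand = c("+", "-"),
    stringsAsFactors = FALSE
  )
  cds <- data.frame(
    gene_id = c("gA", "gB"), transcript_id = c("gA.t1", "gB.t1"),
    protein_id = c("gA.p1", "gB.p1"), start = c(3001L, 5001L),
    end = c(3300L, 5300L), stringsAsFactors = FALSE
  )
  gene_models(genes, cds)
}
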