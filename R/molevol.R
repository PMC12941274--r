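# Nei-Gojobori (1986) Ka/Ks with Jukes-Cantor multiple-hit correction:
# synonymous/nonsynonymous site counting, substitution-pathway averaging of
# differences, codon bootstrap, and protein-guided codon back-translation.

GENETIC_CODE_TABLE <- Biostrings::GENETIC_CODE
STOP_CODONS <- names(GENETIC_CODE_TABLE)[GENETIC_CODE_TABLE == "*"]
SENSE_CODONS <- names(GENETIC_CODE_TABLE)[GENETIC_CODE_TABLE != "*"]
DNA_BASES <- c("A", "C", "G", "T")

translate_codon <- function(codon) {
  aa <- GENETIC_CODE_TABLE[codon]
  if (is.na(aa)) stop("not a valid codon: ", codon)
  unname(aa)
}

#' Translate a coding sequence with the standard genetic code
#'
#' @param cds A/C/G/T string whose length is a multiple of 3.
#' @param allow_terminal_stop Tolerate (and drop) a final stop codon.
#' @return Peptide string.
#' @export
translate_cds <- function(cds, allow_terminal_stop = TRUE) {
  if (nchar(cds) %% 3 != 0) stop("CDS length not a multiple of 3")
  codons <- substring(cds, seq(1, nchar(cds), 3), seq(3, nchar(cds), 3))
  aa <- GENETIC_CODE_TABLE[codons]
  if (anyNA(aa)) stop("invalid codon(s) in CDS")
  aa <- unname(aa)
  n <- length(aa)
  if (allow_terminal_stop && n > 0 && aa[n] == "*") aa <- aa[-n]
  if (any(aa == "*")) stop("internal stop codon at codon ", which(aa == "*")[1])
  paste(aa, collapse = "")
}

#' Synonymous and nonsynonymous site counts of one codon
#'
#' Per codon position, the synonymous fraction is the number of single-base
#' changes preserving the amino acid divided by the number of changes not
#' creating a stop codon; site counts are the sums over the three positions,
#' so s + n = 3 for every stop-free codon. With
#' `stops_as_nonsyn = TRUE` the original convention is used instead: changes
#' to stop codons count as nonsynonymous and every position denominator is 3.
#'
#' @param codon A stop-free A/C/G/T triplet.
#' @param stops_as_nonsyn Count stop-creating changes as nonsynonymous.
#' @return Named numeric vector `c(s = ..., n = ...)`.
#' @export
count_sites <- function(codon, stops_as_nonsyn = FALSE) {
  if (!codon %in% SENSE_CODONS) {
    if (codon %in% STOP_CODONS) stop("stop codon has no site counts: ", codon)
    stop("codon contains invalid/ambiguous bases: ", codon)
  }
  aa <- translate_codon(codon)
  bases <- strsplit(codon, "")[[1]]
  s <- 0
  for (pos in 1:3) {
    syn <- 0L
    valid <- 0L
    for (b in setdiff(DNA_BASES, bases[pos])) {
      mut <- bases
      mut[pos] <- b
      mut_codon <- paste(mut, collapse = "")
      if (mut_codon %in% STOP_CODONS) {
        if (stops_as_nonsyn) valid <- valid + 1L
        next
      }
      valid <- valid + 1L
      if (translate_codon(mut_codon) == aa) syn <- syn + 1L
    }
    denom <- if (stops_as_nonsyn) 3L else valid
    s <- s + syn / denom
  }
  c(s = s, n = 3 - s)
}

perms_of <- function(d) {
  switch(d,
    list(1L),
    list(c(1L, 2L), c(2L, 1L)),
    list(c(1L, 2L, 3L), c(1L, 3L, 2L), c(2L, 1L, 3L),
         c(2L, 3L, 1L), c(3L, 1L, 2L), c(3L, 2L, 1L))
  )
}

#' Pathway-averaged synonymous/nonsynonymous differences between two codons
#'
#' For codons differing at d positions, every order of the d single-base
#' steps is enumerated; pathways passing through a stop codon are excluded
#' (unless all do, in which case all are kept), and the synonymous /
#' nonsynonymous step counts are averaged over the retained pathways.
#' sd + nd equals d.
#'
#' @param codon_a,codon_b Stop-free A/C/G/T triplets.
#' @param stops_as_nonsyn Keep stop-traversing pathways and count every step
#'   by amino-acid identity (stop treated as a distinct residue).
#' @return Named numeric vector `c(sd = ..., nd = ...)`.
#' @export
count_differences <- function(codon_a, codon_b, stops_as_nonsyn = FALSE) {
  for (cd in c(codon_a, codon_b)) {
    if (!cd %in% SENSE_CODONS) stop("stop or invalid codon: ", cd)
  }
  a <- strsplit(codon_a, "")[[1]]
  b <- strsplit(codon_b, "")[[1]]
  diff_pos <- which(a != b)
  d <- length(diff_pos)
  if (d == 0L) return(c(sd = 0, nd = 0))
  paths <- list()
  for (perm in perms_of(d)) {
    cur <- a
    sd <- 0
    nd <- 0
    through_stop <- FALSE
    for (p in diff_pos[perm]) {
      nxt <- cur
      nxt[p] <- b[p]
      cur_codon <- paste(cur, collapse = "")
      nxt_codon <- paste(nxt, collapse = "")
      step_stop <- nxt_codon %in% STOP_CODONS || cur_codon %in% STOP_CODONS
      if (step_stop) through_stop <- TRUE
      aa_cur <- GENETIC_CODE_TABLE[[cur_codon]]
      aa_nxt <- GENETIC_CODE_TABLE[[nxt_codon]]
      # a step touching a stop codon is never synonymous
      if (!step_stop && aa_cur == aa_nxt) sd <- sd + 1 else nd <- nd + 1
      cur <- nxt
    }
    paths[[length(paths) + 1L]] <- c(sd, nd, through_stop)
  }
  m <- do.call(rbind, paths)
  keep <- if (stops_as_nonsyn) rep(TRUE, nrow(m)) else m[, 3] == 0
  if (!any(keep)) keep <- rep(TRUE, nrow(m))  # all pathways hit stops: fallback
  c(sd = mean(m[keep, 1]), nd = mean(m[keep, 2]))
}

# Per-codon site counts and per-pair difference counts are pure lookups;
# memoize them once per convention so long alignments and bootstraps reduce
# to table indexing.
.molevol_cache <- new.env(parent = emptyenv())

site_table <- function(stops_as_nonsyn = FALSE) {
  key <- paste0("sites_", stops_as_nonsyn)
  if (is.null(.molevol_cache[[key]])) {
    tab <- vapply(SENSE_CODONS, count_sites, numeric(2),
                  stops_as_nonsyn = stops_as_nonsyn)
    rownames(tab) <- c("s", "n")
    .molevol_cache[[key]] <- tab
  }
  .molevol_cache[[key]]
}

diff_lookup <- function(codons_a, codons_b, stops_as_nonsyn = FALSE) {
  key <- paste0("diffs_", stops_as_nonsyn)
  if (is.null(.molevol_cache[[key]])) {
    .molevol_cache[[key]] <- new.env(parent = emptyenv())
  }
  env <- .molevol_cache[[key]]
  out <- matrix(0, nrow = 2L, ncol = length(codons_a))
  for (i in seq_along(codons_a)) {
    pk <- paste0(codons_a[i], codons_b[i])
    val <- env[[pk]]
    if (is.null(val)) {
      val <- count_differences(codons_a[i], codons_b[i],
                               stops_as_nonsyn = stops_as_nonsyn)
      env[[pk]] <- val
    }
    out[, i] <- val
  }
  out
}

split_codons <- function(cds) {
  if (nchar(cds) %% 3 != 0) stop("sequence length not a multiple of 3")
  substring(cds, seq(1, nchar(cds), 3), seq(3, nchar(cds), 3))
}

#' Build a codon alignment from two aligned codon sequences
#'
#' Columns with a gap, an ambiguity code, or a stop codon in either sequence
#' are excluded from analysis (pairwise complete deletion); the positions
#' retained are recorded.
#'
#' @param codons_a,codons_b Character vectors of codons (triplets, `---`
#'   allowed) of equal length, or strings whose length is a multiple of 3.
#' @param pair_id Label for the pair.
#' @return Object of class `codon_alignment` with elements `codons_a`,
#'   `codons_b`, `used` (logical), `L_used`.
#' @export
codon_alignment <- function(codons_a, codons_b, pair_id = "pair") {
  if (length(codons_a) == 1L && nchar(codons_a[1]) > 3L) codons_a <- split_codons(codons_a)
  if (length(codons_b) == 1L && nchar(codons_b[1]) > 3L) codons_b <- split_codons(codons_b)
  if (length(codons_a) != length(codons_b)) stop("aligned codon vectors differ in length")
  usable <- function(cd) cd %in% SENSE_CODONS
  used <- vapply(codons_a, usable, logical(1)) & vapply(codons_b, usable, logical(1))
  structure(
    list(pair_id = pair_id, codons_a = unname(codons_a), codons_b = unname(codons_b),
         used = unname(used), L_used = sum(used)),
    class = "codon_alignment"
  )
}

#' Protein-guided back-translation to a codon alignment
#'
#' Replaces each aligned residue by its source codon; residue gaps become
#' codon gaps. Each ungapped peptide must translate exactly from its CDS
#' (standard code, terminal stop tolerated).
#'
#' @param pep_a,pep_b Aligned peptide strings (gaps `-`), equal length.
#' @param cds_a,cds_b Unaligned coding sequences.
#' @param pair_id Label for the pair.
#' @return A [codon_alignment()].
#' @export
backtranslate <- function(pep_a, pep_b, cds_a, cds_b, pair_id = "pair") {
  if (nchar(pep_a) != nchar(pep_b)) stop("aligned peptides differ in length")
  map_one <- function(pep, cds, which) {
    res <- strsplit(pep, "")[[1]]
    ungapped <- paste(res[res != "-"], collapse = "")
    trans <- translate_cds(cds, allow_terminal_stop = TRUE)
    if (nchar(trans) != nchar(ungapped)) {
      stop("CDS length inconsistent with peptide for sequence ", which,
           " (", nchar(trans), " vs ", nchar(ungapped), " residues)")
    }
    mism <- which(strsplit(trans, "")[[1]] != strsplit(ungapped, "")[[1]])
    if (length(mism) > 0L) {
      stop("translation mismatch for sequence ", which, " at residue ", mism[1])
    }
    codons <- split_codons(cds)[seq_len(nchar(ungapped))]
    out <- rep("---", length(res))
    out[res != "-"] <- codons
    out
  }
  codon_alignment(map_one(pep_a, cds_a, "a"), map_one(pep_b, cds_b, "b"), pair_id)
}

jc_correct <- function(p) {
  if (is.na(p)) return(NA_real_)
  if (p >= 0.75) return(NA_real_)  # saturation: distance undefined
  -0.75 * log(1 - 4 * p / 3)
}

#' Nei-Gojobori (Jukes-Cantor) Ka/Ks for one codon alignment
#'
#' S and N are per-sequence site sums averaged over the two sequences;
#' Sd and Nd are pathway-averaged difference sums over the used columns;
#' pX = Xd / X and dX = -(3/4) ln(1 - (4/3) pX). omega = dN/dS when dS > 0.
#' pX >= 3/4 leaves the corresponding distance (and omega) as NA rather than
#' raising an error.
#'
#' @param aln A [codon_alignment()].
#' @param stops_as_nonsyn Passed to [count_sites()] / [count_differences()].
#' @return One-row data.frame (pair_id, L_used, S, N, Sd, Nd, pS, pN, dS,
#'   dN, omega).
#' @export
nei_gojobori <- function(aln, stops_as_nonsyn = FALSE) {
  stopifnot(inherits(aln, "codon_alignment"))
  if (aln$L_used == 0L) stop("no usable codon columns")
  ca <- aln$codons_a[aln$used]
  cb <- aln$codons_b[aln$used]
  st <- site_table(stops_as_nonsyn)
  sites_a <- st[, ca, drop = FALSE]
  sites_b <- st[, cb, drop = FALSE]
  S <- (sum(sites_a[1, ]) + sum(sites_b[1, ])) / 2
  N <- (sum(sites_a[2, ]) + sum(sites_b[2, ])) / 2
  diffs <- diff_lookup(ca, cb, stops_as_nonsyn)
  Sd <- sum(diffs[1, ])
  Nd <- sum(diffs[2, ])
  pS <- if (S > 0) Sd / S else NA_real_
  pN <- if (N > 0) Nd / N else NA_real_
  dS <- jc_correct(pS)
  dN <- jc_correct(pN)
  omega <- if (!is.na(dS) && !is.na(dN) && dS > 0) dN / dS else NA_real_
  data.frame(
    pair_id = aln$pair_id, L_used = aln$L_used, S = S, N = N, Sd = Sd, Nd = Nd,
    pS = pS, pN = pN, dS = dS, dN = dN, omega = omega, stringsAsFactors = FALSE
  )
}

#' Codon bootstrap standard errors of dN and dS
#'
#' Resamples codon columns with replacement `reps` times and returns the
#' standard deviation of dN and dS across replicates. Replicates with an
#' undefined distance are dropped and counted.
#'
#' @param aln A [codon_alignment()] with at least two usable columns.
#' @param reps Number of bootstrap replicates.
#' @param seed Integer seed (deterministic output).
#' @param stops_as_nonsyn Passed through to [nei_gojobori()].
#' @return List with `se_dN`, `se_dS`, `n_boot`, `n_dropped_dN`,
#'   `n_dropped_dS`.
#' @export
bootstrap_kaks <- function(aln, reps = 1000L, seed = 1L, stops_as_nonsyn = FALSE) {
  stopifnot(inherits(aln, "codon_alignment"), reps >= 1L)
  if (aln$L_used < 2L) stop("bootstrap needs at least 2 usable codon columns")
  ca <- aln$codons_a[aln$used]
  cb <- aln$codons_b[aln$used]
  L <- length(ca)
  # site and difference counts are per-column: precompute once, resample sums
  st <- site_table(stops_as_nonsyn)
  sites_a <- st[, ca, drop = FALSE]
  sites_b <- st[, cb, drop = FALSE]
  diffs <- diff_lookup(ca, cb, stops_as_nonsyn)
  s_col <- (sites_a[1, ] + sites_b[1, ]) / 2
  n_col <- (sites_a[2, ] + sites_b[2, ]) / 2
  old <- .Random.seed_safe()
  on.exit(.restore_seed(old))
  set.seed(seed)
  dN <- numeric(reps)
  dS <- numeric(reps)
  for (r in seq_len(reps)) {
    idx <- sample.int(L, L, replace = TRUE)
    S <- sum(s_col[idx])
    N <- sum(n_col[idx])
    Sd <- sum(diffs[1, idx])
    Nd <- sum(diffs[2, idx])
    dS[r] <- jc_correct(if (S > 0) Sd / S else NA_real_)
    dN[r] <- jc_correct(if (N > 0) Nd / N else NA_real_)
  }
  ok_N <- !is.na(dN)
  ok_S <- !is.na(dS)
  if (!any(ok_N) || !any(ok_S)) stop("all bootstrap replicates undefined")
  list(
    se_dN = stats::sd(dN[ok_N]),
    se_dS = stats::sd(dS[ok_S]),
    n_boot = reps, n_dropped_dN = sum(!ok_N), n_dropped_dS = sum(!ok_S)
  )
}

#' Ka/Ks over a list of pairs with an omega summary
#'
#' @param pairs Named list of [codon_alignment()] objects.
#' @param labels Optional character vector (e.g. orthologous/paralogous)
#'   parallel to `pairs`.
#' @param bootstrap Number of bootstrap replicates (0 to skip).
#' @param seed Base seed; each pair derives its own stream.
#' @return List with `table` (one row per pair, bootstrap SEs appended) and
#'   `summary` (per label: pairs, defined omegas, fraction omega > 1 and < 1
#'   among defined omegas).
#' @export
batch_kaks <- function(pairs, labels = NULL, bootstrap = 0L, seed = 1L) {
  if (length(pairs) == 0L) stop("empty pair list")
  if (is.null(labels)) labels <- rep("all", length(pairs))
  stopifnot(length(labels) == length(pairs))
  rows <- lapply(seq_along(pairs), function(i) {
    res <- nei_gojobori(pairs[[i]])
    if (bootstrap > 0L && pairs[[i]]$L_used >= 2L) {
      bs <- bootstrap_kaks(pairs[[i]], reps = bootstrap, seed = seed + i)
      res$se_dN <- bs$se_dN
      res$se_dS <- bs$se_dS
    } else {
      res$se_dN <- NA_real_
      res$se_dS <- NA_real_
    }
    res$label <- labels[i]
    res
  })
  tab <- do.call(rbind, rows)
  summ <- do.call(rbind, lapply(split(tab, tab$label), function(d) {
    defined <- d$omega[!is.na(d$omega)]
    data.frame(
      label = d$label[1], n_pairs = nrow(d), n_defined = length(defined),
      frac_omega_gt1 = if (length(defined)) mean(defined > 1) else NA_real_,
      frac_omega_lt1 = if (length(defined)) mean(defined < 1) else NA_real_,
      mean_omega = if (length(defined)) mean(defined) else NA_real_,
      stringsAsFactors = FALSE
    )
  }))
  rownames(summ) <- NULL
  list(table = tab, summary = summ)
}

.Random.seed_safe <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
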