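# Synthetic genomes with a verifiable truth ledger: multi-chromosome
# genomes with uniform-length planted genes, gene families laid out as
# tandem arrays / proximal pairs / dispersed copies, promoters with planted
# cis-element occurrences, codon pairs diverged at a controlled dN/dS,
# reciprocal homolog evidence with planted phylostrata, and differential
# expression tables with planted significant sets.

# Stable per-operation RNG streams: each operation derives its own seed from
# (master seed, label) so adding a stage never perturbs earlier outputs.
stream_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * (seq_len(nchar(label)) %% 31 + 1))
  as.integer((as.numeric(seed) * 7919 + h * 104729) %% .Machine$integer.max)
}

with_seed <- function(seed, code) {
  old <- .Random.seed_safe()
  on.exit(.restore_seed(old))
  set.seed(seed)
  force(code)
}

random_dna <- function(n, gc_fraction) {
  if (n <= 0L) return("")
  probs <- c(A = (1 - gc_fraction) / 2, C = gc_fraction / 2,
             G = gc_fraction / 2, T = (1 - gc_fraction) / 2)
  paste(sample(names(probs), n, replace = TRUE, prob = probs), collapse = "")
}

random_cds <- function(n_codons) {
  stopifnot(n_codons >= 3L)
  internal <- sample(SENSE_CODONS, n_codons - 2L, replace = TRUE)
  paste(c("ATG", internal, sample(STOP_CODONS, 1L)), collapse = "")
}

#' Default synthetic-genome configuration
#'
#' Four chromosomes of 30 uniform-length genes (300 bp single-exon CDS)
#' separated by 4.2 kb intergenic stretches at GC 0.45 — a desk-scale
#' caricature of a compact animal genome whose spacing leaves every gene a
#' full, non-overlapping 2 kb promoter window regardless of strand.
#'
#' @return Named list of generator parameters.
#' @export
default_genome_config <- function() {
  list(n_chrom = 4L, genes_per_chrom = 30L, gene_len_bp = 300L,
       intergenic_bp = 4200L, gc_fraction = 0.45)
}

#' Simulate an annotated genome
#'
#' Chromosomes carry non-overlapping, uniform-length, single-exon genes on
#' alternating strands, each CDS beginning ATG, ending with a stop, free of
#' internal stops, with at least `intergenic_bp` between genes. Deterministic
#' given (config, seed).
#'
#' @param config List with n_chrom, genes_per_chrom, gene_len_bp (multiple
#'   of 3, >= 9), intergenic_bp, gc_fraction in (0,1); optional chrom_len_bp
#'   forces a chromosome length (error if too short).
#' @param seed Integer master seed.
#' @return Object of class `zfam_sim`: list(seqs, models, hits, ledger).
#' @export
simulate_genome <- function(config = default_genome_config(), seed = 1L) {
  cfg <- utils::modifyList(default_genome_config(), config)
  ints <- c(cfg$n_chrom, cfg$genes_per_chrom, cfg$gene_len_bp, cfg$intergenic_bp)
  if (any(ints < 1L)) stop("config integers must be >= 1")
  if (cfg$gc_fraction <= 0 || cfg$gc_fraction >= 1) stop("gc_fraction must lie in (0,1)")
  if (cfg$gene_len_bp %% 3 != 0 || cfg$gene_len_bp < 9L) {
    stop("gene_len_bp must be a multiple of 3 and >= 9")
  }
  needed <- cfg$genes_per_chrom * cfg$gene_len_bp +
    (cfg$genes_per_chrom + 1L) * cfg$intergenic_bp
  chrom_len <- if (!is.null(cfg$chrom_len_bp)) cfg$chrom_len_bp else needed
  if (chrom_len < needed) {
    stop("chromosome too short for requested gene count: need ", needed,
         " bp, have ", chrom_len)
  }
  seed <- as.integer(seed)
  with_seed(stream_seed(seed, "simulate_genome"), {
    seqs <- character(0)
    genes <- list()
    cds <- list()
    n_codons <- cfg$gene_len_bp %/% 3L
    for (ci in seq_len(cfg$n_chrom)) {
      chrom <- sprintf("chr%d", ci)
      pieces <- character(0)
      pos <- 0L
      for (gi in seq_len(cfg$genes_per_chrom)) {
        pieces <- c(pieces, random_dna(cfg$intergenic_bp, cfg$gc_fraction))
        pos <- pos + cfg$intergenic_bp
        gene_id <- sprintf("%s_g%03d", chrom, gi)
        strand <- if (gi %% 2L == 1L) "+" else "-"
        cds_seq <- random_cds(n_codons)
        genomic <- if (strand == "+") cds_seq else reverse_complement(cds_seq)
        pieces <- c(pieces, genomic)
        genes[[gene_id]] <- data.frame(
          gene_id = gene_id, chrom = chrom, start = pos + 1L,
          end = pos + cfg$gene_len_bp, strand = strand, stringsAsFactors = FALSE
        )
        cds[[gene_id]] <- data.frame(
          gene_id = gene_id, transcript_id = paste0(gene_id, ".t1"),
          protein_id = paste0(gene_id, ".p1"), start = pos + 1L,
          end = pos + cfg$gene_len_bp, stringsAsFactors = FALSE
        )
        pos <- pos + cfg$gene_len_bp
      }
      tail_len <- chrom_len - pos
      pieces <- c(pieces, random_dna(tail_len, cfg$gc_fraction))
      seqs[[chrom]] <- paste(pieces, collapse = "")
    }
    models <- gene_models(do.call(rbind, genes), do.call(rbind, cds))
    ledger <- list(
      seed = seed, config = cfg,
      planted_families = list(),
      planted_duplication = character(0),
      planted_motif_counts = data.frame(gene_id = character(0), motif_id = character(0),
                                        iupac = character(0), count = integer(0),
                                        stringsAsFactors = FALSE),
      planted_omega = numeric(0),
      planted_strata = character(0),
      planted_de = character(0)
    )
    structure(list(seqs = seqs, models = models, hits = NULL, ledger = ledger),
              class = "zfam_sim")
  })
}

#' @export
print.zfam_sim <- function(x, ...) {
  cat("zfam_sim:", length(x$seqs), "chromosome(s),", nrow(x$models$genes),
      "genes,", length(x$ledger$planted_families), "planted family(ies)\n")
  invisible(x)
}

#' Strand-aware CDS sequence of one gene
#'
#' @param sim A `zfam_sim` object.
#' @param gene_id Gene id.
#' @return CDS string in reading orientation.
#' @export
cds_sequence <- function(sim, gene_id) {
  g <- sim$models$genes
  row <- g[g$gene_id == gene_id, , drop = FALSE]
  if (nrow(row) == 0L) stop("unknown gene: ", gene_id)
  seg <- sim$models$cds[sim$models$cds$gene_id == gene_id, , drop = FALSE]
  parts <- substring(sim$seqs[[row$chrom]], seg$start, seg$end)
  s <- paste(parts, collapse = "")
  if (row$strand == "+") s else reverse_complement(s)
}

#' Translated protein sequences of all genes
#'
#' @param sim A `zfam_sim` object.
#' @return Named character vector protein per gene id.
#' @export
protein_sequences <- function(sim) {
  ids <- sim$models$genes$gene_id
  stats::setNames(vapply(ids, function(g) translate_cds(cds_sequence(sim, g)),
                         character(1)), ids)
}

replace_gene_cds <- function(sim, gene_id, new_cds) {
  g <- sim$models$genes
  row <- g[g$gene_id == gene_id, , drop = FALSE]
  if (nchar(new_cds) != row$end - row$start + 1L) stop("replacement CDS length mismatch")
  genomic <- if (row$strand == "+") new_cds else reverse_complement(new_cds)
  s <- sim$seqs[[row$chrom]]
  sim$seqs[[row$chrom]] <- paste0(
    substr(s, 1L, row$start - 1L), genomic, substr(s, row$end + 1L, nchar(s))
  )
  sim
}

mutate_cds <- function(cds_seq, rate) {
  if (rate == 0) return(cds_seq)
  codons <- split_codons(cds_seq)
  n <- length(codons)
  for (i in seq(2L, n - 1L)) {
    bases <- strsplit(codons[i], "")[[1]]
    hit <- stats::runif(3) < rate
    if (!any(hit)) next
    for (tries in 1:50) {
      cand <- bases
      for (k in which(hit)) cand[k] <- sample(setdiff(DNA_BASES, bases[k]), 1L)
      cand_codon <- paste(cand, collapse = "")
      if (!cand_codon %in% STOP_CODONS) {
        codons[i] <- cand_codon
        break
      }
    }
  }
  paste(codons, collapse = "")
}

planted_slots <- function(sim) {
  unique(unlist(sim$ledger$planted_families, use.names = FALSE))
}

#' Plant a gene family into a simulated genome
#'
#' Copies of a founder gene overwrite existing (equal-length) gene slots
#' according to `layout`: `tandem` copies occupy consecutive gene ranks
#' right of the founder, `proximal` copies sit 2-10 ranks from the founder
#' on its chromosome (never adjacent to another member), `dispersed` copies
#' go to other chromosomes. Copy CDSs are per-site mutated versions of the
#' founder (start and stop codons fixed, internal stops rejected). An
#' all-vs-all hit table connecting exactly the members (plus self-hits) is
#' appended, and the ledger records each member's implied duplication class.
#'
#' @param sim A `zfam_sim` object.
#' @param family_size Number of members (founder + copies).
#' @param layout Character vector of length `family_size - 1` over
#'   tandem/proximal/dispersed.
#' @param mutation_rate Per-site substitution probability in [0, 0.2).
#' @param seed Integer seed.
#' @param family_id Family label.
#' @return Updated `zfam_sim`.
#' @export
plant_family <- function(sim, family_size, layout, mutation_rate = 0,
                         seed = 1L, family_id = NULL) {
  stopifnot(inherits(sim, "zfam_sim"))
  if (length(layout) != family_size - 1L) stop("layout length must be family_size - 1")
  if (!all(layout %in% c("tandem", "proximal", "dispersed"))) {
    stop("layout entries must be tandem/proximal/dispersed")
  }
  if (mutation_rate < 0 || mutation_rate >= 0.2) stop("mutation_rate must lie in [0, 0.2)")
  if (is.null(family_id)) family_id <- sprintf("fam%02d", length(sim$ledger$planted_families) + 1L)
  n_chrom <- length(sim$seqs)
  t <- sum(layout == "tandem")
  p <- sum(layout == "proximal")
  d <- sum(layout == "dispersed")
  if (d > 0L && n_chrom < 2L) stop("dispersed layout impossible with a single chromosome")
  idx <- gene_rank_index(sim$models)
  used <- planted_slots(sim)
  free <- !(idx$gene_id %in% used)
  with_seed(stream_seed(seed, paste0("plant_family:", family_id)), {
    # founder chromosome: needs a free run of t+1 ranks plus p proximal slots
    pick <- NULL
    for (chrom in sample(unique(idx$chrom))) {
      sub <- idx[idx$chrom == chrom, , drop = FALSE]
      sub_free <- free[match(sub$gene_id, idx$gene_id)]
      nr <- nrow(sub)
      starts <- sample(seq_len(nr))
      for (r in starts) {
        if (r + t > nr || !all(sub_free[r:(r + t)])) next
        member_ranks <- r:(r + t)
        # proximal candidates: within 10 of founder rank r, >= 2 from members
        cand <- setdiff(seq_len(nr), member_ranks)
        cand <- cand[abs(cand - r) <= 10L & sub_free[cand]]
        prox <- integer(0)
        for (k in seq_len(p)) {
          ok <- cand[vapply(cand, function(x) {
            all(abs(x - c(member_ranks, prox)) >= 2L)
          }, logical(1))]
          if (length(ok) == 0L) break
          chosen <- if (length(ok) == 1L) ok else sample(ok, 1L)
          prox <- c(prox, chosen)
        }
        if (length(prox) == p) {
          pick <- list(chrom = chrom, founder_rank = r, tandem_ranks = if (t > 0L) (r + 1L):(r + t) else integer(0),
                       prox_ranks = prox, sub = sub)
          break
        }
      }
      if (!is.null(pick)) break
    }
    if (is.null(pick)) stop("no room for tandem insertion (no suitable free slot run)")
    # dispersed slots: on chromosomes other than the founder's, > 10 ranks
    # from any same-chromosome member
    disp_genes <- character(0)
    if (d > 0L) {
      other <- setdiff(unique(idx$chrom), pick$chrom)
      for (k in seq_len(d)) {
        chrom_k <- other[(k - 1L) %% length(other) + 1L]
        sub2 <- idx[idx$chrom == chrom_k, , drop = FALSE]
        taken_ranks <- sub2$rank[sub2$gene_id %in% c(used, disp_genes)]
        member_ranks_here <- sub2$rank[sub2$gene_id %in% disp_genes]
        ok <- sub2$rank[!(sub2$gene_id %in% c(used, disp_genes))]
        ok <- ok[vapply(ok, function(x) {
          length(member_ranks_here) == 0L || all(abs(x - member_ranks_here) > 10L)
        }, logical(1))]
        if (length(ok) == 0L) stop("no free slot for dispersed copy on ", chrom_k)
        chosen <- if (length(ok) == 1L) ok else sample(ok, 1L)
        disp_genes <- c(disp_genes, sub2$gene_id[sub2$rank == chosen])
      }
    }
    founder_gene <- pick$sub$gene_id[pick$sub$rank == pick$founder_rank]
    tandem_genes <- pick$sub$gene_id[match(pick$tandem_ranks, pick$sub$rank)]
    prox_genes <- pick$sub$gene_id[match(pick$prox_ranks, pick$sub$rank)]
    members <- c(founder_gene, tandem_genes, prox_genes, disp_genes)
    founder_cds <- cds_sequence(sim, founder_gene)
    for (m in setdiff(members, founder_gene)) {
      sim <- replace_gene_cds(sim, m, mutate_cds(founder_cds, mutation_rate))
    }
    # implied duplication classes under the classifier's rank rules
    classes <- c(
      stats::setNames(if (t > 0L) "tandem" else if (p > 0L) "proximal" else "dispersed", founder_gene),
      stats::setNames(rep("tandem", t), tandem_genes),
      stats::setNames(rep("proximal", p), prox_genes),
      stats::setNames(rep("dispersed", d), disp_genes)
    )
    pairs <- expand.grid(q = members, s = members, stringsAsFactors = FALSE)
    hits <- data.frame(
      query_id = pairs$q, subject_id = pairs$s,
      percent_identity = ifelse(pairs$q == pairs$s, 100, 100 * (1 - mutation_rate)),
      alignment_length = nchar(founder_cds) / 3,
      mismatches = 0, gap_opens = 0, q_start = 1, q_end = nchar(founder_cds) / 3,
      s_start = 1, s_end = nchar(founder_cds) / 3,
      e_value = 1e-30, bit_score = 500, stringsAsFactors = FALSE
    )
    hits$self_hit <- hits$query_id == hits$subject_id
    sim$hits <- rbind(sim$hits, hits)
    sim$ledger$planted_families[[family_id]] <- members
    sim$ledger$planted_duplication[members] <- classes[members]
    sim
  })
}

#' Ledger duplication classes over the whole genome
#'
#' Planted members carry their layout-implied class; every other gene is a
#' singleton.
#'
#' @param sim A `zfam_sim` object.
#' @return Named character vector gene_id -> class.
#' @export
ledger_duplication_classes <- function(sim) {
  ids <- sim$models$genes$gene_id
  cls <- stats::setNames(rep("singleton", length(ids)), ids)
  pl <- sim$ledger$planted_duplication
  cls[names(pl)] <- pl
  cls
}

#' Reference motif counter (generation-side oracle)
#'
#' Direct IUPAC membership scan, independent of the regex scanner: all
#' match start positions are found by per-position base-set comparison and
#' reduced greedily left-to-right for the non-overlapping count.
#'
#' @param sequence A/C/G/T/N string.
#' @param iupac IUPAC word.
#' @param overlapping Count every match start instead.
#' @return Integer count.
#' @export
naive_motif_count <- function(sequence, iupac, overlapping = FALSE) {
  n <- nchar(sequence)
  L <- nchar(iupac)
  if (L == 0L || n < L) return(0L)
  iupac_sets <- list(
    A = "A", C = "C", G = "G", T = "T", R = c("A", "G"), Y = c("C", "T"),
    S = c("G", "C"), W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
    B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
    V = c("A", "C", "G"), N = c("A", "C", "G", "T")
  )
  chars <- strsplit(toupper(sequence), "")[[1]]
  pat <- strsplit(toupper(iupac), "")[[1]]
  ok <- rep(TRUE, n - L + 1L)
  for (k in seq_len(L)) {
    ok <- ok & chars[seq_len(n - L + 1L) + k - 1L] %in% iupac_sets[[pat[k]]]
  }
  starts <- which(ok)
  if (overlapping) return(length(starts))
  count <- 0L
  nxt <- 1L
  for (s in starts) {
    if (s >= nxt) {
      count <- count + 1L
      nxt <- s + L
    }
  }
  count
}

upstream_plant_interval <- function(sim, gene_id, window = 2000L) {
  g <- sim$models$genes
  row <- g[g$gene_id == gene_id, , drop = FALSE]
  atg <- start_codon_positions(sim$models)
  a <- atg[atg$gene_id == gene_id, , drop = FALSE]
  chrom_genes <- g[g$chrom == row$chrom & g$gene_id != gene_id, , drop = FALSE]
  len <- nchar(sim$seqs[[row$chrom]])
  if (row$strand == "+") {
    prev_end <- suppressWarnings(max(0L, chrom_genes$end[chrom_genes$end < a$atg_pos]))
    lo <- max(1L, a$atg_pos - window, prev_end + 1L)
    hi <- a$atg_pos - 1L
  } else {
    next_start <- chrom_genes$start[chrom_genes$start > a$atg_pos]
    next_start <- if (length(next_start)) min(next_start) else len + 1L
    lo <- a$atg_pos + 1L
    hi <- min(len, a$atg_pos + window, next_start - 1L)
  }
  list(chrom = row$chrom, strand = row$strand, lo = lo, hi = hi)
}

realize_iupac <- function(iupac) {
  sets <- list(
    A = "A", C = "C", G = "G", T = "T", R = c("A", "G"), Y = c("C", "T"),
    S = c("G", "C"), W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
    B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
    V = c("A", "C", "G"), N = c("A", "C", "G", "T")
  )
  paste(vapply(strsplit(toupper(iupac), "")[[1]], function(ch) {
    s <- sets[[ch]]
    if (is.null(s)) stop("invalid IUPAC character: ", ch)
    if (length(s) == 1L) s else sample(s, 1L)
  }, character(1)), collapse = "")
}

#' Plant cis-element occurrences into promoter windows
#'
#' For every (gene, motif, count) row the upstream window (strand-aware,
#' clipped to the intergenic gap) is rebuilt: planted words are concrete
#' realizations of the IUPAC pattern placed non-overlapping at random
#' offsets over an iid background at the genome's GC fraction, and the
#' background is redrawn until the greedy non-overlapping count of every
#' listed motif in the window equals exactly its requested count (including
#' zeros). The ledger records the planted count per (gene, motif).
#'
#' @param sim A `zfam_sim` object.
#' @param instances data.frame with columns gene_id, motif_id, iupac, count.
#' @param seed Integer seed.
#' @param window Upstream window size.
#' @param max_tries Redraw attempts per gene before giving up.
#' @return Updated `zfam_sim`.
#' @export
plant_promoter_motifs <- function(sim, instances, seed = 1L, window = 2000L,
                                  max_tries = 200L) {
  stopifnot(inherits(sim, "zfam_sim"),
            all(c("gene_id", "motif_id", "iupac", "count") %in% names(instances)))
  if (any(instances$count < 0)) stop("negative planted count")
  gc <- sim$ledger$config$gc_fraction
  with_seed(stream_seed(seed, "plant_promoter_motifs"), {
    for (gid in unique(instances$gene_id)) {
      ins <- instances[instances$gene_id == gid, , drop = FALSE]
      iv <- upstream_plant_interval(sim, gid, window)
      W <- iv$hi - iv$lo + 1L
      if (W <= 0L) {
        if (any(ins$count > 0)) stop("gene ", gid, " has no upstream window to plant into")
        next
      }
      words_len <- sum(ins$count * nchar(ins$iupac))
      if (words_len > W) {
        stop("requested motif occurrences do not fit upstream of ", gid,
             " (", words_len, " bp of motifs, ", W, " bp available)")
      }
      # adaptive placement, longest motifs first: words of one motif may
      # legitimately contain matches of a shorter motif, so each motif is
      # topped up only to its remaining deficit against the live window
      ins <- ins[order(-nchar(ins$iupac)), , drop = FALSE]
      placed <- NULL
      for (try in seq_len(max_tries)) {
        bg <- strsplit(random_dna(W, gc), "")[[1]]
        occupied <- rep(FALSE, W)
        ok <- TRUE
        for (r in seq_len(nrow(ins))) {
          target <- ins$count[r]
          L <- nchar(ins$iupac[r])
          n_placed <- 0L
          repeat {
            cnt <- naive_motif_count(paste(bg, collapse = ""), ins$iupac[r])
            if (cnt == target) break
            if (cnt > target || n_placed > target + 5L) {
              ok <- FALSE
              break
            }
            occ <- cumsum(c(0L, occupied))
            starts <- seq_len(W - L + 1L)
            cand <- starts[occ[starts + L] - occ[starts] == 0L]
            if (length(cand) == 0L) {
              ok <- FALSE
              break
            }
            s <- if (length(cand) == 1L) cand else sample(cand, 1L)
            occupied[s:(s + L - 1L)] <- TRUE
            # prefer a realization that creates no matches of the other
            # listed motifs inside the word (guaranteed containments can
            # never reach zero; their targets were raised by the caller)
            others <- setdiff(ins$iupac, ins$iupac[r])
            word <- NULL
            best_score <- Inf
            for (att in 1:30) {
              w <- realize_iupac(ins$iupac[r])
              score <- if (length(others) == 0L) 0L else {
                sum(vapply(others, function(o) {
                  naive_motif_count(w, o, overlapping = TRUE)
                }, integer(1)))
              }
              if (score < best_score) {
                word <- w
                best_score <- score
              }
              if (best_score == 0L) break
            }
            bg[s:(s + L - 1L)] <- strsplit(word, "")[[1]]
            n_placed <- n_placed + 1L
          }
          if (!ok) break
        }
        if (!ok) next
        candidate <- paste(bg, collapse = "")
        counts_ok <- all(vapply(seq_len(nrow(ins)), function(r) {
          naive_motif_count(candidate, ins$iupac[r]) == ins$count[r]
        }, logical(1)))
        if (counts_ok) {
          placed <- candidate
          break
        }
      }
      if (is.null(placed)) {
        stop("could not realize requested motif counts upstream of ", gid,
             " in ", max_tries, " attempts")
      }
      # write back: the window was built in reading orientation (5'->3'
      # toward the gene); reverse-complement for minus-strand genes
      genomic <- if (iv$strand == "+") placed else reverse_complement(placed)
      s <- sim$seqs[[iv$chrom]]
      sim$seqs[[iv$chrom]] <- paste0(
        substr(s, 1L, iv$lo - 1L), genomic, substr(s, iv$hi + 1L, nchar(s))
      )
      add <- data.frame(gene_id = gid, motif_id = ins$motif_id, iupac = ins$iupac,
                        count = as.integer(ins$count), stringsAsFactors = FALSE)
      sim$ledger$planted_motif_counts <- rbind(sim$ledger$planted_motif_counts, add)
    }
    sim
  })
}

#' Does every realization of one IUPAC word contain a match of another?
#'
#' TRUE iff the second word fits inside the first at some offset with every
#' aligned position of the first a subset of the second's base class, so
#' that any concrete realization of the first necessarily matches the
#' second.
#'
#' @param container,contained IUPAC words.
#' @return Logical.
#' @export
motif_always_contains <- function(container, contained) {
  sets <- list(
    A = "A", C = "C", G = "G", T = "T", R = c("A", "G"), Y = c("C", "T"),
    S = c("G", "C"), W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
    B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
    V = c("A", "C", "G"), N = c("A", "C", "G", "T")
  )
  a <- strsplit(toupper(container), "")[[1]]
  b <- strsplit(toupper(contained), "")[[1]]
  if (length(b) > length(a)) return(FALSE)
  if (identical(a, b)) return(FALSE)
  for (off in 0:(length(a) - length(b))) {
    fits <- all(vapply(seq_along(b), function(k) {
      all(sets[[a[off + k]]] %in% sets[[b[k]]])
    }, logical(1)))
    if (fits) return(TRUE)
  }
  FALSE
}

#' Make per-gene motif target counts satisfiable under containment
#'
#' If every realization of motif A necessarily contains a match of motif B
#' (e.g. an 8-mer whose core is a shorter element), a window holding
#' `count(A)` copies of A cannot show fewer than `count(A)` matches of B.
#' This helper raises each contained motif's target to the sum its
#' containers guarantee, per gene.
#'
#' @param instances data.frame (gene_id, motif_id, iupac, count).
#' @return The instances with adjusted counts.
#' @export
harmonize_motif_targets <- function(instances) {
  out <- instances
  for (gid in unique(out$gene_id)) {
    rows <- which(out$gene_id == gid)
    words <- out$iupac[rows]
    counts <- out$count[rows]
    for (j in seq_along(words)) {
      guaranteed <- 0L
      for (i in seq_along(words)) {
        if (i != j && motif_always_contains(words[i], words[j])) {
          guaranteed <- guaranteed + counts[i]
        }
      }
      counts[j] <- max(counts[j], guaranteed)
    }
    out$count[rows] <- counts
  }
  out
}

#' Simulate a codon-sequence pair diverged at a controlled dN/dS
#'
#' Starting from a random stop-free codon sequence, `n_events` accepted
#' single-base substitution events are applied to one copy: a proposal is
#' drawn at a uniform site, proposals creating stop codons are always
#' redrawn, and for omega <= 1 nonsynonymous proposals are accepted with
#' probability omega (synonymous always); for omega > 1 synonymous
#' proposals are accepted with probability 1/omega (nonsynonymous always).
#'
#' @param n_codons Number of codons.
#' @param n_events Number of accepted substitution events.
#' @param omega Target dN/dS (> 0; 0 allowed as the synonymous-only limit).
#' @param seed Integer seed.
#' @return List (cds_a, cds_b, truth = list(omega, n_events, n_syn_events,
#'   n_nonsyn_events)).
#' @export
simulate_codon_pair <- function(n_codons, n_events, omega, seed = 1L) {
  if (n_codons < 1L) stop("n_codons must be >= 1")
  if (n_events < 0L) stop("n_events must be >= 0")
  if (omega < 0) stop("omega must be >= 0")
  with_seed(stream_seed(seed, "simulate_codon_pair"), {
    codons_a <- sample(SENSE_CODONS, n_codons, replace = TRUE)
    codons_b <- codons_a
    n_syn <- 0L
    n_nonsyn <- 0L
    for (ev in seq_len(n_events)) {
      repeat {
        j <- sample.int(n_codons, 1L)
        k <- sample.int(3L, 1L)
        bases <- strsplit(codons_b[j], "")[[1]]
        bases[k] <- sample(setdiff(DNA_BASES, bases[k]), 1L)
        cand <- paste(bases, collapse = "")
        if (cand %in% STOP_CODONS) next
        syn <- GENETIC_CODE_TABLE[[cand]] == GENETIC_CODE_TABLE[[codons_b[j]]]
        p_accept <- if (omega <= 1) {
          if (syn) 1 else omega
        } else {
          if (syn) 1 / omega else 1
        }
        if (stats::runif(1) < p_accept) {
          codons_b[j] <- cand
          if (syn) n_syn <- n_syn + 1L else n_nonsyn <- n_nonsyn + 1L
          break
        }
      }
    }
    list(
      cds_a = paste(codons_a, collapse = ""),
      cds_b = paste(codons_b, collapse = ""),
      truth = list(omega = omega, n_events = n_events,
                   n_syn_events = n_syn, n_nonsyn_events = n_nonsyn)
    )
  })
}

#' Simulate reciprocal homolog evidence consistent with planted gene ages
#'
#' Panel species at or younger than a gene's planted stratum receive
#' reciprocal E-values below 1e-5 in both directions; species in older
#' strata get at least one direction at or above 1e-5.
#'
#' @param gene_strata Named character vector gene_id -> planted stratum.
#' @param ladder A [lineage_ladder()] whose species map covers the panel.
#' @param seed Integer seed.
#' @return data.frame (gene_id, species_id, e_forward, e_reverse).
#' @export
simulate_homolog_evidence <- function(gene_strata, ladder, seed = 1L) {
  stopifnot(inherits(ladder, "lineage_ladder"))
  bad <- setdiff(unique(gene_strata), ladder$strata)
  if (length(bad) > 0L) stop("planted stratum not on ladder: ", paste(bad, collapse = ", "))
  species <- names(ladder$species_strata)
  sp_idx <- match(ladder$species_strata, ladder$strata)
  with_seed(stream_seed(seed, "simulate_homolog_evidence"), {
    rows <- lapply(names(gene_strata), function(g) {
      gi <- match(gene_strata[[g]], ladder$strata)
      younger <- sp_idx >= gi
      e_f <- ifelse(younger, 10^stats::runif(length(species), -30, -6),
                    10^stats::runif(length(species), -30, -6))
      e_r <- ifelse(younger, 10^stats::runif(length(species), -30, -6),
                    10^stats::runif(length(species), -4, 0))
      data.frame(gene_id = g, species_id = species, e_forward = e_f,
                 e_reverse = e_r, stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
}

#' Simulate a differential-expression table with a planted significant set
#'
#' Planted significant genes satisfy |log2FC| >= log2(lfc_magnitude) and
#' p < 0.05; every other gene fails at least one criterion.
#'
#' @param genes Character vector of gene ids.
#' @param frac_signif Fraction of genes planted significant.
#' @param lfc_magnitude Minimum linear fold change of planted genes.
#' @param seed Integer seed.
#' @param condition Condition label.
#' @return List (table = data.frame(gene_id, condition, log2fc, p),
#'   planted = named character up/down/ns).
#' @export
simulate_de_table <- function(genes, frac_signif = 0.2, lfc_magnitude = 2,
                              seed = 1L, condition = "radiation") {
  stopifnot(frac_signif >= 0, frac_signif <= 1, lfc_magnitude > 1)
  with_seed(stream_seed(seed, "simulate_de_table"), {
    n <- length(genes)
    n_sig <- floor(frac_signif * n)
    sig <- if (n_sig > 0L) sample(genes, n_sig) else character(0)
    planted <- stats::setNames(rep("ns", n), genes)
    lfc <- numeric(n)
    p <- numeric(n)
    names(lfc) <- names(p) <- genes
    for (g in genes) {
      if (g %in% sig) {
        dirn <- sample(c("up", "down"), 1L)
        planted[g] <- dirn
        mag <- log2(lfc_magnitude) + stats::rexp(1, rate = 2)
        lfc[g] <- if (dirn == "up") mag else -mag
        p[g] <- stats::runif(1, 1e-8, 0.049)
      } else {
        if (stats::runif(1) < 0.5) {
          lfc[g] <- stats::runif(1, -0.99, 0.99)   # fails the fold-change filter
          p[g] <- stats::runif(1, 1e-6, 1)
        } else {
          lfc[g] <- stats::runif(1, -4, 4)
          p[g] <- stats::runif(1, 0.05, 1)          # fails the p filter
        }
      }
    }
    list(
      table = data.frame(gene_id = genes, condition = condition,
                         log2fc = unname(lfc), p = unname(p),
                         stringsAsFactors = FALSE),
      planted = planted
    )
  })
}

#' Write a truth ledger to a JSON text file
#'
#' @param ledger Ledger list from a `zfam_sim`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ledger <- function(ledger, path) {
  led <- ledger
  # named atomic vectors serialize as JSON objects only as lists
  for (f in c("planted_duplication", "planted_strata", "planted_de", "planted_omega")) {
    led[[f]] <- as.list(led[[f]])
  }
  jsonlite::write_json(led, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a truth ledger written by [write_ledger()]
#'
#' @param path Ledger JSON path.
#' @return Ledger list.
#' @export
read_ledger <- function(path) {
  led <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (f in c("planted_duplication", "planted_strata", "planted_de")) {
    v <- unlist(led[[f]])
    led[[f]] <- if (is.null(v)) character(0) else v
  }
  v <- unlist(led$planted_omega)
  led$planted_omega <- if (is.null(v)) numeric(0) else v
  led
}

#' Write a simulated study to disk (FASTA + GFF3 + hit table + ledger)
#'
#' @param sim A `zfam_sim` object.
#' @param dir Output directory (created if needed).
#' @return Named character vector of written paths.
#' @export
write_sim <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    genome = file.path(dir, "genome.fa"),
    gff = file.path(dir, "annotation.gff3"),
    hits = file.path(dir, "self_hits.tsv"),
    ledger = file.path(dir, "truth_ledger.json")
  )
  write_fasta(sim$seqs, paths["genome"])
  write_gff3(sim$models, paths["gff"])
  if (!is.null(sim$hits)) write_hit_table(sim$hits, paths["hits"])
  write_ledger(sim$ledger, paths["ledger"])
  paths
}
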