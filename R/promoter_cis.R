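# Promoter extraction (2000 bp upstream of the start codon, strand-aware)
# and cis-element occurrence counting via PFM -> IUPAC degenerate consensus
# -> character-class pattern scanning.

IUPAC_MAP <- c(
  A = "A", C = "C", G = "G", T = "T",
  R = "[AG]", Y = "[CT]", S = "[GC]", W = "[AT]", K = "[GT]", M = "[AC]",
  B = "[CGT]", D = "[AGT]", H = "[ACT]", V = "[ACG]", N = "[ACGT]"
)

SET_TO_IUPAC <- c(
  A = "A", C = "C", G = "G", T = "T",
  AC = "M", AG = "R", AT = "W", CG = "S", CT = "Y", GT = "K",
  ACG = "V", ACT = "H", AGT = "D", CGT = "B", ACGT = "N"
)

#' Extract upstream promoter windows for all genes
#'
#' For a plus-strand gene with start codon at position s the window is
#' `[max(1, s - window), s - 1]` taken as-is; for a minus-strand gene with
#' start codon at position e it is `[e + 1, min(chrom_len, e + window)]`
#' reverse-complemented. Windows clipped at a chromosome end are flagged
#' truncated; a start codon at the chromosome edge yields an empty promoter
#' (not an error).
#'
#' @param models A [gene_models()] object.
#' @param genome Named character vector of chromosome sequences.
#' @param window Upstream window size in bp.
#' @return data.frame (gene_id, chrom, strand, start, end, sequence,
#'   length, truncated); start/end are 1-based plus-strand coordinates of
#'   the source interval (start > end marks an empty window).
#' @export
extract_upstream <- function(models, genome, window = 2000L) {
  stopifnot(inherits(models, "gene_models"))
  if (window < 1L) stop("window must be >= 1")
  window <- as.integer(window)
  atg <- start_codon_positions(models)
  missing_chr <- setdiff(unique(atg$chrom), names(genome))
  if (length(missing_chr) > 0L) {
    stop("chromosome(s) absent from genome: ", paste(missing_chr, collapse = ", "))
  }
  rows <- lapply(seq_len(nrow(atg)), function(i) {
    chrom <- atg$chrom[i]
    len <- nchar(genome[[chrom]])
    if (atg$strand[i] == "+") {
      s <- atg$atg_pos[i]
      lo <- max(1L, s - window)
      hi <- s - 1L
      seq <- if (hi >= lo) substr(genome[[chrom]], lo, hi) else ""
    } else {
      e <- atg$atg_pos[i]
      lo <- e + 1L
      hi <- min(len, e + window)
      seq <- if (hi >= lo) reverse_complement(substr(genome[[chrom]], lo, hi)) else ""
    }
    data.frame(
      gene_id = atg$gene_id[i], chrom = chrom, strand = atg$strand[i],
      start = lo, end = hi, sequence = seq, length = nchar(seq),
      truncated = nchar(seq) < window, stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' IUPAC degenerate consensus of a position frequency matrix
#'
#' Per column with sorted counts c1 >= c2 >= c3 >= c4 and total T: the top
#' base if c1 > T/2 and c1 > 2 c2; else the two-base code if c1 + c2 >
#' (3/4) T; else the three-base code if the rarest base has count 0;
#' else N. (The rule of the familiar `degenerate_consensus` attribute.)
#'
#' @param pfm PFM record from [read_jaspar()], or a bare 4 x L counts
#'   matrix with rows A, C, G, T.
#' @return IUPAC string of length L.
#' @export
pfm_to_degenerate_consensus <- function(pfm) {
  counts <- if (is.list(pfm)) pfm$counts else pfm
  stopifnot(is.matrix(counts), nrow(counts) == 4L)
  if (is.null(rownames(counts))) rownames(counts) <- c("A", "C", "G", "T")
  if (ncol(counts) < 1L) stop("PFM has zero columns")
  out <- character(ncol(counts))
  for (j in seq_len(ncol(counts))) {
    col <- counts[c("A", "C", "G", "T"), j]
    total <- sum(col)
    if (total <= 0) stop("all-zero PFM column at position ", j)
    ord <- order(-col, names(col))  # count desc, alphabetical tie-break
    sorted <- col[ord]
    if (sorted[1] > total / 2 && sorted[1] > 2 * sorted[2]) {
      out[j] <- names(sorted)[1]
    } else if (sorted[1] + sorted[2] > 0.75 * total) {
      key <- paste(sort(names(sorted)[1:2]), collapse = "")
      out[j] <- SET_TO_IUPAC[[key]]
    } else if (min(col) == 0) {
      key <- paste(sort(names(col)[col > 0]), collapse = "")
      out[j] <- SET_TO_IUPAC[[key]]
    } else {
      out[j] <- "N"
    }
  }
  paste(out, collapse = "")
}

#' Compile an IUPAC degenerate word into a character-class pattern
#'
#' A/C/G/T map to themselves and each degenerate code to its base class
#' (R -> `[AG]`, ..., N -> `[ACGT]`); the result is validated by a
#' compilation check before use. An N in a scanned sequence matches no
#' pattern position because the classes contain only A/C/G/T.
#'
#' @param iupac Non-empty IUPAC string.
#' @param motif_id Optional label.
#' @return Object of class `motif_pattern`: list(motif_id, iupac, pattern).
#' @export
iupac_to_pattern <- function(iupac, motif_id = iupac) {
  if (!is.character(iupac) || length(iupac) != 1L || nchar(iupac) == 0L) {
    stop("iupac must be a single non-empty string")
  }
  chars <- strsplit(toupper(iupac), "")[[1]]
  bad <- which(!chars %in% names(IUPAC_MAP))
  if (length(bad) > 0L) {
    stop("invalid IUPAC character '", chars[bad[1]], "' at position ", bad[1])
  }
  pattern <- paste(IUPAC_MAP[chars], collapse = "")
  ok <- tryCatch({
    regexpr(pattern, "ACGT")
    TRUE
  }, error = function(e) FALSE)
  if (!ok) stop("pattern failed to compile: ", pattern)
  structure(list(motif_id = motif_id, iupac = toupper(iupac), pattern = pattern),
            class = "motif_pattern")
}

#' Count motif occurrences in one promoter sequence
#'
#' Non-overlapping left-to-right (greedy) matching on the given strand,
#' case-insensitive; `overlapping = TRUE` counts every start position
#' instead.
#'
#' @param sequence Promoter sequence over A/C/G/T/N.
#' @param pattern A [iupac_to_pattern()] object (or IUPAC string).
#' @param overlapping Count overlapping matches.
#' @return Non-negative integer count.
#' @export
count_occurrences <- function(sequence, pattern, overlapping = FALSE) {
  if (is.character(pattern)) pattern <- iupac_to_pattern(pattern)
  stopifnot(inherits(pattern, "motif_pattern"))
  seq <- toupper(sequence)
  if (nchar(seq) == 0L) return(0L)
  if (overlapping) {
    hits <- gregexpr(paste0("(?=", pattern$pattern, ")"), seq, perl = TRUE)[[1]]
  } else {
    hits <- gregexpr(pattern$pattern, seq)[[1]]
  }
  if (hits[1] == -1L) 0L else length(hits)
}

#' Scan all promoters against all motif patterns
#'
#' @param promoters data.frame from [extract_upstream()] (columns gene_id,
#'   sequence), or a named character vector of sequences.
#' @param patterns List of [iupac_to_pattern()] objects (or IUPAC strings).
#' @param overlapping Count overlapping matches.
#' @return Integer matrix genes x motifs with an attribute
#'   `has_any_element`: named logical, TRUE where a gene has at least one
#'   occurrence of any motif.
#' @export
scan_all <- function(promoters, patterns, overlapping = FALSE) {
  if (is.data.frame(promoters)) {
    seqs <- stats::setNames(promoters$sequence, promoters$gene_id)
  } else {
    seqs <- promoters
  }
  patterns <- lapply(patterns, function(p) {
    if (is.character(p)) iupac_to_pattern(p) else p
  })
  ids <- vapply(patterns, function(p) p$motif_id, character(1))
  if (anyDuplicated(ids)) {
    ids <- make.unique(ids)
  }
  mat <- matrix(0L, nrow = length(seqs), ncol = length(patterns),
                dimnames = list(names(seqs), ids))
  for (j in seq_along(patterns)) {
    mat[, j] <- vapply(seqs, count_occurrences, integer(1),
                       pattern = patterns[[j]], overlapping = overlapping)
  }
  attr(mat, "has_any_element") <- rowSums(mat) > 0
  mat
}

#' The packaged nematode cis-element set
#'
#' Twenty stress- and hormone-response transcription-factor binding motifs
#' (JASPAR nematode CORE derived) shipped as IUPAC words, used for promoter
#' scanning of the family genes.
#'
#' @return data.frame (element, iupac).
#' @export
nematode_elements <- function() {
  path <- system.file("extdata", "nematode_elements.tsv", package = "zfam")
  if (path == "") path <- file.path("inst", "extdata", "nematode_elements.tsv")
  read_tsv(path)
}
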