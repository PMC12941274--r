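#' @import methods
#' @importFrom stats setNames
NULL

DNA_ALPHABET <- c("A", "C", "G", "T", "N")

#' Read a FASTA file into a named character vector
#'
#' Sequences are uppercased and returned in file order. Record ids are the
#' first whitespace-delimited token of each header and must be unique.
#'
#' @param path Path to an (optionally gzipped) FASTA file.
#' @param alphabet `"dna"` restricts sequences to A/C/G/T/N; `"protein"`
#'   restricts to the 20 standard residues; `"any"` skips the check.
#' @return Named character vector of uppercase sequences.
#' @export
read_fasta <- function(path, alphabet = c("dna", "protein", "any")) {
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) stop("file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("empty FASTA file: ", path)
  ids <- sub("\\s.*$", "", names(set))
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0L) {
    stop("duplicate FASTA id(s): ", paste(unique(dup), collapse = ", "))
  }
  seqs <- toupper(as.character(set))
  names(seqs) <- ids
  if (alphabet != "any") {
    allowed <- if (alphabet == "dna") DNA_ALPHABET else strsplit(AA_LETTERS, "")[[1]]
    bad <- vapply(seqs, function(s) {
      any(!strsplit(s, "")[[1]] %in% allowed)
    }, logical(1))
    if (any(bad)) {
      stop(
        "sequence(s) with characters outside the ", alphabet, " alphabet: ",
        paste(ids[bad], collapse = ", ")
      )
    }
  }
  seqs
}

#' Write a named character vector of sequences as FASTA
#'
#' @param seqs Named character vector.
#' @param path Output path.
#' @param width Line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  stopifnot(length(seqs) > 0L, !is.null(names(seqs)))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Construct a gene-model set
#'
#' Coordinates are 1-based inclusive throughout (the GFF3 convention, kept
#' internally so that no conversion step exists to get wrong).
#'
#' @param genes data.frame with columns gene_id, chrom, start, end, strand.
#' @param cds data.frame with columns gene_id, transcript_id, protein_id,
#'   start, end (one row per CDS segment, ordered 5' to 3' on the genome).
#' @return Object of class `gene_models`.
#' @export
gene_models <- function(genes, cds) {
  need_g <- c("gene_id", "chrom", "start", "end", "strand")
  need_c <- c("gene_id", "transcript_id", "protein_id", "start", "end")
  stopifnot(all(need_g %in% names(genes)), all(need_c %in% names(cds)))
  genes <- as.data.frame(genes)[, need_g]
  cds <- as.data.frame(cds)[, need_c]
  if (any(!genes$strand %in% c("+", "-"))) {
    stop("unknown strand symbol: ", paste(unique(setdiff(genes$strand, c("+", "-"))), collapse = ", "))
  }
  if (any(genes$start > genes$end)) stop("gene with start > end")
  idx <- match(cds$gene_id, genes$gene_id)
  if (anyNA(idx)) {
    stop("CDS references absent gene(s): ", paste(unique(cds$gene_id[is.na(idx)]), collapse = ", "))
  }
  out <- cds$start < genes$start[idx] | cds$end > genes$end[idx]
  if (any(out)) {
    stop("CDS segment outside parent gene span for gene(s): ", paste(unique(cds$gene_id[out]), collapse = ", "))
  }
  genes <- genes[order(genes$chrom, genes$start), , drop = FALSE]
  rownames(genes) <- NULL
  rownames(cds) <- NULL
  structure(list(genes = genes, cds = cds), class = "gene_models")
}

#' @export
print.gene_models <- function(x, ...) {
  cat(
    "gene_models:", nrow(x$genes), "genes on",
    length(unique(x$genes$chrom)), "chromosome(s),",
    length(unique(x$cds$transcript_id)), "transcript(s)\n"
  )
  invisible(x)
}

#' Read gene models from a GFF3 file
#'
#' Parses gene/mRNA/CDS features linked by ID/Parent attributes. Coordinates
#' stay 1-based inclusive as in GFF3.
#'
#' @param path Path to a GFF3 file.
#' @return A [gene_models()] object.
#' @export
read_gff3 <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  gr <- rtracklayer::import(path, format = "gff3")
  df <- as.data.frame(gr)
  df$strand <- as.character(df$strand)
  df$seqnames <- as.character(df$seqnames)
  df$type <- as.character(df$type)
  if (any(!df$strand %in% c("+", "-"))) {
    stop("unknown strand symbol in GFF3 (only +/- supported)")
  }
  genes_df <- df[df$type == "gene", , drop = FALSE]
  mrna_df <- df[df$type == "mRNA", , drop = FALSE]
  cds_df <- df[df$type == "CDS", , drop = FALSE]
  if (nrow(genes_df) == 0L) stop("no gene features in ", path)
  first_parent <- function(p) vapply(p, function(v) if (length(v)) v[[1]] else NA_character_, character(1))
  mrna_parent <- first_parent(mrna_df$Parent)
  if (anyNA(mrna_parent) || any(!mrna_parent %in% genes_df$ID)) {
    bad <- mrna_df$ID[is.na(mrna_parent) | !mrna_parent %in% genes_df$ID]
    stop("mRNA with missing/unknown Parent gene: ", paste(bad, collapse = ", "))
  }
  cds_parent <- first_parent(cds_df$Parent)
  if (anyNA(cds_parent) || any(!cds_parent %in% mrna_df$ID)) {
    stop("CDS with missing/unknown Parent mRNA")
  }
  protein_id <- if ("protein_id" %in% names(mrna_df)) mrna_df$protein_id else mrna_df$ID
  protein_id[is.na(protein_id)] <- mrna_df$ID[is.na(protein_id)]
  genes <- data.frame(
    gene_id = genes_df$ID, chrom = genes_df$seqnames,
    start = genes_df$start, end = genes_df$end, strand = genes_df$strand,
    stringsAsFactors = FALSE
  )
  tx2gene <- setNames(mrna_parent, mrna_df$ID)
  tx2prot <- setNames(protein_id, mrna_df$ID)
  cds <- data.frame(
    gene_id = unname(tx2gene[cds_parent]),
    transcript_id = cds_parent,
    protein_id = unname(tx2prot[cds_parent]),
    start = cds_df$start, end = cds_df$end,
    stringsAsFactors = FALSE
  )
  cds <- cds[order(cds$gene_id, cds$transcript_id, cds$start), , drop = FALSE]
  gene_models(genes, cds)
}

#' Write gene models to a GFF3 file
#'
#' @param models A [gene_models()] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(models, path) {
  stopifnot(inherits(models, "gene_models"))
  g <- models$genes
  cds <- models$cds
  tx <- unique(cds[, c("gene_id", "transcript_id", "protein_id")])
  tx_span <- do.call(rbind, lapply(seq_len(nrow(tx)), function(i) {
    seg <- cds[cds$transcript_id == tx$transcript_id[i], , drop = FALSE]
    data.frame(start = min(seg$start), end = max(seg$end))
  }))
  gi <- match(tx$gene_id, g$gene_id)
  gr_genes <- GenomicRanges::GRanges(
    g$chrom, IRanges::IRanges(g$start, g$end), g$strand,
    type = "gene", ID = g$gene_id
  )
  gr_tx <- GenomicRanges::GRanges(
    g$chrom[gi], IRanges::IRanges(tx_span$start, tx_span$end), g$strand[gi],
    type = "mRNA", ID = tx$transcript_id, Parent = as.character(tx$gene_id),
    protein_id = tx$protein_id
  )
  ci <- match(cds$gene_id, g$gene_id)
  gr_cds <- GenomicRanges::GRanges(
    g$chrom[ci], IRanges::IRanges(cds$start, cds$end), g$strand[ci],
    type = "CDS", ID = paste0("cds-", cds$transcript_id),
    Parent = as.character(cds$transcript_id), phase = 0L
  )
  gr <- suppressWarnings(c(gr_genes, gr_tx, gr_cds))
  gr <- gr[order(as.character(GenomicRanges::seqnames(gr)), GenomicRanges::start(gr),
                 match(gr$type, c("gene", "mRNA", "CDS")))]
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Longest-protein transcript of each gene
#'
#' Protein length is derived from summed CDS segment length; ties break to the
#' lexicographically smallest protein id.
#'
#' @param models A [gene_models()] object.
#' @return data.frame (gene_id, transcript_id, protein_id, cds_length).
#' @export
representative_transcripts <- function(models) {
  stopifnot(inherits(models, "gene_models"))
  cds <- models$cds
  len <- tapply(cds$end - cds$start + 1L, cds$transcript_id, sum)
  tx <- unique(cds[, c("gene_id", "transcript_id", "protein_id")])
  tx$cds_length <- as.integer(len[tx$transcript_id])
  tx <- tx[order(tx$gene_id, -tx$cds_length, tx$protein_id), , drop = FALSE]
  rep <- tx[!duplicated(tx$gene_id), , drop = FALSE]
  rownames(rep) <- NULL
  rep
}

#' Genomic position of the start codon of each gene
#'
#' Strand-aware first CDS base of the representative (longest-protein)
#' transcript: the minimum CDS start on the plus strand, the maximum CDS end
#' on the minus strand.
#'
#' @param models A [gene_models()] object.
#' @return data.frame (gene_id, chrom, strand, atg_pos) with 1-based positions.
#' @export
start_codon_positions <- function(models) {
  rep <- representative_transcripts(models)
  g <- models$genes
  cds <- models$cds[models$cds$transcript_id %in% rep$transcript_id, , drop = FALSE]
  pos <- vapply(rep$gene_id, function(gid) {
    seg <- cds[cds$gene_id == gid, , drop = FALSE]
    strand <- g$strand[g$gene_id == gid]
    if (strand == "+") min(seg$start) else max(seg$end)
  }, numeric(1))
  gi <- match(rep$gene_id, g$gene_id)
  data.frame(
    gene_id = rep$gene_id, chrom = g$chrom[gi], strand = g$strand[gi],
    atg_pos = as.integer(pos), stringsAsFactors = FALSE
  )
}

#' Read a JASPAR-format position frequency matrix file
#'
#' Parses the JASPAR CORE text dialect: a `>` header (`>ID NAME`) followed by
#' four rows `A [ counts ]`, `C [...]`, `G [...]`, `T [...]`.
#'
#' @param path Path to a JASPAR text file (may contain several motifs).
#' @return List of PFM records, each a list with `motif_id`, `motif_name`
#'   and `counts` (4 x L numeric matrix with rows A, C, G, T).
#' @export
read_jaspar <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty JASPAR file: ", path)
  headers <- grep("^>", lines)
  if (length(headers) == 0L) stop("no '>' header in JASPAR file: ", path)
  bounds <- c(headers, length(lines) + 1L)
  out <- vector("list", length(headers))
  for (i in seq_along(headers)) {
    head_tok <- strsplit(sub("^>", "", lines[headers[i]]), "\\s+")[[1]]
    motif_id <- head_tok[1]
    motif_name <- if (length(head_tok) > 1L) head_tok[2] else head_tok[1]
    body <- lines[(headers[i] + 1L):(bounds[i + 1L] - 1L)]
    rows <- list()
    for (ln in body) {
      m <- regmatches(ln, regexec("^\\s*([ACGT])\\s*\\[?([^\\]]*)\\]?\\s*$", ln, perl = TRUE))[[1]]
      if (length(m) != 3L) stop("malformed JASPAR matrix row: '", ln, "'")
      vals <- suppressWarnings(as.numeric(strsplit(trimws(m[3]), "\\s+")[[1]]))
      if (anyNA(vals)) stop("non-numeric count in JASPAR row: '", ln, "'")
      rows[[m[2]]] <- vals
    }
    missing <- setdiff(c("A", "C", "G", "T"), names(rows))
    if (length(missing) > 0L) {
      stop("JASPAR motif ", motif_id, " missing row(s): ", paste(missing, collapse = ", "))
    }
    lens <- lengths(rows[c("A", "C", "G", "T")])
    if (length(unique(lens)) != 1L) stop("JASPAR motif ", motif_id, " has rows of unequal length")
    counts <- do.call(rbind, rows[c("A", "C", "G", "T")])
    rownames(counts) <- c("A", "C", "G", "T")
    if (any(counts < 0)) stop("negative count in JASPAR motif ", motif_id)
    if (ncol(counts) < 1L) stop("JASPAR motif ", motif_id, " has zero columns")
    if (any(colSums(counts) <= 0)) stop("JASPAR motif ", motif_id, " has an all-zero column")
    out[[i]] <- list(motif_id = motif_id, motif_name = motif_name, counts = counts)
  }
  out
}

#' Read a 12-column tabular alignment (BLAST outfmt 6 dialect) hit table
#'
#' Extra columns beyond the canonical 12 are ignored. Self-hits are kept but
#' flagged in the `self_hit` column.
#'
#' @param path Path to a tab-separated hit table without header.
#' @return data.frame with the 12 canonical columns plus `self_hit`.
#' @export
read_hit_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  cols <- c(
    "query_id", "subject_id", "percent_identity", "alignment_length",
    "mismatches", "gap_opens", "q_start", "q_end", "s_start", "s_end",
    "e_value", "bit_score"
  )
  df <- utils::read.table(path, sep = "\t", header = FALSE, stringsAsFactors = FALSE,
                          colClasses = "character", fill = FALSE)
  if (ncol(df) < 12L) stop("hit table has fewer than 12 columns: ", path)
  df <- df[, 1:12]
  names(df) <- cols
  num_cols <- cols[3:12]
  for (cc in num_cols) {
    v <- suppressWarnings(as.numeric(df[[cc]]))
    if (anyNA(v)) stop("non-numeric value in hit-table column '", cc, "'")
    df[[cc]] <- v
  }
  if (any(df$e_value < 0)) stop("negative e-value in hit table")
  df$self_hit <- df$query_id == df$subject_id
  df
}

#' Write a hit table in the 12-column tabular dialect
#'
#' @param hits data.frame with at least the 12 canonical columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_hit_table <- function(hits, path) {
  cols <- c(
    "query_id", "subject_id", "percent_identity", "alignment_length",
    "mismatches", "gap_opens", "q_start", "q_end", "s_start", "s_end",
    "e_value", "bit_score"
  )
  stopifnot(all(cols %in% names(hits)))
  utils::write.table(hits[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a result table as tab-separated text with a header row
#'
#' @param df data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a tab-separated table with a header row
#' @param path Input path.
#' @return data.frame.
#' @export
read_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}

reverse_complement <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}
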