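# MCScanX-style duplicate-gene classification from an all-vs-all protein
# hit table plus chromosomal gene order: tandem (adjacent gene ranks),
# proximal (rank distance 2..proximal_max_rank on one chromosome),
# dispersed (any other homolog), singleton.

#' Gene rank index per chromosome
#'
#' Genes of each chromosome sorted by start coordinate and given consecutive
#' integer ranks starting at 1; independent of input row order.
#'
#' @param models A [gene_models()] object (or its `genes` data.frame).
#' @return data.frame (gene_id, chrom, start, rank).
#' @export
gene_rank_index <- function(models) {
  genes <- if (inherits(models, "gene_models")) models$genes else models
  stopifnot(all(c("gene_id", "chrom", "start") %in% names(genes)))
  genes <- genes[order(genes$chrom, genes$start, genes$gene_id), , drop = FALSE]
  genes$rank <- stats::ave(seq_len(nrow(genes)), genes$chrom, FUN = seq_along)
  rownames(genes) <- NULL
  genes[, c("gene_id", "chrom", "start", "rank")]
}

#' Classify genes as singleton/dispersed/proximal/tandem
#'
#' Builds an undirected homology graph from hits with e_value < `e_max`
#' (self-hits dropped) and applies the rank rules with priority
#' tandem > proximal > dispersed. Hits are interpreted at gene level:
#' supply a `protein_to_gene` map when the hit table carries protein ids.
#'
#' @param hits Hit table data.frame (see [read_hit_table()]).
#' @param index Rank index from [gene_rank_index()].
#' @param e_max E-value threshold (strict `<`).
#' @param proximal_max_rank Largest rank distance still called proximal.
#' @param protein_to_gene Optional named character vector mapping hit ids to
#'   gene ids.
#' @return data.frame (gene_id, class, witness) covering every indexed gene.
#' @export
classify_duplicates <- function(hits, index, e_max = 1e-5,
                                proximal_max_rank = 10L,
                                protein_to_gene = NULL) {
  stopifnot(all(c("query_id", "subject_id", "e_value") %in% names(hits)))
  q <- hits$query_id
  s <- hits$subject_id
  if (!is.null(protein_to_gene)) {
    q <- unname(protein_to_gene[q])
    s <- unname(protein_to_gene[s])
    if (anyNA(q) || anyNA(s)) stop("hit id(s) missing from protein_to_gene map")
  }
  keep <- hits$e_value < e_max & q != s
  q <- q[keep]
  s <- s[keep]
  unknown <- setdiff(unique(c(q, s)), index$gene_id)
  if (length(unknown) > 0L) {
    stop("gene(s) in hit table absent from rank index: ", paste(unknown, collapse = ", "))
  }
  # undirected, deduplicated edge list
  edges <- unique(data.frame(
    a = pmin(q, s), b = pmax(q, s), stringsAsFactors = FALSE
  ))
  chrom <- stats::setNames(index$chrom, index$gene_id)
  rank <- stats::setNames(index$rank, index$gene_id)
  neighbours <- split(c(edges$b, edges$a), c(edges$a, edges$b))
  calls <- lapply(index$gene_id, function(g) {
    nb <- sort(unique(neighbours[[g]]))  # deterministic witness choice
    if (is.null(nb) || length(nb) == 0L) {
      return(data.frame(gene_id = g, class = "singleton", witness = NA_character_,
                        stringsAsFactors = FALSE))
    }
    same <- nb[chrom[nb] == chrom[g]]
    dist <- abs(rank[same] - rank[g])
    cls <- "dispersed"
    wit <- nb[1]
    if (length(same) > 0L && any(dist == 1L)) {
      cls <- "tandem"
      wit <- same[which(dist == 1L)[1]]
    } else if (length(same) > 0L && any(dist >= 2L & dist <= proximal_max_rank)) {
      cls <- "proximal"
      wit <- same[which(dist >= 2L & dist <= proximal_max_rank)[1]]
    }
    data.frame(gene_id = g, class = cls, witness = wit, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, calls)
  rownames(out) <- NULL
  out
}

#' Per-class duplication counts and fractions for a gene subset
#'
#' @param calls Output of [classify_duplicates()].
#' @param subset Character vector of gene ids (default: all classified genes).
#' @return data.frame (class, n, fraction) over the four classes.
#' @export
duplication_summary <- function(calls, subset = NULL) {
  if (is.null(subset)) subset <- calls$gene_id
  if (length(subset) == 0L) stop("empty gene subset")
  missing <- setdiff(subset, calls$gene_id)
  if (length(missing) > 0L) stop("unclassified gene(s): ", paste(missing, collapse = ", "))
  cls <- calls$class[match(subset, calls$gene_id)]
  lev <- c("singleton", "dispersed", "proximal", "tandem")
  counts <- table(factor(cls, levels = lev))
  data.frame(class = lev, n = as.integer(counts),
             fraction = as.numeric(counts) / length(subset),
             stringsAsFactors = FALSE)
}
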