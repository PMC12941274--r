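# Phylostratigraphic gene-age assignment from reciprocal homology evidence
# against a species panel mapped onto an ordered lineage ladder.

#' Default lineage ladder
#'
#' The four age grades used for tardigrade genes, oldest to youngest.
#' @export
DEFAULT_LADDER <- c("Cellular organisms", "Eukaryota", "Metazoa", "Tardigrada-specific")

#' Build a lineage ladder
#'
#' @param strata Character vector of stratum labels ordered oldest to
#'   youngest.
#' @param species_strata Named character vector mapping species id to the
#'   youngest stratum containing it; the focal species must map to the
#'   youngest stratum.
#' @return Object of class `lineage_ladder`.
#' @export
lineage_ladder <- function(strata, species_strata) {
  stopifnot(length(strata) >= 1L, !anyDuplicated(strata))
  bad <- setdiff(unique(species_strata), strata)
  if (length(bad) > 0L) stop("species mapped to unknown stratum: ", paste(bad, collapse = ", "))
  structure(list(strata = strata, species_strata = species_strata),
            class = "lineage_ladder")
}

#' Reciprocal-hit homolog call
#'
#' A species carries a homolog iff both the forward and the reverse E-value
#' are strictly below `e_max`.
#'
#' @param e_forward,e_reverse E-values of the two alignment directions.
#' @param e_max Threshold (strict `<`).
#' @return Logical.
#' @export
call_homolog <- function(e_forward, e_reverse, e_max = 1e-5) {
  if (any(c(e_forward, e_reverse) < 0)) stop("negative E-value")
  e_forward < e_max & e_reverse < e_max
}

#' Phylostratigraphic stratum of one gene
#'
#' The oldest ladder stratum containing at least one species with a called
#' (reciprocal) homolog; a gene with homologs in no non-focal species falls
#' into the youngest stratum.
#'
#' @param evidence data.frame with columns species_id, e_forward, e_reverse
#'   (rows for one gene).
#' @param ladder A [lineage_ladder()].
#' @param e_max Reciprocal threshold.
#' @return Stratum label.
#' @export
assign_stratum <- function(evidence, ladder, e_max = 1e-5) {
  stopifnot(inherits(ladder, "lineage_ladder"))
  youngest <- ladder$strata[length(ladder$strata)]
  if (nrow(evidence) == 0L) return(youngest)
  unknown <- setdiff(evidence$species_id, names(ladder$species_strata))
  if (length(unknown) > 0L) {
    stop("species absent from ladder: ", paste(unknown, collapse = ", "))
  }
  hom <- call_homolog(evidence$e_forward, evidence$e_reverse, e_max)
  if (!any(hom)) return(youngest)
  strata_hit <- ladder$species_strata[evidence$species_id[hom]]
  ladder$strata[min(match(strata_hit, ladder$strata))]
}

#' Stratum assignment for a table of genes
#'
#' @param evidence data.frame with columns gene_id, species_id, e_forward,
#'   e_reverse.
#' @param ladder A [lineage_ladder()].
#' @param gene_ids Optional full gene universe (genes without evidence rows
#'   get the youngest stratum).
#' @param e_max Reciprocal threshold.
#' @return data.frame (gene_id, stratum).
#' @export
assign_strata <- function(evidence, ladder, gene_ids = NULL, e_max = 1e-5) {
  if (is.null(gene_ids)) gene_ids <- unique(evidence$gene_id)
  rows <- lapply(gene_ids, function(g) {
    ev <- evidence[evidence$gene_id == g, , drop = FALSE]
    data.frame(gene_id = g, stratum = assign_stratum(ev, ladder, e_max),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Gene counts per age stratum
#'
#' @param assignments data.frame (gene_id, stratum) from [assign_strata()].
#' @param ladder A [lineage_ladder()] fixing the stratum order.
#' @return data.frame (stratum, n_genes) in ladder order.
#' @export
age_distribution <- function(assignments, ladder) {
  if (nrow(assignments) == 0L) stop("empty assignment table")
  counts <- table(factor(assignments$stratum, levels = ladder$strata))
  data.frame(stratum = names(counts), n_genes = as.integer(counts),
             stringsAsFactors = FALSE)
}
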