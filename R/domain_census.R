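# Domain-distribution census: for each domain, the fraction m of focal-set
# domain proteins carrying it, the analogous fraction M over a reference
# superkingdom panel, their ratio p = m/M, and superkingdom-exclusivity calls.

dedup_domain_table <- function(table, e_max) {
  need <- c("protein_id", "species_id", "domain_accession", "e_value")
  stopifnot(all(need %in% names(table)))
  if (any(table$e_value < 0)) stop("negative e-value in domain table")
  table <- table[table$e_value <= e_max, , drop = FALSE]
  unique(table[, c("protein_id", "species_id", "domain_accession")])
}

#' Domain-distribution census (m, M, p = m/M)
#'
#' m is the number of distinct focal proteins carrying a domain divided by
#' the number of distinct focal proteins carrying any domain; M is the same
#' fraction over the reference panel; p = m/M compares the two. Counting is
#' by distinct (protein, domain) pairs, so repeated hits never inflate a
#' fraction.
#'
#' @param focal_table,reference_table data.frames with columns protein_id,
#'   species_id, domain_accession, e_value.
#' @param domain_filter Optional accession set restricting the rows reported
#'   (denominators still use all domains).
#' @param e_max Domain-hit E-value cutoff (inclusive).
#' @return data.frame sorted by descending focal protein count, with columns
#'   domain_accession, n_focal_proteins, total_focal_domain_proteins, m,
#'   n_ref_proteins, total_ref_domain_proteins, M, p, p_defined.
#' @export
compute_census <- function(focal_table, reference_table, domain_filter = NULL,
                           e_max = 1e-2) {
  focal <- dedup_domain_table(focal_table, e_max)
  ref <- dedup_domain_table(reference_table, e_max)
  if (nrow(focal) == 0L) stop("empty focal table after E-value filtering")
  if (nrow(ref) == 0L) stop("empty reference table after E-value filtering")
  total_focal <- length(unique(focal$protein_id))
  total_ref <- length(unique(ref$protein_id))
  domains <- unique(c(focal$domain_accession, ref$domain_accession))
  if (!is.null(domain_filter)) domains <- intersect(domains, domain_filter)
  n_focal <- vapply(domains, function(d) {
    length(unique(focal$protein_id[focal$domain_accession == d]))
  }, integer(1))
  n_ref <- vapply(domains, function(d) {
    length(unique(ref$protein_id[ref$domain_accession == d]))
  }, integer(1))
  m <- n_focal / total_focal
  M <- n_ref / total_ref
  p <- ifelse(M > 0, m / M, NA_real_)
  out <- data.frame(
    domain_accession = domains,
    n_focal_proteins = n_focal, total_focal_domain_proteins = total_focal, m = m,
    n_ref_proteins = n_ref, total_ref_domain_proteins = total_ref, M = M,
    p = p, p_defined = M > 0, stringsAsFactors = FALSE
  )
  out <- out[order(-out$n_focal_proteins, out$domain_accession), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Domains exclusive to a single superkingdom
#'
#' A domain is exclusive to superkingdom K iff at least one panel protein in
#' K carries it and no protein outside K does.
#'
#' @param reference_table Domain table (see [compute_census()]).
#' @param grouping Named character vector species_id -> superkingdom
#'   (Archaea/Bacteria/Eukaryota).
#' @param e_max Domain-hit E-value cutoff (inclusive).
#' @return data.frame (domain_accession, superkingdom) of exclusive domains.
#' @export
find_exclusive_domains <- function(reference_table, grouping, e_max = 1e-2) {
  tab <- dedup_domain_table(reference_table, e_max)
  unmapped <- setdiff(unique(tab$species_id), names(grouping))
  if (length(unmapped) > 0L) {
    stop("species without superkingdom mapping: ", paste(unmapped, collapse = ", "))
  }
  tab$superkingdom <- unname(grouping[tab$species_id])
  rows <- lapply(unique(tab$domain_accession), function(d) {
    sk <- unique(tab$superkingdom[tab$domain_accession == d])
    if (length(sk) == 1L) {
      data.frame(domain_accession = d, superkingdom = sk, stringsAsFactors = FALSE)
    } else NULL
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L) {
    return(data.frame(domain_accession = character(0), superkingdom = character(0),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out[order(out$domain_accession), , drop = FALSE]
}
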