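# Family-membership logic: longest-isoform representative selection, union
# of evidence channels at channel-specific E-value thresholds, domain
# validation across four sources, and a manual exclusion list.

#' Default channel thresholds for candidate evidence
#' @export
DEFAULT_CHANNEL_THRESHOLDS <- c(
  blastp = 1e-5, hmm_seed = 1e-2, hmm_full = 1e-5, hmm_pfam = 1e-2
)

VALIDATION_SOURCES <- c("CDD", "SMART", "Pfam", "InterPro")

#' Longest protein isoform per gene
#'
#' Longest length wins; ties break to the lexicographically smallest
#' protein id.
#'
#' @param proteins data.frame with columns gene_id, protein_id, length.
#' @return Named character vector gene_id -> protein_id.
#' @export
select_longest_isoform <- function(proteins) {
  stopifnot(all(c("gene_id", "protein_id", "length") %in% names(proteins)))
  if (nrow(proteins) == 0L) stop("empty protein table")
  if (any(is.na(proteins$length))) stop("missing protein length")
  ord <- proteins[order(proteins$gene_id, -proteins$length, proteins$protein_id), ]
  sel <- ord[!duplicated(ord$gene_id), ]
  stats::setNames(sel$protein_id, sel$gene_id)
}

#' Merge candidate evidence channels
#'
#' Union of proteins passing their channel's E-value threshold (inclusive
#' `<=` for blastp, strict `<` for the HMM channels, following the
#' identification protocol); each retained protein is annotated with its
#' supporting channels.
#'
#' @param evidence data.frame with columns protein_id, channel, e_value.
#' @param thresholds Named numeric vector of per-channel thresholds.
#' @return data.frame (protein_id, channels, n_channels), one row per
#'   retained protein.
#' @export
merge_candidates <- function(evidence, thresholds = DEFAULT_CHANNEL_THRESHOLDS) {
  stopifnot(all(c("protein_id", "channel", "e_value") %in% names(evidence)))
  if (any(thresholds <= 0)) stop("thresholds must be positive")
  bad <- setdiff(unique(evidence$channel), names(thresholds))
  if (length(bad) > 0L) stop("unknown evidence channel(s): ", paste(bad, collapse = ", "))
  if (any(evidence$e_value < 0)) stop("negative e-value in evidence")
  thr <- thresholds[evidence$channel]
  strict <- evidence$channel != "blastp"
  pass <- ifelse(strict, evidence$e_value < thr, evidence$e_value <= thr)
  ev <- evidence[pass, , drop = FALSE]
  if (nrow(ev) == 0L) {
    return(data.frame(protein_id = character(0), channels = character(0),
                      n_channels = integer(0), stringsAsFactors = FALSE))
  }
  ch <- lapply(split(ev$channel, ev$protein_id), function(x) sort(unique(x)))
  out <- data.frame(
    protein_id = names(ch),
    channels = vapply(ch, paste, character(1), collapse = ","),
    n_channels = lengths(ch), stringsAsFactors = FALSE
  )
  out <- out[order(out$protein_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Validate candidates against domain databases and exclusions
#'
#' A candidate survives iff at least one of the four validation sources
#' confirms the family domain and the protein is not on the manual
#' exclusion list. Provenance (supporting channels and validating sources)
#' is carried through; dropped candidates are reported with a reason.
#'
#' @param candidates Output of [merge_candidates()].
#' @param validation data.frame with columns protein_id, source
#'   (CDD/SMART/Pfam/InterPro), has_c4_domain (logical); at most one row per
#'   (protein, source).
#' @param exclusions Character vector of protein ids removed manually.
#' @return List with `family` (retained rows, plus validating_sources) and
#'   `dropped` (protein_id, reason).
#' @export
validate_family <- function(candidates, validation,
                            exclusions = character(0)) {
  stopifnot(all(c("protein_id", "source", "has_c4_domain") %in% names(validation)))
  bad_src <- setdiff(unique(validation$source), VALIDATION_SOURCES)
  if (length(bad_src) > 0L) stop("unknown validation source(s): ", paste(bad_src, collapse = ", "))
  key <- paste(validation$protein_id, validation$source)
  if (anyDuplicated(key)) stop("duplicate (protein, source) validation rows")
  rows <- lapply(seq_len(nrow(candidates)), function(i) {
    pid <- candidates$protein_id[i]
    v <- validation[validation$protein_id == pid & validation$has_c4_domain, , drop = FALSE]
    if (pid %in% exclusions) {
      return(list(drop = data.frame(protein_id = pid, reason = "manual",
                                    stringsAsFactors = FALSE)))
    }
    if (nrow(v) == 0L) {
      return(list(drop = data.frame(protein_id = pid, reason = "no_validating_source",
                                    stringsAsFactors = FALSE)))
    }
    keep <- candidates[i, , drop = FALSE]
    keep$validating_sources <- paste(sort(unique(v$source)), collapse = ",")
    list(keep = keep)
  })
  family <- do.call(rbind, lapply(rows, function(r) r$keep))
  dropped <- do.call(rbind, lapply(rows, function(r) r$drop))
  if (is.null(family)) {
    family <- data.frame(protein_id = character(0), channels = character(0),
                         n_channels = integer(0), validating_sources = character(0),
                         stringsAsFactors = FALSE)
  }
  if (is.null(dropped)) {
    dropped <- data.frame(protein_id = character(0), reason = character(0),
                          stringsAsFactors = FALSE)
  }
  rownames(family) <- NULL
  rownames(dropped) <- NULL
  list(family = family, dropped = dropped)
}
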