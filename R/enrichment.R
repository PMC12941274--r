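# Hypergeometric over/under-representation testing with Benjamini-Hochberg
# correction, the signed +/- log10(P) score, and set enrichment with the
# q < 0.05 / fold-enrichment > 2 reporting filter.

check_counts <- function(N, K, n, k) {
  vals <- c(N = N, K = K, n = n, k = k)
  if (any(vals < 0) || any(vals != floor(vals))) {
    stop("contingency counts must be non-negative integers")
  }
  if (K > N) stop("K > N")
  if (n > N) stop("n > N")
  if (k > min(n, K)) stop("k > min(n, K)")
  if (k < max(0, n + K - N)) stop("k below the hypergeometric support")
  invisible(TRUE)
}

#' Upper-tail hypergeometric probability P(X >= k)
#'
#' Probability of drawing at least `k` successes in a sample of `n` from a
#' population of `N` containing `K` successes.
#'
#' @param N Population size.
#' @param K Population successes.
#' @param n Sample size.
#' @param k Sample successes.
#' @return Exact tail probability.
#' @export
hypergeom_upper <- function(N, K, n, k) {
  check_counts(N, K, n, k)
  if (k == 0) return(1)
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Lower-tail hypergeometric probability P(X <= k)
#'
#' @inheritParams hypergeom_upper
#' @return Exact tail probability.
#' @export
hypergeom_lower <- function(N, K, n, k) {
  check_counts(N, K, n, k)
  if (k == min(n, K)) return(1)
  stats::phyper(k, K, N - K, n, lower.tail = TRUE)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate control; q-values are returned in the input
#' order.
#'
#' @param p_values Numeric vector of p-values in (0, 1].
#' @return Numeric vector of q-values.
#' @export
bh_adjust <- function(p_values) {
  if (length(p_values) == 0L) return(numeric(0))
  if (any(!is.finite(p_values)) || any(p_values <= 0) || any(p_values > 1)) {
    stop("p-values must lie in (0, 1]")
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Signed -log10 enrichment score
#'
#' Positive for enrichment, negative for depletion. A term with fold
#' enrichment exactly 1 is scored on the depleted side (tie-break).
#'
#' @param p P-value of the directional test.
#' @param direction `"enriched"` or `"depleted"`.
#' @return Signed score.
#' @export
signed_score <- function(p, direction = c("enriched", "depleted")) {
  direction <- match.arg(direction)
  if (p <= 0 || p > 1) stop("p must lie in (0, 1]")
  sgn <- if (direction == "enriched") 1 else -1
  sgn * -log10(p)
}

#' Directional hypergeometric test for one category
#'
#' Chooses the upper tail when the sample is over-represented (fold
#' enrichment > 1) and the lower tail otherwise; both tails are returned.
#'
#' @inheritParams hypergeom_upper
#' @return One-row data.frame (k, n, K, N, fold_enrichment, direction,
#'   p_value, p_upper, p_lower, signed_lgP).
#' @export
hypergeom_test <- function(N, K, n, k) {
  check_counts(N, K, n, k)
  fold <- if (K == 0) NA_real_ else (k / n) / (K / N)
  p_up <- hypergeom_upper(N, K, n, k)
  p_lo <- hypergeom_lower(N, K, n, k)
  direction <- if (!is.na(fold) && fold > 1) "enriched" else "depleted"
  p <- if (direction == "enriched") p_up else p_lo
  data.frame(
    k = k, n = n, K = K, N = N, fold_enrichment = fold,
    direction = direction, p_value = p, p_upper = p_up, p_lower = p_lo,
    signed_lgP = signed_score(p, direction), stringsAsFactors = FALSE
  )
}

#' Term-set enrichment of a study set against a population
#'
#' One directional hypergeometric test per term with at least one study-set
#' gene, Benjamini-Hochberg correction across all tested terms, and the
#' reporting filter q < `q_max` and fold enrichment > `fe_min`.
#'
#' @param study_set Character vector of study gene ids (subset of the
#'   population).
#' @param annotations data.frame with columns `gene_id` and `term_id`
#'   (one row per gene-term annotation); its distinct gene ids define the
#'   population.
#' @param q_max Adjusted-p reporting threshold.
#' @param fe_min Fold-enrichment reporting threshold.
#' @param test_empty_terms If TRUE, also test terms with zero study-set genes.
#' @return List with `table` (all tested terms, with q-values and a
#'   `reported` flag) and `reported` (the filtered rows).
#' @export
enrich_sets <- function(study_set, annotations, q_max = 0.05, fe_min = 2,
                        test_empty_terms = FALSE) {
  stopifnot(is.data.frame(annotations), all(c("gene_id", "term_id") %in% names(annotations)))
  if (length(study_set) == 0L) stop("empty study set")
  study_set <- unique(study_set)
  ann <- unique(annotations[, c("gene_id", "term_id")])
  population <- unique(ann$gene_id)
  missing <- setdiff(study_set, population)
  if (length(missing) > 0L) {
    stop("study gene(s) absent from population: ", paste(missing, collapse = ", "))
  }
  N <- length(population)
  n <- length(study_set)
  terms <- unique(ann$term_id)
  rows <- lapply(terms, function(tm) {
    genes_with <- unique(ann$gene_id[ann$term_id == tm])
    K <- length(genes_with)
    k <- sum(study_set %in% genes_with)
    if (k == 0L && !test_empty_terms) return(NULL)
    cbind(term_id = tm, hypergeom_test(N, K, n, k), stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L) stop("no term with a study-set gene to test")
  tab <- do.call(rbind, rows)
  tab$q_value <- bh_adjust(tab$p_value)
  tab$reported <- tab$q_value < q_max & !is.na(tab$fold_enrichment) &
    tab$fold_enrichment > fe_min & tab$direction == "enriched"
  tab <- tab[order(tab$p_value), , drop = FALSE]
  rownames(tab) <- NULL
  list(table = tab, reported = tab[tab$reported, , drop = FALSE])
}
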