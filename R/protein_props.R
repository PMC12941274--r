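# Physicochemical protein properties: molecular weight (average masses),
# Kyte-Doolittle GRAVY with the hydrophilic/hydrophobic binary, and the
# Guruprasad dipeptide instability index.

AA_LETTERS <- "ACDEFGHIKLMNPQRSTVWY"

# Average (not monoisotopic) residue masses, Da (Expasy convention).
AA_AVG_MASS <- c(
  A = 71.0788, R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
  E = 129.1155, Q = 128.1307, G = 57.0519, H = 137.1411, I = 113.1594,
  L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P = 97.1167,
  S = 87.0782, T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326
)
WATER_MASS <- 18.0153

# Kyte & Doolittle (1982) hydropathy scale.
KYTE_DOOLITTLE <- c(
  A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5, E = -3.5,
  G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9, M = 1.9, F = 2.8,
  P = -1.6, S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2
)

# Guruprasad, Reddy & Pandit (1990) dipeptide instability weight values
# (DIWV), indexed DIWV[first, second]. Unlisted dipeptides carry weight 1.
diwv_matrix <- function() {
  aa <- strsplit(AA_LETTERS, "")[[1]]
  m <- matrix(1, 20, 20, dimnames = list(aa, aa))
  set <- function(first, pairs) {
    for (p in names(pairs)) m[first, p] <<- pairs[[p]]
  }
  set("A", c(C = 44.94, D = -7.49, H = -7.49, P = 20.26))
  set("C", c(D = 20.26, H = 33.60, M = 33.60, L = 20.26, Q = -6.54,
             P = 20.26, T = 33.60, W = 24.68, V = -6.54))
  set("D", c(F = -6.54, K = -7.49, S = 20.26, R = -6.54, T = -14.03))
  set("E", c(C = 44.94, E = 33.60, D = 20.26, I = 20.26, H = -6.54,
             Q = 20.26, P = 20.26, S = 20.26, W = -14.03))
  set("F", c(D = 13.34, K = -14.03, P = 20.26, Y = 33.601))
  set("G", c(A = -7.49, E = -6.54, G = 13.34, I = -7.49, K = -7.49,
             N = -7.49, T = -7.49, W = 13.34, Y = -7.49))
  set("H", c(G = -9.37, F = -9.37, I = 44.94, K = 24.68, N = 24.68,
             P = -1.88, T = -6.54, W = -1.88, Y = 44.94))
  set("I", c(E = 44.94, H = 13.34, K = -7.49, L = 20.26, P = -1.88,
             V = -7.49))
  set("K", c(G = -7.49, I = -7.49, M = 33.60, L = -7.49, Q = 24.64,
             P = -6.54, R = 33.60, V = -7.49))
  set("L", c(K = -7.49, Q = 33.60, P = 20.26, R = 20.26, W = 24.68))
  set("M", c(A = 13.34, H = 58.28, M = -1.88, Q = -6.54, P = 44.94,
             S = 44.94, R = -6.54, T = -1.88, Y = 24.68))
  set("N", c(C = -1.88, G = -14.03, F = -14.03, I = 44.94, K = 24.68,
             Q = -6.54, P = -1.88, T = -7.49, W = -9.37))
  set("P", c(A = 20.26, C = -6.54, E = 18.38, D = -6.54, F = 20.26,
             M = -6.54, Q = 20.26, P = 20.26, S = 20.26, R = -6.54,
             W = -1.88, V = 20.26))
  set("Q", c(C = -6.54, E = 20.26, D = 20.26, F = -6.54, Q = 20.26,
             P = 20.26, S = 44.94, V = -6.54, Y = -6.54))
  set("R", c(G = -7.49, H = 20.26, N = 13.34, Q = 20.26, P = 20.26,
             S = 44.94, R = 58.28, W = 58.28, Y = -6.54))
  set("S", c(C = 33.60, E = 20.26, Q = 20.26, P = 44.94, S = 20.26,
             R = 20.26))
  set("T", c(E = 20.26, G = -7.49, F = 13.34, N = -14.03, Q = -6.54,
             W = -14.03))
  set("V", c(D = -14.03, G = -7.49, K = -1.88, P = 20.26, T = -7.49,
             Y = -6.54))
  set("W", c(A = -14.03, G = -9.37, H = 24.68, M = 24.68, L = 13.34,
             N = 13.34, T = -14.03, V = -7.49))
  set("Y", c(A = 24.68, E = -6.54, D = 24.68, G = -7.49, H = 13.34,
             M = 44.94, P = 13.34, R = -15.91, T = -7.49, W = -9.37,
             Y = 13.34))
  m
}
DIWV <- diwv_matrix()

check_protein <- function(sequence) {
  if (length(sequence) != 1L || !is.character(sequence) || nchar(sequence) == 0L) {
    stop("sequence must be a single non-empty string")
  }
  res <- strsplit(sequence, "")[[1]]
  bad <- setdiff(res, strsplit(AA_LETTERS, "")[[1]])
  if (length(bad) > 0L) {
    stop("nonstandard residue(s): ", paste(unique(bad), collapse = ", "))
  }
  res
}

#' Protein molecular weight from average residue masses
#'
#' Sum of Expasy average residue masses plus one water.
#'
#' @param sequence Protein sequence (20 standard residues).
#' @return Molecular weight in Da.
#' @export
molecular_weight <- function(sequence) {
  res <- check_protein(sequence)
  sum(AA_AVG_MASS[res]) + WATER_MASS
}

#' Grand average of hydropathy (GRAVY)
#'
#' Mean Kyte-Doolittle hydropathy over all residues. Negative values mark a
#' hydrophilic protein.
#'
#' @param sequence Protein sequence.
#' @return GRAVY score (dimensionless).
#' @export
gravy <- function(sequence) {
  res <- check_protein(sequence)
  mean(KYTE_DOOLITTLE[res])
}

#' Guruprasad instability index
#'
#' (10 / L) times the sum of dipeptide instability weight values over the
#' L - 1 ordered dipeptides; values above 40 conventionally predict an
#' unstable protein in vitro.
#'
#' @param sequence Protein sequence of length >= 2.
#' @return Instability index (dimensionless).
#' @export
instability_index <- function(sequence) {
  res <- check_protein(sequence)
  L <- length(res)
  if (L < 2L) stop("sequence must have length >= 2")
  idx <- cbind(res[-L], res[-1L])
  (10 / L) * sum(DIWV[idx])
}

#' Physicochemical property table for a set of proteins
#'
#' @param proteins Named character vector of protein sequences.
#' @param cds_lengths Optional named integer vector of CDS lengths (nt),
#'   matched by protein id.
#' @return data.frame with one row per protein: lengths, molecular weight,
#'   GRAVY with hydropathy class (hydrophilic iff GRAVY < 0), instability
#'   index with stability class (unstable iff > 40).
#' @export
protein_properties <- function(proteins, cds_lengths = NULL) {
  stopifnot(length(proteins) > 0L, !is.null(names(proteins)))
  rows <- lapply(names(proteins), function(id) {
    s <- proteins[[id]]
    g <- gravy(s)
    ii <- instability_index(s)
    data.frame(
      protein_id = id,
      cds_length = if (!is.null(cds_lengths) && id %in% names(cds_lengths)) {
        as.integer(cds_lengths[[id]])
      } else NA_integer_,
      protein_length = nchar(s),
      molecular_weight = molecular_weight(s),
      gravy = g,
      hydropathy_class = if (g < 0) "hydrophilic" else "hydrophobic",
      instability_index = ii,
      stability_class = if (ii > 40) "unstable" else "stable",
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}
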