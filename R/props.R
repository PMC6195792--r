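# Average (not monoisotopic) residue masses in daltons and the Kyte-Doolittle
# hydropathy scale, as used by the ExPASy Compute pI/Mw and ProtParam tools.
AA_AVG_MASS <- c(
  A = 71.0788,  R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
  E = 129.1155, Q = 128.1307, G = 57.0519,  H = 137.1411, I = 113.1594,
  L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P = 97.1167,
  S = 87.0782,  T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326)
WATER_AVG_MASS <- 18.01524

KD_HYDROPATHY <- c(
  A = 1.8,  R = -4.5, N = -3.5, D = -3.5, C = 2.5,
  E = -3.5, Q = -3.5, G = -0.4, H = -3.2, I = 4.5,
  L = 3.8,  K = -3.9, M = 1.9,  F = 2.8,  P = -1.6,
  S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2)

# Bjellqvist pKa values (ExPASy Compute pI/Mw): side chains, the C-terminal
# carboxyl, and residue-dependent N-terminal amine.
PKA_SIDE <- c(D = 4.05, E = 4.45, C = 9.0, Y = 10.0, H = 5.98, K = 10.0, R = 12.0)
PKA_CTERM <- 3.55
PKA_NTERM <- c(A = 7.59, M = 7.00, S = 6.93, P = 8.36, T = 6.82, V = 7.44,
               E = 7.70, G = 7.50)
PKA_NTERM_DEFAULT <- 7.50

check_strict_protein <- function(protein) {
  seq <- toupper(as.character(protein))
  chars <- strsplit(seq, "")[[1]]
  if (length(chars) == 0L) stop("empty sequence")
  bad <- which(!chars %in% names(AA_AVG_MASS))
  if (length(bad)) {
    stop("unknown or ambiguous residue(s) '",
         paste(unique(chars[bad]), collapse = "', '"),
         "' at position(s) ", paste(bad, collapse = ", "))
  }
  chars
}

#' Protein molecular weight
#'
#' Sum of average residue masses plus one water, matching the ExPASy
#' convention. Ambiguity letters (including `X`) are rejected.
#'
#' @param protein protein string.
#' @return mass in daltons.
#' @examples
#' molecular_weight("G")  # 75.07, free glycine
#' @export
molecular_weight <- function(protein) {
  chars <- check_strict_protein(protein)
  sum(AA_AVG_MASS[chars]) + WATER_AVG_MASS
}

#' Grand average of hydropathy (GRAVY)
#'
#' Mean Kyte-Doolittle hydropathy over all residues; positive values indicate
#' overall hydrophobic proteins.
#'
#' @param protein protein string.
#' @return dimensionless mean hydropathy in `[-4.5, 4.5]`.
#' @export
gravy <- function(protein) {
  chars <- check_strict_protein(protein)
  mean(KD_HYDROPATHY[chars])
}

#' Net charge of a protein at a given pH
#'
#' Henderson-Hasselbalch sum over the two termini and the ionizable side
#' chains (D, E, C, Y, H, K, R) using the Bjellqvist/ExPASy pKa set.
#'
#' @param protein protein string.
#' @param pH pH value(s).
#' @return net charge (vectorized over `pH`).
#' @export
net_charge <- function(protein, pH) {
  chars <- check_strict_protein(protein)
  counts <- table(factor(chars, levels = names(AA_AVG_MASS)))
  nterm_pka <- PKA_NTERM[chars[1L]]
  if (is.na(nterm_pka)) nterm_pka <- PKA_NTERM_DEFAULT
  pos_pka <- c(nterm_pka, rep(PKA_SIDE["H"], counts[["H"]]),
               rep(PKA_SIDE["K"], counts[["K"]]),
               rep(PKA_SIDE["R"], counts[["R"]]))
  neg_pka <- c(PKA_CTERM, rep(PKA_SIDE["D"], counts[["D"]]),
               rep(PKA_SIDE["E"], counts[["E"]]),
               rep(PKA_SIDE["C"], counts[["C"]]),
               rep(PKA_SIDE["Y"], counts[["Y"]]))
  vapply(pH, function(p) {
    sum(1 / (1 + 10^(p - pos_pka))) - sum(1 / (1 + 10^(neg_pka - p)))
  }, numeric(1))
}

#' Theoretical isoelectric point
#'
#' pH at which the net charge is zero, found by bisection on `[0, 14]`. The
#' net charge is strictly decreasing in pH, so the root is unique.
#'
#' @param protein protein string.
#' @param tol bisection stops when `|charge| < tol`.
#' @return pI in pH units.
#' @export
isoelectric_point <- function(protein, tol = 1e-4) {
  lo <- 0; hi <- 14
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    q <- net_charge(protein, mid)
    if (abs(q) < tol) return(mid)
    if (q > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Physicochemical property table
#'
#' One row per protein with length, molecular weight, theoretical pI and
#' GRAVY, laid out like a family-survey characterization table. Values are
#' unrounded; round at report time (MW and pI are conventionally shown to 2
#' decimals, GRAVY to 3).
#'
#' @param proteome named character vector of protein sequences.
#' @return data.frame with columns `id`, `length`, `mw`, `pi`, `gravy`.
#' @export
protein_properties <- function(proteome) {
  proteome <- validate_seqs(proteome, "protein")
  data.frame(
    id = names(proteome),
    length = nchar(proteome),
    mw = vapply(proteome, molecular_weight, numeric(1)),
    pi = vapply(proteome, isoelectric_point, numeric(1)),
    gravy = vapply(proteome, gravy, numeric(1)),
    stringsAsFactors = FALSE, row.names = NULL)
}
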