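# Standard genetic code, sense codons, and cached NG86 lookup tables.
.kaks_cache <- new.env(parent = emptyenv())

genetic_code <- function() {
  gc <- Biostrings::GENETIC_CODE
  stats::setNames(as.character(gc), names(gc))
}

sense_codons <- function() {
  gc <- genetic_code()
  names(gc)[gc != "*"]
}

translate_codon <- function(codon) {
  aa <- genetic_code()[[codon]]
  if (is.null(aa)) stop("not a codon: ", codon)
  aa
}

#' Synonymous and nonsynonymous site counts of a codon
#'
#' Nei-Gojobori (1986) site counting: each codon position contributes the
#' fraction of its 3 possible single-nucleotide changes that are synonymous
#' to the synonymous site count S, and the remainder to N; changes to stop
#' codons count as nonsynonymous. S + N = 3 for every sense codon.
#'
#' @param codon a 3-letter sense codon (standard code).
#' @return named numeric vector `c(S = ..., N = ...)`.
#' @examples
#' codon_sites("TTT")  # S = 1/3
#' @export
codon_sites <- function(codon) {
  codon <- toupper(codon)
  if (!grepl("^[ACGT]{3}$", codon))
    stop("ambiguous base or malformed codon: ", codon)
  gc <- genetic_code()
  aa <- gc[[codon]]
  if (aa == "*") stop("stop codon: ", codon)
  s <- 0
  for (pos in 1:3) {
    orig <- substr(codon, pos, pos)
    for (nt in setdiff(c("A", "C", "G", "T"), orig)) {
      mut <- codon
      substr(mut, pos, pos) <- nt
      if (gc[[mut]] == aa) s <- s + 1 / 3   # stop targets are nonsynonymous
    }
  }
  c(S = s, N = 3 - s)
}

# Average synonymous/nonsynonymous differences between two sense codons over
# all minimal substitution paths. Paths passing through a stop codon are
# excluded and the average renormalized; if every path is blocked, all paths
# are used with steps to/from stops counted as nonsynonymous.
codon_path_diffs <- function(codon_a, codon_b) {
  gc <- genetic_code()
  diff_pos <- which(strsplit(codon_a, "")[[1]] != strsplit(codon_b, "")[[1]])
  k <- length(diff_pos)
  if (k == 0L) return(c(sd = 0, nd = 0))
  perms <- if (k == 1L) list(diff_pos) else {
    if (k == 2L) list(diff_pos, rev(diff_pos)) else {
      idx <- list(c(1,2,3), c(1,3,2), c(2,1,3), c(2,3,1), c(3,1,2), c(3,2,1))
      lapply(idx, function(o) diff_pos[o])
    }
  }
  walk <- function(order) {
    cur <- codon_a
    sd <- 0; nd <- 0; blocked <- FALSE
    for (pos in order) {
      nxt <- cur
      substr(nxt, pos, pos) <- substr(codon_b, pos, pos)
      if (gc[[nxt]] == "*") blocked <- TRUE
      # a step is synonymous iff the residue is unchanged and neither end is
      # a stop; in the all-blocked fallback, stop-crossing steps count as
      # nonsynonymous
      if (gc[[nxt]] == gc[[cur]] && gc[[nxt]] != "*" && gc[[cur]] != "*")
        sd <- sd + 1
      else
        nd <- nd + 1
      cur <- nxt
    }
    list(sd = sd, nd = nd, blocked = blocked)
  }
  res <- lapply(perms, walk)
  ok <- !vapply(res, `[[`, logical(1), "blocked")
  use <- if (any(ok)) res[ok] else res
  c(sd = mean(vapply(use, `[[`, numeric(1), "sd")),
    nd = mean(vapply(use, `[[`, numeric(1), "nd")))
}

# Lazily built 61 x 61 lookup tables of per-pair Sd and Nd, and per-codon
# S; makes kaks_pair O(n codons).
ng86_tables <- function() {
  if (!is.null(.kaks_cache$tables)) return(.kaks_cache$tables)
  codons <- sense_codons()
  n <- length(codons)
  s_sites <- vapply(codons, function(cd) codon_sites(cd)[["S"]], numeric(1))
  sd <- matrix(0, n, n, dimnames = list(codons, codons))
  nd <- matrix(0, n, n, dimnames = list(codons, codons))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j <= i) next
      d <- codon_path_diffs(codons[i], codons[j])
      sd[i, j] <- sd[j, i] <- d[["sd"]]
      nd[i, j] <- nd[j, i] <- d[["nd"]]
    }
  }
  .kaks_cache$tables <- list(codons = codons, s_sites = s_sites, sd = sd, nd = nd)
  .kaks_cache$tables
}

split_codons <- function(x) {
  n <- nchar(x)
  if (n %% 3L != 0L) stop("sequence length not divisible by 3")
  substring(x, seq(1L, n, 3L), seq(3L, n, 3L))
}

jc_correct <- function(p) -3 / 4 * log(1 - 4 / 3 * p)

#' Pairwise Ka/Ks by the Nei-Gojobori (1986) method
#'
#' Takes a codon alignment of two CDS strings (equal length, divisible by 3;
#' gaps `-` allowed in whole-codon units). Codon pairs containing a gap or
#' ambiguous base are skipped. Observed synonymous/nonsynonymous differences
#' average over all minimal substitution paths (stop-crossing paths excluded);
#' proportions are Jukes-Cantor corrected to per-site rates.
#'
#' @param cds_a,cds_b aligned CDS strings.
#' @return object of class `kaks_result`: list with `S`, `N`, `Sd`, `Nd`,
#'   `pS`, `pN`, `Ka`, `Ks`, `n_codons` (ungapped codon pairs used), and
#'   `saturated` (TRUE when a proportion reached 3/4 and the correction is
#'   undefined, in which case the rate is `NA`).
#' @export
kaks_pair <- function(cds_a, cds_b) {
  cds_a <- toupper(as.character(cds_a)); cds_b <- toupper(as.character(cds_b))
  if (nchar(cds_a) != nchar(cds_b))
    stop("aligned CDS strings must have equal length")
  cod_a <- split_codons(cds_a); cod_b <- split_codons(cds_b)
  usable <- grepl("^[ACGT]{3}$", cod_a) & grepl("^[ACGT]{3}$", cod_b)
  cod_a <- cod_a[usable]; cod_b <- cod_b[usable]
  if (length(cod_a) == 0L) stop("no ungapped codon pairs to compare")
  tb <- ng86_tables()
  if (any(!cod_a %in% tb$codons) || any(!cod_b %in% tb$codons))
    stop("internal stop codon in input CDS")
  # sites: average of the two sequences
  S <- (sum(tb$s_sites[cod_a]) + sum(tb$s_sites[cod_b])) / 2
  N <- 3 * length(cod_a) - S
  idx <- cbind(match(cod_a, tb$codons), match(cod_b, tb$codons))
  Sd <- sum(tb$sd[idx]); Nd <- sum(tb$nd[idx])
  pS <- Sd / S; pN <- Nd / N
  saturated <- pS >= 3 / 4 || pN >= 3 / 4
  Ks <- if (pS >= 3 / 4) NA_real_ else jc_correct(pS)
  Ka <- if (pN >= 3 / 4) NA_real_ else jc_correct(pN)
  structure(list(S = S, N = N, Sd = Sd, Nd = Nd, pS = pS, pN = pN,
                 Ka = Ka, Ks = Ks, n_codons = length(cod_a),
                 saturated = saturated),
            class = "kaks_result")
}

#' @export
print.kaks_result <- function(x, ...) {
  cat(sprintf("NG86 over %d codons: S=%.2f N=%.2f Sd=%.2f Nd=%.2f  Ka=%s Ks=%s%s\n",
              x$n_codons, x$S, x$N, x$Sd, x$Nd,
              formatC(x$Ka, digits = 4, format = "f"),
              formatC(x$Ks, digits = 4, format = "f"),
              if (x$saturated) "  [saturated]" else ""))
  invisible(x)
}

#' Protein-guided codon alignment of two CDS
#'
#' Translates both CDS, globally aligns the proteins, and back-threads the
#' codons so gaps only occur in whole-codon units and the frame is preserved.
#' A single terminal stop codon, if present, is dropped before translation.
#'
#' @param cds_a,cds_b unaligned CDS strings (length divisible by 3, no
#'   internal stops).
#' @return list with aligned `a` and `b` CDS strings of equal length.
#' @export
codon_align <- function(cds_a, cds_b) {
  strip_stop <- function(x) {
    cods <- split_codons(toupper(x))
    if (genetic_code()[[cods[length(cods)]]] == "*")
      cods <- cods[-length(cods)]
    cods
  }
  cod_a <- strip_stop(cds_a); cod_b <- strip_stop(cds_b)
  gc <- genetic_code()
  prot_a <- paste(gc[cod_a], collapse = ""); prot_b <- paste(gc[cod_b], collapse = "")
  if (grepl("\\*", prot_a) || grepl("\\*", prot_b))
    stop("internal stop codon in input CDS")
  aln <- Biostrings::pairwiseAlignment(Biostrings::AAString(prot_a),
                                       Biostrings::AAString(prot_b),
                                       type = "global")
  pa <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  pb <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  ia <- 0L; ib <- 0L
  out_a <- character(length(pa)); out_b <- character(length(pb))
  for (i in seq_along(pa)) {
    if (pa[i] == "-") out_a[i] <- "---" else { ia <- ia + 1L; out_a[i] <- cod_a[ia] }
    if (pb[i] == "-") out_b[i] <- "---" else { ib <- ib + 1L; out_b[i] <- cod_b[ib] }
  }
  list(a = paste(out_a, collapse = ""), b = paste(out_b, collapse = ""))
}

#' Ka/Ks ratio, divergence date, and selection class
#'
#' Divergence time in million years is `Ks / (2 * lambda_rate) * 1e-6`, the
#' standard synonymous-clock dating with `lambda_rate` substitutions per
#' synonymous site per year (default 6.5e-9, the grass clock rate). The
#' selection class follows the usual reading of the ratio: `< 1` purifying,
#' `= 1` (within 1e-9) neutral, `> 1` positive.
#'
#' @param ka,ks nonsynonymous and synonymous rates (non-negative).
#' @param lambda_rate clock rate in substitutions/site/year.
#' @return list with `ratio` (`NA` when `ks` is 0 and `ka > 0`), `mya`, and
#'   `selection_class` (`NA` when the ratio is undefined).
#' @examples
#' ratio_and_date(0.0258, 0.1829)  # ratio 0.141061, 14.06923 Mya
#' @export
ratio_and_date <- function(ka, ks, lambda_rate = 6.5e-9) {
  stopifnot(ka >= 0, ks >= 0, lambda_rate > 0)
  mya <- ks / (2 * lambda_rate) * 1e-6
  if (ks == 0) {
    return(list(ratio = NA_real_, mya = 0, selection_class = NA_character_))
  }
  ratio <- ka / ks
  cls <- if (abs(ratio - 1) < 1e-9) "neutral" else
    if (ratio < 1) "purifying" else "positive"
  list(ratio = ratio, mya = mya, selection_class = cls)
}

#' Ka/Ks table for a set of gene pairs
#'
#' Runs [codon_align()] and [kaks_pair()] on each listed pair and appends the
#' ratio, divergence date and selection class, mirroring the layout of a
#' duplication-dating table.
#'
#' @param cds named character vector of CDS strings.
#' @param pairs data.frame with columns `gene_a`, `gene_b`.
#' @param lambda_rate clock rate passed to [ratio_and_date()].
#' @return data.frame with one row per pair.
#' @export
kaks_table <- function(cds, pairs, lambda_rate = 6.5e-9) {
  stopifnot(all(c("gene_a", "gene_b") %in% names(pairs)))
  missing <- setdiff(unique(c(pairs$gene_a, pairs$gene_b)), names(cds))
  if (length(missing)) stop("CDS missing for: ", paste(missing, collapse = ", "))
  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    aln <- codon_align(cds[[pairs$gene_a[i]]], cds[[pairs$gene_b[i]]])
    kk <- kaks_pair(aln$a, aln$b)
    rd <- ratio_and_date(kk$Ka, kk$Ks, lambda_rate)
    data.frame(gene_a = pairs$gene_a[i], gene_b = pairs$gene_b[i],
               ka = kk$Ka, ks = kk$Ks, ratio = rd$ratio, mya = rd$mya,
               selection_class = if (is.null(rd$selection_class)) NA else rd$selection_class,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
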