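IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T"))

iupac_regex <- function(iupac, element_id = iupac) {
  chars <- strsplit(toupper(iupac), "")[[1]]
  bad <- setdiff(chars, names(IUPAC_SETS))
  if (length(bad)) {
    stop("invalid IUPAC code(s) '", paste(unique(bad), collapse = "', '"),
         "' in element ", element_id)
  }
  paste(vapply(chars, function(ch) {
    s <- IUPAC_SETS[[ch]]
    if (length(s) == 1L) s else paste0("[", paste(s, collapse = ""), "]")
  }, character(1)), collapse = "")
}

#' Load a PLACE-style cis-element table
#'
#' Expects a TSV with header columns `element_id` and `iupac` (extra columns
#' ignored). Every pattern is validated against the 15-letter IUPAC alphabet.
#'
#' @param path TSV file; lines starting with `#` are comments.
#' @return data.frame with columns `element_id`, `iupac`.
#' @export
load_place_table <- function(path) {
  df <- read_table(path, c(element_id = "character", iupac = "character"))
  dup <- df$element_id[duplicated(df$element_id)]
  if (length(dup)) stop("duplicate element_id: ", paste(unique(dup), collapse = ", "))
  if (any(!nzchar(df$iupac))) stop("empty IUPAC pattern")
  df$iupac <- toupper(df$iupac)
  for (i in seq_len(nrow(df))) iupac_regex(df$iupac[i], df$element_id[i])
  df[, c("element_id", "iupac")]
}

#' The packaged cis-element mini-table
#'
#' Seventeen named plant cis-regulatory elements (CAAT box, DOF core, E-box,
#' pollen- and root-activity motifs, and others) with IUPAC definitions taken
#' from the public PLACE database records; see the fixture file header for
#' provenance. This is a convenience subset for promoter scans, not a PLACE
#' redistribution.
#'
#' @return data.frame as from [load_place_table()].
#' @export
place_elements <- function() {
  load_place_table(system.file("extdata", "place_elements.tsv",
                               package = "famscan", mustWork = TRUE))
}

#' Scan a promoter for cis-element matches
#'
#' Every position and strand where an element's IUPAC pattern matches is
#' reported; overlapping and self-overlapping matches are all counted. Minus
#' strand hits are found by scanning the reverse complement and reported with
#' coordinates on the forward strand; the matched sequence satisfies the
#' pattern on the reported strand. Hits are ordered by (element, strand,
#' start). Starts are 0-based.
#'
#' @param promoter a single nucleotide string (named or not).
#' @param motifs data.frame with `element_id`, `iupac` columns.
#' @param gene_id id recorded in the hits (defaults to the name of
#'   `promoter`, or `""`).
#' @param both_strands scan the minus strand too (default TRUE).
#' @return data.frame with columns `gene_id`, `element_id`, `start`,
#'   `strand`, `match`.
#' @export
scan_promoter <- function(promoter, motifs, gene_id = NULL,
                          both_strands = TRUE) {
  stopifnot(length(promoter) == 1L)
  if (is.null(gene_id))
    gene_id <- if (!is.null(names(promoter))) names(promoter) else ""
  seq_f <- toupper(as.character(promoter))
  n <- nchar(seq_f)
  seq_r <- if (both_strands) revcomp(seq_f) else NULL
  out <- list()
  for (i in seq_len(nrow(motifs))) {
    el <- motifs$element_id[i]
    rx <- paste0("(?=(", iupac_regex(motifs$iupac[i], el), "))")
    m <- nchar(motifs$iupac[i])
    if (m > n) next
    starts_f <- gregexpr(rx, seq_f, perl = TRUE)[[1]]
    if (starts_f[1] != -1L) {
      out[[length(out) + 1L]] <- data.frame(
        gene_id = gene_id, element_id = el,
        start = as.integer(starts_f) - 1L, strand = "+",
        match = substring(seq_f, starts_f, starts_f + m - 1L),
        stringsAsFactors = FALSE)
    }
    if (both_strands) {
      starts_r <- gregexpr(rx, seq_r, perl = TRUE)[[1]]
      if (starts_r[1] != -1L) {
        out[[length(out) + 1L]] <- data.frame(
          gene_id = gene_id, element_id = el,
          start = n - (as.integer(starts_r) - 1L) - m, strand = "-",
          match = substring(seq_r, starts_r, starts_r + m - 1L),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0L) {
    return(data.frame(gene_id = character(), element_id = character(),
                      start = integer(), strand = character(),
                      match = character(), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res <- res[order(res$element_id, res$strand, res$start), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Scan a set of promoters
#'
#' @param promoters named character vector of promoter sequences.
#' @param motifs data.frame with `element_id`, `iupac`.
#' @param both_strands scan both strands (default TRUE).
#' @return combined hits data.frame (see [scan_promoter()]).
#' @export
scan_promoters <- function(promoters, motifs, both_strands = TRUE) {
  promoters <- validate_seqs(promoters, "dna")
  do.call(rbind, lapply(names(promoters), function(g) {
    scan_promoter(promoters[[g]], motifs, g, both_strands)
  }))
}

#' Shared and gene-specific cis-elements
#'
#' Summarizes a hit table across genes: elements present in every gene's
#' promoter are shared; elements present in exactly one are gene-specific.
#' With a single gene every element found is, degenerately, both.
#'
#' @param hits data.frame from [scan_promoters()].
#' @param genes character vector of all gene ids scanned (defaults to the
#'   ids present in `hits`; pass explicitly so genes with zero hits count).
#' @return list with `shared` (character vector), `specific` (named
#'   character vector, element -> gene) and `counts` (gene x element hit
#'   count table).
#' @export
summarize_elements <- function(hits, genes = unique(hits$gene_id)) {
  if (length(genes) < 1L) stop("at least one gene required")
  elements <- sort(unique(hits$element_id))
  counts <- table(factor(hits$gene_id, levels = genes),
                  factor(hits$element_id, levels = elements))
  present <- counts > 0
  n_genes_with <- colSums(present)
  shared <- elements[n_genes_with == length(genes)]
  specific_el <- elements[n_genes_with == 1L]
  specific <- vapply(specific_el, function(e) {
    genes[which(present[, e])]
  }, character(1))
  list(shared = shared, specific = specific, counts = counts)
}
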