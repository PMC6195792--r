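# Longest common extension of cds[ci..] vs genomic[gi..] (1-based indices
# into character vectors).
lce <- function(cds, gen, ci, gi) {
  n <- min(length(cds) - ci, length(gen) - gi) + 1L
  if (n <= 0L) return(0L)
  a <- cds[ci:(ci + n - 1L)]
  b <- gen[gi:(gi + n - 1L)]
  neq <- which(a != b)
  if (length(neq) == 0L) n else neq[1L] - 1L
}

# Exact spliced chaining of a CDS into a genomic string. Returns an exon
# matrix (0-based half-open) or NULL. Search order encodes the preference:
# canonical GT..AG introns first (canonical_only = TRUE pass), then leftmost
# intron start, then shortest intron. Introns must be >= min_intron bp.
splice_chain <- function(cds, gen, min_intron = 20L, canonical_only = TRUE) {
  nc <- length(cds); ng <- length(gen)
  failed <- new.env(parent = emptyenv())
  solve <- function(ci, gi) {
    key <- paste0(ci, ":", gi)
    if (!is.null(failed[[key]])) return(NULL)
    ext <- lce(cds, gen, ci, gi)
    rem <- nc - ci + 1L
    if (ext >= rem) {
      # final exon consumes the rest of the CDS
      return(matrix(c(gi - 1L, gi - 1L + rem), ncol = 2L))
    }
    if (ext >= 1L) {
      for (l in seq_len(ext)) {          # exon length, leftmost intron first
        s <- gi + l                       # intron start (1-based)
        if (canonical_only &&
            !(s + 1L <= ng && gen[s] == "G" && gen[s + 1L] == "T")) next
        nxt_cds <- cds[ci + l]
        r_min <- s + min_intron
        if (r_min > ng) next
        for (r in r_min:ng) {             # resumption position, shortest intron first
          if (gen[r] != nxt_cds) next
          if (gen[r - 1L] != "G" || gen[r - 2L] != "A") {
            if (canonical_only) next
          }
          tail_sol <- solve(ci + l, r)
          if (!is.null(tail_sol)) {
            return(rbind(matrix(c(gi - 1L, gi - 1L + l), ncol = 2L), tail_sol))
          }
        }
      }
    }
    failed[[key]] <- TRUE
    NULL
  }
  hits <- which(gen == cds[1L])
  for (g0 in hits) {
    sol <- solve(1L, g0)
    if (!is.null(sol)) return(sol)
  }
  NULL
}

#' Infer exon-intron structure from CDS and genomic sequence
#'
#' Finds an exon chain on the genomic sequence whose spliced concatenation
#' reproduces the CDS exactly (mismatch tolerance 0). Among multiple
#' solutions the preference is: (1) all introns at least `min_intron` bp
#' (always enforced), (2) canonical GT..AG intron boundaries, (3) leftmost
#' intron placement. If the CDS does not embed on the plus strand, the
#' reverse complement is tried and the model is returned with strand `-`.
#'
#' @param cds CDS string (length divisible by 3).
#' @param genomic genomic string containing the gene (flanks/UTRs tolerated).
#' @param gene_id id recorded on the model.
#' @param min_intron minimum intron length in bp (default 20).
#' @return a [gene_model()]; exon coordinates are 0-based half-open on
#'   `genomic`.
#' @export
infer_structure <- function(cds, genomic, gene_id = "gene", min_intron = 20L) {
  cds <- toupper(as.character(cds)); genomic <- toupper(as.character(genomic))
  if (nchar(cds) %% 3L != 0L) stop("CDS length not divisible by 3")
  if (nchar(genomic) < nchar(cds))
    stop("genomic sequence shorter than the CDS")
  cds_v <- strsplit(cds, "")[[1]]
  for (strand in c("+", "-")) {
    gen_str <- if (strand == "+") genomic else revcomp(genomic)
    gen_v <- strsplit(gen_str, "")[[1]]
    sol <- splice_chain(cds_v, gen_v, min_intron, canonical_only = TRUE)
    if (is.null(sol))
      sol <- splice_chain(cds_v, gen_v, min_intron, canonical_only = FALSE)
    if (!is.null(sol)) {
      if (strand == "-") {
        # map intervals from the reverse complement back onto the input string
        n <- nchar(genomic)
        sol <- cbind(n - sol[, 2], n - sol[, 1])
        sol <- sol[rev(seq_len(nrow(sol))), , drop = FALSE]
      }
      return(gene_model(gene_id, genomic, sol, strand))
    }
  }
  stop("no-splice-solution: CDS for '", gene_id,
       "' cannot be spliced exactly from the genomic sequence")
}

#' Intron annotation of a gene model
#'
#' @param model a [gene_model()].
#' @return data.frame with one row per intron: `start`, `end` (0-based
#'   half-open on the genomic string, in CDS order), `length`, `phase`
#'   (cumulative CDS length mod 3 at the upstream junction) and `canonical`
#'   (GT..AG boundaries read on the coding strand).
#' @export
intron_annotation <- function(model) {
  stopifnot(inherits(model, "gene_model"))
  ex <- model$exons
  n <- nrow(ex)
  if (n < 2L) {
    return(data.frame(start = integer(), end = integer(), length = integer(),
                      phase = integer(), canonical = logical()))
  }
  introns <- cbind(start = ex[-n, 2], end = ex[-1L, 1])
  exon_len <- ex[, 2] - ex[, 1]
  if (model$strand == "+") {
    cum <- cumsum(exon_len)[-n]
  } else {
    # CDS reads from the last exon backwards on the minus strand
    cum <- cumsum(rev(exon_len))[-n]
    introns <- introns[rev(seq_len(n - 1L)), , drop = FALSE]
  }
  canon <- vapply(seq_len(nrow(introns)), function(i) {
    iv <- introns[i, ]
    s <- substr(model$genomic, iv[1] + 1L, iv[2])
    if (model$strand == "-") s <- revcomp(s)
    nchar(s) >= 4L && substr(s, 1L, 2L) == "GT" &&
      substr(s, nchar(s) - 1L, nchar(s)) == "AG"
  }, logical(1))
  data.frame(start = as.integer(introns[, 1]), end = as.integer(introns[, 2]),
             length = as.integer(introns[, 2] - introns[, 1]),
             phase = as.integer(cum %% 3L), canonical = canon,
             row.names = NULL)
}

#' Intron phases of a gene model
#'
#' Phase of intron i is the cumulative length of the upstream exons mod 3:
#' 0 when the intron falls between codons, 1 or 2 when it interrupts one.
#'
#' @param model a [gene_model()].
#' @return integer vector of phases (length = intron count).
#' @export
intron_phases <- function(model) {
  intron_annotation(model)$phase
}

#' Gene-structure summary table
#'
#' @param models list of [gene_model()] objects.
#' @return data.frame with per-gene exon/intron counts and CDS length.
#' @export
structure_table <- function(models) {
  rows <- lapply(models, function(m) {
    ia <- intron_annotation(m)
    data.frame(gene_id = m$gene_id, strand = m$strand,
               n_exons = nrow(m$exons), n_introns = nrow(ia),
               cds_length = sum(m$exons[, 2] - m$exons[, 1]),
               all_canonical = all(ia$canonical),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Write gene models as GFF3
#'
#' Emits gene, exon and intron features with 1-based inclusive coordinates
#' per the GFF3 convention (internal coordinates stay 0-based half-open).
#'
#' @param models list of [gene_model()] objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_structure_gff3 <- function(models, path) {
  lines <- c("##gff-version 3")
  for (m in models) {
    span <- range(m$exons)
    lines <- c(lines, paste(m$gene_id, "famscan", "gene",
                            span[1] + 1L, span[2], ".", m$strand, ".",
                            paste0("ID=", m$gene_id), sep = "\t"))
    for (i in seq_len(nrow(m$exons))) {
      lines <- c(lines, paste(m$gene_id, "famscan", "exon",
                              m$exons[i, 1] + 1L, m$exons[i, 2], ".",
                              m$strand, ".",
                              paste0("Parent=", m$gene_id), sep = "\t"))
    }
    ia <- intron_annotation(m)
    for (i in seq_len(nrow(ia))) {
      lines <- c(lines, paste(m$gene_id, "famscan", "intron",
                              ia$start[i] + 1L, ia$end[i], ".", m$strand, ".",
                              paste0("Parent=", m$gene_id), sep = "\t"))
    }
  }
  writeLines(lines, path)
  invisible(path)
}
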