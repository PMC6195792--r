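AA_LETTERS <- c("A","C","D","E","F","G","H","I","K","L","M","N","P","Q","R",
                "S","T","V","W","Y")
DNA_LETTERS <- c("A","C","G","T")

#' Validate a set of sequences
#'
#' Checks ids for uniqueness and sequences against an alphabet. All sequences
#' in the package are plain named character vectors, uppercased; `X` is
#' tolerated in proteins and `N` in nucleotide sequences.
#'
#' @param seqs named character vector of sequences.
#' @param type `"protein"` or `"dna"`.
#' @return the validated (uppercased) vector, invisibly classed by type.
#' @keywords internal
validate_seqs <- function(seqs, type = c("protein", "dna")) {
  type <- match.arg(type)
  if (length(seqs) == 0L) stop("no sequences")
  ids <- names(seqs)
  if (is.null(ids) || any(!nzchar(ids))) stop("all sequences must be named")
  dup <- ids[duplicated(ids)]
  if (length(dup)) stop("duplicate id(s): ", paste(unique(dup), collapse = ", "))
  seqs <- toupper(seqs)
  if (any(!nzchar(seqs))) {
    stop("empty sequence(s): ", paste(ids[!nzchar(seqs)], collapse = ", "))
  }
  allowed <- if (type == "protein") c(AA_LETTERS, "X") else c(DNA_LETTERS, "N")
  bad <- vapply(seqs, function(s) {
    any(!strsplit(s, "")[[1]] %in% allowed)
  }, logical(1))
  if (any(bad)) {
    stop("sequence(s) with letters outside the ", type, " alphabet: ",
         paste(ids[bad], collapse = ", "))
  }
  seqs
}

#' Read a FASTA file
#'
#' Reads a multi-record FASTA into a named character vector. The id is the
#' header token before the first whitespace; records keep file order and
#' lowercase (soft-masked) letters are uppercased.
#'
#' @param path path to a FASTA file.
#' @param type `"protein"` or `"dna"`; controls alphabet validation.
#' @return named character vector of sequences, in file order.
#' @examples
#' tf <- tempfile(fileext = ".fa")
#' writeLines(c(">a some description", "MKV"), tf)
#' read_fasta(tf, "protein")
#' @export
read_fasta <- function(path, type = c("protein", "dna")) {
  type <- match.arg(type)
  if (!file.exists(path)) stop("file not found: ", path)
  set <- if (type == "protein") {
    Biostrings::readAAStringSet(path)
  } else {
    Biostrings::readDNAStringSet(path)
  }
  if (length(set) == 0L) stop("empty FASTA file: ", path)
  seqs <- as.character(set)
  names(seqs) <- vapply(names(set), function(h) strsplit(h, "\\s+")[[1]][1],
                        character(1), USE.NAMES = FALSE)
  validate_seqs(seqs, type)
}

#' Write sequences to FASTA
#'
#' @param seqs named character vector.
#' @param path output path.
#' @param width line wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 60L) {
  if (is.null(names(seqs)) || any(!nzchar(names(seqs))))
    stop("all sequences must be named")
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Read a delimited table with a required schema
#'
#' Thin wrapper around [utils::read.delim()] that checks required columns are
#' present and coerces them to the given types, preserving row order.
#'
#' @param path TSV file with a header row.
#' @param schema named character vector mapping column name to one of
#'   `"character"`, `"numeric"`, `"integer"`.
#' @return data.frame with at least the schema columns, typed.
#' @export
read_table <- function(path, schema) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                          comment.char = "#")
  missing <- setdiff(names(schema), names(df))
  if (length(missing)) {
    stop("missing column(s): ", paste(missing, collapse = ", "))
  }
  for (col in names(schema)) {
    df[[col]] <- switch(schema[[col]],
      character = as.character(df[[col]]),
      numeric   = as.numeric(df[[col]]),
      integer   = as.integer(df[[col]]),
      stop("unknown schema type: ", schema[[col]]))
  }
  df
}

#' Write a phylogenetic tree to Newick
#'
#' Bootstrap supports, when present as node labels, are serialized as
#' internal-node labels per the usual Newick convention.
#'
#' @param tree an [ape::phylo] object with named leaves.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  stopifnot(inherits(tree, "phylo"))
  if (length(tree$tip.label) < 2L) stop("tree must have at least 2 leaves")
  if (any(is.na(tree$tip.label) | !nzchar(tree$tip.label)))
    stop("unnamed leaf in tree")
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Read a Newick tree
#'
#' @param path Newick file.
#' @return an [ape::phylo] object.
#' @export
read_newick <- function(path) {
  tr <- ape::read.tree(path)
  if (is.null(tr)) stop("could not parse Newick file: ", path)
  tr
}

#' Reverse-complement a nucleotide string
#'
#' Handles the full 15-letter IUPAC degenerate alphabet, so it applies to
#' cis-element patterns as well as plain sequence.
#'
#' @param x a single nucleotide/IUPAC string.
#' @return the reverse complement string.
#' @export
revcomp <- function(x) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", R = "Y", Y = "R", S = "S",
            W = "W", K = "M", M = "K", B = "V", V = "B", D = "H", H = "D",
            N = "N")
  chars <- rev(strsplit(toupper(x), "")[[1]])
  bad <- setdiff(chars, names(comp))
  if (length(bad)) stop("cannot complement letter(s): ", paste(bad, collapse = ", "))
  paste(comp[chars], collapse = "")
}

#' Construct a gene model
#'
#' A gene model ties a genomic sequence to an ordered exon chain. Exons are
#' 0-based half-open `[start, end)` intervals on the genomic sequence; all
#' internal coordinates in the package follow this convention and 1-based
#' numbers appear only in rendered reports.
#'
#' @param gene_id gene identifier.
#' @param genomic genomic nucleotide string.
#' @param exons two-column matrix (`start`, `end`), 0-based half-open, sorted.
#' @param strand `"+"` or `"-"` (exon coordinates are always on the given
#'   genomic string; `"-"` records that the CDS reads from its reverse
#'   complement).
#' @return object of class `gene_model`.
#' @export
gene_model <- function(gene_id, genomic, exons, strand = "+") {
  stopifnot(is.matrix(exons), ncol(exons) == 2L, strand %in% c("+", "-"))
  if (nrow(exons) == 0L) stop("at least one exon required")
  if (any(exons[, 1] >= exons[, 2])) stop("empty or inverted exon interval")
  if (is.unsorted(exons[, 1], strictly = TRUE) && nrow(exons) > 1L)
    stop("exons must be sorted by start")
  if (nrow(exons) > 1L && any(exons[-1L, 1] < exons[-nrow(exons), 2]))
    stop("exons overlap")
  if (exons[nrow(exons), 2] > nchar(genomic)) stop("exon beyond genomic end")
  colnames(exons) <- c("start", "end")
  structure(list(gene_id = gene_id, genomic = toupper(genomic),
                 exons = exons, strand = strand),
            class = "gene_model")
}

#' @export
print.gene_model <- function(x, ...) {
  n_ex <- nrow(x$exons)
  cat("Gene model ", x$gene_id, " (", x$strand, " strand): ",
      n_ex, " exon(s), ", n_ex - 1L, " intron(s), genomic span ",
      nchar(x$genomic), " bp\n", sep = "")
  invisible(x)
}

#' Spliced CDS of a gene model
#'
#' Concatenates the exon sequences (reverse-complementing for `-` strand
#' models, where exons are stored on the plus strand of the given genomic
#' string).
#'
#' @param model a [gene_model()].
#' @return CDS string.
#' @export
splice_cds <- function(model) {
  stopifnot(inherits(model, "gene_model"))
  parts <- apply(model$exons, 1L, function(iv) {
    substr(model$genomic, iv[1] + 1L, iv[2])
  })
  cds <- paste(parts, collapse = "")
  if (model$strand == "-") cds <- revcomp(cds)
  cds
}

#' Read an FPKM expression matrix
#'
#' Expects a TSV whose first column holds gene ids and remaining columns one
#' tissue each; values must be non-negative.
#'
#' @param path TSV file.
#' @return numeric matrix, genes in rows, tissues in columns.
#' @export
read_fpkm <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (ncol(df) < 3L) stop("FPKM table needs a gene column and >= 2 tissues")
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(df[[1L]])
  if (anyNA(m)) stop("non-numeric FPKM value(s)")
  if (any(m < 0)) stop("negative FPKM value(s)")
  m
}
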