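#' Compile a PROSITE-dialect motif pattern
#'
#' Patterns are hyphen-separated tokens read left to right. Supported tokens:
#' literal residues (a multi-letter literal like `ELL` is a run of single
#' literal positions), bracketed alternative sets `[ED]`, the wildcard `X`,
#' and repeat counts `(n)` or `(n,m)` after a residue, set or `X`. A `0`
#' inside a bracket (e.g. `[LIMV0]`) or the repeat `(0,1)` marks the position
#' as optional (matched 0 or 1 times).
#'
#' @param source_text pattern string, e.g. `"L-X(2)-G-[ED]-ELL"`.
#' @return object of class `motif_pattern` with one row per position run:
#'   allowed residue set, `min` and `max` repeat counts.
#' @examples
#' p <- compile_pattern("L-X(2)-G")
#' motif_min_length(p)  # 4
#' @export
compile_pattern <- function(source_text) {
  stopifnot(is.character(source_text), length(source_text) == 1L)
  tokens <- strsplit(source_text, "-", fixed = TRUE)[[1]]
  if (length(tokens) == 0L || any(!nzchar(tokens)))
    stop("empty token in pattern: ", source_text)
  positions <- list()
  for (k in seq_along(tokens)) {
    tok <- tokens[k]
    # split off a trailing (n) / (n,m) repeat
    min_rep <- 1L; max_rep <- 1L
    rep_m <- regmatches(tok, regexec("^(.*)\\((\\d+)(,(\\d+))?\\)$", tok))[[1]]
    if (length(rep_m)) {
      tok <- rep_m[2]
      min_rep <- as.integer(rep_m[3])
      max_rep <- if (nzchar(rep_m[5])) as.integer(rep_m[5]) else min_rep
      if (min_rep > max_rep)
        stop("repeat minimum exceeds maximum in token ", k, ": ", tokens[k])
    }
    if (grepl("\\(|\\)", tok))
      stop("unbalanced parentheses in token ", k, ": ", tokens[k])
    optional <- FALSE
    if (grepl("^\\[", tok)) {
      if (!grepl("^\\[[A-Z0]+\\]$", tok))
        stop("malformed bracket set in token ", k, ": ", tokens[k])
      set <- strsplit(sub("^\\[(.*)\\]$", "\\1", tok), "")[[1]]
      if ("0" %in% set) {          # a 0 in the set marks the position optional
        optional <- TRUE
        set <- setdiff(set, "0")
      }
      bad <- setdiff(set, AA_LETTERS)
      if (length(bad) || length(set) == 0L)
        stop("illegal residue letter(s) in token ", k, ": ", tokens[k])
      if (optional) min_rep <- 0L
      positions[[length(positions) + 1L]] <-
        list(set = set, min = min_rep, max = max_rep)
    } else if (tok == "X") {
      positions[[length(positions) + 1L]] <-
        list(set = AA_LETTERS, min = min_rep, max = max_rep)
    } else {
      if (!grepl("^[A-Z]+$", tok) || grepl("X", tok))
        stop("illegal residue letter(s) in token ", k, ": ", tok)
      letters_k <- strsplit(tok, "")[[1]]
      bad <- setdiff(letters_k, AA_LETTERS)
      if (length(bad))
        stop("illegal residue letter(s) in token ", k, ": ", tok)
      if (length(letters_k) > 1L && (min_rep != 1L || max_rep != 1L))
        stop("repeat count on multi-residue literal in token ", k, ": ", tokens[k])
      for (ch in letters_k) {
        positions[[length(positions) + 1L]] <-
          list(set = ch, min = min_rep, max = max_rep)
      }
    }
  }
  structure(list(source_text = source_text, positions = positions),
            class = "motif_pattern")
}

#' @export
print.motif_pattern <- function(x, ...) {
  cat("Motif pattern <", x$source_text, ">: ", length(x$positions),
      " position runs, match length ", motif_min_length(x), "-",
      motif_max_length(x), " aa\n", sep = "")
  invisible(x)
}

#' Minimal / maximal match length of a compiled pattern
#'
#' @param pattern a [compile_pattern()] result.
#' @return integer length.
#' @export
motif_min_length <- function(pattern) {
  sum(vapply(pattern$positions, `[[`, integer(1), "min"))
}

#' @rdname motif_min_length
#' @export
motif_max_length <- function(pattern) {
  sum(vapply(pattern$positions, `[[`, integer(1), "max"))
}

# Regex for a compiled pattern. X runs compile to a character class over the
# 20 residues (not ".") so that sequence letters outside the alphabet never
# match a wildcard.
pattern_regex <- function(pattern) {
  paste(vapply(pattern$positions, function(p) {
    cls <- if (length(p$set) == 1L) p$set else
      paste0("[", paste(p$set, collapse = ""), "]")
    if (p$min == 1L && p$max == 1L) cls
    else paste0(cls, "{", p$min, ",", p$max, "}")
  }, character(1)), collapse = "")
}

#' Scan a protein for motif matches
#'
#' Reports one hit per matching start position: the shortest match that can be
#' anchored there (variable-length repeats expand non-greedily). Overlapping
#' starts are all reported; hits are ordered by start. Coordinates are 0-based
#' half-open on the protein.
#'
#' @param pattern a [compile_pattern()] result or pattern string.
#' @param protein a single protein string, or a named vector of length 1.
#' @param protein_id id to record in the hits (defaults to the name of
#'   `protein`, or `""`).
#' @return data.frame with columns `protein_id`, `start`, `end`, `match`
#'   (possibly 0 rows).
#' @export
scan_motif <- function(pattern, protein, protein_id = NULL) {
  if (is.character(pattern)) pattern <- compile_pattern(pattern)
  stopifnot(inherits(pattern, "motif_pattern"), length(protein) == 1L)
  if (is.null(protein_id))
    protein_id <- if (!is.null(names(protein))) names(protein) else ""
  seq <- toupper(as.character(protein))
  n <- nchar(seq)
  lo <- motif_min_length(pattern); hi <- motif_max_length(pattern)
  rx_prefix <- paste0("^(?:", pattern_regex(pattern), ")")
  hits <- list()
  for (s in seq_len(max(n - lo + 1L, 0L))) {
    tail_seq <- substr(seq, s, min(n, s + hi - 1L))
    if (regexpr(rx_prefix, tail_seq, perl = TRUE) == -1L) next
    # shortest anchored full match at this start
    for (len in lo:min(hi, nchar(tail_seq))) {
      cand <- substr(tail_seq, 1L, len)
      if (grepl(paste0(rx_prefix, "$"), cand, perl = TRUE)) {
        hits[[length(hits) + 1L]] <-
          data.frame(protein_id = protein_id, start = s - 1L,
                     end = s - 1L + len, match = cand,
                     stringsAsFactors = FALSE)
        break
      }
    }
  }
  if (length(hits) == 0L)
    return(data.frame(protein_id = character(), start = integer(),
                      end = integer(), match = character(),
                      stringsAsFactors = FALSE))
  do.call(rbind, hits)
}

#' The packaged CNGC motif patterns
#'
#' `stringent_pattern()` is the stringent plant-CNGC diagnostic motif spanning
#' the phosphate-binding cassette (PBC) and hinge within the CNBD;
#' `consensus_pattern()` is the broader plant consensus with optional
#' positions. Both are kept byte-exact to their published strings.
#'
#' @return a `motif_pattern`.
#' @export
stringent_pattern <- function() {
  compile_pattern(paste0(
    "L-X(2)-G-[ED]-ELL-[TSG]-W-[ACY]-L-X(10,20)-[SA]-X-T-X(7)-",
    "[EQ]-[AG]-F-X-L"))
}

#' @rdname stringent_pattern
#' @export
consensus_pattern <- function() {
  compile_pattern(paste0(
    "[LIMV0]-X(2)-[GSANCR]-X-[FVIYASCL]-X-G-X(0,1)-X(0,1)-[EDAQGH]-L-",
    "[LIVFA]-X-[WRCMLS0]-X-[LMSIQAFT0]-X(7,37)-[SAC]-X(9)-[VTIALMS]-",
    "X(0,1)-[EQDN]-[AGSVT]-[FYL]-X-[LIVF]"))
}

# Percent identity of the shorter sequence over a global alignment.
identity_over_shorter <- function(a, b) {
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b), type = "global",
    substitutionMatrix = NULL, gapOpening = 10, gapExtension = 0.5)
  Biostrings::pid(aln, type = "PID3")   # 100 * matches / shorter length
}

#' Identify gene-family candidates by motif scan
#'
#' The identification pipeline: every protein is scanned for the diagnostic
#' motif; candidates must carry at least one hit, be at least `min_length`
#' residues long, and not be redundant. Redundancy collapses exact duplicate
#' sequences and near-duplicates at or above `redundancy_identity` percent
#' identity over a global alignment of the shorter sequence, keeping the
#' longer member.
#'
#' @param proteome named character vector of protein sequences.
#' @param pattern a `motif_pattern` (default the stringent CNGC motif) or
#'   pattern string.
#' @param min_length minimum accepted length in residues (default 200).
#' @param redundancy_identity percent-identity threshold for collapsing
#'   near-duplicates (default 99).
#' @param candidates optional character vector of ids to restrict the scan to,
#'   e.g. an externally produced candidate list from a homology search.
#' @return object of class `identification_report`: a data.frame with one row
#'   per scanned protein and columns `id`, `length`, `motif_found`,
#'   `pass_length`, `redundant_with` (`NA` or the id kept instead), and
#'   `accepted`.
#' @export
identify_cngc <- function(proteome, pattern = stringent_pattern(),
                          min_length = 200L, redundancy_identity = 99,
                          candidates = NULL) {
  if (length(proteome) == 0L) {
    rep0 <- data.frame(id = character(), length = integer(),
                       motif_found = logical(), pass_length = logical(),
                       redundant_with = character(), accepted = logical(),
                       stringsAsFactors = FALSE)
    return(structure(rep0, class = c("identification_report", "data.frame")))
  }
  proteome <- validate_seqs(proteome, "protein")
  if (!is.null(candidates)) {
    missing <- setdiff(candidates, names(proteome))
    if (length(missing)) stop("candidate id(s) not in proteome: ",
                              paste(missing, collapse = ", "))
    proteome <- proteome[names(proteome) %in% candidates]
  }
  if (is.character(pattern)) pattern <- compile_pattern(pattern)
  ids <- names(proteome)
  lens <- nchar(proteome)
  motif_found <- vapply(ids, function(id) {
    nrow(scan_motif(pattern, proteome[[id]], id)) > 0L
  }, logical(1))
  pass_length <- lens >= min_length
  redundant_with <- rep(NA_character_, length(ids))
  # redundancy is judged among records passing the other two filters,
  # longest first so the longer member of a near-duplicate pair is kept
  pool <- ids[motif_found & pass_length]
  pool <- pool[order(-lens[match(pool, ids)], pool)]
  kept <- character()
  for (id in pool) {
    dup_of <- NA_character_
    for (k in kept) {
      if (proteome[[id]] == proteome[[k]] ||
          identity_over_shorter(proteome[[id]], proteome[[k]]) >= redundancy_identity) {
        dup_of <- k
        break
      }
    }
    if (is.na(dup_of)) kept <- c(kept, id) else
      redundant_with[match(id, ids)] <- dup_of
  }
  rep <- data.frame(id = ids, length = as.integer(lens),
                    motif_found = motif_found, pass_length = pass_length,
                    redundant_with = redundant_with,
                    accepted = motif_found & pass_length & is.na(redundant_with),
                    stringsAsFactors = FALSE, row.names = NULL)
  structure(rep, class = c("identification_report", "data.frame"))
}

#' @export
print.identification_report <- function(x, ...) {
  cat("Family identification: ", sum(x$accepted), " accepted of ",
      nrow(x), " scanned (", sum(x$motif_found), " with motif, ",
      sum(!x$pass_length), " below length cutoff, ",
      sum(!is.na(x$redundant_with)), " redundant)\n", sep = "")
  NextMethod()
}
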