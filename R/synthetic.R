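# Seeded generators that emulate the inputs of each pipeline stage: proteins
# carrying (or lacking) the diagnostic PBC+hinge motif, genes with planted
# GT..AG introns, promoters with planted IUPAC elements, codon duplicate
# pairs at controlled divergence, tissue-specific FPKM matrices, and simple
# clade-structured protein alignments. Every generator is a pure function of
# its arguments: the RNG state is set from `seed` on entry and restored on
# exit.

with_seed <- function(seed, expr) {
  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, globalenv())
  })
  set.seed(seed)
  force(expr)
}

random_protein <- function(length) {
  paste(sample(AA_LETTERS, length, replace = TRUE), collapse = "")
}

random_dna <- function(length) {
  paste(sample(DNA_LETTERS, length, replace = TRUE), collapse = "")
}

#' Expand a motif pattern to a random realization
#'
#' Draws one string accepted by the pattern: each position run picks a repeat
#' count uniformly in `[min, max]` and residues uniformly from its allowed
#' set. Any string produced is matched by the pattern it came from.
#'
#' @param pattern a [compile_pattern()] result.
#' @param seed integer seed, or `NULL` to use the current RNG state.
#' @return a single string.
#' @export
expand_pattern <- function(pattern, seed = NULL) {
  stopifnot(inherits(pattern, "motif_pattern"))
  draw <- function() {
    paste(vapply(pattern$positions, function(p) {
      k <- if (p$max > p$min) sample(p$min:p$max, 1L) else p$min
      if (k == 0L) return("")
      paste(sample(p$set, k, replace = TRUE), collapse = "")
    }, character(1)), collapse = "")
  }
  if (is.null(seed)) draw() else with_seed(seed, draw())
}

#' Generate a CNGC-like protein with a planted diagnostic motif
#'
#' A random background sequence with one expansion of `pattern` inserted at a
#' recorded position, so the motif scanner recovers it by construction.
#'
#' @param seed integer seed.
#' @param length total protein length (default 650 aa, mid-range for plant
#'   CNGCs).
#' @param pattern diagnostic pattern (default [stringent_pattern()]).
#' @param id record id.
#' @return list with `record` (named character vector of length 1),
#'   `motif_start` (0-based), `motif_seq`.
#' @export
gen_cngc_protein <- function(seed, length = 650L, pattern = stringent_pattern(),
                             id = "cngc") {
  if (length < motif_min_length(pattern))
    stop("protein length shorter than the minimal motif span")
  with_seed(seed, {
    motif <- expand_pattern(pattern)
    m <- nchar(motif)
    start <- sample.int(length - m + 1L, 1L) - 1L   # 0-based
    bg <- random_protein(length - m)
    seq <- paste0(substr(bg, 1L, start), motif,
                  substr(bg, start + 1L, nchar(bg)))
    list(record = stats::setNames(seq, id), motif_start = start,
         motif_seq = motif)
  })
}

#' Generate a decoy (AKT/KAT-like) protein without the diagnostic motif
#'
#' Emulates the key false-positive class of CNGC identification: channel-like
#' proteins that must not match the diagnostic motif. Random backgrounds are
#' rejection-sampled until the scanner finds no hit.
#'
#' @param seed integer seed.
#' @param length protein length.
#' @param pattern pattern that must not match.
#' @param id record id.
#' @return named character vector of length 1.
#' @export
gen_decoy_protein <- function(seed, length = 650L,
                              pattern = stringent_pattern(), id = "decoy") {
  with_seed(seed, {
    for (i in 1:100) {
      seq <- random_protein(length)
      if (nrow(scan_motif(pattern, seq, id)) == 0L)
        return(stats::setNames(seq, id))
    }
    stop("could not sample a motif-free decoy")   # astronomically unlikely
  })
}

#' Generate a mixed proteome with known family membership
#'
#' `n_cngc` motif-carrying proteins and `n_decoy` motif-free decoys, lengths
#' drawn uniformly from `length_range` (default 326-745 aa, the observed
#' range of maize CNGC lengths).
#'
#' @param seed integer seed.
#' @param n_cngc,n_decoy member counts (defaults 12 and 11, the survey's
#'   CNGC and AKT/KAT set sizes).
#' @param length_range length range in residues.
#' @param pattern diagnostic pattern.
#' @return list with `proteome` (named character vector, CNGCs first),
#'   `truth` (data.frame: id, is_cngc, motif_start).
#' @export
gen_proteome <- function(seed, n_cngc = 12L, n_decoy = 11L,
                         length_range = c(326L, 745L),
                         pattern = stringent_pattern()) {
  with_seed(seed, {
    sub_seeds <- sample.int(.Machine$integer.max - 1L, n_cngc + n_decoy)
    lens <- sample(length_range[1]:length_range[2], n_cngc + n_decoy,
                   replace = TRUE)
    seqs <- character(0); truth <- list()
    for (i in seq_len(n_cngc)) {
      g <- gen_cngc_protein(sub_seeds[i], lens[i], pattern,
                            id = sprintf("CNGC%02d", i))
      seqs <- c(seqs, g$record)
      truth[[length(truth) + 1L]] <- data.frame(
        id = names(g$record), is_cngc = TRUE, motif_start = g$motif_start,
        stringsAsFactors = FALSE)
    }
    for (i in seq_len(n_decoy)) {
      rec <- gen_decoy_protein(sub_seeds[n_cngc + i], lens[n_cngc + i],
                               pattern, id = sprintf("AKT%02d", i))
      seqs <- c(seqs, rec)
      truth[[length(truth) + 1L]] <- data.frame(
        id = names(rec), is_cngc = FALSE, motif_start = NA_integer_,
        stringsAsFactors = FALSE)
    }
    list(proteome = seqs, truth = do.call(rbind, truth))
  })
}

random_cds <- function(n_codons, start_codon = TRUE) {
  cods <- sample(sense_codons(), n_codons, replace = TRUE)
  if (start_codon) cods[1L] <- "ATG"
  paste(cods, collapse = "")
}

#' Generate a gene model with planted canonical introns
#'
#' A random CDS (no internal stops) is interrupted by `n_introns` GT..AG
#' introns at recorded positions and phases, with random flanks on both
#' sides. The generator verifies that [infer_structure()]'s preference rules
#' (canonical, leftmost) recover exactly the planted chain and redraws the
#' rare ambiguous layouts, so the recorded structure is the unique preferred
#' solution.
#'
#' @param seed integer seed.
#' @param n_codons CDS length in codons (default 400).
#' @param n_introns intron count, 0-7 (default drawn uniformly from 0:7, the
#'   observed maize CNGC range).
#' @param intron_length_range intron lengths in bp, minimum 20.
#' @param flank_range length range of the flanks added on each side.
#' @param gene_id id recorded on the model.
#' @return list with `model` (the planted [gene_model()]), `cds`, `genomic`,
#'   `phases` (planted intron phases).
#' @export
gen_gene_model <- function(seed, n_codons = 400L, n_introns = NULL,
                           intron_length_range = c(60L, 300L),
                           flank_range = c(50L, 300L), gene_id = "gene") {
  stopifnot(intron_length_range[1] >= 20L)
  with_seed(seed, {
    if (is.null(n_introns)) n_introns <- sample(0:7, 1L)
    stopifnot(n_introns >= 0L, n_introns <= n_codons - 1L)
    for (attempt in 1:50) {
      cds <- random_cds(n_codons)
      cds_len <- nchar(cds)
      cut_pool <- setdiff(seq_len(cds_len - 1L), 0L)
      cuts <- sort(sample(cut_pool, n_introns))
      introns <- vapply(seq_len(max(n_introns, 0L)), function(i) {
        len <- sample(intron_length_range[1]:intron_length_range[2], 1L)
        paste0("GT", random_dna(len - 4L), "AG")
      }, character(1))
      left <- random_dna(sample(flank_range[1]:flank_range[2], 1L))
      right <- random_dna(sample(flank_range[1]:flank_range[2], 1L))
      # assemble genomic and record exon intervals (0-based half-open)
      pieces <- character(0)
      exon_bounds <- c(0L, cuts, cds_len)
      pos <- nchar(left)
      exons <- matrix(0L, nrow = n_introns + 1L, ncol = 2L)
      pieces <- left
      for (k in seq_len(n_introns + 1L)) {
        ex_seq <- substr(cds, exon_bounds[k] + 1L, exon_bounds[k + 1L])
        exons[k, ] <- c(pos, pos + nchar(ex_seq))
        pieces <- c(pieces, ex_seq)
        pos <- pos + nchar(ex_seq)
        if (k <= n_introns) {
          pieces <- c(pieces, introns[k])
          pos <- pos + nchar(introns[k])
        }
      }
      pieces <- c(pieces, right)
      genomic <- paste(pieces, collapse = "")
      model <- gene_model(gene_id, genomic, exons, "+")
      inferred <- try(infer_structure(cds, genomic, gene_id), silent = TRUE)
      if (!inherits(inferred, "try-error") &&
          identical(unname(inferred$exons), unname(exons)) &&
          inferred$strand == "+") {
        return(list(model = model, cds = cds, genomic = genomic,
                    phases = as.integer(cuts %% 3L)))
      }
    }
    stop("could not plant an unambiguous gene structure")
  })
}

# single-nucleotide non-stop neighbours of `codon` of the requested class
codon_options <- function(codon, synonymous) {
  gc <- genetic_code()
  out <- character(0)
  for (pos in 1:3) {
    orig <- substr(codon, pos, pos)
    for (nt in setdiff(DNA_LETTERS, orig)) {
      mut <- codon
      substr(mut, pos, pos) <- nt
      if (gc[[mut]] == "*") next
      if ((gc[[mut]] == gc[[codon]]) == synonymous) out <- c(out, mut)
    }
  }
  out
}

# single-nucleotide changes of `codon` at ts/tv-weighted random, restricted
# to synonymous or nonsynonymous non-stop outcomes
mutate_codon <- function(codon, synonymous, ts_tv) {
  gc <- genetic_code()
  transitions <- c(A = "G", G = "A", C = "T", T = "C")
  opts <- list()
  for (pos in 1:3) {
    orig <- substr(codon, pos, pos)
    for (nt in setdiff(DNA_LETTERS, orig)) {
      mut <- codon
      substr(mut, pos, pos) <- nt
      if (gc[[mut]] == "*") next
      syn <- gc[[mut]] == gc[[codon]]
      if (syn != synonymous) next
      w <- if (transitions[[orig]] == nt) ts_tv else 1
      opts[[length(opts) + 1L]] <- list(mut = mut, w = w)
    }
  }
  if (length(opts) == 0L) return(NULL)
  w <- vapply(opts, `[[`, numeric(1), "w")
  opts[[sample.int(length(opts), 1L, prob = w)]]$mut
}

#' Generate a duplicate CDS pair with controlled divergence
#'
#' Copies a random ancestor CDS and applies `Poisson(S * pS)` synonymous and
#' `Poisson(N * pN)` nonsynonymous single-nucleotide codon changes to one
#' copy, with transition/transversion bias and stop codons rejected. The raw
#' proportions pS, pN are chosen so the Jukes-Cantor-corrected rates target
#' `target_ks` and `target_ka = omega * target_ks`. The realized event
#' counts are recorded as truth.
#'
#' @param seed integer seed.
#' @param n_codons CDS length in codons (default 900).
#' @param target_ks target synonymous rate (<= 0.7).
#' @param omega target Ka/Ks ratio (<= 1). Defaults 0.18 and 0.14, the
#'   magnitudes of the maize within-genome duplication pair.
#' @param ts_tv transition/transversion rate ratio (default 2).
#' @return list with `cds_a`, `cds_b`, `target_ks`, `target_ka`,
#'   `n_syn_events`, `n_nonsyn_events`.
#' @export
gen_duplicate_pair <- function(seed, n_codons = 900L, target_ks = 0.18,
                               omega = 0.14, ts_tv = 2) {
  stopifnot(target_ks >= 0, target_ks <= 0.7, omega >= 0, omega <= 1)
  with_seed(seed, {
    anc <- random_cds(n_codons, start_codon = FALSE)
    cods <- split_codons(anc)
    tb <- ng86_tables()
    S <- sum(tb$s_sites[cods]); N <- 3 * n_codons - S
    raw_p <- function(rate) 3 / 4 * (1 - exp(-4 / 3 * rate))
    n_syn <- stats::rpois(1L, S * raw_p(target_ks))
    n_non <- stats::rpois(1L, N * raw_p(target_ks * omega))
    # changes land on distinct codons per class, so the observed difference
    # proportion matches the Jukes-Cantor inversion of the target rate in
    # expectation (multiple hits would deflate it)
    applied_syn <- 0L; applied_non <- 0L
    syn_ok <- which(vapply(cods, function(cd)
      length(codon_options(cd, TRUE)) > 0L, logical(1)))
    if (n_syn > length(syn_ok)) stop("no synonymous positions left")
    for (k in sample(syn_ok, min(n_syn, length(syn_ok)))) {
      cods[k] <- mutate_codon(cods[k], synonymous = TRUE, ts_tv)
      applied_syn <- applied_syn + 1L
    }
    non_ok <- which(vapply(cods, function(cd)
      length(codon_options(cd, FALSE)) > 0L, logical(1)))
    for (k in sample(non_ok, min(n_non, length(non_ok)))) {
      cods[k] <- mutate_codon(cods[k], synonymous = FALSE, ts_tv)
      applied_non <- applied_non + 1L
    }
    list(cds_a = anc, cds_b = paste(cods, collapse = ""),
         target_ks = target_ks, target_ka = target_ks * omega,
         n_syn_events = applied_syn, n_nonsyn_events = applied_non)
  })
}

#' Generate a promoter with planted cis-elements
#'
#' Instantiates each requested element from its IUPAC pattern (random base
#' per degenerate code), places the instances at non-overlapping random
#' positions and strands in a random background of `length` bp (default
#' 1,500 bp, the upstream window used for promoter scans).
#'
#' @param seed integer seed.
#' @param elements data.frame with `element_id`, `iupac` rows to plant (may
#'   repeat ids to plant several copies).
#' @param length promoter length in bp.
#' @param both_strands plant on random strands (default TRUE).
#' @param id promoter/gene id.
#' @return list with `record` (named character vector), `planted`
#'   (data.frame gene_id, element_id, start (0-based), strand, match).
#' @export
gen_promoter <- function(seed, elements, length = 1500L, both_strands = TRUE,
                         id = "promoter") {
  n_el <- nrow(elements)
  if (n_el > 0L && sum(nchar(elements$iupac)) > length)
    stop("planted elements do not fit in the promoter")
  with_seed(seed, {
    bg <- strsplit(random_dna(length), "")[[1]]
    occupied <- rep(FALSE, length)
    planted <- list()
    for (i in seq_len(n_el)) {
      iupac <- toupper(elements$iupac[i])
      m <- nchar(iupac)
      inst <- paste(vapply(strsplit(iupac, "")[[1]], function(ch) {
        sample(IUPAC_SETS[[ch]], 1L)
      }, character(1)), collapse = "")
      strand <- if (both_strands && stats::runif(1) < 0.5) "-" else "+"
      placed_seq <- if (strand == "+") inst else revcomp(inst)
      ok <- FALSE
      for (try in 1:500) {
        s <- sample.int(length - m + 1L, 1L)      # 1-based start
        if (!any(occupied[s:(s + m - 1L)])) { ok <- TRUE; break }
      }
      if (!ok) stop("could not place element ", elements$element_id[i],
                    " without overlap")
      bg[s:(s + m - 1L)] <- strsplit(placed_seq, "")[[1]]
      occupied[s:(s + m - 1L)] <- TRUE
      planted[[length(planted) + 1L]] <- data.frame(
        gene_id = id, element_id = elements$element_id[i],
        start = s - 1L, strand = strand, match = inst,
        stringsAsFactors = FALSE)
    }
    planted <- if (length(planted)) do.call(rbind, planted) else
      data.frame(gene_id = character(), element_id = character(),
                 start = integer(), strand = character(), match = character(),
                 stringsAsFactors = FALSE)
    list(record = stats::setNames(paste(bg, collapse = ""), id),
         planted = planted)
  })
}

#' Generate an FPKM matrix with planted expression classes
#'
#' Tissue-specific genes get one dominant log-normal tissue and low
#' background elsewhere; uniform genes near-equal moderate values; silent
#' genes all values below the expressed threshold.
#'
#' @param seed integer seed.
#' @param n_specific,n_uniform,n_silent gene counts per class (defaults
#'   8/3/1, echoing a 12-gene family with one silent pseudogene-like member).
#' @param tissues tissue labels (default the six-survey set).
#' @param expressed_threshold threshold used for the silent class.
#' @return list with `fpkm` (matrix) and `truth` (data.frame gene_id, class,
#'   specific_tissue).
#' @export
gen_fpkm <- function(seed, n_specific = 8L, n_uniform = 3L, n_silent = 1L,
                     tissues = c("ear", "embryo", "endosperm", "pollen",
                                 "root", "tassel"),
                     expressed_threshold = 1.0) {
  stopifnot(length(tissues) >= 2L)
  with_seed(seed, {
    n_genes <- n_specific + n_uniform + n_silent
    ids <- sprintf("GENE%02d", seq_len(n_genes))
    m <- matrix(0, n_genes, length(tissues),
                dimnames = list(ids, tissues))
    truth <- data.frame(gene_id = ids,
                        class = rep(c("specific", "uniform", "silent"),
                                    c(n_specific, n_uniform, n_silent)),
                        specific_tissue = NA_character_,
                        stringsAsFactors = FALSE)
    for (i in seq_len(n_genes)) {
      if (truth$class[i] == "specific") {
        top <- sample(seq_along(tissues), 1L)
        m[i, ] <- stats::rlnorm(length(tissues), log(0.3), 0.4)
        m[i, top] <- stats::rlnorm(1L, log(80), 0.5)
        truth$specific_tissue[i] <- tissues[top]
      } else if (truth$class[i] == "uniform") {
        base <- stats::rlnorm(1L, log(20), 0.3)
        m[i, ] <- base * stats::runif(length(tissues), 0.95, 1.05)
      } else {
        m[i, ] <- stats::runif(length(tissues), 0, expressed_threshold * 0.5)
      }
    }
    list(fpkm = m, truth = truth)
  })
}

#' Generate a clade-structured protein alignment
#'
#' Evolves a random ancestral sequence into `n_clades` well-separated clades
#' of `n_per_clade` leaves each: heavy substitution between clades, light
#' substitution within. Useful for bootstrap and group-assignment checks;
#' leaves are named `<clade>_<i>` and the clade labels are the ground truth.
#'
#' @param seed integer seed.
#' @param n_clades,n_per_clade clade layout.
#' @param length alignment length in residues.
#' @param between,within expected substitutions per site between and within
#'   clades.
#' @param clade_labels optional labels (default LETTERS).
#' @return list with `msa` (named character vector) and `truth` (named
#'   character vector leaf -> clade label).
#' @export
gen_clade_msa <- function(seed, n_clades = 2L, n_per_clade = 4L, length = 200L,
                          between = 0.6, within = 0.05,
                          clade_labels = LETTERS[seq_len(n_clades)]) {
  with_seed(seed, {
    mutate <- function(seq_chars, rate) {
      n_mut <- stats::rpois(1L, rate * length(seq_chars))
      if (n_mut == 0L) return(seq_chars)
      pos <- sample.int(length(seq_chars), min(n_mut, length(seq_chars)))
      seq_chars[pos] <- sample(AA_LETTERS, length(pos), replace = TRUE)
      seq_chars
    }
    root <- strsplit(random_protein(length), "")[[1]]
    msa <- character(0); truth <- character(0)
    for (cl in seq_len(n_clades)) {
      anc <- mutate(root, between)
      for (i in seq_len(n_per_clade)) {
        leaf <- paste(mutate(anc, within), collapse = "")
        nm <- paste0(clade_labels[cl], "_", i)
        msa[nm] <- leaf
        truth[nm] <- clade_labels[cl]
      }
    }
    list(msa = msa, truth = truth)
  })
}
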