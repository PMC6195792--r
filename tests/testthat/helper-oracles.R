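# Independent brute-force oracles. These re-derive expected results by the
# most literal method available and deliberately share no code path with the
# package internals they check.

# --- motif scanning: position-by-position backtracking matcher -------------

# does pattern (a motif_pattern's position list) match seq[start..start+len-1]
# exactly?
oracle_match_here <- function(positions, chars, start, len) {
  rec <- function(pi, si) {
    if (pi > length(positions)) return(si == start + len)
    p <- positions[[pi]]
    for (k in p$min:p$max) {
      if (si + k > start + len + 1) break
      ok <- TRUE
      if (k > 0) {
        for (t in seq_len(k)) {
          if (!(chars[si + t - 1] %in% p$set)) { ok <- FALSE; break }
        }
      }
      if (ok && rec(pi + 1, si + k)) return(TRUE)
    }
    FALSE
  }
  rec(1, start)
}

# all (start, shortest-len) hits, 0-based half-open, like scan_motif
oracle_scan <- function(pattern, seq) {
  chars <- strsplit(seq, "")[[1]]
  n <- length(chars)
  lo <- motif_min_length(pattern); hi <- motif_max_length(pattern)
  hits <- NULL
  for (s in seq_len(n)) {
    for (len in lo:hi) {
      if (s + len - 1 > n) break
      if (oracle_match_here(pattern$positions, chars, s, len)) {
        hits <- rbind(hits, data.frame(start = s - 1L, end = s - 1L + len))
        break
      }
    }
  }
  if (is.null(hits)) data.frame(start = integer(), end = integer()) else hits
}

# a random syntactically valid PROSITE-dialect pattern
oracle_random_pattern <- function() {
  aas <- c("A","C","D","E","F","G","H","I","K","L","M","N","P","Q","R",
           "S","T","V","W","Y")
  n_tok <- sample(3:6, 1)
  toks <- vapply(seq_len(n_tok), function(i) {
    kind <- sample(c("lit", "set", "x", "xrep", "setrep"), 1)
    switch(kind,
      lit = sample(aas, 1),
      set = paste0("[", paste(sample(aas, sample(2:4, 1)), collapse = ""), "]"),
      x = "X",
      xrep = {
        a <- sample(0:3, 1); b <- a + sample(0:3, 1)
        paste0("X(", a, ",", b, ")")
      },
      setrep = paste0("[", paste(sample(aas, 2), collapse = ""), "](",
                      sample(1:2, 1), ")"))
  }, character(1))
  paste(toks, collapse = "-")
}

# --- NG86: literal path enumeration over codon pairs -----------------------

oracle_codon_table <- local({
  tab <- NULL
  function() {
    if (is.null(tab)) {
      gc <- Biostrings::GENETIC_CODE
      tab <<- stats::setNames(as.character(gc), names(gc))
    }
    tab
  }
})

oracle_perms <- function(v) {
  if (length(v) <= 1) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (rest in oracle_perms(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
  }
  out
}

oracle_pair_diffs <- function(ca, cb) {
  gc <- oracle_codon_table()
  a <- strsplit(ca, "")[[1]]; b <- strsplit(cb, "")[[1]]
  dp <- which(a != b)
  if (length(dp) == 0) return(c(sd = 0, nd = 0))
  paths <- oracle_perms(dp)
  tallies <- list()
  for (ord in paths) {
    cur <- a; sd <- 0; nd <- 0; blocked <- FALSE
    for (pos in ord) {
      nxt <- cur; nxt[pos] <- b[pos]
      c_cur <- paste(cur, collapse = ""); c_nxt <- paste(nxt, collapse = "")
      if (gc[[c_nxt]] == "*") blocked <- TRUE
      if (gc[[c_nxt]] != "*" && gc[[c_cur]] != "*" &&
          gc[[c_nxt]] == gc[[c_cur]]) sd <- sd + 1 else nd <- nd + 1
      cur <- nxt
    }
    tallies[[length(tallies) + 1]] <- list(sd = sd, nd = nd, blocked = blocked)
  }
  ok <- Filter(function(t) !t$blocked, tallies)
  use <- if (length(ok)) ok else tallies
  c(sd = mean(vapply(use, `[[`, numeric(1), "sd")),
    nd = mean(vapply(use, `[[`, numeric(1), "nd")))
}

oracle_sdnd <- function(cds_a, cds_b) {
  n <- nchar(cds_a) / 3
  sd <- 0; nd <- 0
  for (i in seq_len(n)) {
    ca <- substr(cds_a, 3 * i - 2, 3 * i)
    cb <- substr(cds_b, 3 * i - 2, 3 * i)
    d <- oracle_pair_diffs(ca, cb)
    sd <- sd + d[["sd"]]; nd <- nd + d[["nd"]]
  }
  c(sd = sd, nd = nd)
}

oracle_random_sense_cds <- function(n_codons) {
  gc <- oracle_codon_table()
  sense <- names(gc)[gc != "*"]
  paste(sample(sense, n_codons, replace = TRUE), collapse = "")
}

# --- promoter scanning: sliding window over IUPAC sets ---------------------

oracle_iupac_sets <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A","G"), Y = c("C","T"), S = c("C","G"), W = c("A","T"),
  K = c("G","T"), M = c("A","C"), B = c("C","G","T"), D = c("A","G","T"),
  H = c("A","C","T"), V = c("A","C","G"), N = c("A","C","G","T"))

oracle_scan_strand <- function(seq, iupac) {
  chars <- strsplit(seq, "")[[1]]
  pat <- strsplit(iupac, "")[[1]]
  m <- length(pat); n <- length(chars)
  starts <- integer(0)
  if (m > n) return(starts)
  for (s in 1:(n - m + 1)) {
    ok <- TRUE
    for (t in seq_len(m)) {
      if (!(chars[s + t - 1] %in% oracle_iupac_sets[[pat[t]]])) { ok <- FALSE; break }
    }
    if (ok) starts <- c(starts, s - 1L)
  }
  starts
}

oracle_revcomp <- function(x) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  paste(rev(comp[strsplit(x, "")[[1]]]), collapse = "")
}

# --- distances -------------------------------------------------------------

oracle_poisson_pair <- function(a, b) {
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  use <- ca != "-" & cb != "-" & ca != "X" & cb != "X"
  p <- sum(ca[use] != cb[use]) / sum(use)
  -log(1 - p)
}

# random additive distance matrix from a random binary tree; returns both
random_additive_case <- function(n_taxa) {
  tr <- ape::rtree(n_taxa, br = function(n) stats::runif(n, 0.2, 1))
  tr$tip.label <- sort(tr$tip.label)
  D <- ape::cophenetic.phylo(tr)
  D <- D[order(rownames(D)), order(colnames(D))]
  list(tree = tr, D = D)
}

rf_dist <- function(t1, t2) {
  phangorn::RF.dist(ape::unroot(t1), ape::unroot(t2))
}
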