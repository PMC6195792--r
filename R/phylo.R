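#' Poisson-corrected protein distance matrix
#'
#' For each pair of aligned rows, sites where either sequence has a gap (`-`)
#' or `X` are deleted pairwise; p is the fraction of differing compared
#' sites, and the Poisson-corrected distance is `-ln(1 - p)`. A pair with
#' `p >= 1 - 1e-12` is saturated: its distance is set to `-ln(1e-12)` and
#' flagged in the `"saturated"` attribute.
#'
#' @param msa named character vector of equal-length aligned protein
#'   sequences.
#' @return symmetric numeric matrix with taxa names, zero diagonal, and a
#'   logical `"saturated"` attribute matrix.
#' @export
poisson_distance <- function(msa) {
  if (length(msa) < 2L) stop("alignment must contain at least 2 sequences")
  ids <- names(msa)
  if (is.null(ids) || any(!nzchar(ids))) stop("all rows must be named")
  if (length(unique(nchar(msa))) != 1L)
    stop("alignment rows differ in length")
  mat <- do.call(rbind, strsplit(toupper(msa), ""))
  rownames(mat) <- ids
  ok <- mat != "-" & mat != "X"
  n <- length(ids)
  D <- matrix(0, n, n, dimnames = list(ids, ids))
  sat <- matrix(FALSE, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      comp <- ok[i, ] & ok[j, ]
      m <- sum(comp)
      if (m == 0L)
        stop("no comparable sites for pair ", ids[i], " / ", ids[j])
      p <- sum(mat[i, comp] != mat[j, comp]) / m
      if (p >= 1 - 1e-12) {
        D[i, j] <- D[j, i] <- -log(1e-12)
        sat[i, j] <- sat[j, i] <- TRUE
      } else {
        D[i, j] <- D[j, i] <- -log(1 - p)
      }
    }
  }
  attr(D, "saturated") <- sat
  D
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei neighbor joining with the Q criterion. Ties in Q are broken
#' deterministically toward the lexicographically smallest taxon pair (each
#' internal node inherits the smaller of its children's labels for
#' tie-breaking). Negative branch lengths are clamped to zero with the
#' deficit moved to the sibling edge, so total path lengths are preserved.
#'
#' @param D symmetric distance matrix with taxon names (from
#'   [poisson_distance()] or any additive/near-additive source).
#' @return unrooted [ape::phylo] tree (trifurcating root node).
#' @export
nj_tree <- function(D) {
  if (!isTRUE(all.equal(D, t(D), check.attributes = FALSE)))
    stop("distance matrix is not symmetric")
  ids <- rownames(D)
  if (is.null(ids) || length(ids) < 3L) stop("need >= 3 named taxa")
  # working copies: `node` holds the Newick fragment for each active cluster,
  # `label` its tie-break key
  d <- D; storage.mode(d) <- "double"
  node <- ids
  label <- ids
  fmt <- function(x) formatC(max(x, 0), format = "g", digits = 15)
  while (length(node) > 3L) {
    n <- length(node)
    r <- rowSums(d)
    Q <- (n - 2) * d - outer(r, r, "+")
    diag(Q) <- Inf
    best <- NULL; best_q <- Inf; best_key <- NULL
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        key <- paste(sort(c(label[i], label[j])), collapse = "\r")
        if (Q[i, j] < best_q - 1e-12 ||
            (abs(Q[i, j] - best_q) <= 1e-12 && !is.null(best_key) &&
             key < best_key)) {
          best <- c(i, j); best_q <- Q[i, j]; best_key <- key
        }
      }
    }
    i <- best[1]; j <- best[2]
    bi <- d[i, j] / 2 + (r[i] - r[j]) / (2 * (n - 2))
    bj <- d[i, j] - bi
    if (bi < 0) { bj <- bj + bi; bi <- 0 }
    if (bj < 0) { bi <- bi + bj; bj <- 0 }
    new_node <- paste0("(", node[i], ":", fmt(bi), ",",
                       node[j], ":", fmt(bj), ")")
    new_label <- min(label[i], label[j])
    du <- (d[i, ] + d[j, ] - d[i, j]) / 2
    keep <- setdiff(seq_len(n), c(i, j))
    d <- rbind(cbind(d[keep, keep, drop = FALSE], du[keep]),
               c(du[keep], 0))
    node <- c(node[keep], new_node)
    label <- c(label[keep], new_label)
  }
  # closing trifurcation: three-point formulas
  b1 <- (d[1, 2] + d[1, 3] - d[2, 3]) / 2
  b2 <- (d[1, 2] + d[2, 3] - d[1, 3]) / 2
  b3 <- (d[1, 3] + d[2, 3] - d[1, 2]) / 2
  ord <- order(label)
  bl <- c(b1, b2, b3)[ord]
  nodes <- node[ord]
  nwk <- paste0("(", nodes[1], ":", fmt(bl[1]), ",", nodes[2], ":", fmt(bl[2]),
                ",", nodes[3], ":", fmt(bl[3]), ");")
  ape::read.tree(text = nwk)
}

# Canonical bipartition keys of a tree: for every internal edge, the leaf set
# on the side not containing the alphabetically first taxon, as a collapsed
# string. Trivial (pendant) splits are skipped.
bipartition_keys <- function(tree) {
  tips <- sort(tree$tip.label)
  ref <- tips[1L]
  n_tip <- length(tree$tip.label)
  keys <- character(0)
  node_ids <- integer(0)
  # clade tip sets per internal node (rooted representation)
  for (node in (n_tip + 1L):(n_tip + tree$Nnode)) {
    clade <- ape::extract.clade(tree, node)$tip.label
    side <- if (ref %in% clade) setdiff(tree$tip.label, clade) else clade
    if (length(side) < 2L || length(side) > n_tip - 2L) next
    keys <- c(keys, paste(sort(side), collapse = "\r"))
    node_ids <- c(node_ids, node)
  }
  list(keys = keys, nodes = node_ids)
}

#' Bootstrap supports for a neighbor-joining protein tree
#'
#' Builds the full-data tree with [poisson_distance()] + [nj_tree()], then
#' resamples alignment columns with replacement `n_reps` times and records,
#' for each internal bipartition of the full tree, the percentage of
#' replicate trees containing it. Supports are attached as internal-node
#' labels. Fully reproducible for a fixed `seed`.
#'
#' @param msa named character vector of aligned protein sequences.
#' @param n_reps number of bootstrap replicates (>= 1).
#' @param seed integer RNG seed.
#' @return [ape::phylo] tree with `node.label` holding integer percent
#'   supports (empty for the root).
#' @export
bootstrap_support <- function(msa, n_reps = 1000L, seed = 1L) {
  stopifnot(n_reps >= 1L)
  msa <- msa[order(names(msa))]   # taxon input order must not matter
  full <- nj_tree(poisson_distance(msa))
  bp <- bipartition_keys(full)
  hit <- stats::setNames(numeric(length(bp$keys)), bp$keys)
  len <- nchar(msa[[1L]])
  chars <- do.call(rbind, strsplit(toupper(msa), ""))
  rownames(chars) <- names(msa)
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  for (rep in seq_len(n_reps)) {
    cols <- sample.int(len, len, replace = TRUE)
    rep_msa <- apply(chars[, cols, drop = FALSE], 1L, paste, collapse = "")
    tr <- try(nj_tree(poisson_distance(rep_msa)), silent = TRUE)
    if (inherits(tr, "try-error")) next
    rep_keys <- bipartition_keys(tr)$keys
    found <- bp$keys %in% rep_keys
    hit[found] <- hit[found] + 1
  }
  support <- round(100 * hit / n_reps)
  n_tip <- length(full$tip.label)
  labels <- rep("", full$Nnode)
  labels[bp$nodes - n_tip] <- as.character(as.integer(support))
  full$node.label <- labels
  full
}

#' Assign query leaves to reference groups on a tree
#'
#' Each unlabeled leaf takes the group of the smallest split (side of an
#' edge of the unrooted tree) containing it whose labeled members exist and
#' are unanimous; if the smallest labeled split is mixed, the leaf is
#' `unplaced`.
#'
#' @param tree an [ape::phylo] tree.
#' @param references named character vector mapping reference leaf names to
#'   group labels; every group should have at least 2 reference leaves.
#' @return named character vector mapping every non-reference leaf to a
#'   group label or `"unplaced"`.
#' @export
assign_groups <- function(tree, references) {
  stopifnot(inherits(tree, "phylo"))
  missing <- setdiff(names(references), tree$tip.label)
  if (length(missing))
    stop("reference leaf/leaves missing from tree: ",
         paste(missing, collapse = ", "))
  n_tip <- length(tree$tip.label)
  # all splits: both sides of every internal edge
  sides <- list()
  for (node in (n_tip + 1L):(n_tip + tree$Nnode)) {
    clade <- ape::extract.clade(tree, node)$tip.label
    if (length(clade) >= 2L && length(clade) <= n_tip - 1L) {
      sides[[length(sides) + 1L]] <- clade
      comp <- setdiff(tree$tip.label, clade)
      if (length(comp) >= 2L) sides[[length(sides) + 1L]] <- comp
    }
  }
  sizes <- vapply(sides, length, integer(1))
  sides <- sides[order(sizes)]
  queries <- setdiff(tree$tip.label, names(references))
  out <- stats::setNames(rep("unplaced", length(queries)), queries)
  for (q in queries) {
    for (side in sides) {
      if (!(q %in% side)) next
      labs <- unique(references[intersect(side, names(references))])
      if (length(labs) == 0L) next
      if (length(labs) == 1L) out[[q]] <- labs
      break   # smallest labeled split decides, unanimous or not
    }
  }
  out
}
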