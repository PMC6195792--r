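test_that("Poisson-corrected distances match hand and brute-force counts", {
  msa <- c(a = "MKVLWAACDE", b = "MKVLWAACDE")
  D <- poisson_distance(msa)
  expect_equal(D["a", "b"], 0)

  # 10 sites, 1 difference: p = 0.1, d = -ln(0.9)
  msa2 <- c(a = "MKVLWAACDE", b = "MKVLWAACDD")
  expect_equal(poisson_distance(msa2)["a", "b"], -log(0.9))

  # gaps are deleted pairwise
  msa3 <- c(a = "MKVL-AACDE", b = "MKWLWAAC-E")
  ora <- oracle_poisson_pair(msa3[["a"]], msa3[["b"]])
  expect_equal(poisson_distance(msa3)["a", "b"], ora)

  set.seed(5)
  msa4 <- vapply(1:5, function(i) {
    paste(sample(c("A", "C", "D", "E", "-"), 60, replace = TRUE,
                 prob = c(0.3, 0.3, 0.2, 0.15, 0.05)), collapse = "")
  }, character(1))
  names(msa4) <- paste0("t", 1:5)
  D4 <- poisson_distance(msa4)
  for (i in 1:4) for (j in (i + 1):5) {
    expect_equal(D4[i, j],
                 oracle_poisson_pair(msa4[[i]], msa4[[j]]))
  }
  expect_equal(D4, t(D4))
})

test_that("three taxa solve the closed-form branch lengths", {
  D <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- nj_tree(D)
  expect_setequal(tr$tip.label, c("a", "b", "c"))
  bl <- stats::setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(bl[["a"]], 1)   # (3 + 4 - 5) / 2
  expect_equal(bl[["b"]], 2)
  expect_equal(bl[["c"]], 3)
})

test_that("an additive 4-taxon matrix is reconstructed exactly", {
  tr0 <- ape::read.tree(text = "((a:1,b:2):1,(c:3,d:4):1);")
  D <- ape::cophenetic.phylo(tr0)
  got <- nj_tree(D)
  expect_equal(rf_dist(got, tr0), 0)
  # path lengths, not just topology, are recovered
  got_D <- ape::cophenetic.phylo(got)
  expect_equal(got_D[rownames(D), colnames(D)], D, tolerance = 1e-9)
  expect_error(nj_tree(matrix(c(0, 1, 2, 0), 2, dimnames = list(c("a", "b"), c("a", "b")))),
               "symmetric|taxa")
})

test_that("NJ reconstructs random additive trees of 4-8 taxa", {
  set.seed(17)
  for (i in 1:50) {
    case <- random_additive_case(sample(4:8, 1))
    got <- nj_tree(case$D)
    expect_equal(rf_dist(got, case$tree), 0, label = paste("case", i))
  }
})

test_that("NJ agrees with an independent implementation on noisy matrices", {
  set.seed(29)
  for (i in 1:10) {
    msa <- gen_clade_msa(i, n_clades = 3, n_per_clade = 3, length = 150)$msa
    D <- poisson_distance(msa)
    expect_equal(rf_dist(nj_tree(D), ape::nj(D)), 0, label = paste("msa", i))
  }
})

test_that("taxon input order does not change the topology", {
  msa <- gen_clade_msa(19, n_clades = 2, n_per_clade = 4, length = 120)$msa
  t1 <- nj_tree(poisson_distance(msa))
  perm <- sample(names(msa))
  t2 <- nj_tree(poisson_distance(msa[perm]))
  expect_equal(rf_dist(t1, t2), 0)
})

test_that("bootstrap supports are reproducible percentages on internal edges", {
  msa <- gen_clade_msa(3, n_clades = 2, n_per_clade = 4, length = 400,
                       between = 0.8, within = 0.05)
  tr <- bootstrap_support(msa$msa, n_reps = 1, seed = 7)
  sup <- suppressWarnings(as.integer(tr$node.label[nzchar(tr$node.label)]))
  expect_true(all(sup %in% c(0L, 100L)))

  # the two well-separated clades get >= 95% support
  tr2 <- bootstrap_support(msa$msa, n_reps = 200, seed = 3)
  keysupport <- function(tree, tips) {
    n_tip <- length(tree$tip.label)
    for (node in (n_tip + 1):(n_tip + tree$Nnode)) {
      clade <- sort(ape::extract.clade(tree, node)$tip.label)
      other <- sort(setdiff(tree$tip.label, clade))
      if (identical(clade, sort(tips)) || identical(other, sort(tips)))
        return(as.integer(tree$node.label[node - n_tip]))
    }
    NA_integer_
  }
  a_tips <- names(msa$truth)[msa$truth == "A"]
  expect_gte(keysupport(tr2, a_tips), 95L)

  # bit-reproducible for a fixed seed, invariant to taxon order
  tr3 <- bootstrap_support(msa$msa, n_reps = 200, seed = 3)
  expect_identical(ape::write.tree(tr2), ape::write.tree(tr3))
  tr4 <- bootstrap_support(msa$msa[sample(names(msa$msa))], n_reps = 200,
                           seed = 3)
  expect_identical(ape::write.tree(tr2), ape::write.tree(tr4))
})

test_that("group assignment follows the smallest unanimous split", {
  tr <- ape::read.tree(text = paste0(
    "((((r1:1,s1:1):1,o:1):1,q1:1):2,(r2:1,s2:1):2,(t1:1,t2:1,q2:1):2);"))
  refs <- c(r1 = "I", r2 = "I", s1 = "II", s2 = "II", t1 = "III", t2 = "III")
  got <- assign_groups(tr, refs)
  expect_identical(got[["q2"]], "III")  # inside the pure III clade
  expect_identical(got[["o"]], "unplaced")  # smallest labeled split mixes I and II
  expect_error(assign_groups(tr, c(zz = "I")), "missing")
})

test_that("planted group clades are assigned with full accuracy", {
  msa <- gen_clade_msa(5, n_clades = 5, n_per_clade = 4, length = 300,
                       between = 0.7, within = 0.05,
                       clade_labels = c("I", "II", "III", "IVa", "IVb"))
  tr <- nj_tree(poisson_distance(msa$msa))
  # first two leaves of each clade are references, the rest are queries
  is_ref <- grepl("_[12]$", names(msa$truth))
  refs <- msa$truth[is_ref]
  got <- assign_groups(tr, refs)
  queries <- names(msa$truth)[!is_ref]
  expect_identical(got[queries], msa$truth[queries])
})
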