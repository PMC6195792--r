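test_that("codon site counts partition the 3 sites of every sense codon", {
  # hand-enumerated: of TTT's 9 single-nt changes only TTT->TTC is silent
  expect_equal(unname(codon_sites("TTT")), c(1 / 3, 8 / 3))
  # ATG: all 9 changes alter the residue
  expect_equal(unname(codon_sites("ATG")), c(0, 3))
  expect_error(codon_sites("TAA"), "stop")
  expect_error(codon_sites("ATN"), "ambiguous")

  gc <- oracle_codon_table()
  for (cd in names(gc)[gc != "*"]) {
    s <- codon_sites(cd)
    expect_equal(unname(s[["S"]] + s[["N"]]), 3)
    # independent enumeration of the 9 single-nucleotide changes
    syn <- 0
    for (pos in 1:3) {
      for (nt in setdiff(c("A", "C", "G", "T"), substr(cd, pos, pos))) {
        mut <- cd
        substr(mut, pos, pos) <- nt
        if (gc[[mut]] != "*" && gc[[mut]] == gc[[cd]]) syn <- syn + 1
      }
    }
    expect_equal(s[["S"]], syn / 3, label = cd)
  }
})

test_that("pairwise Ka/Ks behaves on identical and hand-computed pairs", {
  cds <- oracle_random_sense_cds(30)
  kk <- kaks_pair(cds, cds)
  expect_equal(kk$Ka, 0)
  expect_equal(kk$Ks, 0)

  # 10 identical codons except one synonymous third-position change:
  # GGT -> GGC (Gly). Sd = 1, Nd = 0, S = 10 codons' synonymous sites.
  a <- paste(rep("GGT", 10), collapse = "")
  b <- paste(c(rep("GGT", 9), "GGC"), collapse = "")
  kk <- kaks_pair(a, b)
  expect_equal(kk$Sd, 1)
  expect_equal(kk$Nd, 0)
  expect_equal(kk$S, 10)   # GGN is 4-fold degenerate: 1 synonymous site/codon
  expect_equal(kk$Ks, -3 / 4 * log(1 - 4 / 3 * (1 / 10)))
  expect_equal(kk$Ka, 0)

  # gapped codons are skipped
  kk2 <- kaks_pair(paste0(a, "---"), paste0(b, "GGT"))
  expect_equal(kk2$n_codons, 10L)
  expect_error(kaks_pair("GGT", "TAA"), "stop")
})

test_that("Sd/Nd match the path-enumeration oracle on random codon pairs", {
  set.seed(1)
  for (i in 1:100) {
    a <- oracle_random_sense_cds(30)
    b <- oracle_random_sense_cds(30)
    kk <- kaks_pair(a, b)
    want <- oracle_sdnd(a, b)
    expect_equal(kk$Sd, want[["sd"]], tolerance = 1e-9, label = paste("seed-case", i))
    expect_equal(kk$Nd, want[["nd"]], tolerance = 1e-9)
    # symmetry in the two sequences
    rev_kk <- kaks_pair(b, a)
    expect_equal(rev_kk$Sd, kk$Sd)
    expect_equal(rev_kk$S, kk$S)
  }
})

test_that("codon alignment back-threads gaps in whole-codon units", {
  # b lacks one internal codon of a
  a <- "ATGAAATTTGGGTGCTAA"
  b <- "ATGAAAGGGTGC"
  aln <- codon_align(a, b)
  expect_equal(nchar(aln$a), nchar(aln$b))
  expect_equal(nchar(aln$a) %% 3, 0)
  gaps <- gregexpr("-+", aln$b)[[1]]
  expect_true(all(attr(gaps, "match.length") %% 3 == 0))
  expect_identical(gsub("-", "", aln$a), "ATGAAATTTGGGTGC")  # stop stripped
  kk <- kaks_pair(aln$a, aln$b)
  expect_equal(kk$n_codons, 4L)
  expect_equal(kk$Ks, 0)
})

test_that("ratio, divergence date, and selection class follow the clock formula", {
  rd <- ratio_and_date(0.0258, 0.1829)
  expect_equal(round(rd$ratio, 6), 0.141061)
  expect_equal(round(rd$mya, 5), 14.06923)
  expect_identical(rd$selection_class, "purifying")

  expect_equal(ratio_and_date(0, 0)$mya, 0)
  expect_true(is.na(ratio_and_date(0.1, 0)$ratio))
  expect_equal(ratio_and_date(0.1, 0)$mya, 0)

  rd2 <- ratio_and_date(0.0993 * 2, 0.0993)
  expect_equal(rd2$ratio, 2)
  expect_identical(rd2$selection_class, "positive")
  expect_identical(ratio_and_date(0.1, 0.1)$selection_class, "neutral")

  # mya is strictly increasing in Ks and scales as 1/lambda
  ks <- seq(0.05, 1, by = 0.05)
  mya <- vapply(ks, function(k) ratio_and_date(0.01, k)$mya, numeric(1))
  expect_true(all(diff(mya) > 0))
  expect_equal(ratio_and_date(0.01, 0.2, lambda_rate = 1.3e-8)$mya,
               ratio_and_date(0.01, 0.2, lambda_rate = 6.5e-9)$mya / 2)
})

test_that("the pair table joins alignment, estimation, and dating", {
  dp <- gen_duplicate_pair(4, n_codons = 300)
  cds <- c(a = dp$cds_a, b = dp$cds_b)
  tab <- kaks_table(cds, data.frame(gene_a = "a", gene_b = "b"))
  expect_equal(nrow(tab), 1L)
  expect_identical(tab$selection_class, "purifying")
  expect_equal(tab$mya, tab$ks / (2 * 6.5e-9) * 1e-6)
  expect_error(kaks_table(cds, data.frame(gene_a = "a", gene_b = "zz")), "zz")
})
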