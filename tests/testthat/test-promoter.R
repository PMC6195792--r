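test_that("the packaged element table loads and validates", {
  pl <- place_elements()
  expect_equal(nrow(pl), 17L)
  expect_true(all(c("CAATBOX1", "DOFCOREZM", "ACGTCBOX") %in% pl$element_id))
  expect_identical(pl$iupac[pl$element_id == "CAATBOX1"], "CAAT")

  tf <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("element_id\tiupac", "E1\tCAAT", "E1\tTGAC"), tf)
  expect_error(load_place_table(tf), "duplicate element_id")
  writeLines(c("element_id\tiupac", "E1\tCAJT"), tf)
  expect_error(load_place_table(tf), "E1")
})

test_that("simple plus-strand matches are located", {
  motifs <- data.frame(element_id = "CAATBOX1", iupac = "CAAT")
  hits <- scan_promoter("GGCAATTT", motifs, "g", both_strands = FALSE)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$start, 2L)
  expect_identical(hits$match, "CAAT")
})

test_that("scanning equals a sliding-window oracle, both strands", {
  set.seed(11)
  prom <- paste(sample(c("A", "C", "G", "T"), 1500, replace = TRUE),
                collapse = "")
  pl <- place_elements()
  hits <- scan_promoter(prom, pl, "g")
  for (i in seq_len(nrow(pl))) {
    iu <- pl$iupac[i]; el <- pl$element_id[i]; m <- nchar(iu)
    fwd <- oracle_scan_strand(prom, iu)
    rev_hits <- oracle_scan_strand(oracle_revcomp(prom), iu)
    rev_on_fwd <- sort(nchar(prom) - rev_hits - m)
    got <- hits[hits$element_id == el, ]
    expect_identical(got$start[got$strand == "+"], fwd, label = el)
    expect_identical(sort(got$start[got$strand == "-"]), rev_on_fwd, label = el)
  }
})

test_that("minus-strand hits equal plus-strand hits of the reverse-complemented pattern", {
  set.seed(23)
  for (i in 1:10) {
    prom <- paste(sample(c("A", "C", "G", "T"), 300, replace = TRUE),
                  collapse = "")
    iu <- paste(sample(c("A", "C", "G", "T", "R", "Y", "N", "W", "S"),
                       sample(4:8, 1), replace = TRUE), collapse = "")
    motifs <- data.frame(element_id = "E", iupac = iu)
    rc_motifs <- data.frame(element_id = "E", iupac = revcomp(iu))
    minus <- scan_promoter(prom, motifs, "g")
    minus <- minus[minus$strand == "-", ]
    plus_rc <- scan_promoter(prom, rc_motifs, "g", both_strands = FALSE)
    expect_identical(sort(minus$start), sort(plus_rc$start))
  }
})

test_that("hit starts shift exactly with a prepended offset", {
  set.seed(31)
  prom <- paste(sample(c("A", "C", "G", "T"), 200, replace = TRUE), collapse = "")
  pl <- place_elements()[1:6, ]
  base <- scan_promoter(prom, pl, "g", both_strands = FALSE)
  shifted <- scan_promoter(paste0("ACGTACGTACG", prom), pl, "g",
                           both_strands = FALSE)
  # restrict to hits inside the original window (the junction can add new ones)
  shifted <- shifted[shifted$start >= 11, ]
  in_both <- merge(transform(base, start = start + 11L), shifted,
                   by = c("element_id", "start"))
  expect_equal(nrow(in_both), nrow(base))
})

test_that("planted elements are recovered with their strands", {
  pl <- place_elements()
  plant <- pl[match(c("CAATBOX1", "DOFCOREZM", "ACGTCBOX", "TATABOX3",
                      "HDZIP2ATATHB2"), pl$element_id), ]
  g <- gen_promoter(11, plant)
  hits <- scan_promoter(g$record, pl)
  found <- merge(g$planted, hits,
                 by = c("gene_id", "element_id", "start", "strand"))
  expect_equal(nrow(found), nrow(g$planted))
})

test_that("shared and gene-specific element summaries behave", {
  # one gene degenerately makes every element both shared and specific
  motifs <- data.frame(element_id = c("E1", "E2"), iupac = c("CAAT", "TGAC"))
  h1 <- scan_promoters(c(g1 = "GGCAATCCTGACGG"), motifs)
  s1 <- summarize_elements(h1)
  expect_setequal(s1$shared, c("E1", "E2"))
  expect_setequal(names(s1$specific), c("E1", "E2"))

  # three synthetic promoters sharing exactly one planted element
  pl <- place_elements()
  common <- pl[pl$element_id == "ACGTCBOX", ]   # 6-mer, rare by chance
  proms <- character(0)
  for (s in 1:3) {
    g <- gen_promoter(400 + s, common, length = 120L, both_strands = FALSE,
                      id = paste0("g", s))
    proms <- c(proms, g$record)
  }
  hits <- scan_promoters(proms, pl[pl$element_id %in%
                                     c("ACGTCBOX", "CTRMCAMV35S"), ])
  sm <- summarize_elements(hits, genes = paste0("g", 1:3))
  expect_true("ACGTCBOX" %in% sm$shared)
  expect_equal(unname(sm$counts["g1", "ACGTCBOX"] >= 1), TRUE)
})
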