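test_that("pattern compilation mirrors the dialect tokens", {
  p <- compile_pattern("L-X(2)-G")
  expect_equal(motif_min_length(p), 4L)
  expect_equal(nrow(scan_motif(p, "LAAG")), 1L)
  expect_equal(nrow(scan_motif(p, "LAG")), 0L)

  # multi-residue literal tokens expand to one position each
  p2 <- compile_pattern("G-[ED]-ELL")
  expect_equal(motif_min_length(p2), 5L)
  expect_equal(scan_motif(p2, "AGDELLK")$match, "GDELL")

  # a 0 inside a bracket makes the position optional
  p3 <- compile_pattern("[LIMV0]-X(2)-[GSANCR]")
  expect_equal(motif_min_length(p3), 3L)
  expect_equal(nrow(scan_motif(p3, "AAG")), 1L)   # optional leading residue absent
  expect_equal(scan_motif(p3, "LAAG")$start[1], 0L)

  # X(0,1) is an optional wildcard
  p4 <- compile_pattern("G-X(0,1)-W")
  expect_setequal(scan_motif(p4, "GWAGAW")$match, c("GW", "GAW"))
})

test_that("malformed patterns fail with the offending token", {
  expect_error(compile_pattern("L-X(3,2)-G"), "token 2")
  expect_error(compile_pattern("L-[JZ]-G"), "token 2")
  expect_error(compile_pattern("L-[AB-G"), "token")
  expect_error(compile_pattern("L--G"), "empty token")
})

test_that("the packaged patterns compile to their published spans", {
  sp <- stringent_pattern()
  # minimal length: oracle sums the minimum repeat of each expanded position
  min_oracle <- sum(vapply(sp$positions, `[[`, integer(1), "min"))
  expect_equal(motif_min_length(sp), min_oracle)
  expect_equal(motif_min_length(sp), 37L)
  expect_equal(motif_max_length(sp), 47L)
  # every random expansion is matched by the pattern it came from
  for (s in 1:20) {
    real <- expand_pattern(sp, seed = s)
    expect_gte(nrow(scan_motif(sp, real)), 1L)
  }
  cp <- consensus_pattern()
  expect_gte(nrow(scan_motif(cp, expand_pattern(cp, seed = 1))), 1L)
})

test_that("scan equals the brute-force matcher on simple and random input", {
  p <- compile_pattern("C-A-A-T")
  h <- scan_motif(p, "MCAATK", "x")
  expect_equal(h$start, 1L)
  expect_equal(h$end, 5L)

  # fixed pseudo-random 1000-aa sequence against the stringent motif
  set.seed(42)
  seq1k <- paste(sample(c("A","C","D","E","F","G","H","I","K","L","M","N",
                          "P","Q","R","S","T","V","W","Y"), 1000,
                        replace = TRUE), collapse = "")
  sp <- stringent_pattern()
  expect_identical(scan_motif(sp, seq1k)[, c("start", "end")],
                   oracle_scan(sp, seq1k))

  # random patterns x random sequences
  set.seed(7)
  for (i in 1:25) {
    src <- oracle_random_pattern()
    p <- compile_pattern(src)
    seq <- paste(sample(c("A","C","G","L","T","V","W","Y","E","D"), 80,
                        replace = TRUE), collapse = "")
    got <- scan_motif(p, seq)[, c("start", "end")]
    want <- oracle_scan(p, seq)
    expect_identical(got, want, label = paste("pattern", src))
  }
})

test_that("identification accepts planted family members and only them", {
  expect_equal(nrow(identify_cngc(character(0))), 0L)

  pg <- gen_proteome(seed = 5, n_cngc = 6L, n_decoy = 5L)
  rep <- identify_cngc(pg$proteome)
  expect_setequal(rep$id[rep$accepted], pg$truth$id[pg$truth$is_cngc])

  # redundancy: an exact duplicate of a member is collapsed, keeping one
  dup <- pg$proteome[pg$truth$id[pg$truth$is_cngc][1]]
  names(dup) <- "DUPLICATE"
  rep2 <- identify_cngc(c(pg$proteome, dup))
  expect_equal(sum(rep2$accepted), 6L)
  expect_equal(sum(!is.na(rep2$redundant_with)), 1L)

  # short motif-bearing fragments fall to the length filter
  frag <- substr(pg$proteome[[rep$id[rep$accepted][1]]], 1, 150)
  short_hit <- gen_cngc_protein(99, length = 150L, id = "FRAG")
  rep3 <- identify_cngc(c(pg$proteome, short_hit$record))
  expect_false(rep3$accepted[rep3$id == "FRAG"])
  expect_true(rep3$motif_found[rep3$id == "FRAG"])
})

test_that("raising the length cutoff never adds accepted candidates", {
  pg <- gen_proteome(seed = 8, n_cngc = 5L, n_decoy = 4L,
                     length_range = c(150L, 500L))
  accepted_at <- function(L) {
    r <- identify_cngc(pg$proteome, min_length = L)
    r$id[r$accepted]
  }
  prev <- accepted_at(100L)
  for (L in c(200L, 300L, 400L, 500L)) {
    cur <- accepted_at(L)
    expect_true(all(cur %in% prev))
    prev <- cur
  }
})
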