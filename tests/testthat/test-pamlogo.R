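test_that("flanks are read in spacer sense on both strands", {
  sp <- random_spacers(3)
  v <- virus_with_plants(list(plant_spec(1, "viral", 1.0, region = "rep"),
                              plant_spec(2, "complementary", 1.0, region = "cap")),
                         sp)
  m <- matches_from_truth(v$truth)
  fl <- extract_flanks(m, c(v1 = v$sequence), "upstream", 10L, "all")
  expect_length(fl$sequences, 2L)
  expect_true(all(nchar(fl$sequences) == 10L))
  # the planted PAM "CCN" shows as CC at flank positions -3, -2 on BOTH strands
  for (s in fl$sequences) expect_identical(substr(s, 8L, 9L), "CC")

  # planting the same spacer on either strand yields the same flank string
  v2 <- virus_with_plants(list(plant_spec(3, "viral", 1.0, region = "rep")), sp,
                          seed_offset = 5L)
  m2 <- matches_from_truth(v2$truth)
  f2 <- extract_flanks(m2, c(v1 = v2$sequence), "upstream", 3L, "all")
  expect_identical(unname(substr(f2$sequences, 1L, 2L)), "CC")
})

test_that("best-per-spacer selection keeps one representative per spacer", {
  m <- data.frame(spacer = c("sp1", "sp1", "sp2"), genome = c("a", "b", "a"),
                  strand = "+", start = c(50L, 60L, 70L), end = c(86L, 96L, 106L),
                  score = c(30L, 36L, 20L), evalue = c(1e-3, 1e-6, 1e-2),
                  identity = 1, gaps_query = 0L, gaps_subject = 0L,
                  mode = "glocal", stringsAsFactors = FALSE)
  gs <- c(a = random_dna(500L), b = random_dna(500L))
  fl <- extract_flanks(m, gs, "upstream", 10L, "best-per-spacer")
  expect_length(fl$sequences, 2L)
  expect_identical(sort(names(fl$sequences)), c("sp1", "sp2"))
  # sp1's representative is the higher-scoring hit in genome b
  expect_identical(unname(fl$sequences["sp1"]), substr(gs[["b"]], 51L, 60L))
})

test_that("PFM frequencies, counts and information content are exact", {
  fl <- structure(list(side = "upstream", flank_len = 4L, selection = "all",
                       sequences = c("AACC", "AACG", "ACGT", "AATT")),
                  class = "flank_set")
  pfm <- build_pfm(fl)
  expect_equal(colSums(pfm$freq), rep(1, 4))
  # frequencies reconstruct integer counts
  expect_true(all(abs(pfm$freq * pfm$n - round(pfm$freq * pfm$n)) < 1e-9))
  expect_equal(pfm$ic[1], 2)                      # all-A column
  expect_equal(pfm$positions, -4:-1)

  # uniform column carries no information
  flu <- structure(list(side = "downstream", flank_len = 1L, selection = "all",
                        sequences = c("A", "C", "G", "T")),
                   class = "flank_set")
  expect_equal(build_pfm(flu)$ic[1], 0)

  # hand-evaluated mixed column: 18 C, 3 A, 1 G, 1 T of 23
  fl23 <- structure(list(side = "upstream", flank_len = 1L, selection = "all",
                         sequences = c(rep("C", 18), rep("A", 3), "G", "T")),
                    class = "flank_set")
  f <- c(18, 3, 1, 1) / 23
  expect_equal(build_pfm(fl23)$ic[1], 2 + sum(f * log2(f)), tolerance = 1e-12)
})

test_that("PFM is invariant to sequence order", {
  withr::with_seed(12L, {
    seqs <- vapply(1:15, function(i) random_dna(10L), character(1))
  })
  mk <- function(ss) structure(list(side = "upstream", flank_len = 10L,
                                    selection = "all", sequences = ss),
                               class = "flank_set")
  p1 <- build_pfm(mk(seqs))
  p2 <- build_pfm(mk(rev(seqs)))
  expect_equal(p1$freq, p2$freq)
  expect_equal(p1$ic, p2$ic)
})

test_that("motif calling reports penetrance and completeness correctly", {
  # planted CC at -3,-2 in 80% of 20 flanks; -1 left random
  withr::with_seed(44L, {
    seqs <- vapply(1:20, function(i) random_dna(10L), character(1))
    carriers <- 1:16
    for (i in carriers) substr(seqs[i], 8, 9) <- "CC"
  })
  fl <- structure(list(side = "upstream", flank_len = 10L, selection = "all",
                       sequences = seqs), class = "flank_set")
  mc <- call_motif(build_pfm(fl), conservation_threshold = 0.5)
  expect_match(mc$motif, "CC$")
  expect_true(all(c(-3, -2) %in% mc$offsets))
  expect_gte(mc$any_position, mc$completeness)

  # full penetrance gives completeness 1 (noise positions left uncalled)
  withr::with_seed(210L, {
    seqs2 <- vapply(1:10, function(i) paste0(random_dna(7L), "CCA"), character(1))
  })
  fl2 <- structure(list(side = "upstream", flank_len = 10L, selection = "all",
                        sequences = seqs2), class = "flank_set")
  mc2 <- call_motif(build_pfm(fl2), 0.6)
  expect_equal(mc2$completeness, 1)

  # 18 of 23 complete reproduces the 78% completeness figure
  withr::with_seed(211L, {
    seqs3 <- c(vapply(1:18, function(i) paste0(random_dna(7L), "CC", random_dna(1L)),
                      character(1)),
               vapply(1:5, function(i) paste0(random_dna(7L), "AT", random_dna(1L)),
                      character(1)))
  })
  fl3 <- structure(list(side = "upstream", flank_len = 10L, selection = "all",
                        sequences = seqs3), class = "flank_set")
  mc3 <- call_motif(build_pfm(fl3), 0.6)
  expect_equal(round(100 * mc3$completeness), 78)

  # nothing conserved: empty motif
  withr::with_seed(3L, {
    flr <- structure(list(side = "upstream", flank_len = 8L, selection = "all",
                          sequences = vapply(1:40, function(i) random_dna(8L),
                                             character(1))),
                     class = "flank_set")
  })
  expect_identical(call_motif(build_pfm(flr), 0.9)$motif, "")
})
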