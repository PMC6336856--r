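test_that("exact substring and small hand cases score as expected", {
  a <- glocal_align("ACGT", "AAACGTTT")
  expect_equal(a$score, 4L)
  expect_equal(c(a$start, a$end), c(2L, 6L))
  expect_equal(a$identity, 1)
  expect_equal(a$gaps_query + a$gaps_subject, 0L)

  # full-query coverage forces the mismatch through
  b <- glocal_align("ACGT", "ACTT")
  expect_equal(b$score, 2L)

  # gap vs mismatch arbitration: one length-2 subject insertion (8 - 3 = 5)
  # beats two mismatches (6 - 2 = 4); the brute-force oracle agrees
  al <- glocal_align("ACGTACGT", "ACGTTTACGT")
  expect_equal(al$score, 5L)
  expect_equal(al$score,
               spacerhost:::glocal_brute_cpp("ACGTACGT", "ACGTTTACGT", 1, -1, 2, 1))
  expect_equal(al$gaps_query, 2L)
})

test_that("invalid inputs and parameters are rejected", {
  expect_error(glocal_align("ACGTACGT", "ACG"), "shorter")
  expect_error(align_params(match = -1), "match")
  expect_error(align_params(gap_open = -1, gap_extend = -2), "gap_open")
})

test_that("DP equals the exhaustive oracle on random small instances", {
  withr::with_seed(421L, {
    for (i in 1:250) {
      q <- random_dna(sample(4:10, 1))
      s <- random_dna(sample(nchar(q):14, 1))
      expect_identical(glocal_align(q, s)$score,
                       spacerhost:::glocal_brute_cpp(q, s, 1L, -1L, 2L, 1L))
    }
  })
})

test_that("glocal agrees with an independent global-local implementation", {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                  baseOnly = TRUE)
  withr::with_seed(99L, {
    for (i in 1:100) {
      q <- random_dna(sample(10:36, 1))
      s <- random_dna(sample(50:300, 1))
      pa <- Biostrings::pairwiseAlignment(q, s, type = "global-local",
                                          substitutionMatrix = mat,
                                          gapOpening = 1, gapExtension = 1)
      expect_equal(glocal_align(q, s)$score, Biostrings::score(pa))
    }
  })
})

test_that("strand symmetry, relaxation and monotonicity properties hold", {
  withr::with_seed(5L, {
    for (i in 1:200) {
      q <- random_dna(sample(8:20, 1)); s <- random_dna(sample(20:80, 1))
      sc <- glocal_align(q, s)$score
      expect_identical(sc, glocal_align(revcomp(q), revcomp(s))$score)
      loc <- local_align(q, s)
      if (!is.null(loc)) expect_gte(loc$score, sc)
    }
    # planting substitutions never increases the score
    q <- random_dna(36L)
    s <- paste0(random_dna(400L), q, random_dna(400L))
    prev <- glocal_align(q, s)$score
    qq <- strsplit(q, "")[[1]]
    for (k in 1:10) {
      p <- sample(36L, 1)
      qq[p] <- spacerhost:::mutate_base(qq[p])
      sc <- glocal_align(paste(qq, collapse = ""), s)$score
      expect_lte(sc, prev)
      prev <- sc
    }
  })
})

test_that("score always re-sums from the traceback strings", {
  withr::with_seed(31L, {
    for (i in 1:100) {
      q <- random_dna(sample(8:30, 1)); s <- random_dna(sample(30:120, 1))
      a <- glocal_align(q, s)
      expect_identical(score_from_strings(a$aligned_query, a$aligned_subject),
                       a$score)
      # the query row covers the full query in glocal mode
      expect_identical(gsub("-", "", a$aligned_query), q)
    }
  })
})

test_that("local alignment clips noisy flanks, glocal does not", {
  withr::with_seed(77L, {
    core <- random_dna(10L)
    q <- paste0("GGGGGGG", core, "GGGGGGG")
    s <- paste0(random_dna(50L), gsub("G", "A", core), core,
                random_dna(50L))
  })
  loc <- local_align(q, s)
  glo <- glocal_align(q, s)
  expect_lt(glo$end - glo$start, nchar(s))
  expect_lt(loc$query_end - loc$query_start, nchar(q))  # flanks clipped
  expect_identical(gsub("-", "", glo$aligned_query), q)

  # an all-mismatch pair has no positive local alignment
  expect_null(local_align("AAAA", "TTTTTTTT"))
})

test_that("scan recovers planted protospacers with strand and coordinates", {
  sp <- random_spacers(3)
  v <- virus_with_plants(list(plant_spec(1, "viral", 1.0, region = "rep"),
                              plant_spec(2, "complementary", 1.0, region = "cap")),
                         sp)
  model <- small_model()
  hits <- scan_spacers(sp, c(v1 = v$sequence), evalue_model = model)
  expect_setequal(hits$spacer, c("sp1", "sp2"))
  for (i in seq_len(nrow(v$truth))) {
    tr <- v$truth[i, ]
    hh <- hits[hits$spacer == paste0("sp", tr$spacer_index), ]
    expect_equal(nrow(hh), 1L)
    expect_identical(hh$strand, tr$strand)
    expect_equal(hh$start, tr$start)
    expect_equal(hh$identity, 1)
    expect_lte(hh$evalue, 0.01)
  }
})

test_that("an origin-spanning protospacer is recovered once, not twice", {
  sp <- random_spacers(2)
  v <- virus_with_plants(list(plant_spec(1, "viral", 1.0, at = 2480L,
                                         with_pam = FALSE)), sp)
  hits <- scan_spacers(sp[1], c(v1 = v$sequence), evalue_model = small_model())
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$start, 2480)
  expect_gt(hits$end, 2500)   # wraps the origin
  expect_equal(hits$identity, 1)
})

test_that("scan refuses uncalibrated query lengths", {
  sp <- stats::setNames(random_dna(20L), "sp1")
  expect_error(scan_spacers(sp, c(g = random_dna(2500L)),
                            evalue_model = small_model(36L)),
               "not calibrated")
})

test_that("frame preservation rule: compensated or off-by-three gaps pass", {
  mk <- function(gq, gs) list(gaps_query = gq, gaps_subject = gs,
                              start = 10, end = 45)
  expect_identical(check_frame_preservation(mk(1L, 1L)), "ok")
  expect_identical(check_frame_preservation(mk(0L, 3L)), "ok")
  expect_identical(check_frame_preservation(mk(3L, 0L)), "ok")
  expect_identical(check_frame_preservation(mk(2L, 0L)), "flagged")
  expect_identical(check_frame_preservation(mk(1L, 3L)), "flagged")
  # outside genes the rule does not apply
  ann <- data.frame(feature = "rep", start = 100L, end = 400L, strand = "+",
                    type = "gene")
  expect_identical(check_frame_preservation(mk(2L, 0L), ann, 2500L), "ok")
})
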