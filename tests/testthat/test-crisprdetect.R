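test_that("planted arrays are recovered exactly, satellite on the opposite strand", {
  cfg <- small_host_cfg(seed = 42L, n_spacers = 10L)
  h <- generate_host(cfg)
  arr <- find_arrays(h$sequence, min_repeats = 2L)
  expect_length(arr, 2L)
  b1 <- arr[[1]]; b2 <- arr[[2]]
  expect_equal(nrow(b1$instances), 11L)
  expect_equal(nrow(b1$spacers), 10L)
  expect_identical(b1$consensus, cfg$repeat_seq)
  expect_identical(b1$spacers$seq, h$truth$b1$spacers$seq)
  expect_equal(b1$instances$start, h$truth$b1$repeat_starts)
  # satellite shares the repeat in the complementary strand
  expect_equal(nrow(b2$instances), 3L)
  expect_identical(revcomp(b2$consensus), cfg$repeat_seq)
  expect_identical(b2$strand, "-")
})

test_that("random sequence without an array yields nothing at default settings", {
  withr::with_seed(314L, {
    g <- random_dna(50000L)
  })
  expect_length(find_arrays(g), 0L)
})

test_that("satellite arrays are kept only nearby and only with the same repeat", {
  cfg <- small_host_cfg(seed = 42L, n_spacers = 10L, b2_distance = 3000L)
  h <- generate_host(cfg)
  arr <- find_arrays(h$sequence, min_repeats = 2L)
  expect_length(attach_satellite_arrays(arr, max_distance = 10000L), 2L)
  expect_length(attach_satellite_arrays(arr, max_distance = 1000L), 1L)
  # an unrelated small cluster is dropped even nearby
  fake <- arr[[2]]
  fake$consensus <- random_dna(31L)
  expect_length(attach_satellite_arrays(list(arr[[1]], fake),
                                        max_distance = 10000L), 1L)
})

test_that("far-away satellites are dropped", {
  cfg <- small_host_cfg(seed = 13L, n_spacers = 8L, b2_distance = 25000L,
                        host_length = 120000L)
  h <- generate_host(cfg)
  arr <- find_arrays(h$sequence, min_repeats = 2L)
  expect_length(arr, 2L)
  expect_length(attach_satellite_arrays(arr, max_distance = 10000L), 1L)
})

test_that("leader side follows terminal-repeat conservation, then AT richness", {
  cfg <- small_host_cfg(seed = 42L, n_spacers = 10L)
  h <- generate_host(cfg)
  arr <- find_arrays(h$sequence, min_repeats = 4L)
  a <- call_leader(arr[[1]], h$sequence)
  expect_identical(a$leader_side, "left")
  expect_identical(a$strand, "+")
  expect_true(a$at_rich_flank)
  expect_identical(get_spacers(a),
                   stats::setNames(h$truth$b1$spacers$seq, paste0("sp", 1:10)))

  # symmetric conservation: decided by the AT-rich flank
  rep31 <- cfg$repeat_seq
  withr::with_seed(8L, {
    spc <- vapply(1:5, function(i) random_dna(36L), character(1))
    locus <- paste0(rep31, paste(paste0(spc, rep31), collapse = ""))
    atl <- paste(sample(c("A", "T"), 200L, replace = TRUE), collapse = "")
    g <- paste0(random_dna(3000L), atl, locus, random_dna(3000L))
  })
  a2 <- find_arrays(g, min_repeats = 4L)[[1]]
  a2 <- call_leader(a2, g)
  expect_identical(a2$leader_side, "left")

  # degenerate repeat on the LEFT puts the leader on the right and flips sense
  withr::with_seed(9L, {
    spc <- vapply(1:6, function(i) random_dna(36L), character(1))
    dv <- strsplit(rep31, "")[[1]]
    for (p in sample(31L, 5L)) dv[p] <- spacerhost:::mutate_base(dv[p])
    locus <- paste0(paste(dv, collapse = ""),
                    paste(paste0(spc, rep31), collapse = ""))
    atr <- paste(sample(c("A", "T"), 200L, replace = TRUE), collapse = "")
    g2 <- paste0(random_dna(3000L), locus, atr, random_dna(3000L))
  })
  a3 <- find_arrays(g2, min_repeats = 4L)[[1]]
  a3 <- call_leader(a3, g2)
  expect_identical(a3$leader_side, "right")
  expect_identical(a3$strand, "-")
  expect_identical(a3$spacers$seq[1], revcomp(spc[6]))
})

test_that("leader calling requires at least four repeats", {
  cfg <- small_host_cfg(seed = 42L, n_spacers = 10L)
  h <- generate_host(cfg)
  arr <- find_arrays(h$sequence, min_repeats = 2L)
  expect_error(call_leader(arr[[2]], h$sequence), ">= 4")
})

test_that("detection mirrors under reverse complement", {
  cfg <- small_host_cfg(seed = 23L, n_spacers = 6L, b2_n_repeats = 0L)
  h <- generate_host(cfg)
  n <- nchar(h$sequence)
  fwd <- find_arrays(h$sequence)
  rev_ <- find_arrays(revcomp(h$sequence))
  expect_length(fwd, 1L)
  expect_length(rev_, 1L)
  expect_identical(rev_[[1]]$consensus, revcomp(fwd[[1]]$consensus))
  expect_equal(sort(n - fwd[[1]]$instances$end), sort(rev_[[1]]$instances$start))
  # and the leader lands on the mirrored side
  af <- call_leader(fwd[[1]], h$sequence)
  ar <- call_leader(rev_[[1]], revcomp(h$sequence))
  expect_identical(af$leader_side, "left")
  expect_identical(ar$leader_side, "right")
  expect_identical(get_spacers(af), get_spacers(ar))
})

test_that("planted leader side is recovered across seeded replicates", {
  hits <- 0L
  n_rep <- 100L
  for (s in seq_len(n_rep)) {
    cfg <- sim_config(seed = 1000L + s, host_length = 30000L, n_spacers = 5L,
                      b2_n_repeats = 0L)
    h <- generate_host(cfg)
    arr <- find_arrays(h$sequence, min_repeats = 4L)
    if (length(arr) != 1L) next
    a <- call_leader(arr[[1]], h$sequence)
    if (a$leader_side == "left") hits <- hits + 1L
  }
  expect_gte(hits, ceiling(0.95 * n_rep))
})
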