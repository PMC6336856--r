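test_that("host generation is deterministic and builds the requested array", {
  cfg <- small_host_cfg(seed = 5L, n_spacers = 4L)
  h1 <- generate_host(cfg)
  h2 <- generate_host(cfg)
  expect_identical(h1$sequence, h2$sequence)
  expect_identical(h1$truth, h2$truth)

  tr <- h1$truth$b1
  expect_equal(length(tr$repeat_starts), 5L)   # n_spacers + 1 repeat copies
  expect_equal(nrow(tr$spacers), 4L)
  expect_equal(anyDuplicated(tr$spacers$seq), 0L)
  # repeats sit where the truth says
  w <- nchar(cfg$repeat_seq)
  for (i in seq_len(4L)) {
    s <- tr$repeat_starts[i]
    expect_identical(substr(h1$sequence, s + 1L, s + w), cfg$repeat_seq)
  }
})

test_that("leader is AT rich and the distal repeat is degenerate", {
  cfg <- small_host_cfg(seed = 12L, n_spacers = 6L, leader_len = 100L,
                        leader_at_fraction = 0.7)
  h <- generate_host(cfg)
  tr <- h$truth$b1
  leader <- substr(h$sequence, tr$leader[1] + 1L, tr$leader[2])
  at <- mean(strsplit(leader, "")[[1]] %in% c("A", "T"))
  # binomial CI: 100 draws at p = 0.7 stay within [0.6, 0.8] w.h.p.
  expect_gte(at, 0.6)
  expect_lte(at, 0.8)

  w <- nchar(cfg$repeat_seq)
  distal0 <- tr$repeat_starts[length(tr$repeat_starts)]
  distal <- substr(h$sequence, distal0 + 1L, distal0 + w)
  d <- sum(strsplit(distal, "")[[1]] != strsplit(cfg$repeat_seq, "")[[1]])
  expect_gte(d, 3L)
  expect_lte(d, 6L)
})

test_that("background composition is near-uniform at scale", {
  cfg <- sim_config(seed = 2L, host_length = 50000L, n_spacers = 4L,
                    b2_n_repeats = 0L)
  h <- generate_host(cfg)
  # GC over the background-dominated contig
  gc <- mean(strsplit(h$sequence, "")[[1]] %in% c("G", "C"))
  expect_gt(gc, 0.45)
  expect_lt(gc, 0.55)
})

test_that("infeasible host sizing errors out", {
  expect_error(sim_config(host_length = 5000L, n_spacers = 111L),
               "too small")
  expect_error(sim_config(nonanucleotide = "NAGTRTTACC"), "9 nt")
})

test_that("exact plants are exact copies with the PAM written upstream", {
  sp <- random_spacers(3)
  v <- virus_with_plants(list(plant_spec(1, "viral", 1.0, region = "rep"),
                              plant_spec(2, "complementary", 1.0, region = "cap")),
                         sp)
  tr <- v$truth
  p1 <- tr[tr$spacer_index == 1, ]
  expect_identical(substr(v$sequence, p1$start + 1L, p1$end), unname(sp[1]))
  expect_identical(substr(v$sequence, p1$start - 2L, p1$start - 1L), "CC")
  # complementary-strand plant: spacer sense is the reverse complement, PAM
  # upstream in spacer sense appears as GG just after the plant on the + strand
  p2 <- tr[tr$spacer_index == 2, ]
  expect_identical(revcomp(substr(v$sequence, p2$start + 1L, p2$end)),
                   unname(sp[2]))
  expect_identical(substr(v$sequence, p2$end + 2L, p2$end + 3L), "GG")
})

test_that("realized identity honours the request up to quantization", {
  sp <- random_spacers(4)
  v <- virus_with_plants(list(plant_spec(1, "viral", 0.9, region = "rep"),
                              plant_spec(2, "viral", 0.8, region = "cap"),
                              plant_spec(3, "complementary", 0.86,
                                         region = "intergenic", with_pam = FALSE)),
                         sp)
  for (i in seq_len(nrow(v$truth))) {
    req <- c(0.9, 0.8, 0.86)[v$truth$spacer_index[i]]
    expect_lte(abs(v$truth$identity[i] - req), 1 / 36 + 1e-9)
  }
})

test_that("subject-side gap plants keep the rep reading frame", {
  sp <- random_spacers(2)
  v <- virus_with_plants(list(plant_spec(1, "viral", 0.97, n_gaps_query = 0L,
                                         n_gaps_subject = 3L, region = "rep")),
                         sp)
  ann <- v$annotation
  rep_row <- ann[ann$feature == "rep", ]
  rep_seq <- substr(v$sequence, rep_row$start + 1L, rep_row$end)
  expect_identical(substr(rep_seq, 1L, 3L), "ATG")
  # overwriting preserves length, so the terminal codon is still a stop in frame
  last <- substr(rep_seq, nchar(rep_seq) - 2L, nchar(rep_seq))
  expect_true(last %in% c("TAA", "TAG", "TGA"))
  expect_equal(nchar(rep_seq) %% 3L, 0L)
})

test_that("the origin nonanucleotide occurs exactly once, viral sense only", {
  for (s in 1:5) {
    sp <- random_spacers(2, seed = s)
    v <- virus_with_plants(list(plant_spec(1, "viral", 1.0, region = "cap")),
                           sp, seed = s)
    fwd <- spacerhost:::iupac_match_starts(v$sequence, "NAGTRTTAC")
    rev_ <- spacerhost:::iupac_match_starts(revcomp(v$sequence), "NAGTRTTAC")
    expect_length(fwd, 1L)
    expect_length(rev_, 0L)
  }
})

test_that("sim configs round-trip through YAML", {
  cfg <- small_host_cfg(seed = 3L, n_spacers = 4L,
                        planted = list(plant_spec(1, "viral", 0.9,
                                                  region = "cap")))
  p <- withr::local_tempfile(fileext = ".yaml")
  write_sim_config(cfg, p)
  cfg2 <- read_sim_config(p)
  expect_identical(generate_host(cfg2)$sequence, generate_host(cfg)$sequence)
  v1 <- generate_virus(cfg, random_spacers(2))
  v2 <- generate_virus(cfg2, random_spacers(2))
  expect_identical(v1$sequence, v2$sequence)
})

test_that("overlapping plant placement raises a placement error", {
  sp <- random_spacers(30)
  plants <- lapply(1:30, function(i) plant_spec(i, "viral", 1.0, region = "intergenic"))
  # 30 x ~44 nt cannot fit the ~360 nt intergenic region
  expect_error(virus_with_plants(plants, sp), "placement|place")
})
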