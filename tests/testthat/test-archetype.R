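test_that("IUPAC orientation semantics follow the motif", {
  pad <- function(core) paste0(strrep("ATGC", 30), core, strrep("GCAT", 30))
  g1 <- pad("TAGTGTTAC")     # T matches N, G matches R: viral sense as-is
  og1 <- orient_genome(g1)
  expect_false(og1$was_reverse_complemented)

  og2 <- orient_genome(revcomp(g1))
  expect_true(og2$was_reverse_complemented)
  expect_identical(og2$sequence, g1)

  # C fails R = A/G: no orientation possible
  expect_error(orient_genome(pad("AAGTCTTAC")), "absent")
  # motif on both strands is ambiguous
  both <- paste0(pad("TAGTGTTAC"), revcomp("AAGTATTAC"), strrep("AT", 20))
  expect_error(orient_genome(both), "ambiguous")
})

test_that("orientation is idempotent and flips annotation coherently", {
  sp <- random_spacers(2)
  v <- virus_with_plants(list(plant_spec(1, "viral", 1.0, region = "rep")), sp)
  og <- orient_genome(v$sequence, annotation = v$annotation, id = "v1")
  expect_false(og$was_reverse_complemented)
  og2 <- orient_genome(og$sequence, annotation = og$annotation, id = "v1")
  expect_identical(og2$sequence, og$sequence)
  expect_identical(og2$annotation, og$annotation)

  ogr <- orient_genome(revcomp(v$sequence), annotation = {
    a <- v$annotation
    L <- nchar(v$sequence)
    data.frame(feature = a$feature, start = L - a$end, end = L - a$start,
               strand = chartr("+-", "-+", a$strand), type = a$type,
               stringsAsFactors = FALSE)
  }, id = "v1rc")
  expect_true(ogr$was_reverse_complemented)
  expect_identical(ogr$sequence, v$sequence)
  rep_f <- ogr$annotation[ogr$annotation$feature == "rep", ]
  rep_0 <- v$annotation[v$annotation$feature == "rep", ]
  expect_equal(rep_f$start, rep_0$start)
  expect_equal(rep_f$end, rep_0$end)
})

test_that("relative positions are fractional offsets within circular segments", {
  ann <- data.frame(feature = c("cap", "rep"), start = c(400L, 1700L),
                    end = c(1300L, 2400L), strand = "+", type = "gene",
                    stringsAsFactors = FALSE)
  L <- 2500L
  # midpoint at the rep start
  expect_equal(relative_position(list(start = 1700L, end = 1700L), ann, L)$fraction, 0)
  # midpoint exactly two-thirds through rep (700 nt gene)
  m <- list(start = 2166L, end = 2168L)
  rp <- relative_position(m, ann, L)
  expect_identical(rp$segment, "rep")
  expect_equal(rp$fraction, 2 / 3, tolerance = 1e-3)
  # intergenic between cap end and rep start
  rp2 <- relative_position(list(start = 1400L, end = 1436L), ann, L)
  expect_identical(rp2$segment, "intergenic_B")
  # the rep-to-cap gap wraps the origin and is intergenic_A
  rp3 <- relative_position(list(start = 2480L, end = 2516L), ann, L)
  expect_identical(rp3$segment, "intergenic_A")
  expect_gt(rp3$fraction, 0)

  # rotation invariance: shift the circular origin, rotate annotation along
  shift <- 600L
  ann_r <- ann
  ann_r$start <- (ann$start + shift) %% L
  ann_r$end <- ann_r$start + (ann$end - ann$start)
  rp_r <- relative_position(list(start = (2166L + shift) %% L,
                                 end = (2168L + shift) %% L), ann_r, L)
  expect_identical(rp_r$segment, "rep")
  expect_equal(rp_r$fraction, rp$fraction, tolerance = 1e-6)
})

test_that("archetype averages segment lengths and conserves placements", {
  sp <- random_spacers(4)
  mk <- function(seed_offset, rep_len, cap_len, id)
    virus_with_plants(list(plant_spec(1, "viral", 1.0, region = "rep"),
                           plant_spec(2, "complementary", 1.0, region = "cap")),
                      sp, seed_offset = seed_offset, id = id,
                      rep_len = rep_len, cap_len = cap_len)
  v1 <- mk(0L, 900L, 975L, "g1")
  v2 <- mk(1L, 750L, 1050L, "g2")
  og <- list(g1 = orient_genome(v1$sequence, annotation = v1$annotation, id = "g1"),
             g2 = orient_genome(v2$sequence, annotation = v2$annotation, id = "g2"))
  m <- rbind(matches_from_truth(v1$truth), matches_from_truth(v2$truth))
  arch <- build_archetype(m, og)
  expect_equal(arch$n_genomes, 2L)
  expect_equal(nrow(arch$placements), nrow(m))   # nothing lost
  expect_equal(arch$segments$mean_length[arch$segments$name == "rep"],
               mean(c(900, 750)))
  expect_equal(arch$segments$mean_length[arch$segments$name == "cap"],
               mean(c(975, 1050)))
  expect_true(all(arch$placements$fraction >= 0 & arch$placements$fraction <= 1))
  expect_true(all(arch$placements$position <=
                    arch$segments$mean_length[match(arch$placements$segment,
                                                    arch$segments$name)]))

  # a genome without gene annotation is excluded with a warning
  og_bad <- c(og, list(g3 = structure(list(id = "g3", sequence = v1$sequence,
                                           was_reverse_complemented = FALSE,
                                           nona_pos = 0L, annotation = NULL,
                                           length = nchar(v1$sequence)),
                                      class = "oriented_genome")))
  m3 <- rbind(m, within(matches_from_truth(v1$truth), genome <- "g3"))
  expect_warning(a2 <- build_archetype(m3, og_bad), "without rep/cap")
  expect_equal(nrow(a2$placements), nrow(m))
})
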