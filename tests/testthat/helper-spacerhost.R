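# Shared fixtures, built in code. A small E-value calibration is cached per
# test run because several files need one.

.cache <- new.env(parent = emptyenv())

small_model <- function(lengths = 36L) {
  key <- paste0("m", paste(lengths, collapse = "_"))
  if (is.null(.cache[[key]]))
    .cache[[key]] <- calibrate_evalue(lengths, calib_db_nt = 2e5,
                                      n_replicates = 200, seed = 99L)
  .cache[[key]]
}

# Host config small enough for fast detection tests.
small_host_cfg <- function(seed = 42L, n_spacers = 10L, host_length = 60000L, ...) {
  sim_config(seed = seed, host_length = host_length, n_spacers = n_spacers, ...)
}

# A virus carrying the given plants over externally supplied spacers.
virus_with_plants <- function(plants, spacers, seed = 7L, id = "v1",
                              seed_offset = 0L, ...) {
  cfg <- sim_config(seed = seed, host_length = 60000L,
                    n_spacers = max(2L, length(spacers)),
                    planted = plants, ...)
  generate_virus(cfg, spacers, id = id, seed_offset = seed_offset)
}

# Matches table assembled from generator ground truth (spacer names sp<i>).
matches_from_truth <- function(truth, identity_col = TRUE) {
  data.frame(spacer = paste0("sp", truth$spacer_index),
             genome = truth$virus_id, strand = truth$strand,
             start = truth$start, end = truth$end,
             score = 36L, evalue = 1e-6,
             identity = if (identity_col) truth$identity else 1,
             gaps_query = truth$gaps_query, gaps_subject = truth$gaps_subject,
             mode = "glocal", stringsAsFactors = FALSE)
}

# Random spacers screened to be free of the origin nonanucleotide on either
# strand, so planting them never creates a second origin motif.
random_spacers <- function(n, len = 36L, seed = 1L) {
  withr::with_seed(seed, {
    draw <- function() {
      repeat {
        s <- random_dna(len)
        if (length(spacerhost:::iupac_match_starts(s, "NAGTRTTAC",
                                                   circular = FALSE)) == 0L &&
            length(spacerhost:::iupac_match_starts(revcomp(s), "NAGTRTTAC",
                                                   circular = FALSE)) == 0L)
          return(s)
      }
    }
    stats::setNames(vapply(seq_len(n), function(i) draw(), character(1)),
                    paste0("sp", seq_len(n)))
  })
}
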