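#!/usr/bin/env Rscript
# Stage 4: PAM discovery from protospacer flanks.
#
# Takes the best glocal match per spacer, reads 10 nt of upstream and
# downstream flank in spacer-transcription sense (non-target strand), builds
# position frequency matrices with per-position information content, and
# calls the conserved motif. A Type I PAM is expected upstream at -3..-1.

library(spacerhost)

matches <- utils::read.table("results/03_matches.tsv", header = TRUE,
                             sep = "\t", stringsAsFactors = FALSE)
matches <- matches[matches$mode == "glocal", , drop = FALSE]
vfiles <- Sys.glob("scratch/sim/virus_*.fasta")
genomes <- unlist(lapply(vfiles, read_fasta))
anns <- lapply(sub("\\.fasta$", ".gff3", vfiles), read_gff3)
names(anns) <- names(genomes)
oriented_seqs <- vapply(names(genomes), function(nm)
  orient_genome(genomes[[nm]], annotation = anns[[nm]], id = nm)$sequence,
  character(1))

out <- list()
for (side in c("upstream", "downstream")) {
  fl <- extract_flanks(matches, oriented_seqs, side, flank_len = 10L,
                       selection = "best-per-spacer")
  pfm <- build_pfm(fl)
  mc <- call_motif(pfm, conservation_threshold = 0.6)
  tab <- as.data.frame(t(rbind(pfm$freq, IC = pfm$ic)))
  tab <- cbind(position = pfm$positions, tab)
  utils::write.table(tab, sprintf("results/04_pfm_%s.tsv", side), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  out[[side]] <- list(motif = mc$motif, offsets = mc$offsets,
                      conservation = as.list(mc$conservation),
                      completeness = mc$completeness,
                      any_position = mc$any_position, n = pfm$n)
  message(sprintf("%-10s n=%d motif '%s' at [%s]; completeness %.2f, any %.2f",
                  side, pfm$n, mc$motif, paste(mc$offsets, collapse = ","),
                  mc$completeness, mc$any_position))
}
jsonlite::write_json(out, "results/04_motif_calls.json", auto_unbox = TRUE,
                     digits = NA, pretty = TRUE)
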