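#!/usr/bin/env Rscript
# Stage 6: archetype genome map.
#
# All the simulated (and real) genomes share one architecture, so every
# representative protospacer can be drawn on a single averaged genome:
# segment lengths are means over the contributing genomes and each
# protospacer sits at its fractional position within its segment.

library(spacerhost)

matches <- utils::read.table("results/03_matches.tsv", header = TRUE,
                             sep = "\t", stringsAsFactors = FALSE)
best <- matches[order(matches$spacer, -matches$score, matches$evalue), ]
best <- best[!duplicated(best$spacer), ]

vfiles <- Sys.glob("scratch/sim/virus_*.fasta")
genomes <- unlist(lapply(vfiles, read_fasta))
anns <- lapply(sub("\\.fasta$", ".gff3", vfiles), read_gff3)
names(anns) <- names(genomes)
oriented <- lapply(names(genomes), function(nm)
  orient_genome(genomes[[nm]], annotation = anns[[nm]], id = nm))
names(oriented) <- names(genomes)

arch <- build_archetype(best, oriented)
print(arch)
print(arch$segments)
utils::write.table(arch$segments, "results/06_archetype_segments.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)
utils::write.table(arch$placements, "results/06_archetype_placements.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)
jsonlite::write_json(list(segments = arch$segments,
                          placements = arch$placements,
                          n_genomes = arch$n_genomes),
                     "results/06_archetype.json", auto_unbox = TRUE,
                     digits = NA, pretty = TRUE)
message(sprintf("placed %d representatives on the archetype (%d genomes)",
                nrow(arch$placements), arch$n_genomes))
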