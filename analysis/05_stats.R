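#!/usr/bin/env Rscript
# Stage 5: strand-bias, density, stop-codon and spacer-age statistics.
#
# The exact one-sided binomial tail quantifies the bias toward targeting the
# encapsidated viral ssDNA strand; target densities are split by gene and by
# coding/template strand; stop-codon usage profiles the amber depletion
# expected for viruses of a pyrrolysine-utilising host; identity decays with
# spacer age (distance from the leader).

library(spacerhost)

matches <- utils::read.table("results/03_matches.tsv", header = TRUE,
                             sep = "\t", stringsAsFactors = FALSE)
glocal_m <- matches[matches$mode == "glocal", , drop = FALSE]
best <- glocal_m[order(glocal_m$spacer, -glocal_m$score, glocal_m$evalue), ]
best <- best[!duplicated(best$spacer), ]
best_all <- matches[order(matches$spacer, -matches$score, matches$evalue), ]
best_all <- best_all[!duplicated(best_all$spacer), ]

bias <- strand_bias_test(nrow(best), sum(best$strand == "+"))
print(bias)
bias_all <- strand_bias_test(nrow(best_all), sum(best_all$strand == "+"))
stats_tab <- data.frame(
  set = c("glocal", "glocal+local"),
  n_total = c(bias$n_total, bias_all$n_total),
  n_viral = c(bias$n_viral, bias_all$n_viral),
  pct_complementary = c(bias$pct_complementary, bias_all$pct_complementary),
  one_sided_p = signif(c(bias$p, bias_all$p), 3))
utils::write.table(stats_tab, "results/05_strand_bias.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)

vfiles <- Sys.glob("scratch/sim/virus_*.fasta")
genomes <- unlist(lapply(vfiles, read_fasta))
anns <- lapply(sub("\\.fasta$", ".gff3", vfiles), read_gff3)
names(anns) <- names(genomes)
dens <- do.call(rbind, lapply(names(genomes), function(nm) {
  m <- glocal_m[glocal_m$genome == nm, , drop = FALSE]
  if (!nrow(m)) return(NULL)
  cbind(genome = nm, target_density(m, anns[[nm]], nchar(genomes[[nm]])))
}))
utils::write.table(dens, "results/05_target_density.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)

# stop-codon usage of the simulated viral CDS set
cds <- unlist(lapply(names(genomes), function(nm) {
  a <- anns[[nm]]
  genes <- a[a$type == "gene", , drop = FALSE]
  vapply(seq_len(nrow(genes)), function(i)
    substr(genomes[[nm]], genes$start[i] + 1L, genes$end[i]), character(1))
}))
prof <- stop_codon_profile(cds, "simulated viral CDS")
print(prof)
utils::write.table(data.frame(codon = names(prof$counts),
                              count = as.integer(prof$counts),
                              percent = round(prof$percent, 2)),
                   "results/05_stop_codons.tsv", sep = "\t", quote = FALSE,
                   row.names = FALSE)

age <- suppressWarnings(identity_by_age(glocal_m))
print(age)
utils::write.table(age, "results/05_identity_by_age.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)

M <- presence_matrix(glocal_m)
pm <- data.frame(spacer = rownames(M), round(M, 3), check.names = FALSE)
utils::write.table(pm, "results/05_presence_matrix.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE, na = "")
message(sprintf("most-targeted genome: %s (%d of %d spacers)",
                names(which.max(attr(M, "targets_per_genome"))),
                max(attr(M, "targets_per_genome")), nrow(M)))
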