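#!/usr/bin/env Rscript
# Stage 1: simulate the study system.
#
# One 2.5 Mb host contig carrying a 112-repeat CRISPR array (31-nt repeat,
# AT-rich leader, degenerate distal repeat) plus a 3-repeat satellite array on
# the opposite strand 3 kb away, and three 2.5 kb circular rep/cap viruses
# carrying 23 planted protospacers (15 on the viral strand, 8 complementary,
# identities 0.91-1.00, PAM "CCN" upstream in 22 of 23).
#
# Large sequence artifacts go to scratch/sim/ (regenerable); ground-truth
# tables go to results/.

library(spacerhost)

seed <- 1L
dir.create("scratch/sim", recursive = TRUE, showWarnings = FALSE)
dir.create("results", recursive = TRUE, showWarnings = FALSE)

strands <- c(rep("viral", 15), rep("complementary", 8))
withr::with_seed(seed, strands <- sample(strands))
region_cycle <- c("rep", "cap", "intergenic", "cap", "rep", "cap", "rep", "cap")
groups <- split(1:23, rep(1:3, length.out = 23))

cfg <- sim_config(seed = seed, n_spacers = 111L)
message("generating 2.5 Mb host with 112-repeat array ...")
host <- generate_host(cfg)
write_fasta(c(host_contig = host$sequence), "scratch/sim/host.fasta")
utils::write.table(host$truth$b1$spacers, "results/01_true_spacers.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)

truths <- list()
for (g in seq_along(groups)) {
  idx <- groups[[g]]
  plants <- lapply(seq_along(idx), function(k)
    plant_spec(idx[k], strands[idx[k]],
               identity_fraction = 1 - (idx[k] - 1) %% 4 * 0.03,
               region = region_cycle[k], with_pam = idx[k] %% 23L != 0L))
  cfgv <- sim_config(seed = seed, n_spacers = 111L, planted = plants)
  v <- generate_virus(cfgv, host$truth$b1$spacers$seq,
                      id = paste0("virus_", g), seed_offset = 10L * g)
  write_fasta(stats::setNames(v$sequence, v$id),
              sprintf("scratch/sim/%s.fasta", v$id))
  write_gff3(v$annotation, sprintf("scratch/sim/%s.gff3", v$id), seqname = v$id)
  truths[[g]] <- v$truth
}
truth <- do.call(rbind, truths)
utils::write.table(truth, "results/01_ground_truth.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
yaml::write_yaml(list(seed = seed, host_length = cfg$host_length,
                      n_spacers = cfg$n_spacers, repeat_seq = cfg$repeat_seq,
                      n_viruses = length(groups), n_plants = nrow(truth),
                      viral_strand_plants = sum(truth$strand == "+")),
                 "results/01_sim_config.yaml")

message(sprintf("planted %d protospacers (%d viral-strand) across %d genomes",
                nrow(truth), sum(truth$strand == "+"), length(groups)))
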