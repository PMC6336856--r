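# spacerhost

CRISPR spacer evidence for assigning small circular ssDNA (CRESS-DNA)
viruses to prokaryotic hosts.

Prokaryotic CRISPR arrays archive fragments of past invaders as spacers
between copies of a repeat; a spacer matching a protospacer in a viral
genome implicates the CRISPR-bearing organism as a host. For ~2.5 kb
smacovirus-like genomes and ~36 nt spacers this needs machinery that
seeded aligners and stock statistics do not provide, and `spacerhost`
implements the full chain:

- **CRISPR detection** — k-mer-seeded discovery of repeat arrays
  (≥ 4 repeats; smaller satellite arrays retained near a selected array when
  they share its repeat on either strand), leader calling from
  terminal-repeat degeneracy with AT-richness tie-break, spacers indexed
  from the leader in transcription (crRNA) sense.
- **Glocal alignment** — the entire spacer aligned against a local region of
  a circular viral genome (affine gaps: match +1, mismatch −1, gap open −2,
  gap extend −1; both strands; origin-spanning hits), plus a plain local
  (Smith–Waterman) fallback mode. Implemented in C++; verified against an
  exhaustive brute-force oracle and an independent library implementation.
- **Empirical E-values** — per-query-length calibration against random
  sequence with an exponential tail fit, linear scaling to database size,
  and the array-level combined significance
  `n_spacers^k × Π e_i`. With the archetypal per-spacer E-values
  (0.002, 7.48×10⁻⁷, 7.06×10⁻⁶, 2.91×10⁻⁸) and n = 111 this gives ≈5×10⁻¹⁴;
  111 queries at cut-off 0.01 expect 1.11 chance matches.
- **PAM discovery** — 10 nt protospacer flanks in spacer sense, position
  frequency matrices with information content (`IC = 2 − H` bits), and
  conservation-threshold motif calls (e.g. `CC` at −3, −2 ⇒ PAM "CCN").
- **Strand-bias and corroborating statistics** — exact one-sided binomial
  tail for viral- vs complementary-strand targeting
  (15 of 23 → p = 0.105), per-region target densities, amber/opal/ochre
  stop-codon profiles, identity-by-spacer-age summaries, and the
  spacer × genome presence matrix.
- **Archetype map** — genomes oriented to the viral sense via the
  replication-origin nonanucleotide `NAGTRTTAC`, protospacers placed at
  fractional positions on an averaged archetype genome.
- **Synthetic data** — seeded generators for megabase hosts with planted
  CRISPR loci and circular rep/cap viruses with planted protospacers
  (controlled identity, gaps, strand, PAM), carrying full ground truth.

## Worked example

Plant two protospacers into a synthetic 2.5 kb virus and recover them:

```r
library(spacerhost)

cfg <- sim_config(seed = 42, host_length = 60000, n_spacers = 10,
                  planted = list(
                    plant_spec(1, "viral", 1.0, region = "rep"),
                    plant_spec(2, "complementary", 0.9, region = "cap")))
host  <- generate_host(cfg)
sp    <- setNames(host$truth$b1$spacers$seq, paste0("sp", 1:10))
virus <- generate_virus(cfg, host$truth$b1$spacers$seq, id = "v1")

model <- calibrate_evalue(unique(nchar(sp)), calib_db_nt = 1e6,
                          n_replicates = 500, seed = 5)
hits  <- scan_spacers(sp, c(v1 = virus$sequence), evalue_model = model,
                      threshold = 0.01)
hits[, c("spacer", "strand", "start", "end", "score", "evalue", "identity")]
#>   spacer strand start  end score       evalue  identity
#> 1    sp1      +  2261 2298    37 8.843581e-15 1.0000000
#> 2    sp2      -  1058 1093    27 1.645642e-08 0.8857143

strand_bias_test(23, 15)
#> 15 of 23 targets on the viral strand (35% complementary); one-sided p = 0.105
```

`sp1` is recovered exactly where it was planted on the viral strand
(E ≈ 9×10⁻¹⁵); `sp2` on the complementary strand at its realized identity
(0.886, i.e. four substitutions over 35 columns). The binomial line is the
strand-bias summary for a 15-of-23 viral-strand split: the probability of a
bias at least this large by chance is 0.105.

## The analysis workflow

`analysis/01_simulate.R` … `analysis/06_archetype.R` run the study
end-to-end at full scale — a 2.5 Mb host with a 112-repeat array plus
opposite-strand satellite, three viruses carrying 23 planted protospacers —
writing per-stage tables under `results/` (large regenerable FASTA goes to
`scratch/`). Each script prints what it found; stage 2, for instance,
recovers the planted 112-repeat array exactly and stage 3 recovers all 23
plants at E ≤ 0.01.

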