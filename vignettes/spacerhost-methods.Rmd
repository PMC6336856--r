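---
title: "Methods: CRISPR spacer evidence for virus-host assignment"
author: "spacerhost"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: CRISPR spacer evidence for virus-host assignment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Small circular Rep-encoding ssDNA (CRESS-DNA) viruses such as smacoviruses
(~2.5 kb, two genes: *rep* and *cap*) are abundant in faecal viromes but have
no confirmed hosts. In prokaryotes, CRISPR arrays archive fragments of past
invaders as spacers, so a spacer matching a protospacer in a viral genome is
strong evidence that the CRISPR-bearing organism is (or was) a host of that
virus. `spacerhost` implements the full computational chain for this kind of
inference on short, fast-evolving queries: CRISPR array detection and leader
calling, a sensitive non-seeded aligner with empirical significance,
array-level combined significance, PAM confirmation, strand-bias and
stop-codon corroboration, and an "archetype" projection that summarises all
targets on one averaged genome. Every stage is validated against seeded
synthetic data with planted ground truth.

## The glocal aligner

Spacers are ~36 nt; seeded heuristics such as BLAST lose sensitivity at this
length, and ordinary local alignment will happily clip a spacer down to its
conserved core, obscuring whether the *whole* spacer matches. The central
aligner is therefore semi-global — "glocal": the **entire query** is aligned
against a **local region of the subject**. In dynamic-programming terms the
first query row is initialised to zero (the alignment may start at any
subject position), terminal subject gaps are free, interior cells follow the
global (Needleman-Wunsch/Gotoh) recurrences with affine gaps, and the
traceback starts from the maximal cell in the last query row. Scoring is
match +1, mismatch −1, gap open −2, gap extend −1, read as: the first gapped
base costs 2 and each additional base 1, so a gap of length *g* costs
*g* + 1. Non-ACGT characters mismatch everything. Ties in the traceback
prefer diagonal moves over gaps in the subject over gaps in the query, and
among equal-scoring ends the smallest subject end coordinate — this makes
results byte-reproducible. A plain Smith-Waterman mode with the same scoring
serves as the fallback search for more diverged targets.

Circular subjects are searched across the origin by extending the subject
with `qlen + 7` wrap-around bases (a little more than the query length so
gapped origin-spanning hits are not truncated); hit coordinates are remapped
modulo the genome length and exact duplicates collapse.

Correctness is not argued, it is tested: the DP equals an exhaustive
branch-and-bound enumeration of *all* glocal alignments on a thousand random
small instances per run, agrees with an independent library implementation
of global-local alignment on random pairs, is strand-symmetric, and its
score always re-sums from the traceback strings.

## Empirical E-values

No analytic Karlin-Altschul statistics exist for this scoring scheme, so
significance is calibrated empirically, per query length: `n_replicates`
random queries are aligned against independent i.i.d.-uniform random
subjects (one fresh query per subject) and the best score per pair is
recorded. The exceedance count `N(S)` per calibration nucleotide estimates
the rate of chance alignments scoring at least `S`; an E-value is that rate
times the searched database size, counting both strands. Beyond the
well-sampled range the survival function is extrapolated with an exponential
tail fitted to its rarest well-populated decade (scores with counts between
1 and a tenth of the sample), which behaves like the Gumbel tails expected
for optimal alignment scores and reaches the 1e-7 territory of real matches
without astronomical simulation. Calibration subject length defaults to
`calib_db_nt / n_replicates`; choosing it equal to the real genome length
makes per-subject exceedance probabilities transfer exactly. The local
fallback search is calibrated against its own (local-alignment) null, since
local scores stochastically dominate glocal scores.

Two consequences of integer scores are worth stating. First, only tabulated
E-values are achievable thresholds: a cut-off of 0.01 actually admits
matches at the largest achievable E-value at or below 0.01, so the expected
chance-match count `n_queries x threshold` is an upper bound; the package's
self-consistency experiment therefore measures honesty at a model-achievable
threshold chosen from a well-sampled region of the calibrated table (counts
at least 1000, keeping the calibration's own sampling error well below the
experiment's). Second, circular search adds ~`qlen/genome_length` extra
search space relative to the linear calibration subjects (≈1.5% here),
a conservative bias we accept.

The array-level combined significance follows first-order chance arithmetic: the
chance of one match at least as good as E-value *e* among *n* spacers is
about *n·e*, so *k* such matches combine to *n^k · Π e_i*; the four
archetypal per-spacer E-values (0.002, 7.48e-7, 7.06e-6, 2.91e-8) with
n = 111 give ≈4.7e-14, and 111 queries at a 0.01 cut-off are expected to
produce 1.11 chance matches.

## CRISPR detection and the leader

The array detector is k-mer-seeded (k = 11): exact 11-mer recurrences at a
distance compatible with one repeat-plus-spacer period (repeat 23-47 nt,
spacer 20-72 nt by default — canonical CRISPR bounds) seed candidate repeat
pairs; chains of pairs become candidate arrays; instances are snapped to a
common frame, and repeat boundaries are refined by column conservation
across instances (all instances when there are six or more — a lone
degenerate terminal barely moves conservation — otherwise the near-exact
subset, so low-copy arrays are not eroded by their degenerate terminal).
Terminal instances are recovered by an approximate extension step with a
larger mismatch allowance (default 8), because the repeat most distant from
the leader is typically degenerate. Arrays need at least four repeats;
smaller satellite arrays are retained only within 10 kb of a selected array
and only when their consensus matches its repeat on either strand. That
comparison is done with the aligner itself (clipping boundary junk) rather
than an ungapped Hamming distance, because boundary calls on two- or
three-copy arrays are underdetermined by a few bases — a known limitation;
satellite instance coordinates are approximate.

The leader side is called primarily from terminal-repeat conservation (the
distal repeat is degenerate; the leader-proximal one is pristine), with
AT-richness of the flank as tie-breaker and as a confirmatory annotation.
Spacers are indexed 1..n from the leader and reported in transcription
(crRNA) sense, which fixes the upstream/downstream orientation used for PAM
flanks. Coordinates are 0-based half-open throughout the package's tables.

## PAM discovery

For each selected match (by default the best representative per spacer:
highest score, then lowest E-value, then first genome in input order), 10 nt
flanks are read adjacent to the protospacer on the non-target strand — the
strand matching the spacer's sense — with upstream meaning 5' of that
reading, where Type I PAMs sit. Flank stacks become position frequency
matrices with information content `IC = 2 − H` bits per column. No
small-sample correction is applied by default (the flag exists): with stacks
of 6-23 sequences the corrected and raw logos rank positions identically and
the raw definition is the simpler reproducible contract. A motif call takes
every position whose dominant base reaches the conservation threshold
(default 0.6, which recovers CCN-like PAMs at the observed ~78% penetrance
without calling noise positions at these stack sizes) and reports per-position
conservation, completeness (fraction of flanks carrying the full motif) and
the any-position fraction.

## Strand bias and the other corroborating statistics

CRESS-DNA viruses encapsidate one strand. If the CRISPR system only engaged
the double-stranded replication intermediate, spacer targets should split
evenly between strands; an excess of viral-strand targets hints at ssDNA
targeting. The test is the exact one-sided binomial tail
`P(X >= n_viral | n, 1/2)` by direct summation — no approximation — and it
is verified against full enumeration of all `2^n` outcomes for small n, and
for calibration of its type-I error at the study's n under the null.
Probabilities are reported to 3 significant figures, percentages to whole
percent (8 complementary of 23 = 35%).

Stop-codon profiling counts the final codon of each CDS as amber (TAG), opal
(TGA) or ochre (TAA), excluding (and counting) sequences that do not end in
a standard stop. Hosts that reassign amber to pyrrolysine are depleted in
amber termination, and so — the argument goes — are their viruses. Age
strata summarise best-match identity by leader distance (modern sp1-9,
middle sp12-27, ancient sp35-72, inclusive): spacer-protospacer identity
decays with spacer age. The presence matrix keeps the best identity per
(spacer, genome) with row/column marginals.

## Genome orientation and the archetype

Genomes are oriented to the viral sense by the replication-origin
nonanucleotide `NAGTRTTAC` (IUPAC), searched on both strands across the
origin: found only on the reverse strand, the genome is
reverse-complemented (annotations flip along); absent or on both strands is
an error. No distance-to-*rep* constraint is enforced — the motif's
"shortly downstream of the rep stop" placement is a property of the data,
not a filter. Since all these genomes share one architecture, every
representative protospacer can be drawn on a single averaged archetype:
segment lengths (intergenic-A, cap, intergenic-B, rep — in that display
order) are means over the genomes contributing representatives, and each
protospacer sits at its fractional position within its segment, anchored at
the protospacer midpoint (symmetric and stable at segment boundaries; start,
midpoint and end anchors are all defensible and midpoint is the neutral one). Matches found only by
the local fallback are marked `local_only`.

## The synthetic study system

The generator defaults *are* the study conditions: a 2.5 Mb host contig
with a 112-repeat array of the 31-mer `GTTAGAAATCCATCTAAACTAGAATGTAAAT`,
35-37 nt spacers (the one stated spacer length is 36), a 150 nt AT-rich
leader (AT fraction 0.7; leaders are AT-rich but no value is stated), a
degenerate distal repeat (3-6 substitutions), and a 3-repeat satellite array
with the same repeat on the opposite strand 3 kb away; viruses are 2.5 kb
circles with *rep* (750 nt) and *cap* (975 nt — 30% larger, matching the
stated ratio) ORFs on the viral strand, the nonanucleotide 20 nt downstream
of the *rep* stop, and protospacers planted with controlled identity, gap
structure, strand and PAM. Background sequence is i.i.d. uniform A/C/G/T —
a neutral null matching the E-value calibration. Substitutions realizing a
requested identity are placed uniformly (never in the PAM when one is
planted, to keep the PAM signal testable); identity is defined as identical
columns over all alignment columns, gaps included, so the realized value
matches the request up to one substitution's quantization. Coordinate origin
is the base after the nonanucleotide. Everything is byte-deterministic under
the config seed.

What the generator does **not** emulate: realistic codon usage or protein
sequence, phylogenetic structure among viruses, compositional biases
(repeats, skews) of real genomes, or sequencing artefacts. Passing tests
demonstrate correctness of the machinery and calibration under the declared
null, not performance on real metagenomes — on real data, compositional
bias makes empirical E-values somewhat optimistic, which is the same caveat
that applies to any i.i.d.-null alignment statistic.

## Numerical and degenerate-input choices

Empty match sets short-circuit cleanly (empty report, no PAM section);
combined significance of an empty E-value list is 1.0; E-values above 1 in
the combination trigger a warning, not clipping. An unreliable tail fit
(too few exceedances) flags scores beyond the observed range rather than
inventing precision. Strata with no matches are omitted with a warning.
Spurious origin motifs created by random background are repaired by
mutating a literal motif position outside any planted feature; if a planted
protospacer itself contains the motif the genome is rejected with an error
rather than silently de-duplicated.

## Problem sizes used in validation

The test-suite experiments use: 1000 random instances for the brute-force
oracle (query ≤ 10 nt, subject ≤ 14 nt) and 1000 for strand symmetry; 200
seeded plants per identity level for recovery; an E-value honesty experiment
with a 5e7 nt calibration (20 000 pairs at the genome length, 2500 nt) and
200 fresh scan replicates of 25 queries against two genomes; 100 seeded
datasets of 23 flanks for PAM recovery at 78% penetrance; 10 000 replicates
for the binomial type-I calibration; and 100 seeded 30 kb hosts for
leader-side recovery. Unit tests run the detector on 60 kb hosts; the
analysis scripts run the full 2.5 Mb study scale. These sizes were chosen so
each check's sampling error is small against the property it tests.
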