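#' Configuration for the synthetic host/virus generators
#'
#' Bundles every tunable of the simulated study system: a megabase-scale host
#' contig carrying a large CRISPR array (plus a small satellite array on the
#' opposite strand ~3 kb away), and small (~2.5 kb) circular Rep/Cap-encoding
#' ssDNA virus genomes into which protospacers are planted with controlled
#' identity, gap structure, strand and PAM. Defaults reproduce the study
#' system: a 2.5 Mb host, a 112-repeat array of the 31-nt repeat
#' `GTTAGAAATCCATCTAAACTAGAATGTAAAT`, 35-37 nt spacers, an AT-rich leader,
#' and 2.5 kb viruses with the replication-origin nonanucleotide `NAGTRTTAC`
#' shortly downstream of the *rep* stop codon.
#'
#' @param seed integer seed; the generators are byte-deterministic given it.
#' @param host_length host contig length (nt).
#' @param repeat_seq CRISPR repeat sequence.
#' @param n_spacers number of spacers in the main (B1-like) array; the array
#'   then has `n_spacers + 1` repeat instances.
#' @param spacer_len_range inclusive (min, max) spacer length in nt.
#' @param leader_len,leader_at_fraction leader length and its target AT
#'   fraction (leaders are AT rich).
#' @param b2_n_repeats,b2_distance repeat count of the small opposite-strand
#'   satellite array and its distance (nt) from the main array; set
#'   `b2_n_repeats = 0` to omit it.
#' @param virus_length circular virus genome length (nt).
#' @param rep_len,cap_len lengths of the *rep* and *cap* ORFs (nt, multiples
#'   of 3); the default *cap* is 30% larger than *rep*.
#' @param ori_gap nt between the *rep* stop codon and the nonanucleotide.
#' @param nonanucleotide IUPAC replication-origin motif (length 9).
#' @param pam IUPAC protospacer adjacent motif written upstream of planted
#'   protospacers (in spacer-transcription sense) when requested.
#' @param stop_probs named probabilities for the ORF terminal stop codon
#'   (TAA/TGA/TAG); amber is rare, mirroring pyrrolysine-using hosts.
#' @param planted list of [plant_spec()] entries.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       host_length = 2500000L,
                       repeat_seq = "GTTAGAAATCCATCTAAACTAGAATGTAAAT",
                       n_spacers = 111L,
                       spacer_len_range = c(35L, 37L),
                       leader_len = 150L,
                       leader_at_fraction = 0.7,
                       b2_n_repeats = 3L,
                       b2_distance = 3000L,
                       virus_length = 2500L,
                       rep_len = 750L,
                       cap_len = 975L,
                       ori_gap = 20L,
                       nonanucleotide = "NAGTRTTAC",
                       pam = "CCN",
                       stop_probs = c(TAA = 0.62, TGA = 0.34, TAG = 0.04),
                       planted = list()) {
  repeat_seq <- toupper(repeat_seq)
  if (nchar(nonanucleotide) != 9L) stop("nonanucleotide must be 9 nt")
  if (rep_len %% 3L || cap_len %% 3L) stop("rep_len and cap_len must be multiples of 3")
  if (leader_at_fraction <= 0 || leader_at_fraction >= 1) stop("leader_at_fraction in (0,1)")
  footprint <- leader_len + (n_spacers + 1L) * nchar(repeat_seq) +
    n_spacers * max(spacer_len_range) +
    (b2_n_repeats > 0L) * (b2_distance + leader_len +
                             b2_n_repeats * (nchar(repeat_seq) + max(spacer_len_range)))
  if (host_length <= footprint + 2000L)
    stop("host_length too small for the configured CRISPR loci")
  ig_total <- virus_length - rep_len - cap_len - ori_gap - 9L
  if (ig_total < 40L) stop("virus gene lengths leave no room for intergenic regions")
  cfg <- list(seed = as.integer(seed), host_length = as.integer(host_length),
              repeat_seq = repeat_seq, n_spacers = as.integer(n_spacers),
              spacer_len_range = as.integer(spacer_len_range),
              leader_len = as.integer(leader_len),
              leader_at_fraction = leader_at_fraction,
              b2_n_repeats = as.integer(b2_n_repeats),
              b2_distance = as.integer(b2_distance),
              virus_length = as.integer(virus_length),
              rep_len = as.integer(rep_len), cap_len = as.integer(cap_len),
              ori_gap = as.integer(ori_gap),
              ig_a = ig_total %/% 2L, ig_b = ig_total - ig_total %/% 2L,
              nonanucleotide = toupper(nonanucleotide), pam = toupper(pam),
              stop_probs = stop_probs, planted = planted)
  class(cfg) <- "sim_config"
  cfg
}

#' Specification of one planted protospacer
#'
#' @param spacer_index 1-based spacer index counted from the leader.
#' @param target_strand `"viral"` (the spacer-identical sequence lies on the
#'   encapsidated viral-sense strand) or `"complementary"`.
#' @param identity_fraction requested alignment identity in (0, 1]; identical
#'   columns over all alignment columns, gap columns included.
#' @param n_gaps_query,n_gaps_subject gap characters to realize in the query
#'   (spacer) and subject (protospacer) rows of the implied alignment, i.e.
#'   bases inserted into / deleted from the planted copy.
#' @param region `"rep"`, `"cap"` or `"intergenic"`; where to place the plant.
#' @param with_pam write the PAM immediately upstream (spacer sense).
#' @param at optional explicit 0-based start on the viral-sense strand
#'   (may wrap the origin); overrides `region`.
#' @return an object of class `plant_spec`.
#' @export
plant_spec <- function(spacer_index, target_strand = c("viral", "complementary"),
                       identity_fraction = 1.0, n_gaps_query = 0L,
                       n_gaps_subject = 0L, region = c("rep", "cap", "intergenic"),
                       with_pam = TRUE, at = NULL) {
  target_strand <- match.arg(target_strand)
  region <- match.arg(region)
  if (identity_fraction <= 0 || identity_fraction > 1)
    stop("identity_fraction must be in (0,1]")
  structure(list(spacer_index = as.integer(spacer_index),
                 target_strand = target_strand,
                 identity_fraction = identity_fraction,
                 n_gaps_query = as.integer(n_gaps_query),
                 n_gaps_subject = as.integer(n_gaps_subject),
                 region = region, with_pam = isTRUE(with_pam),
                 at = if (is.null(at)) NULL else as.integer(at)),
            class = "plant_spec")
}

#' Serialize / restore a simulation config as YAML
#'
#' Plant specs are stored as plain lists and rebuilt on read.
#'
#' @param config a [sim_config()].
#' @param path file path.
#' @return `read_sim_config` returns the restored `sim_config`.
#' @export
write_sim_config <- function(config, path) {
  obj <- unclass(config)
  obj$planted <- lapply(obj$planted, unclass)
  obj$stop_probs <- as.list(obj$stop_probs)
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  obj <- yaml::read_yaml(path)
  obj$stop_probs <- unlist(obj$stop_probs)
  obj$planted <- lapply(obj$planted, function(p)
    plant_spec(p$spacer_index, p$target_strand, p$identity_fraction,
               p$n_gaps_query, p$n_gaps_subject, p$region, p$with_pam,
               at = p$at))
  do.call(sim_config, obj[c("seed", "host_length", "repeat_seq", "n_spacers",
                            "spacer_len_range", "leader_len",
                            "leader_at_fraction", "b2_n_repeats",
                            "b2_distance", "virus_length", "rep_len",
                            "cap_len", "ori_gap", "nonanucleotide", "pam",
                            "stop_probs", "planted")])
}

# AT-rich sequence for leaders.
random_at_rich <- function(n, at) {
  p <- c(at / 2, (1 - at) / 2, (1 - at) / 2, at / 2) # A C G T
  paste(sample(DNA_BASES, n, replace = TRUE, prob = p), collapse = "")
}

# One CRISPR locus in leader-left orientation:
# leader, repeat, sp1, repeat, sp2, ..., sp_n, degenerate terminal repeat.
build_locus <- function(cfg, n_spacers) {
  rep_seq <- cfg$repeat_seq
  leader <- random_at_rich(cfg$leader_len, cfg$leader_at_fraction)
  len_vals <- seq(cfg$spacer_len_range[1], cfg$spacer_len_range[2])
  lens <- len_vals[sample.int(length(len_vals), n_spacers, replace = TRUE)]
  spacers <- vapply(lens, random_dna, character(1))
  # distal repeat carries 3-6 substitutions (poorly conserved terminal repeat)
  nsub <- sample(3:6, 1)
  pos <- sample(nchar(rep_seq), nsub)
  dv <- strsplit(rep_seq, "")[[1]]
  for (p in pos) dv[p] <- mutate_base(dv[p])
  degen <- paste(dv, collapse = "")
  units <- character(0)
  for (i in seq_len(n_spacers)) units <- c(units, rep_seq, spacers[i])
  locus <- paste0(leader, paste(units, collapse = ""), degen)
  list(locus = locus, leader = leader, spacers = spacers, degenerate = degen,
       spacer_lens = lens)
}

#' Generate a synthetic host contig with planted CRISPR loci
#'
#' Produces a uniform-random background contig containing (i) a large
#' leader-left CRISPR array whose repeat most distant from the leader is
#' degenerate (3-6 substitutions) and (ii) optionally a small satellite array
#' with the same repeat on the opposite strand a configurable distance away.
#' Ground-truth coordinates (0-based, half-open) and the spacer sequences in
#' transcription (crRNA) sense are returned alongside the sequence.
#'
#' @param config a [sim_config()].
#' @return list with `sequence` (character string) and `truth` (list with
#'   elements `b1`, `b2`, each holding locus/leader coordinates, repeat
#'   instances and a spacer table).
#' @export
generate_host <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed, {
    L <- config$host_length
    x <- sample(DNA_BASES, L, replace = TRUE)
    b1 <- build_locus(config, config$n_spacers)
    b1_start <- L %/% 3L          # deterministic placement
    b1_len <- nchar(b1$locus)
    x[(b1_start + 1):(b1_start + b1_len)] <- strsplit(b1$locus, "")[[1]]

    rep_w <- nchar(config$repeat_seq)
    # repeat instance starts inside the locus (0-based on contig)
    starts <- integer(config$n_spacers + 1L)
    off <- config$leader_len
    for (i in seq_len(config$n_spacers + 1L)) {
      starts[i] <- b1_start + off
      if (i <= config$n_spacers) off <- off + rep_w + b1$spacer_lens[i]
    }
    sp_starts <- starts[seq_len(config$n_spacers)] + rep_w
    b1_truth <- list(
      start = b1_start, end = b1_start + b1_len, strand = "+",
      leader = c(b1_start, b1_start + config$leader_len), leader_side = "left",
      repeat_starts = starts, degenerate = b1$degenerate,
      spacers = data.frame(index = seq_len(config$n_spacers),
                           seq = b1$spacers,
                           start = sp_starts,
                           end = sp_starts + b1$spacer_lens,
                           stringsAsFactors = FALSE))

    b2_truth <- NULL
    if (config$b2_n_repeats > 0L) {
      b2 <- build_locus(config, config$b2_n_repeats - 1L)
      b2_fwd <- b2$locus
      b2_rc <- revcomp(b2_fwd)
      b2_start <- b1_start + b1_len + config$b2_distance
      x[(b2_start + 1):(b2_start + nchar(b2_rc))] <- strsplit(b2_rc, "")[[1]]
      b2_truth <- list(start = b2_start, end = b2_start + nchar(b2_rc),
                       strand = "-", leader_side = "right",
                       spacers = data.frame(index = seq_len(config$b2_n_repeats - 1L),
                                            seq = b2$spacers,
                                            stringsAsFactors = FALSE))
    }
    list(sequence = paste(x, collapse = ""),
         truth = list(b1 = b1_truth, b2 = b2_truth))
  })
}

# Random in-frame ORF: ATG + sense codons + one stop codon.
random_orf <- function(len, stop_probs) {
  stops <- c("TAA", "TAG", "TGA")
  sense <- setdiff(apply(expand.grid(DNA_BASES, DNA_BASES, DNA_BASES), 1, paste,
                         collapse = ""), stops)
  n_codons <- len %/% 3L - 2L
  stopc <- sample(names(stop_probs), 1, prob = stop_probs)
  paste0("ATG", paste(sample(sense, n_codons, replace = TRUE), collapse = ""), stopc)
}

# Realize a protospacer from a spacer under a plant_spec: deletions, insertions
# and substitutions chosen so the implied alignment has the requested gap
# counts and identity. Returns the subject-side string and realized stats.
realize_protospacer <- function(spacer, spec) {
  v <- strsplit(spacer, "")[[1]]
  lq <- length(v)
  gs <- spec$n_gaps_subject   # query bases deleted from the planted copy
  gq <- spec$n_gaps_query     # extra bases inserted into the planted copy
  if (gs >= lq - 2L) stop("too many subject gaps for spacer length")
  keep <- rep(TRUE, lq)
  if (gs > 0L) keep[sample(2:(lq - 1L), gs)] <- FALSE
  w <- v[keep]
  if (gq > 0L) {
    at <- sort(sample(seq_len(length(w) - 1L), gq, replace = FALSE))
    out <- character(0); prev <- 1L
    for (a in at) {
      out <- c(out, w[prev:a], sample(DNA_BASES, 1))
      prev <- a + 1L
    }
    w <- c(out, w[prev:length(w)])
  }
  cols <- lq + gq
  n_sub <- max(0L, round(lq - gs - spec$identity_fraction * cols))
  if (n_sub > 0L) {
    ps <- sample(seq_along(w), n_sub)
    for (p in ps) w[p] <- mutate_base(w[p])
  }
  realized_identity <- (lq - gs - n_sub) / cols
  list(seq = paste(w, collapse = ""), n_sub = n_sub,
       identity = realized_identity, columns = cols)
}

# Write characters into a circular genome vector, 0-based start.
circ_write <- function(x, start0, chars) {
  L <- length(x)
  idx <- ((start0 + seq_along(chars) - 1L) %% L) + 1L
  x[idx] <- chars
  x
}

#' Generate a synthetic circular smacovirus-like genome
#'
#' Builds a circular genome of `config$virus_length` nt laid out (from the
#' position after the replication-origin nonanucleotide) as intergenic-A,
#' *cap*, intergenic-B, *rep*, a short gap, then the nonanucleotide on the
#' viral-sense strand — i.e. the motif sits shortly downstream of the *rep*
#' stop codon. Protospacers from `spacers` are planted per the `planted`
#' specs in `config` with controlled identity, gap structure, strand and an
#' optional upstream PAM; the genome is post-processed so the nonanucleotide
#' occurs exactly once on the viral-sense strand and never on the complement.
#'
#' @param config a [sim_config()]; its `planted` list drives the plants.
#' @param spacers character vector of spacer sequences (crRNA sense), indexed
#'   by `spacer_index` of the plant specs.
#' @param id genome identifier.
#' @param seed_offset added to the config seed so one config can emit many
#'   distinct genomes deterministically.
#' @return list with `sequence`, `annotation` (0-based half-open feature
#'   table), and `truth` (one row per plant: coordinates on the viral-sense
#'   strand, strand, realized identity and gap counts).
#' @export
generate_virus <- function(config, spacers, id = "virus_1", seed_offset = 0L) {
  stopifnot(inherits(config, "sim_config"))
  bad <- vapply(config$planted, function(p) p$spacer_index > length(spacers),
                logical(1))
  if (any(bad)) stop("planted spacer index outside supplied spacer set")
  withr::with_seed(config$seed + 1000L + as.integer(seed_offset), {
    L <- config$virus_length
    ig_a <- config$ig_a; ig_b <- config$ig_b
    cap0 <- ig_a
    rep0 <- ig_a + config$cap_len + ig_b
    nona0 <- L - 9L
    genome <- paste0(random_dna(ig_a),
                     random_orf(config$cap_len, config$stop_probs),
                     random_dna(ig_b),
                     random_orf(config$rep_len, config$stop_probs),
                     random_dna(config$ori_gap),
                     sample_iupac(config$nonanucleotide))
    stopifnot(nchar(genome) == L)
    x <- strsplit(genome, "")[[1]]

    regions <- list(rep = c(rep0, rep0 + config$rep_len),
                    cap = c(cap0, cap0 + config$cap_len),
                    intergenic = c(cap0 + config$cap_len, rep0))
    occupied <- list(c(nona0 - 1L, L))     # spacing between plants
    core_prot <- list(c(nona0, L))         # bases that must never be touched
    truth <- list()
    for (spec in config$planted) {
      sp <- spacers[[spec$spacer_index]]
      pr <- realize_protospacer(sp, spec)
      plen <- nchar(pr$seq)
      if (!is.null(spec$at)) {
        p0 <- spec$at %% L
      } else {
        rg <- regions[[spec$region]]
        ok <- FALSE
        cand_pos <- seq(rg[1] + 5L, rg[2] - plen - 5L)
        for (try in 1:200) {
          p0 <- cand_pos[sample.int(length(cand_pos), 1)]
          win <- c(p0 - 4L, p0 + plen + 4L)
          clash <- any(vapply(occupied, function(o) win[1] < o[2] && o[1] < win[2],
                              logical(1)))
          if (!clash) { ok <- TRUE; break }
        }
        if (!ok) stop("could not place protospacer without overlap (placement error)")
      }
      ins <- if (spec$target_strand == "viral") pr$seq else revcomp(pr$seq)
      x <- circ_write(x, p0, strsplit(ins, "")[[1]])
      core_prot <- c(core_prot, list(c(p0, p0 + plen)))
      if (spec$with_pam) {
        pam <- strsplit(sample_iupac(config$pam), "")[[1]]   # e.g. C C N
        if (spec$target_strand == "viral") {
          x <- circ_write(x, p0 - length(pam), pam)
          core_prot <- c(core_prot, list(c(p0 - length(pam), p0)))
        } else {
          x <- circ_write(x, p0 + plen, strsplit(revcomp(paste(pam, collapse = "")),
                                                 "")[[1]])
          core_prot <- c(core_prot, list(c(p0 + plen, p0 + plen + length(pam))))
        }
      }
      occupied <- c(occupied, list(c(p0 - 4L, p0 + plen + 4L)))
      truth[[length(truth) + 1L]] <-
        data.frame(virus_id = id, spacer_index = spec$spacer_index,
                   start = p0, end = p0 + plen,
                   strand = if (spec$target_strand == "viral") "+" else "-",
                   identity = pr$identity,
                   gaps_query = spec$n_gaps_query,
                   gaps_subject = spec$n_gaps_subject,
                   with_pam = spec$with_pam,
                   stringsAsFactors = FALSE)
    }

    # enforce a unique viral-sense origin motif
    for (round in 1:20) {
      seqs <- paste(x, collapse = "")
      fwd <- iupac_match_starts(seqs, config$nonanucleotide, circular = TRUE)
      rev_ <- iupac_match_starts(revcomp(seqs), config$nonanucleotide, circular = TRUE)
      spurious_fwd <- setdiff(fwd, nona0)
      rev_fwd_coords <- if (length(rev_)) (L - (rev_ + 9L)) %% L else integer(0)
      extra <- c(spurious_fwd, rev_fwd_coords)
      if (!length(extra)) break
      fixed_any <- FALSE
      for (s0 in extra) {
        # offsets that are literal bases of the motif in either orientation,
        # so a substitution is guaranteed to break the match
        cand <- ((s0 + c(1L, 2L, 3L, 5L, 6L, 7L)) %% L)
        protected <- vapply(cand, function(p) {
          any(vapply(core_prot, function(o) {
            a <- o[1] %% L
            (p >= a && p < a + (o[2] - o[1])) ||
              (p + L >= a && p + L < a + (o[2] - o[1]))
          }, logical(1)))
        }, logical(1))
        cand <- cand[!protected]
        if (!length(cand)) next
        p <- cand[1]
        x[p + 1L] <- mutate_base(x[p + 1L])
        fixed_any <- TRUE
      }
      if (!fixed_any) stop("spurious origin motif inside protected region")
    }

    annotation <- data.frame(
      feature = c("intergenic_A", "cap", "intergenic_B", "rep", "nonanucleotide"),
      start = c(0L, cap0, cap0 + config$cap_len, rep0, nona0),
      end = c(cap0, cap0 + config$cap_len, rep0, rep0 + config$rep_len, L),
      strand = c("*", "+", "*", "+", "+"),
      type = c("intergenic", "gene", "intergenic", "gene", "origin"),
      stringsAsFactors = FALSE)
    list(sequence = paste(x, collapse = ""), annotation = annotation,
         truth = if (length(truth)) do.call(rbind, truth) else
           data.frame(virus_id = character(0)),
         id = id)
  })
}
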