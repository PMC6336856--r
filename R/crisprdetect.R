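#' Detect CRISPR repeat arrays in a genome
#'
#' K-mer-seeded detector for arrays of quasi-identical repeats separated by
#' spacers. Exact k-mer recurrences at a plausible repeat-plus-spacer period
#' seed candidate repeat pairs; chains of pairs become arrays; repeat
#' boundaries are refined by column conservation across instances; terminal
#' instances (which may be degenerate) are recovered by an approximate
#' extension step allowing extra mismatches.
#'
#' Coordinates in all returned tables are 0-based half-open on the forward
#' strand of the supplied contig.
#'
#' @param genome contig sequence (single character string).
#' @param min_repeats minimum repeat instances for an array to be reported.
#' @param repeat_len,spacer_len inclusive (min, max) length bounds.
#' @param max_repeat_mismatch per-instance mismatch tolerance to the
#'   consensus; terminal instances are allowed `terminal_mismatch`.
#' @param terminal_mismatch mismatch allowance for degenerate terminal repeats.
#' @param k seed word size.
#' @param contig contig identifier stored in the result.
#' @return list of `crispr_array` objects (possibly empty): each has the
#'   repeat `consensus`, an `instances` table, a `spacers` table, a `strand`
#'   (`"-"` when the consensus is the reverse complement of an earlier
#'   array's), and leader fields filled by [call_leader()].
#' @export
find_arrays <- function(genome, min_repeats = 4L, repeat_len = c(23L, 47L),
                        spacer_len = c(20L, 72L), max_repeat_mismatch = 3L,
                        terminal_mismatch = 8L, k = 11L, contig = "contig_1") {
  genome <- toupper(genome)
  x <- strsplit(genome, "")[[1]]
  n <- length(x)
  if (n == 0L) stop("empty genome")
  dmin <- repeat_len[1] + spacer_len[1]
  dmax <- repeat_len[2] + spacer_len[2]
  if (n < dmin + k) return(list())

  seed_start <- integer(0); seed_d <- integer(0); seed_len <- integer(0)
  for (d in dmin:dmax) {
    if (n - d < k) break
    eq <- x[1:(n - d)] == x[(1 + d):n]
    rs <- which(eq & !c(FALSE, eq[-length(eq)]))
    if (!length(rs)) next
    re <- which(eq & !c(eq[-1], FALSE))
    len <- re - rs + 1L
    keep <- len >= k
    if (any(keep)) {
      seed_start <- c(seed_start, rs[keep])
      seed_d <- c(seed_d, rep(d, sum(keep)))
      seed_len <- c(seed_len, len[keep])
    }
  }
  if (!length(seed_start)) return(list())
  seeds <- data.frame(start = seed_start, d = seed_d, len = seed_len)
  seeds <- seeds[order(seeds$start, -seeds$len, seeds$d), , drop = FALSE]

  used <- rep(FALSE, nrow(seeds))
  arrays <- list()
  slack <- 3L   # run starts jitter by chance extension into the spacers
  for (si in seq_len(nrow(seeds))) {
    if (used[si]) next
    chain_starts <- integer(0); chain_lens <- integer(0)
    cur <- seeds$start[si]
    repeat {
      hit <- which(!used & abs(seeds$start - cur) <= slack)
      if (!length(hit)) { chain_starts <- c(chain_starts, cur); break }
      hit <- hit[order(abs(seeds$start[hit] - cur), -seeds$len[hit],
                       seeds$d[hit])][1]
      cur <- seeds$start[hit]
      used[abs(seeds$start - cur) <= slack] <- TRUE
      chain_starts <- c(chain_starts, cur)
      chain_lens <- c(chain_lens, seeds$len[hit])
      cur <- cur + seeds$d[hit]
    }
    if (length(chain_starts) < 2L) next
    arr <- refine_array(x, chain_starts, chain_lens, repeat_len, spacer_len,
                        max_repeat_mismatch, terminal_mismatch)
    if (!is.null(arr)) arrays[[length(arrays) + 1L]] <- arr
  }
  arrays <- dedupe_arrays(arrays)
  arrays <- Filter(function(a) nrow(a$instances) >= min_repeats, arrays)
  assign_strands(arrays, max_repeat_mismatch, contig)
}

# Column-majority consensus over equal-length instance strings.
consensus_of <- function(instances) {
  m <- do.call(rbind, strsplit(instances, ""))
  paste(apply(m, 2, function(col) names(which.max(table(col)))), collapse = "")
}

col_conservation <- function(x, starts, offset, width = 1L) {
  # conservation of the single column at `offset` relative to instance starts
  idx <- starts + offset
  ok <- idx >= 1L & idx <= length(x)
  if (sum(ok) < 2L) return(0)
  col <- x[idx[ok]]
  max(table(col)) / length(col)
}

refine_array <- function(x, starts1, seed_lens, repeat_len, spacer_len,
                         max_mm, term_mm) {
  # starts1: 1-based starts of seeded instances
  # seed runs between degenerate instance pairs are truncated, so the longest
  # run is the best width estimate; boundary refinement trims any overshoot
  L0 <- as.integer(max(seed_lens))
  L0 <- min(max(L0, repeat_len[1]), repeat_len[2])
  n <- length(x)
  get_inst <- function(s, w) paste(x[s:(s + w - 1L)], collapse = "")
  if (max(starts1) + L0 - 1L > n || min(starts1) < 1L) return(NULL)
  inst <- vapply(starts1, get_inst, character(1), w = L0)
  cons <- consensus_of(inst)
  # per-instance realignment: seed-run starts jitter by a few bases, snap each
  # instance to the consensus frame
  for (pass in 1:2) {
    starts1 <- vapply(starts1, function(s) {
      offs <- -8:8
      offs <- offs[s + offs >= 1L & s + offs + L0 - 1L <= n]
      dd <- vapply(offs, function(o) hamming(get_inst(s + o, L0), cons), numeric(1))
      s + offs[which.min(dd)]
    }, integer(1))
    starts1 <- sort(unique(starts1))
    inst <- vapply(starts1, get_inst, character(1), w = L0)
    cons <- consensus_of(inst)
  }
  dist <- vapply(inst, hamming, numeric(1), b = cons)
  # Boundary refinement set: with many instances a lone degenerate terminal
  # barely moves column conservation, so use them all (subsetting by distance
  # to the consensus would bias junk edge columns toward agreement). On
  # low-copy arrays exclude mutated instances so their substitutions do not
  # erode the edges.
  if (length(starts1) >= 6L) {
    clean <- starts1
  } else {
    clean <- starts1[dist <= 1L]
    if (length(clean) < 2L) clean <- starts1[dist <= max_mm]
  }
  if (length(clean) < 2L) return(NULL)

  # boundary refinement on the clean set: extend while flanking columns are
  # conserved, trim unconserved edge columns
  left <- 0L; width <- L0
  while (width < repeat_len[2] &&
         col_conservation(x, clean, left - 1L) >= 0.9) {
    left <- left - 1L; width <- width + 1L
  }
  while (width < repeat_len[2] &&
         col_conservation(x, clean, left + width) >= 0.9) {
    width <- width + 1L
  }
  while (width > repeat_len[1] &&
         col_conservation(x, clean, left) < 0.9) {
    left <- left + 1L; width <- width - 1L
  }
  while (width > repeat_len[1] &&
         col_conservation(x, clean, left + width - 1L) < 0.9) {
    width <- width - 1L
  }
  starts1 <- sort(unique(starts1 + left))
  if (min(starts1) < 1L || max(starts1) + width - 1L > n) return(NULL)
  inst <- vapply(starts1, get_inst, character(1), w = width)
  cons <- consensus_of(inst)

  # extend outward over possibly-degenerate instances
  step_range <- (width + spacer_len[1]):(width + spacer_len[2])
  extend <- function(starts1, dir) {
    repeat {
      anchor <- if (dir > 0) max(starts1) else min(starts1)
      cand <- if (dir > 0) anchor + step_range else anchor - step_range
      cand <- cand[cand >= 1L & cand + width - 1L <= n]
      if (!length(cand)) return(starts1)
      dd <- vapply(cand, function(s) hamming(get_inst(s, width), cons), numeric(1))
      b <- which.min(dd)
      if (dd[b] > term_mm) return(starts1)
      starts1 <- sort(c(starts1, cand[b]))
    }
  }
  starts1 <- extend(starts1, +1L)
  starts1 <- extend(starts1, -1L)
  inst <- vapply(starts1, get_inst, character(1), w = width)
  # final consensus from non-degenerate instances
  dist <- vapply(inst, hamming, numeric(1), b = consensus_of(inst))
  core <- inst[dist <= max_mm]
  cons <- if (length(core) >= 2L) consensus_of(core) else consensus_of(inst)

  m <- length(starts1)
  spacer_start <- starts1[-m] + width
  spacer_end <- starts1[-1]
  sp_seq <- vapply(seq_len(m - 1L),
                   function(i) paste(x[spacer_start[i]:(spacer_end[i] - 1L)],
                                     collapse = ""), character(1))
  list(consensus = cons,
       instances = data.frame(start = starts1 - 1L, end = starts1 - 1L + width,
                              seq = inst, mismatches = vapply(inst, hamming,
                                                              numeric(1), b = cons),
                              stringsAsFactors = FALSE),
       spacers = data.frame(start = spacer_start - 1L, end = spacer_end - 1L,
                            seq = sp_seq, stringsAsFactors = FALSE))
}

dedupe_arrays <- function(arrays) {
  if (length(arrays) < 2L) return(arrays)
  spans <- t(vapply(arrays, function(a) c(min(a$instances$start),
                                          max(a$instances$end)), numeric(2)))
  nrep <- vapply(arrays, function(a) nrow(a$instances), integer(1))
  keep <- rep(TRUE, length(arrays))
  ord <- order(-nrep)
  for (i in seq_along(ord)) {
    a <- ord[i]
    if (!keep[a]) next
    for (b in ord[-seq_len(i)]) {
      if (!keep[b]) next
      if (spans[a, 1] < spans[b, 2] && spans[b, 1] < spans[a, 2]) keep[b] <- FALSE
    }
  }
  arrays[keep]
}

assign_strands <- function(arrays, max_mm, contig) {
  out <- list()
  for (a in arrays) {
    strand <- "+"
    for (prev in out) {
      if (abs(nchar(prev$consensus) - nchar(a$consensus)) > 10L) next
      sim <- repeat_similarity(a$consensus, prev$consensus)
      if (max(sim$fwd, sim$rc) <
          repeat_match_threshold(a$consensus, prev$consensus, max_mm)) next
      strand <- if (sim$fwd >= sim$rc) prev$strand
      else if (prev$strand == "+") "-" else "+"
      break
    }
    a$strand <- strand
    a$contig <- contig
    a$leader_side <- "unknown"
    a$leader <- NULL
    class(a) <- "crispr_array"
    out[[length(out) + 1L]] <- a
  }
  ord <- order(vapply(out, function(a) min(a$instances$start), numeric(1)))
  out[ord]
}

#' Retain small satellite arrays near a selected array
#'
#' Arrays with fewer than `min_repeats` repeat instances are kept only when
#' they lie within `max_distance` nt of a larger selected array and share its
#' repeat sequence on either strand (within `max_mismatch`).
#'
#' @param arrays list of `crispr_array` objects, e.g. from [find_arrays()]
#'   run with a lowered `min_repeats` so candidate satellites are present.
#' @param max_distance maximum gap (nt) between array spans.
#' @param min_repeats threshold below which an array counts as a satellite.
#' @param max_mismatch repeat-identity tolerance when matching consensus
#'   sequences.
#' @return filtered list of arrays.
#' @export
attach_satellite_arrays <- function(arrays, max_distance = 10000L,
                                    min_repeats = 4L, max_mismatch = 3L) {
  nrep <- vapply(arrays, function(a) nrow(a$instances), integer(1))
  main <- arrays[nrep >= min_repeats]
  small <- arrays[nrep < min_repeats]
  if (!length(small)) return(arrays)
  span <- function(a) c(min(a$instances$start), max(a$instances$end))
  kept <- Filter(function(s) {
    ss <- span(s)
    any(vapply(main, function(m) {
      ms <- span(m)
      gap <- max(0, max(ms[1], ss[1]) - min(ms[2], ss[2]))
      if (gap > max_distance) return(FALSE)
      approx_same_repeat(s$consensus, m$consensus, max_mismatch)
    }, logical(1)))
  }, small)
  c(main, kept)
}

# Per-orientation local-alignment scores between two repeat consensi.
# Boundary calls on low-copy arrays can be frame-shifted by several bases and
# contaminated with spacer sequence, so the comparison lets the aligner clip
# that junk instead of demanding an ungapped full-length match.
repeat_similarity <- function(a, b) {
  one <- function(q, s) {
    if (nchar(q) > nchar(s)) { tmp <- q; q <- s; s <- tmp }
    al <- local_align(q, s)
    if (is.null(al)) 0L else al$score
  }
  list(fwd = one(a, b), rc = one(revcomp(a), b))
}

# Score two consensi must reach to count as the same repeat: the shared core
# after clipping boundary junk, less the mismatch tolerance.
repeat_match_threshold <- function(a, b, max_mm) {
  max(12L, min(nchar(a), nchar(b)) - 2L * max_mm - 4L)
}

# Do two repeat consensus sequences match on either strand?
approx_same_repeat <- function(a, b, max_mm) {
  if (abs(nchar(a) - nchar(b)) > 10L) return(FALSE)
  sim <- repeat_similarity(a, b)
  max(sim$fwd, sim$rc) >= repeat_match_threshold(a, b, max_mm)
}

#' Call the leader side of a CRISPR array and index its spacers
#'
#' The terminal repeat most distant from the leader degenerates over time, so
#' the side whose terminal repeat is closest to the consensus is called
#' leader-proximal. When both terminal repeats are equally conserved, the
#' AT-rich flank breaks the tie (leaders are AT rich); if neither criterion
#' decides, the side is `"unknown"` and indexing defaults to the left.
#' Spacers are re-indexed 1..n from the leader and reported in transcription
#' (crRNA) sense: as-is for a left leader, reverse-complemented for a right
#' leader. The array strand is set to `"+"` (left leader) or `"-"` (right).
#'
#' @param array a `crispr_array`.
#' @param genome the contig the array was found on.
#' @param flank_len nt of flank examined for AT richness.
#' @return the array with `leader_side`, `leader` coordinates (0-based
#'   half-open), `at_rich_flank` flag, `strand`, and a `spacers` table with
#'   `index` and crRNA-sense `seq`.
#' @export
call_leader <- function(array, genome, flank_len = 150L) {
  stopifnot(inherits(array, "crispr_array"))
  if (nrow(array$instances) < 4L) stop("leader calling needs >= 4 repeats")
  genome <- toupper(genome)
  n <- nchar(genome)
  inst <- array$instances
  d_first <- hamming(inst$seq[1], array$consensus)
  d_last <- hamming(inst$seq[nrow(inst)], array$consensus)
  left0 <- max(0L, inst$start[1] - flank_len)
  flank_left <- substr(genome, left0 + 1L, inst$start[1])
  right1 <- min(n, inst$end[nrow(inst)] + flank_len)
  flank_right <- substr(genome, inst$end[nrow(inst)] + 1L, right1)
  at_bg <- at_fraction(genome)
  at_l <- if (nchar(flank_left)) at_fraction(flank_left) else 0
  at_r <- if (nchar(flank_right)) at_fraction(flank_right) else 0

  side <- if (d_first < d_last) "left"
  else if (d_last < d_first) "right"
  else if (at_l > at_bg && at_l > at_r) "left"
  else if (at_r > at_bg && at_r > at_l) "right"
  else "unknown"

  eff <- if (side == "unknown") "left" else side
  if (eff == "left") {
    array$leader <- c(left0, inst$start[1])
    array$at_rich_flank <- at_l > at_bg
    array$strand <- "+"
    sp <- array$spacers
    sp$index <- seq_len(nrow(sp))
  } else {
    array$leader <- c(inst$end[nrow(inst)], right1)
    array$at_rich_flank <- at_r > at_bg
    array$strand <- "-"
    sp <- array$spacers[rev(seq_len(nrow(array$spacers))), , drop = FALSE]
    sp$seq <- revcomp(sp$seq)
    sp$index <- seq_len(nrow(sp))
    rownames(sp) <- NULL
  }
  if (side == "unknown") array$strand <- "+"
  array$leader_side <- side
  array$spacers <- sp[, c("index", "seq", "start", "end")]
  array
}

#' Extract leader-indexed spacers from arrays
#'
#' Pools crRNA-sense spacers from one or more leader-called arrays into a
#' named character vector (`sp1`, `sp2`, ...; array-qualified as
#' `<array>_sp<i>` when more than one array contributes).
#'
#' @param arrays list of leader-called `crispr_array` objects.
#' @return named character vector of spacer sequences.
#' @export
get_spacers <- function(arrays) {
  if (inherits(arrays, "crispr_array")) arrays <- list(arrays)
  multi <- length(arrays) > 1L
  out <- character(0)
  for (ai in seq_along(arrays)) {
    a <- arrays[[ai]]
    idx <- a$spacers$index %||% seq_len(nrow(a$spacers))  # left-default when no leader
    nm <- paste0(if (multi) paste0("A", ai, "_") else "", "sp", idx)
    out <- c(out, stats::setNames(a$spacers$seq, nm))
  }
  out
}

#' @export
print.crispr_array <- function(x, ...) {
  cat(sprintf("CRISPR array on %s [%d-%d] strand %s: %d repeats (%d nt consensus), %d spacers, leader %s\n",
              x$contig, min(x$instances$start), max(x$instances$end), x$strand,
              nrow(x$instances), nchar(x$consensus), nrow(x$spacers),
              x$leader_side))
  invisible(x)
}
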