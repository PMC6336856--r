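#' Extract protospacer-flanking sequences
#'
#' For each selected match, reads the `flank_len` bases adjacent to the
#' protospacer on the non-target strand, i.e. the strand matching the
#' spacer's (crRNA) sense: upstream means 5' of the spacer-identical reading,
#' which is where Type I PAMs sit. Matches on the genome's minus strand are
#' read from the reverse complement with coordinates remapped, so flanks are
#' always reported in spacer sense.
#'
#' @param matches a [scan_spacers()] table.
#' @param genomes named character vector of (viral-sense) genome sequences.
#' @param side `"upstream"` or `"downstream"` relative to spacer
#'   transcription.
#' @param flank_len flank width in nt (default 10).
#' @param selection `"best-per-spacer"` keeps one representative match per
#'   spacer (highest score, then lowest E-value, then first genome in input
#'   order); `"identical-only"` keeps matches with identity 1; `"all"` keeps
#'   everything.
#' @param circular genomes are circular (flanks always exist); on linear
#'   genomes matches without margin are skipped with a warning.
#' @return a `flank_set`: side, flank_len, selection and a named character
#'   vector `sequences` (one flank per selected match, named by spacer).
#' @export
extract_flanks <- function(matches, genomes, side = c("upstream", "downstream"),
                           flank_len = 10L, selection = c("best-per-spacer",
                                                          "identical-only", "all"),
                           circular = TRUE) {
  side <- match.arg(side)
  selection <- match.arg(selection)
  m <- matches
  if (selection == "identical-only") {
    m <- m[m$identity >= 1, , drop = FALSE]
  } else if (selection == "best-per-spacer") {
    m$.g <- match(m$genome, names(genomes))
    m <- m[order(m$spacer, -m$score, m$evalue, m$.g), , drop = FALSE]
    m <- m[!duplicated(m$spacer), , drop = FALSE]
    m$.g <- NULL
  }
  seqs <- character(0)
  for (i in seq_len(nrow(m))) {
    g <- toupper(genomes[[m$genome[i]]])
    L <- nchar(g)
    s0 <- m$start[i] %% L
    e0 <- s0 + (m$end[i] - m$start[i])
    if (m$strand[i] == "+") {
      a <- if (side == "upstream") c(s0 - flank_len, s0) else c(e0, e0 + flank_len)
      rc <- FALSE
    } else {
      a <- if (side == "upstream") c(e0, e0 + flank_len) else c(s0 - flank_len, s0)
      rc <- TRUE
    }
    if (!circular && (a[1] < 0 || a[2] > L)) {
      warning("match ", m$spacer[i], " on ", m$genome[i],
              " lacks flank margin on a linear genome; skipped")
      next
    }
    fl <- circ_substr(g, a[1] %% L, (a[1] %% L) + flank_len)
    if (rc) fl <- revcomp(fl)
    seqs <- c(seqs, stats::setNames(fl, m$spacer[i]))
  }
  structure(list(side = side, flank_len = as.integer(flank_len),
                 selection = selection, sequences = seqs),
            class = "flank_set")
}

#' Position frequency matrix and information content of a flank set
#'
#' Per-position base frequencies over the stacked flanks plus the information
#' content `IC = 2 - H` bits, `H = -sum f log2 f` over observed bases. No
#' small-sample correction is applied by default (`correction = TRUE` applies
#' the e(n) = 3/(2 ln 2 n) adjustment used by some logo tools).
#'
#' @param flanks a `flank_set` (needs >= 2 sequences).
#' @param correction apply the small-sample information correction.
#' @return a `pfm`: `freq` (4 x P matrix), `counts`, `ic` (bits per
#'   position), `positions` (labels -flank_len..-1 or +1..+flank_len), `n`,
#'   and the source sequences.
#' @export
build_pfm <- function(flanks, correction = FALSE) {
  stopifnot(inherits(flanks, "flank_set"), length(flanks$sequences) >= 2L)
  m <- do.call(rbind, strsplit(flanks$sequences, ""))
  P <- ncol(m)
  counts <- vapply(seq_len(P), function(j) {
    tab <- table(factor(m[, j], levels = DNA_BASES))
    as.numeric(tab)
  }, numeric(4))
  rownames(counts) <- DNA_BASES
  n_eff <- colSums(counts)           # non-ACGT characters drop out per column
  freq <- sweep(counts, 2, pmax(n_eff, 1), "/")
  H <- apply(freq, 2, function(f) {
    f <- f[f > 0]
    -sum(f * log2(f))
  })
  ic <- 2 - H
  if (correction) ic <- pmax(0, ic - 3 / (2 * log(2) * length(flanks$sequences)))
  positions <- if (flanks$side == "upstream")
    seq(-flanks$flank_len, -1L) else seq(1L, flanks$flank_len)
  structure(list(freq = freq, counts = counts, ic = ic,
                 positions = positions, n = length(flanks$sequences),
                 side = flanks$side, sequences = flanks$sequences),
            class = "pfm")
}

#' Call a conserved motif (PAM candidate) from a PFM
#'
#' Positions whose dominant base reaches `conservation_threshold` enter the
#' motif; sub-threshold positions between called ones become N. Completeness
#' is the fraction of flank sequences carrying the dominant base at every
#' called position; `any_position` is the fraction carrying at least one.
#'
#' @param pfm a [build_pfm()] result.
#' @param conservation_threshold minimum dominant-base frequency.
#' @return a `motif_call`: `motif` (IUPAC string over the called span, empty
#'   when nothing is conserved), `offsets`, per-position `conservation`,
#'   `completeness`, `any_position`.
#' @export
call_motif <- function(pfm, conservation_threshold = 0.6) {
  stopifnot(inherits(pfm, "pfm"))
  dom_i <- apply(pfm$freq, 2, which.max)
  dom_base <- DNA_BASES[dom_i]
  dom_f <- vapply(seq_along(dom_i), function(j) pfm$freq[dom_i[j], j], numeric(1))
  called <- which(dom_f >= conservation_threshold)
  if (!length(called))
    return(structure(list(motif = "", offsets = integer(0),
                          conservation = numeric(0), completeness = NA_real_,
                          any_position = NA_real_), class = "motif_call"))
  span <- min(called):max(called)
  motif <- vapply(span, function(j) if (j %in% called) dom_base[j] else "N",
                  character(1))
  m <- do.call(rbind, strsplit(pfm$sequences, ""))
  hit <- m[, called, drop = FALSE] ==
    matrix(dom_base[called], nrow(m), length(called), byrow = TRUE)
  structure(list(motif = paste(motif, collapse = ""),
                 offsets = pfm$positions[span],
                 conservation = stats::setNames(dom_f[called],
                                                pfm$positions[called]),
                 completeness = mean(rowSums(hit) == length(called)),
                 any_position = mean(rowSums(hit) >= 1)),
            class = "motif_call")
}

#' @export
print.motif_call <- function(x, ...) {
  cat(sprintf("motif %s at offsets [%s]; completeness %.2f, any-position %.2f\n",
              x$motif, paste(x$offsets, collapse = ","), x$completeness,
              x$any_position))
  invisible(x)
}
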