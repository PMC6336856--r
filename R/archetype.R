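#' Orient a circular genome to the viral sense via the origin nonanucleotide
#'
#' CRESS-DNA replication starts at a stem-loop whose conserved nonanucleotide
#' (here `NAGTRTTAC`) lies on the encapsidated viral-sense strand. The
#' genome is scanned on both strands for the IUPAC motif (across the origin);
#' if it is found only on the reverse strand the genome is
#' reverse-complemented, with annotation coordinates flipped accordingly.
#'
#' @param genome circular genome sequence.
#' @param motif IUPAC motif (default `NAGTRTTAC`).
#' @param annotation optional 0-based half-open feature table to flip along.
#' @param id genome identifier.
#' @return an `oriented_genome`: `sequence` (viral sense),
#'   `was_reverse_complemented`, `nona_pos` (0-based start), `annotation`,
#'   `id`, `length`.
#' @export
orient_genome <- function(genome, motif = "NAGTRTTAC", annotation = NULL,
                          id = "genome") {
  genome <- toupper(genome)
  L <- nchar(genome)
  fwd <- iupac_match_starts(genome, motif, circular = TRUE)
  rev_ <- iupac_match_starts(revcomp(genome), motif, circular = TRUE)
  if (length(fwd) && length(rev_))
    stop("origin motif on both strands of ", id, "; orientation ambiguous")
  if (!length(fwd) && !length(rev_))
    stop("origin motif absent from ", id, "; cannot orient")
  flipped <- length(rev_) > 0
  if (flipped) {
    genome <- revcomp(genome)
    if (!is.null(annotation)) {
      new_start <- L - annotation$end
      new_end <- L - annotation$start
      annotation$start <- new_start
      annotation$end <- new_end
      annotation$strand <- chartr("+-", "-+", annotation$strand)
    }
    pos <- rev_
  } else pos <- fwd
  if (length(pos) > 1L)
    warning("multiple origin motifs on the viral strand of ", id,
            "; using the first")
  structure(list(id = id, sequence = genome,
                 was_reverse_complemented = flipped,
                 nona_pos = pos[1], annotation = annotation, length = L),
            class = "oriented_genome")
}

# Ordered circular segments (genes + named intergenics) from a gene
# annotation. For the canonical two-gene layout the intergenic upstream of
# cap (through the origin) is intergenic_A and the cap-rep gap intergenic_B.
genome_segments <- function(annotation, genome_len) {
  genes <- annotation[annotation$type == "gene", , drop = FALSE]
  if (!nrow(genes)) stop("annotation has no gene features")
  genes <- genes[order(genes$start), , drop = FALSE]
  segs <- list()
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    segs[[length(segs) + 1L]] <- data.frame(
      name = g$feature, start = g$start, end = g$end, stringsAsFactors = FALSE)
    nxt <- if (i < nrow(genes)) genes$start[i + 1] else genes$start[1] + genome_len
    if (nxt > g$end) {
      nxt_name <- if (i < nrow(genes)) genes$feature[i + 1] else genes$feature[1]
      ig <- if (nxt_name == "cap") "intergenic_A"
      else if (nxt_name == "rep") "intergenic_B"
      else paste0("intergenic_", i)
      segs[[length(segs) + 1L]] <- data.frame(
        name = ig, start = g$end, end = nxt, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, segs)
  out$width <- out$end - out$start
  out
}

#' Relative position of a match within its genome segment
#'
#' The protospacer midpoint is located in the gene or intergenic segment
#' containing it (circular-aware); the fractional position is the midpoint's
#' offset from the segment start over the segment length — e.g. two-thirds
#' of the way from the start codon to the end of the gene.
#'
#' @param match one match row (`start`, `end` on the oriented genome).
#' @param annotation oriented feature table (must contain gene rows).
#' @param genome_len genome length.
#' @return list(segment, fraction).
#' @export
relative_position <- function(match, annotation, genome_len) {
  segs <- genome_segments(annotation, genome_len)
  mid <- ((match$start + match$end) / 2) %% genome_len
  for (i in seq_len(nrow(segs))) {
    off <- (mid - segs$start[i]) %% genome_len
    if (off < segs$width[i])
      return(list(segment = segs$name[i], fraction = off / segs$width[i]))
  }
  stop("midpoint not covered by any segment")  # cannot happen on a partition
}

#' Build an archetype genome map from representative matches
#'
#' All smacovirus-like genomes share one architecture, so protospacers from
#' many genomes can be drawn on a single averaged "archetype": each segment's
#' length is the mean over the genomes contributing representative matches,
#' and every representative is placed at its fractional position within its
#' segment, scaled to the mean segment length. Genomes lacking rep or cap
#' annotation are excluded with a warning.
#'
#' @param matches representative matches (e.g. best per spacer), with
#'   `genome`, `start`, `end`, `strand`, `spacer`, optionally `mode`
#'   (`"local"` rows are marked `local_only`).
#' @param oriented list of [orient_genome()] results keyed by genome name.
#' @param segment_order display order of segments.
#' @return an `archetype_map`: `segments` (name, mean_length, n_genomes),
#'   `placements` (spacer, genome, segment, fraction, position, strand,
#'   local_only), `n_genomes`.
#' @export
build_archetype <- function(matches, oriented,
                            segment_order = c("intergenic_A", "cap",
                                              "intergenic_B", "rep")) {
  usable <- vapply(oriented, function(og) {
    !is.null(og$annotation) &&
      all(c("rep", "cap") %in%
            og$annotation$feature[og$annotation$type == "gene"])
  }, logical(1))
  if (any(!usable))
    warning("excluding genomes without rep/cap annotation: ",
            paste(names(oriented)[!usable], collapse = ", "))
  oriented <- oriented[usable]
  m <- matches[matches$genome %in% names(oriented), , drop = FALSE]
  placements <- list()
  seg_tabs <- list()
  for (gname in unique(m$genome)) {
    og <- oriented[[gname]]
    seg_tabs[[gname]] <- genome_segments(og$annotation, og$length)
  }
  for (i in seq_len(nrow(m))) {
    og <- oriented[[m$genome[i]]]
    rp <- relative_position(m[i, ], og$annotation, og$length)
    placements[[length(placements) + 1L]] <- data.frame(
      spacer = m$spacer[i], genome = m$genome[i], segment = rp$segment,
      fraction = rp$fraction, strand = m$strand[i],
      local_only = if ("mode" %in% names(m)) m$mode[i] == "local" else FALSE,
      stringsAsFactors = FALSE)
  }
  pl <- if (length(placements)) do.call(rbind, placements) else
    data.frame(spacer = character(0), genome = character(0),
               segment = character(0), fraction = numeric(0),
               strand = character(0), local_only = logical(0))
  contrib <- unique(pl$genome)
  seg_names <- unique(unlist(lapply(seg_tabs[contrib], function(s) s$name)))
  seg_names <- c(intersect(segment_order, seg_names),
                 setdiff(seg_names, segment_order))
  segments <- do.call(rbind, lapply(seg_names, function(nm) {
    w <- vapply(seg_tabs[contrib], function(s) {
      i <- match(nm, s$name)
      if (is.na(i)) NA_real_ else s$width[i]
    }, numeric(1))
    data.frame(name = nm, mean_length = mean(w, na.rm = TRUE),
               n_genomes = sum(!is.na(w)), stringsAsFactors = FALSE)
  }))
  if (nrow(pl))
    pl$position <- pl$fraction *
      segments$mean_length[match(pl$segment, segments$name)]
  structure(list(segments = segments, placements = pl,
                 n_genomes = length(contrib)),
            class = "archetype_map")
}

#' @export
print.archetype_map <- function(x, ...) {
  cat(sprintf("archetype over %d genomes: %d placements across %d segments\n",
              x$n_genomes, nrow(x$placements), nrow(x$segments)))
  invisible(x)
}
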