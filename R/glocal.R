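#' Alignment scoring parameters
#'
#' Match +1, mismatch -1, gap open -2, gap extend -1: a gap of length g costs
#' `|gap_open| + (g-1) * |gap_extend|`, i.e. the first gapped base pays the
#' open cost and each additional base the extend cost. Any non-ACGT base
#' scores as a mismatch against everything.
#'
#' @param match,mismatch,gap_open,gap_extend integer scores (penalties
#'   negative).
#' @param mode `"glocal"` (entire query against a local subject region) or
#'   `"local"` (Smith-Waterman).
#' @return an `align_params` object.
#' @export
align_params <- function(match = 1L, mismatch = -1L, gap_open = -2L,
                         gap_extend = -1L, mode = c("glocal", "local")) {
  mode <- match.arg(mode)
  if (match <= 0 || mismatch >= 0) stop("need match > 0 > mismatch")
  if (gap_open > gap_extend || gap_extend >= 0)
    stop("need gap_open <= gap_extend < 0")
  structure(list(match = as.integer(match), mismatch = as.integer(mismatch),
                 gap_open = as.integer(gap_open),
                 gap_extend = as.integer(gap_extend), mode = mode),
            class = "align_params")
}

aln_stats <- function(aq, as_) {
  qa <- strsplit(aq, "")[[1]]; sa <- strsplit(as_, "")[[1]]
  ident <- sum(qa == sa & qa != "-")
  list(identity = if (length(qa)) ident / length(qa) else 0,
       gaps_query = sum(qa == "-"), gaps_subject = sum(sa == "-"),
       columns = length(qa))
}

#' Recompute an alignment score from its aligned strings
#'
#' @param aligned_query,aligned_subject gapped alignment rows.
#' @param params an [align_params()].
#' @return integer score under the affine-gap convention.
#' @export
score_from_strings <- function(aligned_query, aligned_subject, params = align_params()) {
  qa <- strsplit(aligned_query, "")[[1]]; sa <- strsplit(aligned_subject, "")[[1]]
  stopifnot(length(qa) == length(sa))
  score <- 0L
  in_gap <- 0L   # 0 none, 1 gap in query row, 2 gap in subject row
  for (i in seq_along(qa)) {
    if (qa[i] == "-") {
      score <- score + if (in_gap == 1L) params$gap_extend else params$gap_open
      in_gap <- 1L
    } else if (sa[i] == "-") {
      score <- score + if (in_gap == 2L) params$gap_extend else params$gap_open
      in_gap <- 2L
    } else {
      score <- score + if (qa[i] == sa[i] && qa[i] %in% DNA_BASES)
        params$match else params$mismatch
      in_gap <- 0L
    }
  }
  score
}

#' Glocal (query-global, subject-local) alignment
#'
#' Aligns the entire query against the best-scoring local region of the
#' subject: subject-terminal gaps are free, the query must be fully covered,
#' gaps are affine, and the traceback starts from the maximal cell in the
#' last query row (ties prefer diagonal moves and the smallest subject end).
#'
#' @param query,subject DNA strings; the subject must be at least as long as
#'   the query.
#' @param params an [align_params()].
#' @return an `alignment` object: `score`, subject `start`/`end` (0-based
#'   half-open), `aligned_query`, `aligned_subject`, `identity` (identical
#'   columns over all columns, gap columns included), `gaps_query`,
#'   `gaps_subject`.
#' @export
glocal_align <- function(query, subject, params = align_params()) {
  query <- toupper(query); subject <- toupper(subject)
  if (nchar(subject) < nchar(query)) stop("subject shorter than query")
  r <- glocal_align_cpp(query, subject, params$match, params$mismatch,
                        -params$gap_open, -params$gap_extend)
  st <- aln_stats(r$aligned_query, r$aligned_subject)
  structure(list(score = r$score, start = r$sstart, end = r$send,
                 aligned_query = r$aligned_query,
                 aligned_subject = r$aligned_subject,
                 identity = st$identity, gaps_query = st$gaps_query,
                 gaps_subject = st$gaps_subject, mode = "glocal",
                 params = params),
            class = "alignment")
}

#' Local (Smith-Waterman) alignment
#'
#' Both query and subject ends are free. Returns `NULL` when no alignment has
#' a positive score.
#'
#' @inheritParams glocal_align
#' @return an `alignment` object with additional `query_start`/`query_end`,
#'   or `NULL`.
#' @export
local_align <- function(query, subject, params = align_params(mode = "local")) {
  query <- toupper(query); subject <- toupper(subject)
  if (nchar(subject) < nchar(query)) stop("subject shorter than query")
  r <- local_align_cpp(query, subject, params$match, params$mismatch,
                       -params$gap_open, -params$gap_extend)
  if (r$score <= 0L) return(NULL)
  st <- aln_stats(r$aligned_query, r$aligned_subject)
  structure(list(score = r$score, start = r$sstart, end = r$send,
                 query_start = r$qstart, query_end = r$qend,
                 aligned_query = r$aligned_query,
                 aligned_subject = r$aligned_subject,
                 identity = st$identity, gaps_query = st$gaps_query,
                 gaps_subject = st$gaps_subject, mode = "local",
                 params = params),
            class = "alignment")
}

#' @export
print.alignment <- function(x, ...) {
  cat(sprintf("%s alignment: score %d, subject [%d,%d), identity %.3f, gaps q/s %d/%d\n",
              x$mode, x$score, x$start, x$end, x$identity, x$gaps_query,
              x$gaps_subject))
  cat(" ", x$aligned_query, "\n ", x$aligned_subject, "\n")
  invisible(x)
}

#' Scan spacers against viral genomes
#'
#' Aligns every spacer against both strands of every genome (circular genomes
#' are searched across the origin) and reports the best alignment per
#' (spacer, genome, strand) whose E-value passes the threshold. Coordinates
#' are 0-based half-open on the genome's given (viral-sense) orientation;
#' `end` may exceed the genome length for origin-spanning hits. `strand` is
#' `"+"` when the spacer-identical sequence lies on the given strand (viral)
#' and `"-"` for the complementary strand.
#'
#' @param spacers named character vector of spacer sequences (crRNA sense).
#' @param genomes named character vector of genome sequences (viral sense).
#' @param params an [align_params()]; `mode = "local"` runs the plain local
#'   fallback search instead.
#' @param evalue_model a calibrated [calibrate_evalue()] model covering every
#'   query length present.
#' @param threshold E-value cut-off (default 0.01).
#' @param circular treat genomes as circular.
#' @param threshold_overrides optional named numeric, per-spacer threshold
#'   replacing the global one (e.g. to retain a borderline spacer confirmed
#'   independently).
#' @return data.frame of matches: spacer, genome, strand, start, end, score,
#'   evalue, identity, gaps_query, gaps_subject, aligned_query,
#'   aligned_subject, mode.
#' @export
scan_spacers <- function(spacers, genomes, params = align_params(),
                         evalue_model, threshold = 0.01, circular = TRUE,
                         threshold_overrides = NULL) {
  stopifnot(length(spacers) > 0)
  if (is.null(names(spacers))) names(spacers) <- paste0("sp", seq_along(spacers))
  if (length(genomes) && is.null(names(genomes)))
    names(genomes) <- paste0("genome_", seq_along(genomes))
  db_nt <- 2 * sum(nchar(genomes))
  lens <- unique(nchar(spacers))
  covered <- vapply(lens, function(L) evalue_covers(evalue_model, L), logical(1))
  if (!all(covered))
    stop("E-value model not calibrated for query length(s): ",
         paste(lens[!covered], collapse = ", "))
  rows <- list()
  for (gi in seq_along(genomes)) {
    gname <- names(genomes)[gi]
    g <- toupper(genomes[[gi]])
    L <- nchar(g)
    for (strand in c("+", "-")) {
      gs <- if (strand == "+") g else revcomp(g)
      for (si in seq_along(spacers)) {
        q <- toupper(spacers[[si]])
        qlen <- nchar(q)
        ext <- if (circular) min(L, qlen + 7L) else 0L
        subject <- paste0(gs, substr(gs, 1, ext))
        if (nchar(subject) < qlen) next
        aln <- if (params$mode == "local") local_align(q, subject, params)
               else glocal_align(q, subject, params)
        if (is.null(aln)) next
        thr <- threshold
        sname <- names(spacers)[si]
        if (!is.null(threshold_overrides) && sname %in% names(threshold_overrides))
          thr <- threshold_overrides[[sname]]
        ev <- evalue(evalue_model, qlen, aln$score, db_nt)
        if (ev > thr) next
        # map to viral-sense forward coordinates
        s0 <- aln$start %% L
        alen <- aln$end - aln$start
        if (strand == "+") {
          start <- s0; end <- s0 + alen
        } else {
          e_rc <- s0 + alen
          start <- (L - e_rc) %% L
          end <- start + alen
        }
        rows[[length(rows) + 1L]] <- data.frame(
          spacer = sname, genome = gname, strand = strand,
          start = start, end = end, score = aln$score, evalue = ev,
          identity = aln$identity, gaps_query = aln$gaps_query,
          gaps_subject = aln$gaps_subject,
          aligned_query = aln$aligned_query,
          aligned_subject = aln$aligned_subject,
          mode = params$mode, stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows))
    return(data.frame(spacer = character(0), genome = character(0),
                      strand = character(0), start = integer(0),
                      end = integer(0), score = integer(0),
                      evalue = numeric(0), identity = numeric(0),
                      gaps_query = integer(0), gaps_subject = integer(0),
                      aligned_query = character(0),
                      aligned_subject = character(0), mode = character(0),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  # circular wrap can report the same hit at start and start+L; coordinates
  # are already remapped mod L, so exact duplicates collapse here
  key <- paste(out$spacer, out$genome, out$strand, out$start, sep = "\r")
  out <- out[!duplicated(key), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Frame-preservation check for a coding-region match
#'
#' Gaps in a believable protospacer alignment within a coding region either
#' compensate (equal counts in query and subject) or differ by exactly three,
#' leaving the reading frame intact.
#'
#' @param match one row of the [scan_spacers()] table (or any list with
#'   `gaps_query` and `gaps_subject`).
#' @param annotation optional feature table; when given, the rule is applied
#'   only if the match midpoint falls in a `gene` feature, otherwise `"ok"`.
#' @param genome_len genome length, needed with `annotation` for circular
#'   midpoint arithmetic.
#' @return `"ok"` or `"flagged"`.
#' @export
check_frame_preservation <- function(match, annotation = NULL, genome_len = NULL) {
  gq <- match$gaps_query; gs <- match$gaps_subject
  if (!is.null(annotation)) {
    stopifnot(!is.null(genome_len))
    mid <- ((match$start + match$end) / 2) %% genome_len
    genes <- annotation[annotation$type == "gene", , drop = FALSE]
    in_gene <- any(mid >= genes$start & mid < genes$end)
    if (!in_gene) return("ok")
  }
  if (gq == gs || abs(gq - gs) == 3L) "ok" else "flagged"
}
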