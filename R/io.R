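#' Write sequences to FASTA
#'
#' @param seqs named character vector.
#' @param path output path.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

#' Read a FASTA file into a named character vector
#' @param path FASTA path.
#' @export
read_fasta <- function(path) {
  # Biostrings silently drops invalid codes with a warning; treat that as a
  # parse error so malformed records never pass through quietly
  x <- withCallingHandlers(
    Biostrings::readDNAStringSet(path),
    warning = function(w) {
      if (grepl("invalid one-letter sequence codes", conditionMessage(w)))
        stop("malformed FASTA (non-IUPAC characters) in ", path)
    })
  stats::setNames(as.character(x), sub("\\s.*$", "", names(x)))
}

#' Write a feature table as GFF3
#'
#' Converts the package's 0-based half-open feature tables to the 1-based
#' inclusive GFF3 convention via rtracklayer.
#'
#' @param annotation data.frame with feature, start, end, strand, type.
#' @param path output path.
#' @param seqname sequence name for column 1.
#' @export
write_gff3 <- function(annotation, path, seqname = "seq1") {
  strand <- ifelse(annotation$strand %in% c("+", "-"), annotation$strand, "*")
  gr <- GenomicRanges::GRanges(
    seqnames = seqname,
    ranges = IRanges::IRanges(start = annotation$start + 1L, end = annotation$end),
    strand = strand,
    type = annotation$type, Name = annotation$feature)
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read a GFF3 file into the package's 0-based feature-table form
#' @param path GFF3 path.
#' @export
read_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  data.frame(feature = if (!is.null(gr$Name)) as.character(gr$Name)
             else as.character(gr$type),
             start = BiocGenerics::start(gr) - 1L,
             end = BiocGenerics::end(gr),
             strand = as.character(BiocGenerics::strand(gr)),
             type = as.character(gr$type),
             stringsAsFactors = FALSE)
}

# Minimal GenBank flat-file reader: LOCUS (name, topology), FEATURES CDS
# (plain or complement() single-interval locations, /gene or /product label)
# and ORIGIN sequence. Enough for two-gene viral records; no joins.
read_genbank_record <- function(lines) {
  locus <- grep("^LOCUS", lines, value = TRUE)[1]
  toks <- strsplit(trimws(locus), "\\s+")[[1]]
  id <- toks[2]
  circular <- any(tolower(toks) == "circular")
  ori_i <- grep("^ORIGIN", lines)[1]
  if (is.na(ori_i)) stop("GenBank record without ORIGIN: ", id)
  seq_lines <- lines[(ori_i + 1):length(lines)]
  seq_lines <- seq_lines[!grepl("^//", seq_lines)]
  seqs <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))
  feat_i <- grep("^FEATURES", lines)[1]
  ann <- NULL
  if (!is.na(feat_i)) {
    block <- lines[(feat_i + 1):(ori_i - 1)]
    cds_i <- grep("^\\s{5}CDS\\s", block)
    rows <- list()
    for (ci in cds_i) {
      loc <- trimws(sub("^\\s{5}CDS\\s+", "", block[ci]))
      strand <- if (grepl("^complement", loc)) "-" else "+"
      nums <- as.integer(regmatches(loc, gregexpr("[0-9]+", loc))[[1]])
      if (length(nums) < 2) next
      # find a label among following qualifier lines
      label <- NA_character_
      j <- ci + 1
      while (j <= length(block) && grepl("^\\s{10,}", block[j])) {
        qm <- regmatches(block[j], regexec("/(gene|product)=\"([^\"]+)\"", block[j]))[[1]]
        if (length(qm) == 3) { label <- qm[3]; break }
        j <- j + 1
      }
      rows[[length(rows) + 1L]] <- data.frame(
        feature = if (is.na(label)) paste0("CDS_", length(rows) + 1L) else label,
        start = min(nums) - 1L, end = max(nums), strand = strand,
        type = "gene", stringsAsFactors = FALSE)
    }
    if (length(rows)) ann <- do.call(rbind, rows)
  }
  list(id = id, sequence = seqs, annotation = ann, circular = circular)
}

#' Read sequences (and annotations) from FASTA or GenBank
#'
#' @param path input file.
#' @param format `"fasta"` or `"genbank"`.
#' @return list with `sequences` (named character vector), `annotations`
#'   (named list of feature tables or NULL) and `circular` (named logical,
#'   GenBank topology or NA).
#' @export
read_sequences <- function(path, format = c("fasta", "genbank")) {
  format <- match.arg(format)
  if (format == "fasta") {
    seqs <- read_fasta(path)
    return(list(sequences = seqs,
                annotations = stats::setNames(vector("list", length(seqs)),
                                              names(seqs)),
                circular = stats::setNames(rep(NA, length(seqs)), names(seqs))))
  }
  lines <- readLines(path)
  bounds <- grep("^LOCUS", lines)
  if (!length(bounds)) stop("no LOCUS line; not a GenBank file: ", path)
  ends <- c(bounds[-1] - 1L, length(lines))
  recs <- lapply(seq_along(bounds),
                 function(i) read_genbank_record(lines[bounds[i]:ends[i]]))
  ids <- vapply(recs, `[[`, character(1), "id")
  list(sequences = stats::setNames(vapply(recs, `[[`, character(1), "sequence"), ids),
       annotations = stats::setNames(lapply(recs, `[[`, "annotation"), ids),
       circular = stats::setNames(vapply(recs, `[[`, logical(1), "circular"), ids))
}

#' Write a matches table as TSV
#' @param matches data.frame from [scan_spacers()].
#' @param path output path.
#' @export
write_matches_tsv <- function(matches, path) {
  utils::write.table(matches, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
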