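#' @useDynLib spacerhost, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats dbinom runif lm coef setNames
#' @importFrom utils head tail write.table read.table
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

DNA_BASES <- c("A", "C", "G", "T")

#' Uniform random DNA string
#'
#' Background sequence model used throughout the synthetic generators and the
#' E-value calibration: i.i.d. bases with the given probabilities (uniform by
#' default).
#'
#' @param n length in nucleotides.
#' @param prob optional length-4 probability vector over A, C, G, T.
#' @return a single character string of length `n`.
#' @export
random_dna <- function(n, prob = NULL) {
  paste(sample(DNA_BASES, n, replace = TRUE, prob = prob), collapse = "")
}

#' Reverse complement of a DNA string
#'
#' IUPAC ambiguity codes are complemented as well (N stays N, R<->Y, etc.).
#'
#' @param x character vector of DNA strings.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  vapply(x, function(s) {
    comp <- chartr("ACGTRYKMBVDHNacgtrykmbvdhn",
                   "TGCAYRMKVBHDNtgcayrmkvbhdn", s)
    paste(rev(strsplit(comp, "")[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# Hamming distance between equal-length strings.
hamming <- function(a, b) {
  va <- strsplit(a, "")[[1]]; vb <- strsplit(b, "")[[1]]
  if (length(va) != length(vb)) stop("hamming() needs equal-length strings")
  sum(va != vb)
}

at_fraction <- function(x) {
  v <- strsplit(toupper(x), "")[[1]]
  mean(v %in% c("A", "T"))
}

gc_fraction <- function(x) {
  v <- strsplit(toupper(x), "")[[1]]
  mean(v %in% c("G", "C"))
}

# All 0-based start positions of an IUPAC motif on the forward strand of a
# (possibly circular) sequence.
iupac_match_starts <- function(seq, motif, circular = TRUE) {
  L <- nchar(seq)
  k <- nchar(motif)
  padded <- if (circular && L >= k) paste0(seq, substr(seq, 1, k - 1)) else seq
  hits <- Biostrings::matchPattern(motif, Biostrings::DNAString(padded), fixed = FALSE)
  starts <- BiocGenerics::start(hits) - 1L
  sort(unique(starts %% L))
}

# Substring of a circular sequence, 0-based half-open; end may exceed L.
circ_substr <- function(seq, start0, end0) {
  L <- nchar(seq)
  if (end0 - start0 > L) stop("window longer than sequence")
  s <- (start0 %% L)
  e <- s + (end0 - start0)
  if (e <= L) substr(seq, s + 1, e)
  else paste0(substr(seq, s + 1, L), substr(seq, 1, e - L))
}

# Draw one realization of an IUPAC motif.
sample_iupac <- function(motif) {
  tab <- list(A = "A", C = "C", G = "G", T = "T",
              R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
              K = c("G", "T"), M = c("A", "C"),
              B = c("C", "G", "T"), D = c("A", "G", "T"),
              H = c("A", "C", "T"), V = c("A", "C", "G"),
              N = DNA_BASES)
  paste(vapply(strsplit(toupper(motif), "")[[1]],
               function(ch) sample(tab[[ch]], 1), character(1)),
        collapse = "")
}

# Substitute a base with a different one, uniformly.
mutate_base <- function(b) sample(setdiff(DNA_BASES, toupper(b)), 1)
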