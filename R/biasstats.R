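#' Exact binomial test for viral-strand targeting bias
#'
#' CRESS-DNA viruses encapsidate one strand (the viral ssDNA); if a CRISPR
#' system only saw the dsDNA replication intermediate, spacer targets should
#' split evenly between the strands. The test computes the exact one-sided
#' tail probability of observing at least `n_viral` viral-strand targets
#' among `n_total` under Binomial(n_total, 1/2), by direct summation of
#' binomial terms (no normal approximation).
#'
#' @param n_total total match count.
#' @param n_viral matches whose protospacer lies on the viral-sense strand.
#' @param alternative `"greater"` (excess viral-strand targeting, the default
#'   question) or `"two.sided"`.
#' @return a `strand_bias` object: counts, `pct_complementary`
#'   (whole-percent), and `p`.
#' @export
strand_bias_test <- function(n_total, n_viral,
                             alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  stopifnot(n_viral >= 0, n_viral <= n_total)
  p <- if (alternative == "greater") {
    sum(dbinom(n_viral:n_total, n_total, 0.5))
  } else {
    stats::binom.test(n_viral, n_total, 0.5, alternative = "two.sided")$p.value
  }
  structure(list(n_total = n_total, n_viral = n_viral,
                 n_complementary = n_total - n_viral,
                 pct_complementary = round(100 * (n_total - n_viral) / n_total),
                 alternative = alternative, p = p),
            class = "strand_bias")
}

#' @export
print.strand_bias <- function(x, ...) {
  cat(sprintf("%d of %d targets on the viral strand (%d%% complementary); one-sided p = %s\n",
              x$n_viral, x$n_total, x$pct_complementary, signif(x$p, 3)))
  invisible(x)
}

#' Protospacer density per genome region
#'
#' Counts matches per annotated region (midpoint rule, circular-aware) with
#' per-kb densities, plus the coding- versus template-strand split inside
#' genes (a match is "coding" when its protospacer lies on the same strand
#' as the gene).
#'
#' @param matches a [scan_spacers()] table for one genome, or matches plus a
#'   `genome` column matching `annotation`'s genome.
#' @param annotation feature table with `feature`, `start`, `end`, `strand`,
#'   `type` columns (0-based half-open; `type == "gene"` rows are genes).
#' @param genome_len genome length for circular midpoint arithmetic.
#' @return data.frame: region, width, count, per_kb, n_coding, n_template.
#' @export
target_density <- function(matches, annotation, genome_len) {
  regions <- annotation[annotation$type %in% c("gene", "intergenic"), , drop = FALSE]
  mids <- ((matches$start + matches$end) / 2) %% genome_len
  assign_region <- function(mid) {
    hit <- which(mid >= regions$start & mid < regions$end)
    if (length(hit)) regions$feature[hit[1]] else "unknown"
  }
  reg <- vapply(mids, assign_region, character(1))
  out <- lapply(seq_len(nrow(regions)), function(i) {
    r <- regions[i, ]
    in_r <- reg == r$feature
    cnt <- sum(in_r)
    width <- r$end - r$start
    coding <- template <- NA_integer_
    if (r$type == "gene") {
      coding <- sum(in_r & matches$strand == r$strand)
      template <- cnt - coding
    }
    data.frame(region = r$feature, width = width, count = cnt,
               per_kb = cnt / width * 1000,
               n_coding = coding, n_template = template,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  if (any(reg == "unknown"))
    res <- rbind(res, data.frame(region = "unknown", width = NA, count =
                                   sum(reg == "unknown"), per_kb = NA,
                                 n_coding = NA, n_template = NA))
  rownames(res) <- NULL
  res
}

#' Stop-codon usage profile of a CDS set
#'
#' Classifies the final three nucleotides of each coding sequence as amber
#' (TAG), opal (TGA) or ochre (TAA); sequences not ending in a standard stop
#' are excluded from the denominator and reported in `n_excluded`.
#' Pyrrolysine-utilising organisms (and, the hypothesis goes, the viruses
#' that infect them) are depleted in amber termination.
#'
#' @param cds_sequences character vector of CDS nucleotide sequences.
#' @param label set label carried into the profile.
#' @return a `stop_codon_profile`: label, `n_cds` (stop-ending), counts and
#'   percentages per codon, `n_excluded`.
#' @export
stop_codon_profile <- function(cds_sequences, label = "set") {
  if (!length(cds_sequences)) stop("empty CDS set")
  last3 <- toupper(substr(cds_sequences, nchar(cds_sequences) - 2L,
                          nchar(cds_sequences)))
  std <- c(amber = "TAG", opal = "TGA", ochre = "TAA")
  counts <- vapply(std, function(cod) sum(last3 == cod), numeric(1))
  n <- sum(counts)
  if (n == 0) stop("no CDS ends in a standard stop codon")
  structure(list(label = label, n_cds = n,
                 counts = counts, percent = 100 * counts / n,
                 n_excluded = length(cds_sequences) - n),
            class = "stop_codon_profile")
}

#' @export
print.stop_codon_profile <- function(x, ...) {
  cat(sprintf("%s: n = %d stop-ending CDS (%d excluded); amber %.2f%%, opal %.2f%%, ochre %.2f%%\n",
              x$label, x$n_cds, x$n_excluded, x$percent["amber"],
              x$percent["opal"], x$percent["ochre"]))
  invisible(x)
}

#' Default spacer-age strata
#'
#' Inclusive leader-distance index ranges: modern sp1-9, middle sp12-27,
#' ancient sp35-72.
#' @return data.frame with name, from, to.
#' @export
default_age_strata <- function() {
  data.frame(name = c("modern", "middle", "ancient"),
             from = c(1L, 12L, 35L), to = c(9L, 27L, 72L),
             stringsAsFactors = FALSE)
}

#' Identity of best matches by spacer age stratum
#'
#' Spacers insert at the leader, so leader-proximal spacers are younger;
#' protospacer identity decays with age. Summarises the best identity per
#' spacer within each stratum.
#'
#' @param matches a [scan_spacers()] table; spacer names must be `sp<i>` (an
#'   optional array qualifier prefix is tolerated).
#' @param strata data.frame like [default_age_strata()] (ranges inclusive,
#'   non-overlapping).
#' @return data.frame per non-empty stratum (empty strata are dropped with a
#'   warning): name, n_spacers, min_identity, mean_identity; attribute
#'   `decay` is TRUE when the first stratum's mean exceeds the last's.
#' @export
identity_by_age <- function(matches, strata = default_age_strata()) {
  if (any(strata$from[-1] <= strata$to[-nrow(strata)]))
    stop("strata ranges must be non-overlapping and ascending")
  idx <- as.integer(sub("^.*?sp", "", matches$spacer))
  best <- tapply(matches$identity, idx, max)
  sp_idx <- as.integer(names(best))
  rows <- list()
  for (i in seq_len(nrow(strata))) {
    in_s <- sp_idx >= strata$from[i] & sp_idx <= strata$to[i]
    if (!any(in_s)) {
      warning("stratum '", strata$name[i], "' has no matches; omitted")
      next
    }
    rows[[length(rows) + 1L]] <- data.frame(
      name = strata$name[i], n_spacers = sum(in_s),
      min_identity = min(best[in_s]), mean_identity = mean(best[in_s]),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (!is.null(out) && nrow(out) >= 2L)
    attr(out, "decay") <- out$mean_identity[1] > out$mean_identity[nrow(out)]
  out
}

#' Spacer-by-genome presence/identity matrix
#'
#' Best identity per (spacer, genome); absence is NA. Row and column
#' marginals (genomes per spacer, targets per genome) are attached as
#' attributes — the machine-readable form of a targets-per-genome table.
#'
#' @param matches a [scan_spacers()] table.
#' @return numeric matrix spacers x genomes with attributes
#'   `genomes_per_spacer` and `targets_per_genome`.
#' @export
presence_matrix <- function(matches) {
  spacers <- unique(matches$spacer)
  # order sp indices numerically when possible
  idx <- suppressWarnings(as.integer(sub("^.*?sp", "", spacers)))
  if (!anyNA(idx)) spacers <- spacers[order(idx)]
  genomes <- unique(matches$genome)
  M <- matrix(NA_real_, length(spacers), length(genomes),
              dimnames = list(spacers, genomes))
  for (i in seq_len(nrow(matches))) {
    r <- matches[i, ]
    cur <- M[r$spacer, r$genome]
    if (is.na(cur) || r$identity > cur) M[r$spacer, r$genome] <- r$identity
  }
  attr(M, "genomes_per_spacer") <- rowSums(!is.na(M))
  attr(M, "targets_per_genome") <- colSums(!is.na(M))
  M
}
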