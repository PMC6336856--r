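#' Run configuration for the spacer-to-host pipeline
#'
#' @param host either a path to a host FASTA/GenBank file or a named list
#'   with a `sequence` string.
#' @param viruses path to a viral multi-FASTA, or a named character vector
#'   of genome sequences.
#' @param annotations named list of feature tables (one per virus), paths to
#'   GFF3 files, or NULL.
#' @param threshold E-value cut-off (default 0.01).
#' @param params an [align_params()].
#' @param calib_db_nt,n_replicates E-value calibration size.
#' @param flank_len PAM flank width.
#' @param strata spacer-age strata (see [default_age_strata()]).
#' @param nonanucleotide origin motif used to orient viruses.
#' @param run_local_fallback also run the plain local search and append its
#'   extra matches (marked `mode = "local"`).
#' @param outdir output directory (created); NULL keeps results in memory.
#' @param seed master seed for calibration.
#' @param min_repeats,satellite_max_distance CRISPR detection settings.
#' @return a `run_config` list.
#' @export
run_config <- function(host, viruses, annotations = NULL, threshold = 0.01,
                       params = align_params(), calib_db_nt = 1e6,
                       n_replicates = 500, flank_len = 10L,
                       strata = default_age_strata(),
                       nonanucleotide = "NAGTRTTAC",
                       run_local_fallback = TRUE, outdir = NULL, seed = 1L,
                       min_repeats = 4L, satellite_max_distance = 10000L) {
  if (threshold <= 0) stop("threshold must be positive")
  structure(as.list(environment()), class = "run_config")
}

resolve_host <- function(host) {
  if (is.character(host) && length(host) == 1L && file.exists(host)) {
    fmt <- if (grepl("\\.(gb|gbk|genbank)$", host, ignore.case = TRUE))
      "genbank" else "fasta"
    rs <- read_sequences(host, fmt)
    return(rs$sequences[[1]])
  }
  if (is.list(host) && !is.null(host$sequence)) return(host$sequence)
  if (is.character(host) && length(host) == 1L) return(host)
  stop("cannot interpret `host`")
}

resolve_viruses <- function(viruses, annotations) {
  if (is.character(viruses) && length(viruses) == 1L && file.exists(viruses)) {
    fmt <- if (grepl("\\.(gb|gbk|genbank)$", viruses, ignore.case = TRUE))
      "genbank" else "fasta"
    rs <- read_sequences(viruses, fmt)
    seqs <- rs$sequences
    ann <- if (is.null(annotations)) rs$annotations else annotations
  } else {
    seqs <- viruses
    ann <- annotations
  }
  if (is.character(annotations) && all(file.exists(annotations)))
    ann <- lapply(annotations, read_gff3)
  list(sequences = seqs, annotations = ann)
}

#' Run the full spacer-to-host analysis
#'
#' Sequences the stages in the order of the underlying protocol: CRISPR
#' detection (with satellite attachment and leader calling), viral-sense
#' orientation of the genomes, E-value calibration, the glocal spacer scan
#' (plus an optional local-alignment fallback pass whose extra spacers are
#' marked), frame-preservation checks, PAM flank logos, strand-bias /
#' density / age statistics, the presence matrix, and the archetype map.
#' Fully deterministic under the config seed; when `outdir` is set every
#' stage output is persisted (TSV/FASTA/JSON) so stages can be audited
#' individually.
#'
#' @param config a [run_config()].
#' @return a `run_report` list; see the fields written in its JSON form.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  host <- resolve_host(config$host)
  vir <- resolve_viruses(config$viruses, config$annotations)
  genomes <- vir$sequences
  out <- function(...) if (!is.null(config$outdir))
    file.path(config$outdir, paste0(...)) else NULL
  if (!is.null(config$outdir))
    dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)

  ## stage 1: CRISPR detection
  arrays <- find_arrays(host, min_repeats = 2L)
  arrays <- attach_satellite_arrays(arrays,
                                    max_distance = config$satellite_max_distance,
                                    min_repeats = config$min_repeats)
  arrays <- lapply(arrays, function(a)
    if (nrow(a$instances) >= 4L) call_leader(a, host) else a)
  big <- Filter(function(a) nrow(a$instances) >= config$min_repeats, arrays)
  if (!length(big)) stop("[crisprdetect] no CRISPR array with >= ",
                         config$min_repeats, " repeats found")
  spacers <- get_spacers(arrays)   # selected arrays incl. satellites, qualified ids
  if (!is.null(config$outdir)) write_fasta(spacers, out("spacers.fasta"))

  ## stage 2: orient viral genomes to the viral sense
  oriented <- list()
  for (g in names(genomes)) {
    og <- tryCatch(orient_genome(genomes[[g]], config$nonanucleotide,
                                 annotation = vir$annotations[[g]], id = g),
                   error = function(e) {
                     warning("[orient] ", conditionMessage(e), "; genome excluded")
                     NULL
                   })
    if (!is.null(og)) oriented[[g]] <- og
  }
  oriented_seqs <- vapply(oriented, `[[`, character(1), "sequence")

  ## stage 3: E-value calibration
  model <- calibrate_evalue(unique(nchar(spacers)), config$params,
                            calib_db_nt = config$calib_db_nt,
                            n_replicates = config$n_replicates,
                            seed = config$seed)
  if (!is.null(config$outdir)) write_evalue_model(model, out("evalue_model.json"))

  ## stage 4: scan (glocal, then optional local fallback)
  matches <- if (length(oriented_seqs))
    scan_spacers(spacers, oriented_seqs, config$params, model,
                 threshold = config$threshold)
  else scan_spacers(spacers, character(0), config$params, model,
                    threshold = config$threshold)
  if (config$run_local_fallback && length(oriented_seqs)) {
    lp <- config$params; lp$mode <- "local"
    model_local <- calibrate_evalue(unique(nchar(spacers)), lp,
                                    calib_db_nt = config$calib_db_nt,
                                    n_replicates = config$n_replicates,
                                    seed = config$seed + 1L)
    loc <- scan_spacers(spacers, oriented_seqs, lp, model_local,
                        threshold = config$threshold)
    extra <- loc[!(loc$spacer %in% matches$spacer), , drop = FALSE]
    matches <- rbind(matches, extra)
  }
  ann_by_genome <- lapply(oriented, `[[`, "annotation")
  if (nrow(matches)) {
    matches$frame <- vapply(seq_len(nrow(matches)), function(i) {
      g <- matches$genome[i]
      check_frame_preservation(matches[i, ], ann_by_genome[[g]],
                               nchar(oriented_seqs[[g]]))
    }, character(1))
  }
  if (!is.null(config$outdir)) write_matches_tsv(matches, out("matches.tsv"))

  glocal_m <- matches[matches$mode == "glocal", , drop = FALSE]

  ## stage 5: PAM logos from best-per-spacer representatives
  pam <- NULL
  if (nrow(glocal_m) >= 2L) {
    fl_up <- extract_flanks(glocal_m, oriented_seqs, "upstream",
                            config$flank_len, "best-per-spacer")
    fl_dn <- extract_flanks(glocal_m, oriented_seqs, "downstream",
                            config$flank_len, "best-per-spacer")
    if (length(fl_up$sequences) >= 2L) {
      pfm_up <- build_pfm(fl_up); pfm_dn <- build_pfm(fl_dn)
      pam <- list(upstream = list(pfm = pfm_up, call = call_motif(pfm_up)),
                  downstream = list(pfm = pfm_dn, call = call_motif(pfm_dn)))
    }
  }

  ## stage 6: statistics
  best_per_spacer <- NULL
  stats_out <- list()
  if (nrow(matches)) {
    m <- matches
    m$.g <- match(m$genome, names(oriented_seqs))
    m <- m[order(m$spacer, -m$score, m$evalue, m$.g), , drop = FALSE]
    best_per_spacer <- m[!duplicated(m$spacer), , drop = FALSE]
    best_per_spacer$.g <- NULL
    bias_glocal <- {
      b <- best_per_spacer[best_per_spacer$mode == "glocal", , drop = FALSE]
      strand_bias_test(nrow(b), sum(b$strand == "+"))
    }
    bias_all <- strand_bias_test(nrow(best_per_spacer),
                                 sum(best_per_spacer$strand == "+"))
    comb <- combined_array_significance(
      best_per_spacer$evalue[best_per_spacer$mode == "glocal"],
      length(spacers))
    age <- suppressWarnings(identity_by_age(glocal_m, config$strata))
    stats_out <- list(strand_bias_glocal = bias_glocal,
                      strand_bias_with_local = bias_all,
                      combined_significance = comb,
                      identity_by_age = age,
                      presence = presence_matrix(matches))
  }

  ## stage 7: archetype
  arch <- NULL
  if (!is.null(best_per_spacer) && nrow(best_per_spacer) && length(oriented))
    arch <- tryCatch(build_archetype(best_per_spacer, oriented),
                     error = function(e) NULL)

  report <- list(
    n_arrays = length(big), n_spacers = length(spacers),
    n_genomes = length(oriented_seqs),
    arrays = lapply(big, function(a)
      list(consensus = a$consensus, n_repeats = nrow(a$instances),
           strand = a$strand, leader_side = a$leader_side)),
    n_matches = nrow(matches), matches = matches,
    pam = pam, stats = stats_out, archetype = arch,
    provenance = list(seed = config$seed, threshold = config$threshold,
                      version = as.character(utils::packageVersion("spacerhost"))))
  class(report) <- "run_report"
  if (!is.null(config$outdir)) {
    js <- list(n_arrays = report$n_arrays, n_spacers = report$n_spacers,
               n_genomes = report$n_genomes, n_matches = report$n_matches,
               combined_significance = stats_out$combined_significance,
               strand_bias_p = if (length(stats_out)) stats_out$strand_bias_glocal$p,
               pam_motif = if (!is.null(pam)) pam$upstream$call$motif,
               provenance = report$provenance)
    jsonlite::write_json(js, out("report.json"), auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, null = "null")
  }
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("run_report: %d array(s), %d spacers, %d genomes, %d matches\n",
              x$n_arrays, x$n_spacers, x$n_genomes, x$n_matches))
  if (length(x$stats)) {
    cat(sprintf("  combined array significance: %s\n",
                format(x$stats$combined_significance, digits = 3)))
    print(x$stats$strand_bias_glocal)
  }
  if (!is.null(x$pam)) cat("  upstream PAM call:", x$pam$upstream$call$motif, "\n")
  invisible(x)
}
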