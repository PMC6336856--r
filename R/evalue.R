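#' Calibrate empirical E-values for short-query alignments
#'
#' BLAST-style analytic statistics do not apply to the glocal aligner, so
#' E-values are calibrated empirically: for each query length, `n_replicates`
#' random queries are aligned against independent random subjects (one fresh
#' query per subject; i.i.d. uniform bases, matching the synthetic null) and
#' the best score per (query, subject) pair is recorded. The alignment mode
#' of `params` ("glocal" or "local") selects the null being calibrated. The exceedance count
#' `N(S)` = number of pairs scoring at least S, divided by the calibration
#' database size in nucleotides, estimates the per-nucleotide rate of chance
#' alignments; an E-value for a real search is that rate times the searched
#' database size (both strands counted). Beyond the well-sampled score range
#' the survival function is extrapolated by an exponential (Gumbel-like) tail
#' fitted to its rarest well-populated decade.
#'
#' @param query_lengths integer vector of query lengths to calibrate.
#' @param params an [align_params()].
#' @param calib_db_nt total random-subject nucleotides per length.
#' @param n_replicates number of (query, subject) pairs per length; the
#'   subject length is `calib_db_nt / n_replicates` unless given.
#' @param subject_len optional explicit subject length; choosing it equal to
#'   the real subject-genome length makes per-subject exceedance
#'   probabilities transfer exactly.
#' @param seed RNG seed; calibration is reproducible under it.
#' @param fit_min_count empirical counts at or above this use the raw
#'   survival function; rarer scores use the fitted tail.
#' @return an `evalue_model`.
#' @export
calibrate_evalue <- function(query_lengths, params = align_params(),
                             calib_db_nt = 1e6, n_replicates = 500,
                             subject_len = NULL, seed = 1L,
                             fit_min_count = 10L) {
  query_lengths <- sort(unique(as.integer(query_lengths)))
  if (is.null(subject_len)) subject_len <- as.integer(calib_db_nt / n_replicates)
  stopifnot(subject_len >= max(query_lengths))
  calib_nt <- as.numeric(subject_len) * n_replicates
  entries <- list()
  withr::with_seed(seed, {
    for (L in query_lengths) {
      qs <- vapply(seq_len(n_replicates), function(i) random_dna(L), character(1))
      ss <- vapply(seq_len(n_replicates), function(i) random_dna(subject_len),
                   character(1))
      scores <- score_batch_cpp(qs, ss, params$match, params$mismatch,
                                -params$gap_open, -params$gap_extend,
                                identical(params$mode, "local"))
      smin <- min(scores); smax_obs <- max(scores)
      grid <- smin:L
      exceed <- vapply(grid, function(S) sum(scores >= S), numeric(1))
      # exponential tail on the rarest decade with decent support
      fit_hi <- max(fit_min_count, ceiling(n_replicates / 10))
      pts <- grid[exceed >= 1 & exceed <= fit_hi]
      tail_fit <- list(ok = FALSE, intercept = NA_real_, lambda = NA_real_)
      if (length(pts) >= 3L) {
        fv <- log(exceed[match(pts, grid)])
        fit <- stats::lm(fv ~ pts)
        lam <- -unname(coef(fit)[2])
        if (is.finite(lam) && lam > 0)
          tail_fit <- list(ok = TRUE, intercept = unname(coef(fit)[1]),
                           lambda = lam)
      }
      # effective monotone count table: raw where well sampled, fitted tail
      # (clamped non-increasing) where rare or unobserved
      counts <- numeric(length(grid))
      prev <- Inf
      for (i in seq_along(grid)) {
        S <- grid[i]
        raw <- exceed[i]
        v <- if (raw >= fit_min_count) raw
        else if (tail_fit$ok) exp(tail_fit$intercept - tail_fit$lambda * S)
        else max(raw, 0.5)
        v <- min(v, prev)
        counts[i] <- v
        prev <- v
      }
      entries[[as.character(L)]] <- list(
        length = L, grid = grid, exceed = exceed, counts = counts,
        n = n_replicates, smin = smin, smax_obs = smax_obs,
        tail = tail_fit, unreliable_beyond = if (tail_fit$ok) Inf else smax_obs)
    }
  })
  structure(list(entries = entries, params = params, calib_nt = calib_nt,
                 subject_len = subject_len, n_replicates = n_replicates,
                 seed = seed),
            class = "evalue_model")
}

evalue_covers <- function(model, query_length) {
  inherits(model, "evalue_model") &&
    as.character(query_length) %in% names(model$entries)
}

#' E-value of a score under a calibrated model
#'
#' Scales the calibrated per-nucleotide chance-alignment rate to the searched
#' database size, so E-values are linear in `db_nt` (a doubled database
#' doubles every E-value). Scores below the minimum observed in calibration
#' get the total number of evaluated alignments, scaled; scores beyond the
#' observed range use the fitted exponential tail (with a warning when the
#' fit was unreliable).
#'
#' @param model an `evalue_model`.
#' @param query_length query length (must be calibrated).
#' @param score alignment score (vectorised).
#' @param db_nt searched database size in nucleotides; count both strands if
#'   both were searched.
#' @return numeric E-values.
#' @export
evalue <- function(model, query_length, score, db_nt) {
  key <- as.character(query_length)
  if (!evalue_covers(model, query_length))
    stop("E-value model not calibrated for query length ", query_length)
  e <- model$entries[[key]]
  scale <- db_nt / model$calib_nt
  vapply(score, function(S) {
    if (S < e$smin) return(e$n * scale)
    if (S > max(e$grid)) {
      if (!e$tail$ok)
        warning("score beyond calibrated range with unreliable tail fit")
      cnt <- if (e$tail$ok) exp(e$tail$intercept - e$tail$lambda * S) else 0.5
      return(min(cnt, e$counts[length(e$counts)]) * scale)
    }
    e$counts[match(S, e$grid)] * scale
  }, numeric(1))
}

#' Combined significance of several spacer matches from one array
#'
#' The chance of one match at least as good as E-value e among n spacers is
#' about n*e; the chance of k such matches is about `n_spacers^k * prod(e)`.
#' Feeding the four archetypal per-spacer E-values (0.002, 7.48e-7, 7.06e-6,
#' 2.91e-8) with n = 111 gives ~4.7e-14.
#'
#' @param evalues numeric vector of per-match E-values (k matches).
#' @param n_spacers number of spacers in the array.
#' @return combined probability-scale value; 1.0 for an empty list. Values
#'   above 1 are reported as-is, not clipped.
#' @export
combined_array_significance <- function(evalues, n_spacers) {
  if (!length(evalues)) return(1.0)
  if (any(evalues > 1)) warning("E-values above 1 supplied; combination is approximate")
  n_spacers^length(evalues) * prod(evalues)
}

#' Expected number of chance matches in a threshold search
#'
#' @param n_queries number of query spacers.
#' @param threshold E-value cut-off (> 0).
#' @return `n_queries * threshold`, the expected random match count in a
#'   non-redundant database.
#' @export
expected_random_matches <- function(n_queries, threshold) {
  if (threshold <= 0) stop("threshold must be positive")
  n_queries * threshold
}

#' Serialize / restore an E-value model as JSON
#'
#' @param model an `evalue_model`.
#' @param path file path.
#' @return `read_evalue_model` returns the restored model.
#' @export
write_evalue_model <- function(model, path) {
  obj <- model
  class(obj) <- NULL
  obj$params <- unclass(obj$params)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_evalue_model
#' @export
read_evalue_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$params <- structure(as.list(obj$params), class = "align_params")
  obj$entries <- lapply(obj$entries, function(e) {
    e$tail <- as.list(e$tail)
    e
  })
  class(obj) <- "evalue_model"
  obj
}
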