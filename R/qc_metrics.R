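#' Spectra coverage of a schedule
#'
#' The spectra coverage SC is the ratio of scheduled MS2 events to the
#' theoretical maximum: with `N_p` precursors that received at least one
#' event, `N_spectra` replicates per collision energy and `N_CE` collision
#' energies,
#' `SC = sum_p N_scheduled_p / (N_p * N_spectra * N_CE)`.
#' Precursors without any event do not enter the denominator: they count
#' neither toward `N_p` nor toward the event sum. `SC` is 0 when no
#' precursor was scheduled.
#'
#' @param n_scheduled Integer vector of per-precursor scheduled event
#'   counts; zeros are allowed and ignored.
#' @param n_spectra Replicates per collision energy.
#' @param n_ce Number of collision energies.
#' @return `spectra_coverage()` and `spectra_coverage_total()`: SC as a
#'   fraction in `[0, 1]`. `sc_percent()`: SC as a percentage rounded to
#'   one decimal.
#' @examples
#' spectra_coverage_total(28916, 1396, 5, 6) # 0.6904...
#' sc_percent(spectra_coverage_total(28916, 1396, 5, 6)) # 69.0
#' @export
spectra_coverage <- function(n_scheduled, n_spectra, n_ce) {
  if (any(n_scheduled < 0) || any(n_scheduled > n_spectra * n_ce)) {
    stop("n_scheduled must be within [0, n_spectra * n_ce]")
  }
  n_scheduled <- n_scheduled[n_scheduled > 0]
  spectra_coverage_total(sum(n_scheduled), length(n_scheduled),
                         n_spectra, n_ce)
}

#' @param total_events Total number of scheduled MS2 events.
#' @param n_precursors Number of precursors with at least one event.
#' @rdname spectra_coverage
#' @export
spectra_coverage_total <- function(total_events, n_precursors, n_spectra,
                                   n_ce) {
  if (n_precursors == 0) return(0)
  total_events / (n_precursors * n_spectra * n_ce)
}

#' @param sc Spectra coverage as a fraction.
#' @rdname spectra_coverage
#' @export
sc_percent <- function(sc) round(100 * sc, 1)

#' @param schedule A [simsef_schedule()] result.
#' @param params A [schedule_parameters()] object (replicate and energy
#'   counts); defaults to the schedule's own.
#' @rdname spectra_coverage
#' @export
schedule_coverage <- function(schedule, params = schedule$params) {
  ev <- schedule$events
  if (!nrow(ev)) return(0)
  counts <- table(ev$feature_id)
  spectra_coverage(as.integer(counts), params$n_spectra_per_ce,
                   length(params$collision_energies))
}

#' Integer percentage
#'
#' `round(100 * n / d)`; `NA` for an empty denominator. Used for the
#' count-based quality fractions of [qc_report()].
#'
#' @param n,d Numerator and denominator counts.
#' @return Percentage rounded to the nearest integer.
#' @examples
#' percentage(17887, 23444) # 76
#' @export
percentage <- function(n, d) {
  if (length(d) == 0 || is.na(d) || d == 0) return(NA_real_)
  round(100 * n / d)
}

#' Rate the information content of one MS2 scan
#'
#' A scan is non-empty if at least one signal exceeds the electronic noise
#' level. It passes the information filter if it has at least `min_signals`
#' signals and a base peak of at least `min_bp` (10x the default noise
#' level), and passes the base-peak/TIC filter if the most intense signal
#' contributes less than `bp_tic_max` of the summed intensity — low ratios
#' mean several signals carry the spectrum.
#'
#' @param scan An [ms2_scan()] (or any list with a `peaks` data frame).
#' @param noise Electronic noise level in a.u. (default 100).
#' @param min_signals Minimum number of signals (default 4).
#' @param min_bp Minimum base peak intensity (default 1000).
#' @param bp_tic_max Maximum base-peak/TIC ratio (default 0.5, exclusive).
#' @return One-row data frame with `n_signals`, `base_peak`, `tic`,
#'   `bp_tic_ratio` and the logical flags `non_empty`, `info_pass`,
#'   `bp_tic_pass`.
#' @export
rate_scan <- function(scan, noise = 100, min_signals = 4, min_bp = 1000,
                      bp_tic_max = 0.5) {
  inten <- scan$peaks$intensity
  n <- length(inten)
  bp <- if (n) max(inten) else 0
  tic <- sum(inten)
  ratio <- if (tic > 0) bp / tic else NA_real_
  non_empty <- any(inten > noise)
  data.frame(
    n_signals = n, base_peak = bp, tic = tic, bp_tic_ratio = ratio,
    non_empty = non_empty,
    info_pass = n >= min_signals && bp >= min_bp,
    bp_tic_pass = non_empty && !is.na(ratio) && ratio < bp_tic_max
  )
}

#' @param scans `ms2_scans` list.
#' @rdname rate_scan
#' @return `rate_scans()`: one row per scan.
#' @export
rate_scans <- function(scans, noise = 100, min_signals = 4, min_bp = 1000,
                       bp_tic_max = 0.5) {
  out <- do.call(rbind, lapply(scans, rate_scan, noise = noise,
                               min_signals = min_signals, min_bp = min_bp,
                               bp_tic_max = bp_tic_max))
  if (is.null(out)) out <- rate_scan(list(peaks = data.frame(
    mz = numeric(0), intensity = numeric(0))))[0, ]
  rownames(out) <- NULL
  out
}

#' Cosine similarity of two MS2 peak lists
#'
#' Normalised dot product over greedily matched peaks: all peak pairs
#' within the m/z tolerance are ranked by descending intensity product and
#' accepted greedily without reusing a peak; the score is the sum of
#' matched intensity products divided by the product of the full spectral
#' norms. Identical spectra score 1, spectra without any shared m/z score
#' 0, and the score is invariant to scaling either spectrum.
#'
#' @param a,b Peak data frames with columns `mz`, `intensity` (or
#'   [ms2_scan()] objects).
#' @param mz_tol_da,tol_ppm Fragment m/z tolerance (the larger applies).
#' @return Score in `[0, 1]`; 0 if either spectrum is empty.
#' @export
cosine_similarity <- function(a, b, mz_tol_da = 0.005, tol_ppm = 15) {
  pa <- if (is.data.frame(a)) a else a$peaks
  pb <- if (is.data.frame(b)) b else b$peaks
  if (!nrow(pa) || !nrow(pb)) return(0)
  na2 <- sum(pa$intensity^2)
  nb2 <- sum(pb$intensity^2)
  # candidate pairs within tolerance
  cand <- list()
  for (i in seq_len(nrow(pa))) {
    tol <- max(tol_ppm * pa$mz[i] * 1e-6, mz_tol_da)
    j <- which(abs(pb$mz - pa$mz[i]) <= tol)
    if (length(j)) {
      cand[[length(cand) + 1L]] <- data.frame(
        i = i, j = j, prod = pa$intensity[i] * pb$intensity[j],
        dmz = abs(pb$mz[j] - pa$mz[i]))
    }
  }
  if (!length(cand)) return(0)
  cand <- do.call(rbind, cand)
  cand <- cand[order(-cand$prod, cand$dmz, cand$i, cand$j), , drop = FALSE]
  used_i <- logical(nrow(pa))
  used_j <- logical(nrow(pb))
  dot <- 0
  for (r in seq_len(nrow(cand))) {
    i <- cand$i[r]
    j <- cand$j[r]
    if (used_i[i] || used_j[j]) next
    used_i[i] <- TRUE
    used_j[j] <- TRUE
    dot <- dot + cand$prod[r]
  }
  dot / sqrt(na2 * nb2)
}

#' Intra-feature MS2 similarity
#'
#' Scores all unordered scan pairs within each (feature, collision energy)
#' group and reports the fraction of pairs reaching the similarity
#' threshold. Diverging replicate spectra of one feature flag chimeric or
#' isomeric spatial distributions. Groups with fewer than two scans form no
#' pairs; with no pairs at all the fraction is `NA`.
#'
#' @param scans `ms2_scans` list.
#' @param assignments Result of [assign_scans()] (or its data frame).
#' @param mz_tol_da,tol_ppm Fragment m/z tolerance.
#' @param threshold Similarity threshold (default 0.7).
#' @return List with `pairs` (data frame `feature_id`, `collision_energy`,
#'   `scan_a`, `scan_b`, `score`) and `fraction_above` (share of pairs with
#'   `score >= threshold`, `NA` if no pairs).
#' @export
intra_feature_similarity <- function(scans, assignments, mz_tol_da = 0.005,
                                     tol_ppm = 15, threshold = 0.7) {
  asn <- if (is.data.frame(assignments)) assignments else
    assignments$assignments
  rows <- list()
  key <- paste(asn$feature_id, asn$collision_energy)
  for (k in unique(key)) {
    sub <- asn[key == k, , drop = FALSE]
    n <- nrow(sub)
    if (n < 2) next
    for (i in seq_len(n - 1L)) {
      for (j in seq((i + 1L), n)) {
        rows[[length(rows) + 1L]] <- data.frame(
          feature_id = sub$feature_id[1],
          collision_energy = sub$collision_energy[1],
          scan_a = sub$scan[i], scan_b = sub$scan[j],
          score = cosine_similarity(scans[[sub$scan[i]]],
                                    scans[[sub$scan[j]]],
                                    mz_tol_da, tol_ppm))
      }
    }
  }
  pairs <- if (length(rows)) do.call(rbind, rows) else
    data.frame(feature_id = integer(0), collision_energy = numeric(0),
               scan_a = integer(0), scan_b = integer(0), score = numeric(0))
  rownames(pairs) <- NULL
  list(pairs = pairs,
       fraction_above = if (nrow(pairs)) mean(pairs$score >= threshold)
                        else NA_real_)
}

#' Summary quality report for a SIMSEF run
#'
#' Aggregates the evaluation statistics of a scheduled-and-acquired run:
#' scheduled event count, non-empty scan count, the information and
#' base-peak/TIC pass counts with integer percentages (relative to
#' non-empty scans), the spectra coverage (one-decimal percentage), the
#' share of features with at least one scan passing all criteria and the
#' intra-feature similarity fraction.
#'
#' @param schedule A [simsef_schedule()] result.
#' @param scans `ms2_scans` list.
#' @param assignments Result of [assign_scans()]; computed from `schedule`
#'   when `NULL`.
#' @param noise,min_signals,min_bp,bp_tic_max See [rate_scan()].
#' @param similarity_threshold See [intra_feature_similarity()].
#' @return Object of class `simsef_qc_report`: a list of named statistics.
#' @export
qc_report <- function(schedule, scans, assignments = NULL, noise = 100,
                      min_signals = 4, min_bp = 1000, bp_tic_max = 0.5,
                      similarity_threshold = 0.7) {
  if (is.null(assignments)) assignments <- assign_scans(scans, schedule)
  asn <- assignments$assignments
  rt <- rate_scans(scans, noise, min_signals, min_bp, bp_tic_max)
  n_nonempty <- sum(rt$non_empty)
  n_info <- sum(rt$non_empty & rt$info_pass)
  n_bptic <- sum(rt$non_empty & rt$info_pass & rt$bp_tic_pass)
  all_pass <- rt$non_empty & rt$info_pass & rt$bp_tic_pass
  # features with >=1 non-empty assigned scan, and among them those with a
  # scan passing all criteria
  feat_nonempty <- unique(asn$feature_id[rt$non_empty[asn$scan]])
  feat_best <- unique(asn$feature_id[all_pass[asn$scan]])
  sim <- intra_feature_similarity(scans, asn,
                                  threshold = similarity_threshold)
  structure(list(
    n_scheduled_events = nrow(schedule$events),
    n_scans = length(scans),
    n_non_empty = n_nonempty,
    pct_non_empty = percentage(n_nonempty, length(scans)),
    n_info_pass = n_info,
    pct_info_pass = percentage(n_info, n_nonempty),
    n_bp_tic_pass = n_bptic,
    pct_bp_tic_pass = percentage(n_bptic, n_nonempty),
    sc_percent = sc_percent(schedule_coverage(schedule)),
    n_features_non_empty = length(feat_nonempty),
    n_features_all_criteria = length(feat_best),
    pct_features_all_criteria = percentage(length(feat_best),
                                           length(feat_nonempty)),
    intra_feature_fraction = sim$fraction_above
  ), class = "simsef_qc_report")
}

#' @export
print.simsef_qc_report <- function(x, ...) {
  cat("SIMSEF quality report\n")
  cat(sprintf("  scheduled MS2 events        %d\n", x$n_scheduled_events))
  cat(sprintf("  acquired scans              %d\n", x$n_scans))
  cat(sprintf("  non-empty scans             %d (%s%%)\n", x$n_non_empty,
              format(x$pct_non_empty)))
  cat(sprintf("  >=4 signals & bp >= 1000    %d (%s%% of non-empty)\n",
              x$n_info_pass, format(x$pct_info_pass)))
  cat(sprintf("  base peak / TIC < 0.5       %d (%s%% of non-empty)\n",
              x$n_bp_tic_pass, format(x$pct_bp_tic_pass)))
  cat(sprintf("  spectra coverage SC         %.1f%%\n", x$sc_percent))
  cat(sprintf("  features w/ full-pass scan  %d of %d (%s%%)\n",
              x$n_features_all_criteria, x$n_features_non_empty,
              format(x$pct_features_all_criteria)))
  cat(sprintf("  intra-feature pairs >= 0.7  %s\n",
              ifelse(is.na(x$intra_feature_fraction), "n/a",
                     sprintf("%.2f", x$intra_feature_fraction))))
  invisible(x)
}
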