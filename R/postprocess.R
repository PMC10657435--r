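#' Read and write MS2 scans as MGF
#'
#' Mascot generic format interchange for acquired MS2 scans and consensus
#' spectra. The TITLE line carries the acquisition metadata as
#' `spot=<name> ce=<eV> mob=<low>-<high>` (plus `feature=<id>` when a
#' ground-truth feature id is known), PEPMASS carries the precursor
#' isolation m/z; peak lines are `m/z intensity`. This is the format
#' accepted by molecular-networking platforms.
#'
#' @param scans A list of [ms2_scan()] objects (class `ms2_scans`) or of
#'   consensus spectra from [consensus_spectra()].
#' @param path MGF file path.
#' @return `read_mgf()` returns an `ms2_scans` list; `write_mgf()` returns
#'   `path` invisibly.
#' @export
write_mgf <- function(scans, path) {
  blocks <- lapply(scans, function(s) {
    title <- sprintf("spot=%s ce=%s mob=%.4f-%.4f",
                     s$spot_name %||% "NA",
                     format(s$collision_energy %||% NA),
                     s$mobility_low %||% NA, s$mobility_high %||% NA)
    if (!is.null(s$feature_id) && !is.na(s$feature_id)) {
      title <- sprintf("%s feature=%d", title, s$feature_id)
    }
    c("BEGIN IONS",
      paste0("TITLE=", title),
      sprintf("PEPMASS=%.6f", s$precursor_mz),
      sprintf("%.6f %.4f", s$peaks$mz, s$peaks$intensity),
      "END IONS", "")
  })
  write_lines_lf(unlist(blocks), path)
  invisible(path)
}

#' @rdname write_mgf
#' @export
read_mgf <- function(path) {
  lines <- readLines(path)
  starts <- which(lines == "BEGIN IONS")
  ends <- which(lines == "END IONS")
  if (length(starts) != length(ends)) stop("malformed MGF: unbalanced blocks")
  scans <- vector("list", length(starts))
  for (i in seq_along(starts)) {
    block <- lines[(starts[i] + 1L):(ends[i] - 1L)]
    title <- sub("^TITLE=", "", grep("^TITLE=", block, value = TRUE)[1])
    pep <- as.numeric(sub("^PEPMASS=", "",
                          grep("^PEPMASS=", block, value = TRUE)[1]))
    grab <- function(key) {
      m <- regmatches(title, regexec(paste0(key, "=([^ ]+)"), title))[[1]]
      if (length(m) == 2) m[2] else NA_character_
    }
    num <- function(v) {
      if (is.na(v) || v %in% c("NA", "")) NA_real_ else as.numeric(v)
    }
    mob <- strsplit(grab("mob"), "-", fixed = TRUE)[[1]]
    if (length(mob) < 2) mob <- c(NA_character_, NA_character_)
    peak_lines <- block[!grepl("=", block, fixed = TRUE)]
    peak_lines <- peak_lines[nzchar(trimws(peak_lines))]
    pk <- if (length(peak_lines)) {
      do.call(rbind, lapply(strsplit(peak_lines, "[ \t]+"),
                            function(v) as.numeric(v[1:2])))
    } else matrix(numeric(0), 0, 2)
    fid <- grab("feature")
    scans[[i]] <- ms2_scan(
      spot_name = grab("spot"),
      precursor_mz = pep,
      mobility_low = num(mob[1]),
      mobility_high = num(mob[2]),
      collision_energy = num(grab("ce")),
      mz = pk[, 1], intensity = pk[, 2],
      feature_id = if (is.na(fid) || fid == "NA") NA_integer_
                   else as.integer(fid)
    )
  }
  structure(scans, class = "ms2_scans")
}

#' Assign acquired MS2 scans to image features
#'
#' A scan is assigned to a feature iff all three acquisition identifiers
#' match a scheduled event of that feature: (i) the scan's spot name is a
#' pixel where the feature had a scheduled event, (ii) the precursor m/z is
#' within `max(tol_ppm * mz * 1e-6, tol_da)` of the feature's isolation
#' m/z, and (iii) the scan's mobility window overlaps the scheduled window
#' by at least `min_overlap` of the narrower window's width. If several
#' features match, the one with the smallest precursor m/z difference wins.
#'
#' @param scans `ms2_scans` list.
#' @param schedule A [simsef_schedule()] result.
#' @param tol_ppm,tol_da Precursor m/z tolerance (defaults 5 ppm / 0.005
#'   Da; the larger of the two applies).
#' @param min_overlap Minimum mobility-window overlap as a fraction of the
#'   narrower window (default 0.9).
#' @return List with `assignments` (data frame `scan`, `feature_id`,
#'   `collision_energy`, `spot_name`) and `unassigned` (integer scan
#'   indices).
#' @export
assign_scans <- function(scans, schedule, tol_ppm = 5, tol_da = 0.005,
                         min_overlap = 0.9) {
  ev <- schedule$events
  rows <- list()
  unassigned <- integer(0)
  for (i in seq_along(scans)) {
    s <- scans[[i]]
    cand <- ev[ev$spot_name == s$spot_name, , drop = FALSE]
    if (nrow(cand)) {
      tol <- pmax(tol_ppm * cand$isolation_mz * 1e-6, tol_da)
      dmz <- abs(s$precursor_mz - cand$isolation_mz)
      ov <- pmin(s$mobility_high, cand$mobility_high) -
        pmax(s$mobility_low, cand$mobility_low)
      narrow <- pmin(s$mobility_high - s$mobility_low,
                     cand$mobility_high - cand$mobility_low)
      ok <- dmz <= tol & ov >= min_overlap * narrow
      cand <- cand[ok, , drop = FALSE]
      dmz <- dmz[ok]
    }
    if (!nrow(cand)) {
      unassigned <- c(unassigned, i)
      next
    }
    best <- cand[which.min(dmz), ]
    rows[[length(rows) + 1L]] <- data.frame(
      scan = i, feature_id = best$feature_id,
      collision_energy = s$collision_energy, spot_name = s$spot_name)
  }
  assignments <- if (length(rows)) do.call(rbind, rows) else
    data.frame(scan = integer(0), feature_id = integer(0),
               collision_energy = numeric(0), spot_name = character(0))
  rownames(assignments) <- NULL
  list(assignments = assignments, unassigned = unassigned)
}

#' Merge replicate MS2 scans into a consensus spectrum
#'
#' Pools the peaks of all scans, groups them by m/z using single linkage on
#' the globally sorted peak list — a gap larger than
#' `max(tol_ppm * mz * 1e-6, mz_tol_da)` starts a new group, and a group is
#' also broken when it would span more than 3x that tolerance, to bound
#' drift — and emits one consensus peak per group with the
#' intensity-weighted mean m/z and the maximum member intensity. Because
#' every low-abundance scan can contribute peaks the other replicates lack,
#' merging never discards information; and because grouping operates on the
#' globally sorted list, the result is independent of scan order.
#'
#' @param scans Non-empty list of [ms2_scan()] objects (or consensus
#'   spectra).
#' @param mz_tol_da,tol_ppm Fragment m/z tolerance (defaults 0.005 Da / 15
#'   ppm; the larger applies).
#' @return A consensus spectrum: list with `peaks` (data frame `mz`,
#'   `intensity`), `n_source_scans` and, when unambiguous in the input,
#'   `feature_id` and `collision_energy`.
#' @export
merge_scans <- function(scans, mz_tol_da = 0.005, tol_ppm = 15) {
  if (!length(scans)) stop("cannot merge an empty scan list")
  peaks <- do.call(rbind, lapply(scans, function(s) s$peaks))
  if (!nrow(peaks)) stop("cannot merge scans without peaks")
  o <- order(peaks$mz, peaks$intensity)
  mz <- peaks$mz[o]
  inten <- peaks$intensity[o]
  n <- length(mz)
  grp <- integer(n)
  grp[1] <- 1L
  start_mz <- mz[1]
  for (i in seq_len(n - 1L) + 1L) {
    tol <- max(tol_ppm * mz[i] * 1e-6, mz_tol_da)
    if (mz[i] - mz[i - 1L] > tol || mz[i] - start_mz > 3 * tol) {
      grp[i] <- grp[i - 1L] + 1L
      start_mz <- mz[i]
    } else {
      grp[i] <- grp[i - 1L]
    }
  }
  cm <- vapply(split(seq_len(n), grp),
               function(ix) stats::weighted.mean(mz[ix], inten[ix]), 0)
  ci <- vapply(split(inten, grp), max, 0)
  uniq <- function(field) {
    v <- unique(unlist(lapply(scans, function(s) s[[field]])))
    v <- v[!is.na(v)]
    if (length(v) == 1) v else NA
  }
  list(peaks = data.frame(mz = as.numeric(cm), intensity = as.numeric(ci)),
       n_source_scans = length(scans),
       feature_id = uniq("feature_id"),
       collision_energy = uniq("collision_energy"),
       precursor_mz = uniq("precursor_mz"),
       spot_name = NA_character_,
       mobility_low = uniq("mobility_low"),
       mobility_high = uniq("mobility_high"))
}

#' Consensus spectra per feature, by collision energy and across energies
#'
#' Two-stage consensus building: the scans assigned to a feature are first
#' merged per collision energy ([merge_scans()]), then the per-energy
#' consensus spectra are merged once more into an across-energy consensus,
#' so per-energy artefacts remain inspectable.
#'
#' @param scans `ms2_scans` list.
#' @param assignments Result of [assign_scans()] (or its `assignments`
#'   data frame).
#' @param mz_tol_da,tol_ppm Fragment m/z tolerance, see [merge_scans()].
#' @return List with `per_ce` (list of consensus spectra, one per
#'   (feature, energy) group) and `across_ce` (one per feature, with
#'   `collision_energy = NA`).
#' @export
consensus_spectra <- function(scans, assignments, mz_tol_da = 0.005,
                              tol_ppm = 15) {
  asn <- if (is.data.frame(assignments)) assignments else
    assignments$assignments
  per_ce <- list()
  across <- list()
  for (fid in sort(unique(asn$feature_id))) {
    sub <- asn[asn$feature_id == fid, , drop = FALSE]
    ce_cons <- list()
    for (ce in sort(unique(sub$collision_energy))) {
      idx <- sub$scan[sub$collision_energy == ce]
      cons <- merge_scans(scans[idx], mz_tol_da, tol_ppm)
      cons$feature_id <- fid
      cons$collision_energy <- ce
      ce_cons[[length(ce_cons) + 1L]] <- cons
    }
    per_ce <- c(per_ce, ce_cons)
    all_ce <- merge_scans(ce_cons, mz_tol_da, tol_ppm)
    all_ce$feature_id <- fid
    all_ce$collision_energy <- NA_real_
    across[[length(across) + 1L]] <- all_ce
  }
  list(per_ce = per_ce, across_ce = across)
}
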