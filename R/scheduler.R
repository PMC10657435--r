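#' Scheduling parameters
#'
#' All tunables of the MS2 scheduler in one validated record. Defaults are
#' the acquisition settings of the reference workflow: 1.7 Da quadrupole
#' isolation width, precursor mobility windows clamped to 0.02-0.04 Vs/cm^2,
#' 5 replicate spectra for each of 6 collision energies (20-70 eV), a
#' minimum Euclidean distance of 20 pixels between replicate events of the
#' same collision energy, per-pixel intensity above 3000 a.u. and above 20%
#' of the feature maximum, minimum isolation purity 0.8, 1.65 ms quadrupole
#' switch time and a feature eligibility threshold of 5000 a.u. maximum
#' intensity.
#'
#' @param isolation_width_da Quadrupole isolation width in Da.
#' @param mobility_window_min,mobility_window_max Bounds (Vs/cm^2) the
#'   precursor mobility window width is clamped to.
#' @param n_spectra_per_ce Replicate MS2 spectra per collision energy.
#' @param collision_energies Collision energies in eV (distinct, non-empty).
#' @param min_distance_px Minimum Euclidean distance (pixel units) between
#'   events of the same feature and same collision energy.
#' @param min_pixel_intensity_abs Absolute per-pixel intensity threshold
#'   (a.u.); a pixel qualifies only if the feature intensity exceeds it.
#' @param min_pixel_intensity_rel Relative per-pixel threshold as a fraction
#'   of the feature's maximum intensity; combined with the absolute
#'   threshold by AND, both strict.
#' @param min_purity Minimum isolation purity score in `[0, 1]`.
#' @param quad_switch_time_ms Quadrupole switch time in ms, converted to a
#'   mobility gap via [min_mobility_gap()].
#' @param eligibility_min_intensity A feature is eligible for scheduling only
#'   if its maximum pixel intensity is at least this value (a.u.).
#' @param purity_mz_tol_da m/z tolerance (Da) for counting a frame point as
#'   belonging to the precursor (or one of its isotopes) in
#'   [purity_score()].
#' @param isotope_spacing_da Isotope spacing in Da (default 1.0034).
#' @param n_isotopes_pure Number of isotope positions (starting at the
#'   monoisotopic m/z) counted as pure.
#' @return Object of class `schedule_parameters`.
#' @export
schedule_parameters <- function(isolation_width_da = 1.7,
                                mobility_window_min = 0.02,
                                mobility_window_max = 0.04,
                                n_spectra_per_ce = 5,
                                collision_energies = c(20, 30, 40, 50, 60, 70),
                                min_distance_px = 20,
                                min_pixel_intensity_abs = 3000,
                                min_pixel_intensity_rel = 0.20,
                                min_purity = 0.8,
                                quad_switch_time_ms = 1.65,
                                eligibility_min_intensity = 5000,
                                purity_mz_tol_da = 0.01,
                                isotope_spacing_da = 1.0034,
                                n_isotopes_pure = 2) {
  p <- list(isolation_width_da = isolation_width_da,
            mobility_window_min = mobility_window_min,
            mobility_window_max = mobility_window_max,
            n_spectra_per_ce = as.integer(n_spectra_per_ce),
            collision_energies = as.numeric(collision_energies),
            min_distance_px = min_distance_px,
            min_pixel_intensity_abs = min_pixel_intensity_abs,
            min_pixel_intensity_rel = min_pixel_intensity_rel,
            min_purity = min_purity,
            quad_switch_time_ms = quad_switch_time_ms,
            eligibility_min_intensity = eligibility_min_intensity,
            purity_mz_tol_da = purity_mz_tol_da,
            isotope_spacing_da = isotope_spacing_da,
            n_isotopes_pure = as.integer(n_isotopes_pure))
  num <- c("isolation_width_da", "mobility_window_min", "mobility_window_max",
           "min_distance_px", "min_pixel_intensity_abs",
           "min_pixel_intensity_rel", "quad_switch_time_ms",
           "eligibility_min_intensity", "purity_mz_tol_da",
           "isotope_spacing_da")
  for (k in num) {
    if (!is.finite(p[[k]]) || p[[k]] < 0) stop(k, " must be >= 0")
  }
  if (p$isolation_width_da <= 0) stop("isolation_width_da must be > 0")
  if (p$mobility_window_min > p$mobility_window_max) {
    stop("mobility_window_min must be <= mobility_window_max")
  }
  if (p$min_purity < 0 || p$min_purity > 1) stop("min_purity must be in [0, 1]")
  if (p$n_spectra_per_ce < 1) stop("n_spectra_per_ce must be >= 1")
  if (!length(p$collision_energies) ||
      anyDuplicated(p$collision_energies)) {
    stop("collision_energies must be non-empty and distinct")
  }
  if (p$n_isotopes_pure < 1) stop("n_isotopes_pure must be >= 1")
  structure(p, class = "schedule_parameters")
}

#' @export
print.schedule_parameters <- function(x, ...) {
  cat("schedule_parameters:\n")
  for (k in names(x)) {
    cat(sprintf("  %-26s %s\n", k, paste(format(x[[k]]), collapse = ", ")))
  }
  invisible(x)
}

#' Eligible features in scheduling order
#'
#' A feature is eligible if its maximum pixel intensity reaches
#' `eligibility_min_intensity`. Eligible features are returned sorted by
#' ascending area (summed intensity) so that low-abundance precursors, which
#' are detected in few pixels, are scheduled first while their most intense
#' pixels are still free. Ties are broken by ascending m/z, then ascending
#' feature id, making the order fully deterministic.
#'
#' @param features An [ion_features()] object.
#' @param params A [schedule_parameters()] object.
#' @return The eligible subset of `features$table`, reordered.
#' @export
eligible_features <- function(features, params = schedule_parameters()) {
  ft <- features$table
  ft <- ft[ft$max_intensity >= params$eligibility_min_intensity, , drop = FALSE]
  ft <- ft[order(ft$area, ft$mz, ft$feature_id), , drop = FALSE]
  rownames(ft) <- NULL
  ft
}

#' Precursor mobility isolation window for a feature
#'
#' The window is centred on the feature's mobility apex with a width equal
#' to the detected mobility extent clamped to
#' `[mobility_window_min, mobility_window_max]`, then shifted (width
#' preserved) to lie within the geometry's 1/K0 range.
#'
#' @param feature One row of an [ion_features()] table (or any list with
#'   `mobility_apex`, `mobility_low`, `mobility_high`).
#' @param params A [schedule_parameters()] object.
#' @param geometry A [raster_geometry()].
#' @return Numeric vector `c(low, high)` in Vs/cm^2.
#' @export
assign_mobility_window <- function(feature, params, geometry) {
  apex <- feature$mobility_apex
  if (apex < geometry$mobility_min || apex > geometry$mobility_max) {
    stop("mobility apex outside the geometry 1/K0 range")
  }
  extent <- feature$mobility_high - feature$mobility_low
  w <- min(max(extent, params$mobility_window_min), params$mobility_window_max)
  lo <- apex - w / 2
  hi <- apex + w / 2
  if (lo < geometry$mobility_min) {
    hi <- hi + (geometry$mobility_min - lo)
    lo <- geometry$mobility_min
  }
  if (hi > geometry$mobility_max) {
    lo <- lo - (hi - geometry$mobility_max)
    hi <- geometry$mobility_max
  }
  lo <- max(lo, geometry$mobility_min)
  c(low = lo, high = hi)
}

#' Expected isolation purity of a precursor in one pixel
#'
#' Scores how much of the signal co-isolated with a precursor actually
#' belongs to the precursor ion species. All frame points within the
#' quadrupole isolation m/z window and the precursor's mobility window form
#' the isolated population; points within `purity_mz_tol_da` of the
#' precursor m/z or of one of its first `n_isotopes_pure - 1` isotope
#' positions (spacing `isotope_spacing_da`) count as pure. The score is the
#' pure intensity fraction; an empty isolation region scores 0.
#'
#' @param points Data frame with columns `mz`, `mobility`, `intensity` (one
#'   pixel's frame point cloud, e.g. from [frame_points()]).
#' @param isolation_mz Precursor m/z in Da.
#' @param isolation_width_da Quadrupole isolation width in Da (> 0).
#' @param mobility_low,mobility_high Precursor mobility window (1/K0).
#' @param params A [schedule_parameters()] object (tolerances and isotope
#'   model).
#' @return Purity score in `[0, 1]`.
#' @export
purity_score <- function(points, isolation_mz, isolation_width_da,
                         mobility_low, mobility_high,
                         params = schedule_parameters()) {
  if (!is.finite(isolation_width_da) || isolation_width_da <= 0) {
    stop("isolation_width_da must be > 0")
  }
  if (!nrow(points)) return(0)
  half <- isolation_width_da / 2
  in_s <- points$mz >= isolation_mz - half & points$mz <= isolation_mz + half &
    points$mobility >= mobility_low & points$mobility <= mobility_high
  tot <- sum(points$intensity[in_s])
  if (!is.finite(tot) || tot <= 0) return(0)
  iso <- isolation_mz +
    (seq_len(params$n_isotopes_pure) - 1L) * params$isotope_spacing_da
  pure <- rep(FALSE, nrow(points))
  for (m in iso) {
    pure <- pure | abs(points$mz - m) <= params$purity_mz_tol_da
  }
  sum(points$intensity[in_s & pure]) / tot
}

#' Ramp feasibility of adding a precursor to a pixel
#'
#' Within one TIMS ramp the quadrupole serves precursors in order of
#' descending mobility (elution order). Adding a candidate is feasible iff,
#' after sorting all windows by descending upper edge, every consecutive
#' pair (earlier window i, later window j) leaves at least
#' [min_mobility_gap()] between `low_i` and `high_j` — which also forbids
#' any window overlap.
#'
#' @param windows Data frame (or 2-column matrix) of already scheduled
#'   mobility windows in the pixel, columns `low`, `high`; may have 0 rows.
#' @param candidate Numeric `c(low, high)` of the candidate window.
#' @param geometry A [raster_geometry()].
#' @param params A [schedule_parameters()] object (switch time).
#' @return `TRUE` (accept) or `FALSE` (reject).
#' @export
check_ramp_feasible <- function(windows, candidate, geometry,
                                params = schedule_parameters()) {
  w <- matrix(candidate, 1)
  if (!is.null(windows) && NROW(windows) > 0) {
    w <- rbind(as.matrix(windows), w)
  }
  if (nrow(w) < 2) return(TRUE)
  w <- w[order(-w[, 2]), , drop = FALSE]
  gap <- min_mobility_gap(params$quad_switch_time_ms, geometry)
  all(w[-nrow(w), 1] - w[-1, 2] >= gap)
}

#' Spatial feasibility of a replicate MS2 event
#'
#' Replicate events of the same feature at the same collision energy must be
#' at least `min_distance_px` apart (Euclidean, pixel units) so that
#' replicates sample different sample regions. Events of the same feature at
#' different collision energies are exempt.
#'
#' @param prior_pixels Data frame with columns `x`, `y`: pixels already
#'   holding an event of the same feature and collision energy.
#' @param x,y Candidate pixel.
#' @param params A [schedule_parameters()] object.
#' @return `TRUE` (accept) or `FALSE` (reject).
#' @export
check_spatial <- function(prior_pixels, x, y, params = schedule_parameters()) {
  if (!nrow(prior_pixels)) return(TRUE)
  all(pixel_distance(prior_pixels$x, prior_pixels$y, x, y) >=
        params$min_distance_px)
}

#' Schedule MS2 events across an imaging dataset
#'
#' The core greedy scheduler. Eligible features are visited in ascending
#' area order ([eligible_features()]); for each feature and each collision
#' energy its pixels are walked from the most to the least intense
#' (row-major tie-break). A pixel is accepted iff (i) the feature's
#' intensity there strictly exceeds both the absolute and the relative
#' per-pixel thresholds, (ii) adding the feature's mobility window to the
#' pixel's ramp is feasible ([check_ramp_feasible()]), (iii) the minimum
#' distance to replicates of the same collision energy holds
#' ([check_spatial()]) and (iv) the expected isolation purity
#' ([purity_score()]) reaches `min_purity`. The walk for one
#' (feature, energy) pair stops after `n_spectra_per_ce` acceptances or
#' pixel exhaustion. A second pass then retries every (feature, energy)
#' pair still short of its replicate count with the same checks, but trying
#' pixels that already hold at least one scheduled event first, which keeps
#' the number of consumed MS2 pixels low. The result is deterministic.
#'
#' @param features An [ion_features()] object.
#' @param frames An [ms1_frames()] object on the same geometry.
#' @param params A [schedule_parameters()] object.
#' @return Object of class `simsef_schedule`: list with `events` (data frame
#'   with columns `feature_id`, `x`, `y`, `spot_name`, `collision_energy`,
#'   `isolation_mz`, `isolation_width_da`, `mobility_low`, `mobility_high`,
#'   `purity`), `feature_summary` (per eligible feature: events scheduled,
#'   candidate pixel count and rejection counts by rule) , `params` and
#'   `geometry`.
#' @export
simsef_schedule <- function(features, frames, params = schedule_parameters()) {
  g <- features$geometry
  if (!same_geometry(g, frames$geometry)) {
    stop("features and frames have different raster geometries")
  }
  ft <- eligible_features(features, params)
  nF <- nrow(ft)
  ces <- params$collision_energies
  n_ce <- length(ces)
  n_rep <- params$n_spectra_per_ce

  pix_index <- split_frame_index(frames)
  pts <- frames$points
  ints <- features$intensities

  # per-feature candidate pixels (intensity filter applied up front) and
  # mobility windows
  cand <- vector("list", nF)
  win <- matrix(0, nF, 2)
  rej_intensity <- integer(nF)
  for (fi in seq_len(nF)) {
    f <- ft[fi, ]
    win[fi, ] <- assign_mobility_window(f, params, g)
    ci <- ints[ints$feature_id == f$feature_id, , drop = FALSE]
    ok <- ci$intensity > params$min_pixel_intensity_abs &
      ci$intensity > params$min_pixel_intensity_rel * f$max_intensity
    rej_intensity[fi] <- sum(!ok)
    ci <- ci[ok, , drop = FALSE]
    ci <- ci[order(-ci$intensity, ci$y, ci$x), , drop = FALSE]
    ci$pid <- pixel_id(ci$x, ci$y, g)
    cand[[fi]] <- ci
  }

  # mutable state
  pixel_windows <- vector("list", g$n_cols * g$n_rows)
  counts <- matrix(0L, max(nF, 1L), max(n_ce, 1L))
  acc_x <- vector("list", nF * n_ce) # accepted pixels per (feature, ce)
  acc_y <- vector("list", nF * n_ce)
  purity_cache <- vector("list", nF) # per feature: named by pid
  rej_ramp <- integer(nF)
  rej_spatial <- integer(nF)
  rej_purity <- integer(nF)
  ev <- list()
  nev <- 0L
  pixel_has_event <- logical(g$n_cols * g$n_rows)

  feature_purity <- function(fi, pid, row) {
    cache <- purity_cache[[fi]]
    key <- as.character(pid)
    if (!is.null(cache) && !is.null(cache[[key]])) return(cache[[key]])
    idx <- pix_index[[key]]
    sc <- if (is.null(idx)) 0 else {
      purity_score(pts[idx, , drop = FALSE], ft$mz[fi],
                   params$isolation_width_da, win[fi, 1], win[fi, 2], params)
    }
    if (is.null(cache)) cache <- list()
    cache[[key]] <- sc
    purity_cache[[fi]] <<- cache
    sc
  }

  try_pixel <- function(fi, ci_ce, row) {
    pid <- row$pid
    if (!check_ramp_feasible(pixel_windows[[pid]], win[fi, ], g, params)) {
      rej_ramp[fi] <<- rej_ramp[fi] + 1L
      return(FALSE)
    }
    k <- (fi - 1L) * n_ce + ci_ce
    prior <- data.frame(x = acc_x[[k]] %||% numeric(0),
                        y = acc_y[[k]] %||% numeric(0))
    if (!check_spatial(prior, row$x, row$y, params)) {
      rej_spatial[fi] <<- rej_spatial[fi] + 1L
      return(FALSE)
    }
    if (feature_purity(fi, pid, row) < params$min_purity) {
      rej_purity[fi] <<- rej_purity[fi] + 1L
      return(FALSE)
    }
    # accept
    pixel_windows[[pid]] <<- rbind(pixel_windows[[pid]],
                                   matrix(win[fi, ], 1))
    acc_x[[k]] <<- c(acc_x[[k]], row$x)
    acc_y[[k]] <<- c(acc_y[[k]], row$y)
    counts[fi, ci_ce] <<- counts[fi, ci_ce] + 1L
    pixel_has_event[pid] <<- TRUE
    nev <<- nev + 1L
    ev[[nev]] <<- data.frame(
      feature_id = ft$feature_id[fi], x = row$x, y = row$y,
      spot_name = spot_name(row$x, row$y),
      collision_energy = ces[ci_ce],
      isolation_mz = ft$mz[fi],
      isolation_width_da = params$isolation_width_da,
      mobility_low = win[fi, 1], mobility_high = win[fi, 2],
      purity = feature_purity(fi, pid, row)
    )
    TRUE
  }

  walk <- function(fi, ci_ce, order_idx) {
    ci <- cand[[fi]]
    for (r in order_idx) {
      if (counts[fi, ci_ce] >= n_rep) break
      try_pixel(fi, ci_ce, ci[r, ])
    }
  }

  # phase 1: plain intensity order
  for (fi in seq_len(nF)) {
    nc <- nrow(cand[[fi]])
    if (!nc) next
    for (ci_ce in seq_len(n_ce)) walk(fi, ci_ce, seq_len(nc))
  }
  # phase 2: for shortfalls, try pixels already holding events first
  for (fi in seq_len(nF)) {
    ci <- cand[[fi]]
    nc <- nrow(ci)
    if (!nc) next
    for (ci_ce in seq_len(n_ce)) {
      if (counts[fi, ci_ce] >= n_rep) next
      used <- pixel_has_event[ci$pid] # snapshot for this walk
      walk(fi, ci_ce, order(!used, seq_len(nc)))
    }
  }

  events <- if (nev) do.call(rbind, ev[seq_len(nev)]) else empty_events()
  rownames(events) <- NULL
  summary <- data.frame(
    feature_id = ft$feature_id, area = ft$area,
    max_intensity = ft$max_intensity,
    n_candidate_pixels = vapply(cand, nrow, 1L),
    n_events = if (nF) as.integer(rowSums(counts[seq_len(nF), , drop = FALSE]))
               else integer(0),
    n_target = n_rep * n_ce,
    rejected_intensity = rej_intensity, rejected_ramp = rej_ramp,
    rejected_spatial = rej_spatial, rejected_purity = rej_purity
  )
  structure(list(events = events, feature_summary = summary,
                 params = params, geometry = g),
            class = "simsef_schedule")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

empty_events <- function() {
  data.frame(feature_id = integer(0), x = integer(0), y = integer(0),
             spot_name = character(0), collision_energy = numeric(0),
             isolation_mz = numeric(0), isolation_width_da = numeric(0),
             mobility_low = numeric(0), mobility_high = numeric(0),
             purity = numeric(0))
}

#' @export
print.simsef_schedule <- function(x, ...) {
  cat(sprintf("simsef_schedule: %d events, %d features, %d MS2 pixels\n",
              nrow(x$events), length(unique(x$events$feature_id)),
              length(unique(x$events$spot_name))))
  invisible(x)
}

#' Independent post-hoc validation of a schedule
#'
#' Re-checks every constraint of a schedule from scratch, independently of
#' the scheduler's bookkeeping: per-pixel intensity thresholds, ramp
#' feasibility (pairwise, per pixel), the minimum distance between
#' same-energy replicates (pairwise, per feature and energy), isolation
#' purity (recomputed from the frames) and the per-(feature, energy)
#' replicate cap. Intended as an oracle: [simsef_schedule()] output must
#' validate clean.
#'
#' @param schedule A `simsef_schedule` (or anything with an `events` data
#'   frame of the same shape).
#' @param features,frames The dataset the schedule was built on.
#' @param params A [schedule_parameters()] object; defaults to the
#'   schedule's own.
#' @return Data frame of violations (0 rows if clean) with columns `rule`
#'   (`"intensity"`, `"ramp"`, `"spatial"`, `"purity"`, `"count"`),
#'   `feature_id`, `spot_name`, `collision_energy` and `detail`.
#' @export
validate_schedule <- function(schedule, features, frames,
                              params = schedule$params) {
  ev <- schedule$events
  g <- features$geometry
  viol <- list()
  add <- function(rule, feature_id, spot, ce, detail) {
    viol[[length(viol) + 1L]] <<- data.frame(
      rule = rule, feature_id = feature_id, spot_name = spot,
      collision_energy = ce, detail = detail)
  }
  if (!nrow(ev)) return(empty_violations())
  ints <- features$intensities
  ftab <- features$table

  # intensity rule, per event
  for (i in seq_len(nrow(ev))) {
    e <- ev[i, ]
    fmax <- ftab$max_intensity[match(e$feature_id, ftab$feature_id)]
    sel <- ints$feature_id == e$feature_id & ints$x == e$x & ints$y == e$y
    inten <- if (any(sel)) ints$intensity[sel][1] else 0
    if (!(inten > params$min_pixel_intensity_abs &&
          inten > params$min_pixel_intensity_rel * fmax)) {
      add("intensity", e$feature_id, e$spot_name, e$collision_energy,
          sprintf("pixel intensity %.1f below threshold", inten))
    }
  }

  # purity rule, per event (recomputed from frames)
  for (i in seq_len(nrow(ev))) {
    e <- ev[i, ]
    p <- purity_score(frame_points(frames, e$x, e$y), e$isolation_mz,
                      e$isolation_width_da, e$mobility_low, e$mobility_high,
                      params)
    if (p < params$min_purity) {
      add("purity", e$feature_id, e$spot_name, e$collision_energy,
          sprintf("purity %.3f below %.3f", p, params$min_purity))
    }
  }

  # ramp rule: consecutive windows per pixel in elution order
  gap <- min_mobility_gap(params$quad_switch_time_ms, g)
  for (spot in unique(ev$spot_name)) {
    sub <- ev[ev$spot_name == spot, , drop = FALSE]
    sub <- sub[order(-sub$mobility_high), , drop = FALSE]
    if (nrow(sub) < 2) next
    for (i in seq_len(nrow(sub) - 1L)) {
      if (sub$mobility_low[i] - sub$mobility_high[i + 1L] < gap) {
        add("ramp", sub$feature_id[i], spot, sub$collision_energy[i],
            sprintf("gap to feature %d is %.4f < %.4f",
                    sub$feature_id[i + 1L],
                    sub$mobility_low[i] - sub$mobility_high[i + 1L], gap))
      }
    }
  }

  # spatial rule and replicate cap per (feature, energy)
  key <- paste(ev$feature_id, ev$collision_energy)
  for (k in unique(key)) {
    sub <- ev[key == k, , drop = FALSE]
    n <- nrow(sub)
    if (n > params$n_spectra_per_ce) {
      add("count", sub$feature_id[1], sub$spot_name[1],
          sub$collision_energy[1],
          sprintf("%d events exceed cap %d", n, params$n_spectra_per_ce))
    }
    if (n < 2) next
    for (i in seq_len(n - 1L)) {
      for (j in seq((i + 1L), n)) {
        d <- pixel_distance(sub$x[i], sub$y[i], sub$x[j], sub$y[j])
        if (d < params$min_distance_px) {
          add("spatial", sub$feature_id[1], sub$spot_name[i],
              sub$collision_energy[1],
              sprintf("distance %.2f to %s below %g", d, sub$spot_name[j],
                      params$min_distance_px))
        }
      }
    }
  }

  if (!length(viol)) return(empty_violations())
  out <- do.call(rbind, viol)
  rownames(out) <- NULL
  out
}

empty_violations <- function() {
  data.frame(rule = character(0), feature_id = integer(0),
             spot_name = character(0), collision_energy = numeric(0),
             detail = character(0))
}
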