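#' Specification for a synthetic TIMS-MS1 imaging dataset
#'
#' Defines a complete, self-consistent simulated imaging experiment with
#' known ground truth. Each feature is a Gaussian spatial blob (hotspot with
#' low-intensity margins) with an m/z drawn from `mz_range`, a mobility apex
#' affine in m/z plus noise, and a mobility window of width within
#' `mobility_window_width_range`. A configurable fraction of features gets an
#' isobaric interference partner: a second, unlisted ion species within
#' +/- 0.85 Da and with overlapping mobility, spatially co-located with the
#' feature, so that purity filtering has true positives and negatives to act
#' on. Per-pixel frames contain one monoisotopic point per contributing
#' species (with bounded m/z jitter), an M+1 isotope point where intense
#' enough, and uniform background points below the noise floor.
#'
#' Feature m/z values are drawn with a minimum pairwise separation and
#' background m/z values are kept away from every feature's isotope
#' positions, so the label-based ground-truth purity of any feature window is
#' well defined and must agree exactly with [purity_score()].
#'
#' @param geometry A [raster_geometry()].
#' @param n_features Number of listed features (>= 0).
#' @param seed Integer seed; the same spec generates byte-identical output.
#' @param mz_range m/z range (Da) features are drawn from.
#' @param min_mz_separation_da Minimum pairwise feature m/z separation (Da).
#' @param sigma_px_range Range of spatial blob sigma in pixels; a sigma of 0
#'   collapses the blob onto its centre pixel.
#' @param peak_intensity_range Range (a.u.) of blob peak intensities,
#'   sampled log-uniformly.
#' @param mobility_window_width_range Mobility window width range (Vs/cm^2).
#' @param mobility_jitter Gaussian noise (Vs/cm^2) on the affine
#'   m/z-to-mobility trend.
#' @param interference_fraction Fraction of features given an isobaric
#'   interference partner (default 0.3).
#' @param interference_delta_da Range of |m/z offset| of the partner (Da).
#' @param interference_rel_intensity Partner peak intensity relative to the
#'   host feature's peak intensity.
#' @param noise_floor Intensity (a.u.) below which feature signals are
#'   truncated and below which background points lie (default 100).
#' @param background_points_per_pixel Number of background points per frame.
#' @param mz_jitter_da Half-width of the uniform m/z jitter on signal points;
#'   must stay below the purity m/z tolerance (0.01 Da) for the ground-truth
#'   purity contract to hold.
#' @return Object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(geometry = raster_geometry(32, 32),
                           n_features = 40,
                           seed = 1L,
                           mz_range = c(150, 1000),
                           min_mz_separation_da = 3,
                           sigma_px_range = c(1.5, 4),
                           peak_intensity_range = c(1e4, 3e5),
                           mobility_window_width_range = c(0.02, 0.04),
                           mobility_jitter = 0.02,
                           interference_fraction = 0.3,
                           interference_delta_da = c(0.3, 0.85),
                           interference_rel_intensity = c(0.3, 1.5),
                           noise_floor = 100,
                           background_points_per_pixel = 15,
                           mz_jitter_da = 0.003) {
  if (!inherits(geometry, "raster_geometry")) stop("geometry must be a raster_geometry")
  if (n_features < 0) stop("n_features must be >= 0")
  if (diff(mz_range) <= 0) stop("mz_range must be a non-empty interval")
  if (diff(mz_range) < (n_features - 1) * min_mz_separation_da) {
    stop("mz_range too narrow for n_features at min_mz_separation_da")
  }
  if (interference_fraction < 0 || interference_fraction > 1) {
    stop("interference_fraction must be in [0, 1]")
  }
  wmax <- mobility_window_width_range[2]
  if (wmax >= geometry$mobility_max - geometry$mobility_min) {
    stop("mobility window width exceeds the geometry 1/K0 range")
  }
  structure(
    list(geometry = geometry, n_features = as.integer(n_features),
         seed = as.integer(seed), mz_range = mz_range,
         min_mz_separation_da = min_mz_separation_da,
         sigma_px_range = sigma_px_range,
         peak_intensity_range = peak_intensity_range,
         mobility_window_width_range = mobility_window_width_range,
         mobility_jitter = mobility_jitter,
         interference_fraction = interference_fraction,
         interference_delta_da = interference_delta_da,
         interference_rel_intensity = interference_rel_intensity,
         noise_floor = noise_floor,
         background_points_per_pixel = as.integer(background_points_per_pixel),
         mz_jitter_da = mz_jitter_da),
    class = "synthetic_spec"
  )
}

# isotope spacing and exclusion guard used by the generator; matches the
# scheduler defaults so ground-truth purity and purity_score agree
.iso_spacing <- 1.0034
.n_iso <- 2L
.iso_guard <- 0.05

# positions around which background m/z must not fall
iso_positions <- function(mz) {
  as.vector(outer(mz, (seq_len(.n_iso) - 1L) * .iso_spacing, `+`))
}

#' Generate a synthetic imaging dataset with ground truth
#'
#' Produces the feature list, the per-pixel MS1 frames and a ground-truth
#' table labelling every frame point with the species it originates from
#' (`role` one of `"mono"`, `"isotope"`, `"interference"`, `"background"`;
#' `feature_id` is the host feature for the first three and `NA` for
#' background). Per-pixel feature intensities follow a Gaussian blob
#' truncated below the noise floor; feature `area` and `max_intensity` are
#' exactly consistent with the emitted monoisotopic frame points.
#'
#' @param spec A [synthetic_spec()].
#' @return Object of class `simsef_dataset`: a list with `features`
#'   ([ion_features()]), `frames` ([ms1_frames()]), `truth` (data frame) and
#'   `spec`.
#' @export
generate_dataset <- function(spec) {
  if (!inherits(spec, "synthetic_spec")) stop("spec must be a synthetic_spec")
  with_seed(spec$seed, generate_dataset_impl(spec))
}

generate_dataset_impl <- function(spec) {
  g <- spec$geometry
  n <- spec$n_features

  # feature-level draws --------------------------------------------------
  mzs <- numeric(0)
  for (i in seq_len(n)) {
    repeat {
      cand <- stats::runif(1, spec$mz_range[1], spec$mz_range[2])
      if (!length(mzs) || min(abs(mzs - cand)) >= spec$min_mz_separation_da)
        break
    }
    mzs <- c(mzs, cand)
  }
  cx <- if (n) sample.int(g$n_cols, n, replace = TRUE) - 1L else integer(0)
  cy <- if (n) sample.int(g$n_rows, n, replace = TRUE) - 1L else integer(0)
  sigma <- stats::runif(n, spec$sigma_px_range[1], spec$sigma_px_range[2])
  peak <- 10^stats::runif(n, log10(spec$peak_intensity_range[1]),
                          log10(spec$peak_intensity_range[2]))
  width <- stats::runif(n, spec$mobility_window_width_range[1],
                        spec$mobility_window_width_range[2])
  # apex affine in m/z plus noise, clamped so the window fits the ramp range
  span <- g$mobility_max - g$mobility_min
  apex <- g$mobility_min + 0.1 * span +
    (mzs - spec$mz_range[1]) / diff(spec$mz_range) * 0.8 * span +
    stats::rnorm(n, 0, spec$mobility_jitter)
  apex <- pmin(pmax(apex, g$mobility_min + width / 2),
               g$mobility_max - width / 2)
  has_partner <- stats::runif(n) < spec$interference_fraction

  all_iso <- iso_positions(mzs)

  grid_x <- rep(0:(g$n_cols - 1L), times = g$n_rows)
  grid_y <- rep(0:(g$n_rows - 1L), each = g$n_cols)

  blob <- function(cx0, cy0, sig, pk) {
    if (sig <= 0) {
      keep <- grid_x == cx0 & grid_y == cy0
      inten <- rep(pk, sum(keep))
    } else {
      d2 <- (grid_x - cx0)^2 + (grid_y - cy0)^2
      inten <- pk * exp(-d2 / (2 * sig^2))
      keep <- inten > spec$noise_floor
      inten <- inten[keep]
    }
    data.frame(x = grid_x[keep], y = grid_y[keep], intensity = inten)
  }

  feat_rows <- vector("list", n)
  truth_rows <- list()
  ti <- 0L
  add_truth <- function(df) {
    ti <<- ti + 1L
    truth_rows[[ti]] <<- df
  }

  for (i in seq_len(n)) {
    px <- blob(cx[i], cy[i], sigma[i], peak[i])
    if (!nrow(px)) { # blob entirely below noise floor: keep centre pixel
      px <- data.frame(x = cx[i], y = cy[i], intensity = peak[i])
    }
    feat_rows[[i]] <- data.frame(feature_id = i, x = px$x, y = px$y,
                                 intensity = px$intensity)
    npx <- nrow(px)
    lo <- apex[i] - width[i] / 2
    hi <- apex[i] + width[i] / 2
    add_truth(data.frame(
      feature_id = i, role = "mono", x = px$x, y = px$y,
      mz = mzs[i] + stats::runif(npx, -spec$mz_jitter_da, spec$mz_jitter_da),
      mobility = stats::runif(npx, lo, hi),
      intensity = px$intensity
    ))
    iso_ratio <- min(0.6, 0.01 + 5e-4 * mzs[i])
    iso_int <- px$intensity * iso_ratio
    keep <- iso_int > spec$noise_floor
    if (any(keep)) {
      m <- sum(keep)
      add_truth(data.frame(
        feature_id = i, role = "isotope", x = px$x[keep], y = px$y[keep],
        mz = mzs[i] + .iso_spacing +
          stats::runif(m, -spec$mz_jitter_da, spec$mz_jitter_da),
        mobility = stats::runif(m, lo, hi),
        intensity = iso_int[keep]
      ))
    }
    if (has_partner[i]) {
      # partner m/z offset must avoid every feature's isotope positions
      repeat {
        delta <- sample(c(-1, 1), 1) *
          stats::runif(1, spec$interference_delta_da[1],
                       spec$interference_delta_da[2])
        pmz <- mzs[i] + delta
        if (min(abs(all_iso - pmz)) > .iso_guard) break
      }
      pcx <- min(max(cx[i] + sample(-2:2, 1), 0L), g$n_cols - 1L)
      pcy <- min(max(cy[i] + sample(-2:2, 1), 0L), g$n_rows - 1L)
      psig <- sigma[i] * stats::runif(1, 0.8, 1.2)
      ppk <- peak[i] * stats::runif(1, spec$interference_rel_intensity[1],
                                    spec$interference_rel_intensity[2])
      papex <- min(max(apex[i] + stats::runif(1, -0.01, 0.01),
                       g$mobility_min + width[i] / 2),
                   g$mobility_max - width[i] / 2)
      ppx <- blob(pcx, pcy, psig, ppk)
      if (nrow(ppx)) {
        m <- nrow(ppx)
        add_truth(data.frame(
          feature_id = i, role = "interference", x = ppx$x, y = ppx$y,
          mz = pmz + stats::runif(m, -spec$mz_jitter_da, spec$mz_jitter_da),
          mobility = stats::runif(m, papex - width[i] / 2,
                                  papex + width[i] / 2),
          intensity = ppx$intensity
        ))
      }
    }
  }

  # uniform background below the noise floor, away from isotope positions
  nbg <- spec$background_points_per_pixel * g$n_cols * g$n_rows
  if (nbg > 0) {
    bx <- rep(grid_x, each = spec$background_points_per_pixel)
    by <- rep(grid_y, each = spec$background_points_per_pixel)
    bmz <- stats::runif(nbg, spec$mz_range[1], spec$mz_range[2])
    if (length(all_iso)) {
      repeat {
        bad <- vapply(bmz, function(m) min(abs(all_iso - m)) <= 3 * 0.01,
                      logical(1))
        if (!any(bad)) break
        bmz[bad] <- stats::runif(sum(bad), spec$mz_range[1], spec$mz_range[2])
      }
    }
    add_truth(data.frame(
      feature_id = NA_integer_, role = "background", x = bx, y = by,
      mz = bmz,
      mobility = stats::runif(nbg, g$mobility_min, g$mobility_max),
      intensity = stats::runif(nbg, spec$noise_floor * 0.01,
                               spec$noise_floor * 0.999)
    ))
  }

  truth <- if (ti) do.call(rbind, truth_rows[seq_len(ti)]) else
    data.frame(feature_id = integer(0), role = character(0), x = integer(0),
               y = integer(0), mz = numeric(0), mobility = numeric(0),
               intensity = numeric(0))
  rownames(truth) <- NULL

  table <- data.frame(
    feature_id = seq_len(n), mz = mzs, mobility_apex = apex,
    mobility_low = apex - width / 2, mobility_high = apex + width / 2
  )
  intens <- if (n) do.call(rbind, feat_rows) else
    data.frame(feature_id = integer(0), x = integer(0), y = integer(0),
               intensity = numeric(0))
  features <- ion_features(table, intens, g)
  frames <- ms1_frames(truth[, c("x", "y", "mz", "mobility", "intensity")], g)
  structure(list(features = features, frames = frames, truth = truth,
                 spec = spec),
            class = "simsef_dataset")
}

#' @export
print.simsef_dataset <- function(x, ...) {
  cat(sprintf("simsef_dataset: %d features, %d frame points, seed %d\n",
              nrow(x$features$table), nrow(x$frames$points), x$spec$seed))
  invisible(x)
}

#' Ground-truth isolation purity from point labels
#'
#' Computes the purity of a feature's isolation window at one pixel directly
#' from the generator's ground-truth point labels, independently of the m/z
#' position logic in [purity_score()]: all truth points falling inside the
#' isolation m/z window and the feature's mobility window form the isolated
#' population, and the pure part is the intensity of points labelled with
#' that feature as `"mono"` or `"isotope"`. An empty isolation region gives
#' 0.
#'
#' @param dataset A [generate_dataset()] result.
#' @param feature_id Feature whose window is queried.
#' @param x,y Pixel coordinates.
#' @param isolation_width_da Quadrupole isolation width in Da (default 1.7).
#' @return Purity in `[0, 1]`.
#' @export
purity_from_truth <- function(dataset, feature_id, x, y,
                              isolation_width_da = 1.7) {
  ft <- dataset$features$table
  row <- ft[ft$feature_id == feature_id, ]
  if (!nrow(row)) stop("unknown feature_id")
  tr <- dataset$truth
  tr <- tr[tr$x == x & tr$y == y, , drop = FALSE]
  half <- isolation_width_da / 2
  in_s <- tr$mz >= row$mz - half & tr$mz <= row$mz + half &
    tr$mobility >= row$mobility_low & tr$mobility <= row$mobility_high
  tot <- sum(tr$intensity[in_s])
  if (!is.finite(tot) || tot <= 0) return(0)
  pure <- in_s & !is.na(tr$feature_id) & tr$feature_id == feature_id &
    tr$role %in% c("mono", "isotope")
  sum(tr$intensity[pure]) / tot
}

#' Simulate MS2 acquisition of a schedule
#'
#' Emits one scan per scheduled event. Each feature has a fixed fragment
#' template (a deterministic function of its feature id): a set of fragment
#' m/z values with per-fragment base intensities and optimal collision
#' energies. The intensity vector of a scan is the template weighted by a
#' Gaussian response in collision energy and scaled to the feature's MS1
#' intensity in that pixel, so the same feature fragmented at two energies
#' yields identical fragment m/z sets with different intensity vectors.
#'
#' @param schedule A [simsef_schedule()] result.
#' @param dataset The [generate_dataset()] dataset the schedule was built on
#'   (used for per-pixel precursor intensities).
#' @param intensity_noise Standard deviation of multiplicative log-normal
#'   intensity noise; 0 (default) gives noiseless template scans.
#' @param seed Seed for the noise draws (ignored when `intensity_noise` is
#'   0).
#' @return List of [ms2_scan()] objects, class `ms2_scans`, carrying the
#'   ground-truth `feature_id` of each scan.
#' @export
generate_ms2 <- function(schedule, dataset, intensity_noise = 0, seed = 1L) {
  ev <- schedule$events
  scans <- vector("list", nrow(ev))
  if (!nrow(ev)) return(structure(scans, class = "ms2_scans"))
  ints <- dataset$features$intensities
  run <- function() {
    for (i in seq_len(nrow(ev))) {
      e <- ev[i, ]
      tpl <- fragment_template(e$feature_id, e$isolation_mz)
      w <- tpl$base * exp(-(e$collision_energy - tpl$opt_ce)^2 / (2 * 18^2))
      sel <- ints$feature_id == e$feature_id & ints$x == e$x & ints$y == e$y
      scale <- if (any(sel)) ints$intensity[sel][1] else 5000
      inten <- w / max(w) * scale
      if (intensity_noise > 0) {
        inten <- inten * exp(stats::rnorm(length(inten), 0, intensity_noise))
      }
      scans[[i]] <<- ms2_scan(
        spot_name = e$spot_name, precursor_mz = e$isolation_mz,
        mobility_low = e$mobility_low, mobility_high = e$mobility_high,
        collision_energy = e$collision_energy,
        mz = tpl$mz, intensity = inten,
        feature_id = e$feature_id
      )
    }
  }
  if (intensity_noise > 0) with_seed(seed, run()) else run()
  structure(scans, class = "ms2_scans")
}

# deterministic per-feature fragment template
fragment_template <- function(feature_id, precursor_mz) {
  seed <- as.integer((as.numeric(feature_id) * 48271 + 7) %% 2147483647)
  with_seed(seed, {
    nf <- sample(6:12, 1)
    list(
      mz = sort(stats::runif(nf, 50, max(60, precursor_mz - 10))),
      base = stats::runif(nf, 0.05, 1),
      opt_ce = stats::runif(nf, 15, 75)
    )
  })
}
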