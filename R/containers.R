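#' Mobility-resolved ion image features
#'
#' Container for a feature list produced by mobility-resolved imaging feature
#' detection: one row per feature with its m/z, mobility apex and mobility
#' window, plus a long-format table of per-pixel intensities. `area` (sum of
#' all pixel intensities) and `max_intensity` are recomputed from the
#' intensity table; if the supplied feature table carries its own `area`
#' column that disagrees by more than 1e-6 relative, a warning is emitted and
#' the recomputed value is kept.
#'
#' @param table Data frame with columns `feature_id`, `mz`, `mobility_apex`,
#'   `mobility_low`, `mobility_high` (one row per feature).
#' @param intensities Data frame with columns `feature_id`, `x`, `y`,
#'   `intensity` (one row per feature/pixel pair, intensities > 0).
#' @param geometry A [raster_geometry()].
#' @return Object of class `ion_features` with elements `table` (including
#'   recomputed `area` and `max_intensity`), `intensities` and `geometry`.
#' @export
ion_features <- function(table, intensities, geometry) {
  need_t <- c("feature_id", "mz", "mobility_apex", "mobility_low",
              "mobility_high")
  need_i <- c("feature_id", "x", "y", "intensity")
  miss <- setdiff(need_t, names(table))
  if (length(miss)) stop("feature table missing column(s): ",
                         paste(miss, collapse = ", "))
  miss <- setdiff(need_i, names(intensities))
  if (length(miss)) stop("intensity table missing column(s): ",
                         paste(miss, collapse = ", "))
  if (any(duplicated(table$feature_id))) stop("duplicated feature_id")
  if (nrow(intensities) &&
      !all(intensities$feature_id %in% table$feature_id)) {
    stop("intensity rows for unknown feature_id")
  }
  if (any(intensities$x < 0) || any(intensities$x >= geometry$n_cols) ||
      any(intensities$y < 0) || any(intensities$y >= geometry$n_rows)) {
    stop("pixel indices outside the raster geometry")
  }
  bad <- table$mobility_low >= table$mobility_high |
    table$mobility_low < geometry$mobility_min |
    table$mobility_high > geometry$mobility_max |
    table$mobility_apex < table$mobility_low |
    table$mobility_apex > table$mobility_high
  if (any(bad)) stop("invalid mobility window/apex for feature_id ",
                     paste(table$feature_id[bad], collapse = ", "))
  area <- numeric(nrow(table))
  maxi <- numeric(nrow(table))
  if (nrow(intensities)) {
    sums <- tapply(intensities$intensity, intensities$feature_id, sum)
    maxs <- tapply(intensities$intensity, intensities$feature_id, max)
    idx <- match(as.character(table$feature_id), names(sums))
    area <- ifelse(is.na(idx), 0, as.numeric(sums[idx]))
    maxi <- ifelse(is.na(idx), 0, as.numeric(maxs[idx]))
  }
  if (!is.null(table$area)) {
    rel <- abs(table$area - area) / pmax(abs(area), 1e-300)
    off <- which(is.finite(rel) & rel > 1e-6 & area > 0)
    if (length(off)) {
      warning("stored area disagrees with per-pixel intensities for ",
              "feature_id ", paste(table$feature_id[off], collapse = ", "),
              "; recomputed value kept")
    }
  }
  table <- table[, need_t]
  table$area <- area
  table$max_intensity <- maxi
  rownames(table) <- NULL
  intensities <- intensities[, need_i]
  rownames(intensities) <- NULL
  structure(list(table = table, intensities = intensities,
                 geometry = geometry),
            class = "ion_features")
}

#' @export
print.ion_features <- function(x, ...) {
  cat(sprintf("ion_features: %d features over %d pixel intensities (%d x %d raster)\n",
              nrow(x$table), nrow(x$intensities),
              x$geometry$n_cols, x$geometry$n_rows))
  invisible(x)
}

#' Per-pixel TIMS-MS1 frame point clouds
#'
#' One TIMS-MS1 frame is acquired per pixel; its content is a point cloud of
#' (m/z, 1/K0, intensity) triples. All frames of a run are stored as one long
#' table; use [frame_points()] to extract one pixel's cloud.
#'
#' @param points Data frame with columns `x`, `y`, `mz`, `mobility`,
#'   `intensity`; intensities must be > 0 and mobilities within the geometry
#'   range.
#' @param geometry A [raster_geometry()].
#' @return Object of class `ms1_frames`.
#' @export
ms1_frames <- function(points, geometry) {
  need <- c("x", "y", "mz", "mobility", "intensity")
  miss <- setdiff(need, names(points))
  if (length(miss)) stop("frame table missing column(s): ",
                         paste(miss, collapse = ", "))
  if (nrow(points)) {
    if (any(points$intensity <= 0)) stop("frame intensities must be > 0")
    if (any(points$mobility < geometry$mobility_min) ||
        any(points$mobility > geometry$mobility_max)) {
      stop("frame mobilities outside the geometry 1/K0 range")
    }
    if (any(points$x < 0) || any(points$x >= geometry$n_cols) ||
        any(points$y < 0) || any(points$y >= geometry$n_rows)) {
      stop("frame pixel indices outside the raster geometry")
    }
  }
  points <- points[, need]
  rownames(points) <- NULL
  structure(list(points = points, geometry = geometry),
            class = "ms1_frames")
}

#' @export
print.ms1_frames <- function(x, ...) {
  cat(sprintf("ms1_frames: %d points on a %d x %d raster\n",
              nrow(x$points), x$geometry$n_cols, x$geometry$n_rows))
  invisible(x)
}

#' @param frames An [ms1_frames()] object.
#' @param x,y Pixel coordinates (0-based).
#' @rdname ms1_frames
#' @return `frame_points()`: the subset of `points` at that pixel.
#' @export
frame_points <- function(frames, x, y) {
  p <- frames$points
  p[p$x == x & p$y == y, , drop = FALSE]
}

# split frame point row indices by pixel id; returns list keyed by pixel id
split_frame_index <- function(frames) {
  p <- frames$points
  if (!nrow(p)) return(list())
  split(seq_len(nrow(p)), pixel_id(p$x, p$y, frames$geometry))
}

#' Construct an MS2 scan
#'
#' A single acquired fragmentation spectrum with its acquisition metadata:
#' the spot (pixel) name, precursor isolation m/z, mobility extraction
#' window and collision energy. Peaks are stored sorted by ascending m/z.
#'
#' @param spot_name Spot name of the pixel the scan was acquired in.
#' @param precursor_mz Precursor isolation m/z in Da.
#' @param mobility_low,mobility_high Mobility extraction window (1/K0).
#' @param collision_energy Collision energy in eV.
#' @param mz,intensity Numeric vectors of equal length; intensities > 0.
#' @param feature_id Optional ground-truth feature id (synthetic data).
#' @return Object of class `ms2_scan` with a `peaks` data frame.
#' @export
ms2_scan <- function(spot_name, precursor_mz, mobility_low, mobility_high,
                     collision_energy, mz, intensity, feature_id = NA_integer_) {
  if (length(mz) != length(intensity)) stop("mz/intensity length mismatch")
  if (any(intensity <= 0)) stop("peak intensities must be > 0")
  o <- order(mz)
  structure(
    list(spot_name = spot_name, precursor_mz = precursor_mz,
         mobility_low = mobility_low, mobility_high = mobility_high,
         collision_energy = collision_energy,
         feature_id = feature_id,
         peaks = data.frame(mz = mz[o], intensity = intensity[o])),
    class = "ms2_scan"
  )
}

#' @export
print.ms2_scan <- function(x, ...) {
  cat(sprintf("ms2_scan: spot %s, precursor m/z %.4f, CE %g eV, %d peaks\n",
              x$spot_name, x$precursor_mz, x$collision_energy,
              nrow(x$peaks)))
  invisible(x)
}
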