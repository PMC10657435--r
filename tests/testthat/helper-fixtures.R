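# Small builders used across the test files.

# features object with a single feature whose pixel intensities are given
# as a data.frame(x, y, intensity)
one_feature <- function(px, mz = 400, apex = 1.2, width = 0.03,
                        geometry = raster_geometry(10, 10)) {
  ion_features(
    data.frame(feature_id = 1L, mz = mz, mobility_apex = apex,
               mobility_low = apex - width / 2,
               mobility_high = apex + width / 2),
    data.frame(feature_id = 1L, x = px$x, y = px$y,
               intensity = px$intensity),
    geometry)
}

# frames with a pure precursor point at every pixel of a feature, so any
# purity threshold passes
pure_frames <- function(features) {
  ft <- features$table
  ints <- features$intensities
  idx <- match(ints$feature_id, ft$feature_id)
  ms1_frames(
    data.frame(x = ints$x, y = ints$y, mz = ft$mz[idx],
               mobility = ft$mobility_apex[idx],
               intensity = ints$intensity),
    features$geometry)
}

empty_frames <- function(geometry) {
  ms1_frames(data.frame(x = integer(0), y = integer(0), mz = numeric(0),
                        mobility = numeric(0), intensity = numeric(0)),
             geometry)
}

# permissive parameters: every filter effectively disabled except what the
# caller overrides
loose_params <- function(...) {
  defaults <- list(n_spectra_per_ce = 1, collision_energies = 30,
                   min_distance_px = 0, min_pixel_intensity_abs = 0,
                   min_pixel_intensity_rel = 0, min_purity = 0,
                   quad_switch_time_ms = 0, eligibility_min_intensity = 0)
  args <- utils::modifyList(defaults, list(...))
  do.call(schedule_parameters, args)
}

# uniform-intensity blob covering the full raster
uniform_pixels <- function(geometry, intensity = 1e4) {
  expand.grid(x = 0:(geometry$n_cols - 1), y = 0:(geometry$n_rows - 1),
              intensity = intensity)
}

# deterministic toy scan
toy_scan <- function(mz, intensity, spot = "X000Y000", pmz = 400, ce = 30,
                     lo = 1.19, hi = 1.22, fid = NA_integer_) {
  ms2_scan(spot, pmz, lo, hi, ce, mz, intensity, feature_id = fid)
}

read_bytes <- function(path) readBin(path, "raw", file.size(path))

folder_bytes <- function(root) {
  files <- sort(list.files(root, recursive = TRUE))
  lapply(stats::setNames(file.path(root, files), files), read_bytes)
}
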