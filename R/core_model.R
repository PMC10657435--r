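#' Raster geometry of a TIMS-MS imaging run
#'
#' Describes the rectangular acquisition raster and the trapped ion mobility
#' (TIMS) ramp of an imaging experiment: the number of pixel columns and rows,
#' the raster pitch, the reduced-mobility (1/K0) range scanned by the ramp and
#' the ramp duration. Pixel coordinates everywhere in this package are 0-based
#' with `x` the column and `y` the row index.
#'
#' @param n_cols,n_rows Number of pixel columns / rows (>= 1).
#' @param pitch_um Raster pitch in micrometres (default 50).
#' @param mobility_min,mobility_max Reduced ion mobility range 1/K0 in
#'   Vs/cm^2 covered by the TIMS ramp (defaults 0.65 and 1.75).
#' @param ramp_time_ms TIMS ramp duration in milliseconds (default 150).
#'
#' @return An object of class `raster_geometry`.
#' @examples
#' g <- raster_geometry(128, 96)
#' g$n_cols * g$n_rows # number of pixels
#' @export
raster_geometry <- function(n_cols, n_rows, pitch_um = 50,
                            mobility_min = 0.65, mobility_max = 1.75,
                            ramp_time_ms = 150) {
  n_cols <- as.integer(n_cols)
  n_rows <- as.integer(n_rows)
  if (is.na(n_cols) || n_cols < 1L) stop("n_cols must be >= 1")
  if (is.na(n_rows) || n_rows < 1L) stop("n_rows must be >= 1")
  if (!is.finite(pitch_um) || pitch_um <= 0) stop("pitch_um must be > 0")
  if (!is.finite(mobility_min) || !is.finite(mobility_max) ||
      mobility_min >= mobility_max) {
    stop("mobility_min must be smaller than mobility_max")
  }
  if (!is.finite(ramp_time_ms) || ramp_time_ms <= 0) {
    stop("ramp_time_ms must be > 0")
  }
  structure(
    list(n_cols = n_cols, n_rows = n_rows, pitch_um = pitch_um,
         mobility_min = mobility_min, mobility_max = mobility_max,
         ramp_time_ms = ramp_time_ms),
    class = "raster_geometry"
  )
}

#' @export
print.raster_geometry <- function(x, ...) {
  cat(sprintf("raster_geometry: %d x %d px, pitch %g um, 1/K0 %g-%g Vs/cm2, ramp %g ms\n",
              x$n_cols, x$n_rows, x$pitch_um,
              x$mobility_min, x$mobility_max, x$ramp_time_ms))
  invisible(x)
}

same_geometry <- function(a, b) {
  isTRUE(all.equal(unclass(a), unclass(b)))
}

#' Canonical spot names for raster pixels
#'
#' Imaging acquisitions address each pixel by a textual spot name. The
#' canonical format used here is `"XnnnYnnn"` with zero-padded 0-based column
#' (`x`) and row (`y`) indices, e.g. `"X012Y034"`. Indices above 999 widen the
#' field as needed. `parse_spot_name()` inverts the mapping; alternative
#' vendor naming patterns can be accepted by supplying a custom regular
#' expression with two capture groups (x, then y).
#'
#' @param x,y Integer pixel column / row indices (0-based), vectorised.
#' @return `spot_name()`: character vector. `parse_spot_name()`: a data frame
#'   with integer columns `x` and `y`.
#' @examples
#' spot_name(12, 34)
#' parse_spot_name("X012Y034")
#' @export
spot_name <- function(x, y) {
  if (any(x < 0) || any(y < 0)) stop("pixel indices must be >= 0")
  if (any(x != floor(x)) || any(y != floor(y))) {
    stop("pixel indices must be integers")
  }
  sprintf("X%03dY%03d", as.integer(x), as.integer(y))
}

#' @param s Character vector of spot names.
#' @param pattern Regular expression with two integer capture groups
#'   (column index, then row index).
#' @rdname spot_name
#' @export
parse_spot_name <- function(s, pattern = "^X([0-9]+)Y([0-9]+)$") {
  m <- regmatches(s, regexec(pattern, s))
  bad <- vapply(m, length, 1L) != 3L
  if (any(bad)) {
    stop("malformed spot name(s): ", paste(s[bad], collapse = ", "))
  }
  data.frame(
    x = vapply(m, function(g) as.integer(g[2]), 1L),
    y = vapply(m, function(g) as.integer(g[3]), 1L)
  )
}

#' Euclidean distance between raster pixels
#'
#' Distance in pixel index units (not micrometres); spatial scheduling
#' thresholds such as the minimum distance between replicate MS2 events are
#' stated in pixels.
#'
#' @param x1,y1,x2,y2 Pixel coordinates, vectorised.
#' @return Numeric distance(s) in pixel units.
#' @examples
#' pixel_distance(0, 0, 3, 4) # 5
#' @export
pixel_distance <- function(x1, y1, x2, y2) {
  sqrt((x1 - x2)^2 + (y1 - y2)^2)
}

#' Map reduced mobility to elution time within the TIMS ramp
#'
#' The TIMS ramp releases trapped ions ordered by mobility, scanning from
#' high to low 1/K0. The mapping is linearised: an ion at `mobility_max`
#' elutes at 0 ms and an ion at `mobility_min` at `ramp_time_ms`. This lets
#' the quadrupole switch-time constraint be expressed as a minimum gap in
#' mobility space, see [min_mobility_gap()].
#'
#' @param m Reduced mobility 1/K0 in Vs/cm^2, vectorised.
#' @param geometry A [raster_geometry()].
#' @return Elution time(s) in ms within the ramp.
#' @examples
#' g <- raster_geometry(10, 10)
#' mobility_to_ramp_time(1.20, g) # 75 ms with the default ramp
#' @export
mobility_to_ramp_time <- function(m, geometry) {
  if (any(m < geometry$mobility_min) || any(m > geometry$mobility_max)) {
    stop("mobility outside the geometry 1/K0 range")
  }
  geometry$ramp_time_ms * (geometry$mobility_max - m) /
    (geometry$mobility_max - geometry$mobility_min)
}

#' Minimum mobility gap implied by the quadrupole switch time
#'
#' Between two consecutive precursor isolations in one ramp the quadrupole
#' needs `switch_time_ms` to move to the next isolation m/z. Under the linear
#' ramp mapping this corresponds to a minimum 1/K0 gap between the lower edge
#' of the earlier (higher-mobility) window and the upper edge of the later
#' one.
#'
#' @param switch_time_ms Quadrupole switch time in ms (>= 0).
#' @inheritParams mobility_to_ramp_time
#' @return Minimum gap in Vs/cm^2.
#' @examples
#' min_mobility_gap(1.65, raster_geometry(10, 10)) # 0.0121
#' @export
min_mobility_gap <- function(switch_time_ms, geometry) {
  if (switch_time_ms < 0) stop("switch_time_ms must be >= 0")
  switch_time_ms * (geometry$mobility_max - geometry$mobility_min) /
    geometry$ramp_time_ms
}

#' Read and write raster geometry config files
#'
#' Plain-text `key=value` serialisation of a [raster_geometry()] with keys
#' `n_cols`, `n_rows`, `pitch_um`, `mobility_min`, `mobility_max`,
#' `ramp_time_ms`. Numeric values are written with six decimals so a
#' write/read/write cycle is byte-identical.
#'
#' @param geometry A [raster_geometry()].
#' @param path File path.
#' @return `read_geometry()` returns a [raster_geometry()];
#'   `write_geometry()` returns `path` invisibly.
#' @export
write_geometry <- function(geometry, path) {
  lines <- c(
    sprintf("n_cols=%d", geometry$n_cols),
    sprintf("n_rows=%d", geometry$n_rows),
    sprintf("pitch_um=%.6f", geometry$pitch_um),
    sprintf("mobility_min=%.6f", geometry$mobility_min),
    sprintf("mobility_max=%.6f", geometry$mobility_max),
    sprintf("ramp_time_ms=%.6f", geometry$ramp_time_ms)
  )
  write_lines_lf(lines, path)
  invisible(path)
}

#' @rdname write_geometry
#' @export
read_geometry <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  kv <- strsplit(lines, "=", fixed = TRUE)
  keys <- vapply(kv, `[`, "", 1L)
  vals <- vapply(kv, `[`, "", 2L)
  need <- c("n_cols", "n_rows", "pitch_um", "mobility_min", "mobility_max",
            "ramp_time_ms")
  miss <- setdiff(need, keys)
  if (length(miss)) stop("geometry file missing key(s): ",
                         paste(miss, collapse = ", "))
  v <- as.numeric(vals[match(need, keys)])
  raster_geometry(v[1], v[2], pitch_um = v[3], mobility_min = v[4],
                  mobility_max = v[5], ramp_time_ms = v[6])
}

# write text with LF endings regardless of platform
write_lines_lf <- function(lines, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con = con, sep = "\n")
}

# linear pixel id, row-major, 1-based
pixel_id <- function(x, y, geometry) {
  as.integer(y) * geometry$n_cols + as.integer(x) + 1L
}

# run expr with a temporary RNG seed, restoring global state afterwards
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
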