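#' Write a schedule folder
#'
#' Serialises a schedule to the on-disk layout handed to the acquisition
#' side: a master `schedule.csv` (columns `spot_name`, `x`, `y`,
#' `n_precursors`, `file`, one row per MS2 pixel in row-major order), one
#' precursor list `spots/<spot_name>.csv` per MS2 pixel (columns
#' `feature_id`, `isolation_mz`, `isolation_width_da`, `mobility_low`,
#' `mobility_high`, `collision_energy_ev`, `purity`; rows in ramp order,
#' i.e. descending `mobility_high`), the collision energy list
#' `energies.csv`, the parameter dump `params.yaml` and the raster geometry
#' `geometry.txt`. Numeric formatting is fixed (6 decimals for m/z and
#' mobility window edges, 3 for purity, 1 for collision energy) so output
#' is byte-stable: writing, re-reading and re-writing a folder reproduces
#' it byte for byte. Six decimals on the window edges also make the CSV
#' pipeline lossless: windows derived from 4-decimal feature mobilities
#' have at most 5 decimal places, so a folder read back carries exactly
#' the scheduled windows and [validate_schedule()] reproduces the purity
#' scores bit for bit.
#'
#' @param schedule A [simsef_schedule()] result.
#' @param root Folder to create/populate.
#' @return `root`, invisibly.
#' @export
write_schedule <- function(schedule, root) {
  ev <- schedule$events
  dir.create(root, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(root, "spots"), showWarnings = FALSE)
  g <- schedule$geometry

  master <- "spot_name,x,y,n_precursors,file"
  if (nrow(ev)) {
    # canonical order: spots row-major, entries per spot in ramp order
    ev <- ev[order(ev$y, ev$x, -ev$mobility_high, ev$feature_id,
                   ev$collision_energy), , drop = FALSE]
    spots <- unique(ev[, c("spot_name", "x", "y")])
    for (i in seq_len(nrow(spots))) {
      s <- spots[i, ]
      sub <- ev[ev$spot_name == s$spot_name, , drop = FALSE]
      rows <- sprintf("%d,%.6f,%.6f,%.6f,%.6f,%.1f,%.3f",
                      sub$feature_id, sub$isolation_mz,
                      sub$isolation_width_da, sub$mobility_low,
                      sub$mobility_high, sub$collision_energy, sub$purity)
      write_lines_lf(
        c("feature_id,isolation_mz,isolation_width_da,mobility_low,mobility_high,collision_energy_ev,purity",
          rows),
        file.path(root, "spots", paste0(s$spot_name, ".csv")))
      master <- c(master,
                  sprintf("%s,%d,%d,%d,spots/%s.csv", s$spot_name, s$x, s$y,
                          nrow(sub), s$spot_name))
    }
  }
  write_lines_lf(master, file.path(root, "schedule.csv"))
  write_lines_lf(
    c("collision_energy_ev",
      sprintf("%.1f", schedule$params$collision_energies)),
    file.path(root, "energies.csv"))
  yaml_lf(unclass(schedule$params), file.path(root, "params.yaml"))
  write_geometry(g, file.path(root, "geometry.txt"))
  invisible(root)
}

# yaml::as.yaml with LF line endings
yaml_lf <- function(x, path) {
  write_lines_lf(strsplit(yaml::as.yaml(x), "\n", fixed = TRUE)[[1]], path)
}

#' Read a schedule folder
#'
#' Inverse of [write_schedule()]; reconstructs a `simsef_schedule` from the
#' folder. Each spot listed in the master file must have exactly one spot
#' file with a matching row count.
#'
#' @param root Folder written by [write_schedule()].
#' @return A `simsef_schedule` (without a `feature_summary`).
#' @export
read_schedule <- function(root) {
  master <- utils::read.csv(file.path(root, "schedule.csv"),
                            colClasses = c("character", "integer", "integer",
                                           "integer", "character"))
  params <- do.call(schedule_parameters,
                    yaml::read_yaml(file.path(root, "params.yaml")))
  g <- read_geometry(file.path(root, "geometry.txt"))
  ev <- empty_events()
  if (nrow(master)) {
    parts <- vector("list", nrow(master))
    for (i in seq_len(nrow(master))) {
      s <- master[i, ]
      sub <- utils::read.csv(file.path(root, s$file))
      if (nrow(sub) != s$n_precursors) {
        stop("spot file ", s$file, " has ", nrow(sub),
             " rows but master lists ", s$n_precursors)
      }
      parts[[i]] <- data.frame(
        feature_id = sub$feature_id, x = s$x, y = s$y,
        spot_name = s$spot_name,
        collision_energy = sub$collision_energy_ev,
        isolation_mz = sub$isolation_mz,
        isolation_width_da = sub$isolation_width_da,
        mobility_low = sub$mobility_low, mobility_high = sub$mobility_high,
        purity = sub$purity)
    }
    ev <- do.call(rbind, parts)
    rownames(ev) <- NULL
  }
  structure(list(events = ev, feature_summary = NULL, params = params,
                 geometry = g),
            class = "simsef_schedule")
}

#' Read and write imaging feature lists
#'
#' The interchange format for mobility-resolved imaging feature lists is a
#' single long-format CSV with one row per (feature, pixel) pair and columns
#' `feature_id`, `mz`, `mobility_apex`, `mobility_low`, `mobility_high`,
#' `x`, `y`, `intensity` and optionally `area`. Feature-level values are
#' repeated on every pixel row. On reading, `area` and `max_intensity` are
#' recomputed from the pixel rows; a stored `area` column, if present, is
#' cross-checked and a deviation beyond 1e-6 relative triggers a warning
#' (see [ion_features()]). `write_features()` omits the derived `area`
#' column so that a write/read/write cycle is byte-identical.
#'
#' @param features An [ion_features()] object.
#' @param path CSV file path.
#' @return `read_features()` returns an [ion_features()];
#'   `write_features()` returns `path` invisibly.
#' @export
write_features <- function(features, path) {
  ft <- features$table
  ints <- features$intensities
  idx <- match(ints$feature_id, ft$feature_id)
  rows <- sprintf("%d,%.6f,%.4f,%.4f,%.4f,%d,%d,%.4f",
                  ints$feature_id, ft$mz[idx], ft$mobility_apex[idx],
                  ft$mobility_low[idx], ft$mobility_high[idx],
                  ints$x, ints$y, ints$intensity)
  write_lines_lf(
    c("feature_id,mz,mobility_apex,mobility_low,mobility_high,x,y,intensity",
      rows), path)
  invisible(path)
}

#' @param geometry A [raster_geometry()] for the run the file belongs to.
#' @rdname write_features
#' @export
read_features <- function(path, geometry) {
  df <- utils::read.csv(path)
  need <- c("feature_id", "mz", "mobility_apex", "mobility_low",
            "mobility_high", "x", "y", "intensity")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("feature file missing column(s): ",
                         paste(miss, collapse = ", "))
  first <- !duplicated(df$feature_id)
  table <- df[first, c("feature_id", "mz", "mobility_apex", "mobility_low",
                       "mobility_high"), drop = FALSE]
  if (!is.null(df$area)) table$area <- df$area[first]
  ion_features(table, df[, c("feature_id", "x", "y", "intensity")], geometry)
}

#' Read and write MS1 frame point clouds
#'
#' CSV interchange for per-pixel frame point clouds, columns `x`, `y`,
#' `mz`, `mobility`, `intensity` (m/z with 6 decimals, mobility 4,
#' intensity 4).
#'
#' @param frames An [ms1_frames()] object.
#' @param path CSV file path.
#' @param geometry A [raster_geometry()].
#' @return `read_frames()` returns an [ms1_frames()]; `write_frames()`
#'   returns `path` invisibly.
#' @export
write_frames <- function(frames, path) {
  p <- frames$points
  write_lines_lf(
    c("x,y,mz,mobility,intensity",
      sprintf("%d,%d,%.6f,%.4f,%.4f", p$x, p$y, p$mz, p$mobility,
              p$intensity)), path)
  invisible(path)
}

#' @rdname write_frames
#' @export
read_frames <- function(path, geometry) {
  df <- utils::read.csv(path)
  need <- c("x", "y", "mz", "mobility", "intensity")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("frame file missing column(s): ",
                         paste(miss, collapse = ", "))
  ms1_frames(df, geometry)
}
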