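test_that("parameter validation enforces the documented invariants", {
  p <- schedule_parameters()
  expect_equal(p$isolation_width_da, 1.7)
  expect_equal(p$collision_energies, c(20, 30, 40, 50, 60, 70))
  expect_equal(p$n_spectra_per_ce, 5L)
  expect_error(schedule_parameters(min_purity = 1.2), "min_purity")
  expect_error(schedule_parameters(collision_energies = numeric(0)),
               "collision_energies")
  expect_error(schedule_parameters(collision_energies = c(20, 20)),
               "collision_energies")
  expect_error(schedule_parameters(mobility_window_min = 0.05,
                                   mobility_window_max = 0.02),
               "mobility_window")
})

test_that("eligibility filters on maximum intensity and sorts by area", {
  g <- raster_geometry(5, 5)
  tab <- data.frame(feature_id = 1:4, mz = c(300, 300, 200, 500),
                    mobility_apex = 1.2, mobility_low = 1.18,
                    mobility_high = 1.22)
  ints <- data.frame(
    feature_id = c(1, 2, 3, 4),
    x = 0:3, y = 0,
    intensity = c(10 * 5000, 5000, 5000, 4999))
  ft <- ion_features(tab, ints, g)
  el <- eligible_features(ft, schedule_parameters())
  # feature 4 excluded (4999 < 5000); ties by area broken by m/z then id
  expect_equal(el$feature_id, c(3L, 2L, 1L))
})

test_that("mobility windows clamp the detected extent to the bounds", {
  g <- raster_geometry(5, 5)
  p <- schedule_parameters()
  f <- list(mobility_apex = 1.2, mobility_low = 1.185, mobility_high = 1.215)
  expect_equal(unname(diff(assign_mobility_window(f, p, g))), 0.03)
  f <- list(mobility_apex = 1.2, mobility_low = 1.15, mobility_high = 1.25)
  expect_equal(unname(diff(assign_mobility_window(f, p, g))), 0.04)
  f <- list(mobility_apex = 1.2, mobility_low = 1.1975, mobility_high = 1.2025)
  expect_equal(unname(diff(assign_mobility_window(f, p, g))), 0.02)
  # clipped at the ramp edge with width preserved
  f <- list(mobility_apex = 0.655, mobility_low = 0.64, mobility_high = 0.67)
  w <- assign_mobility_window(f, p, g)
  expect_equal(unname(w["low"]), 0.65)
  expect_equal(unname(diff(w)), 0.03)
  f <- list(mobility_apex = 2.0, mobility_low = 1.9, mobility_high = 2.1)
  expect_error(assign_mobility_window(f, p, g), "apex")
})

test_that("purity score is the pure intensity fraction of the isolation", {
  p <- schedule_parameters()
  pure_only <- data.frame(mz = c(400, 400.002), mobility = c(1.2, 1.21),
                          intensity = c(500, 300))
  expect_equal(purity_score(pure_only, 400, 1.7, 1.18, 1.22, p), 1)
  mixed <- data.frame(mz = c(400, 400.5), mobility = c(1.2, 1.2),
                      intensity = c(800, 200))
  expect_equal(purity_score(mixed, 400, 1.7, 1.18, 1.22, p), 0.8)
  # isotope positions count as pure (wide isolation)
  iso <- data.frame(mz = c(400, 401.0034, 400.5), mobility = 1.2,
                    intensity = c(600, 200, 200))
  expect_equal(purity_score(iso, 400, 3, 1.18, 1.22, p), 0.8)
  # empty isolation region scores 0
  expect_equal(purity_score(mixed, 700, 1.7, 1.18, 1.22, p), 0)
  expect_equal(purity_score(mixed[0, ], 400, 1.7, 1.18, 1.22, p), 0)
  # points outside the mobility window are not isolated
  expect_equal(purity_score(
    data.frame(mz = c(400, 400.5), mobility = c(1.2, 1.5),
               intensity = c(800, 200)), 400, 1.7, 1.18, 1.22, p), 1)
  expect_error(purity_score(mixed, 400, 0, 1.18, 1.22, p), "width")
})

test_that("ramp feasibility enforces the switch-time gap in elution order", {
  g <- raster_geometry(5, 5)
  p <- schedule_parameters() # gap 0.0121
  none <- data.frame(low = numeric(0), high = numeric(0))
  expect_true(check_ramp_feasible(none, c(1.29, 1.33), g, p))
  expect_false(check_ramp_feasible(data.frame(low = 1.29, high = 1.33),
                                   c(1.32, 1.36), g, p))
  # gap 0.013 >= 0.0121: feasible
  expect_true(check_ramp_feasible(data.frame(low = 1.30, high = 1.33),
                                  c(1.26, 1.287), g, p))
  # same windows with a 2 ms switch time (gap 0.0147): infeasible
  p2 <- schedule_parameters(quad_switch_time_ms = 2)
  expect_false(check_ramp_feasible(data.frame(low = 1.30, high = 1.33),
                                   c(1.26, 1.287), g, p2))
})

test_that("spatial check applies per collision energy with >= semantics", {
  p <- schedule_parameters() # min distance 20
  none <- data.frame(x = numeric(0), y = numeric(0))
  expect_true(check_spatial(none, 3, 3, p))
  expect_false(check_spatial(data.frame(x = 0, y = 0), 3, 4, p)) # d = 5
  expect_true(check_spatial(data.frame(x = 0, y = 0), 12, 16, p)) # d = 20
})

test_that("a uniform feature schedules exactly its replicates, spaced out", {
  g <- raster_geometry(10, 10)
  ft <- one_feature(uniform_pixels(g), geometry = g)
  fr <- pure_frames(ft)
  p <- loose_params(n_spectra_per_ce = 2, min_distance_px = 3)
  sch <- simsef_schedule(ft, fr, p)
  expect_equal(nrow(sch$events), 2)
  d <- pixel_distance(sch$events$x[1], sch$events$y[1],
                      sch$events$x[2], sch$events$y[2])
  expect_gte(d, 3)
  expect_equal(nrow(validate_schedule(sch, ft, fr)), 0)
})

test_that("a feature below the purity threshold is reported unscheduled", {
  g <- raster_geometry(6, 6)
  ft <- one_feature(uniform_pixels(g, 1e4), mz = 400, geometry = g)
  # every pixel: precursor 500 + interference 500 -> purity 0.5
  ints <- ft$intensities
  fr <- ms1_frames(rbind(
    data.frame(x = ints$x, y = ints$y, mz = 400, mobility = 1.2,
               intensity = 500),
    data.frame(x = ints$x, y = ints$y, mz = 400.4, mobility = 1.2,
               intensity = 500)), g)
  p <- loose_params(min_purity = 0.8)
  sch <- simsef_schedule(ft, fr, p)
  expect_equal(nrow(sch$events), 0)
  expect_equal(sch$feature_summary$n_events, 0L)
  expect_gt(sch$feature_summary$rejected_purity, 0)
})

test_that("co-pixel features with overlapping windows split across pixels", {
  g <- raster_geometry(8, 8)
  # shared intense pixel (4,4); each feature also has a private pixel
  tab <- data.frame(feature_id = 1:2, mz = c(300, 320),
                    mobility_apex = 1.2, mobility_low = 1.185,
                    mobility_high = 1.215)
  ints <- data.frame(
    feature_id = c(1L, 1L, 2L, 2L),
    x = c(4L, 0L, 4L, 7L), y = c(4L, 0L, 4L, 7L),
    intensity = c(1e4, 5e3, 2e4, 6e3))
  ft <- ion_features(tab, ints, g)
  fr <- pure_frames(ft)
  p <- loose_params(n_spectra_per_ce = 1)
  sch <- simsef_schedule(ft, fr, p)
  expect_equal(nrow(sch$events), 2)
  expect_equal(length(unique(sch$events$spot_name)), 2)
  # brute force: enumerate all feasible pixel assignments and confirm the
  # greedy result is one of them, with the smaller-area feature (id 1) in
  # its own most intense pixel
  feas <- list()
  for (p1 in c("X004Y004", "X000Y000")) {
    for (p2 in c("X004Y004", "X007Y007")) {
      if (p1 != p2) feas[[length(feas) + 1L]] <- c(p1, p2)
    }
  }
  got <- sch$events$spot_name[order(sch$events$feature_id)]
  expect_true(any(vapply(feas, identical, TRUE, y = got)))
  expect_equal(got[1], "X004Y004")
})

test_that("the smaller-area feature wins a single feasible pixel", {
  g <- raster_geometry(5, 5)
  tab <- data.frame(feature_id = 1:2, mz = c(300, 320),
                    mobility_apex = 1.2, mobility_low = 1.185,
                    mobility_high = 1.215)
  ints <- data.frame(feature_id = c(1L, 2L), x = 2L, y = 2L,
                     intensity = c(5e3, 6e3))
  ft <- ion_features(tab, ints, g)
  fr <- pure_frames(ft)
  sch <- simsef_schedule(ft, fr, loose_params())
  expect_equal(nrow(sch$events), 1)
  expect_equal(sch$events$feature_id, 1L)
})

test_that("per-energy intensity walk follows descending intensity", {
  g <- raster_geometry(6, 1)
  px <- data.frame(x = 0:5, y = 0L, intensity = c(1e3, 9e3, 5e3, 8e3, 2e3, 7e3))
  ft <- one_feature(px, geometry = g)
  fr <- pure_frames(ft)
  sch <- simsef_schedule(ft, fr, loose_params(n_spectra_per_ce = 3))
  expect_equal(sch$events$x, c(1L, 3L, 5L))
})

test_that("scheduled events never exceed the per-energy replicate cap", {
  ds <- generate_dataset(synthetic_spec(raster_geometry(18, 18),
                                        n_features = 10, seed = 21))
  p <- schedule_parameters(n_spectra_per_ce = 2,
                           collision_energies = c(20, 50),
                           min_distance_px = 4)
  sch <- simsef_schedule(ds$features, ds$frames, p)
  counts <- table(sch$events$feature_id, sch$events$collision_energy)
  expect_true(all(counts <= 2))
  per_feature <- table(sch$events$feature_id)
  expect_true(all(per_feature <= 2 * 2))
})

test_that("raising the purity threshold never adds events", {
  ds <- generate_dataset(synthetic_spec(raster_geometry(16, 16),
                                        n_features = 12, seed = 31,
                                        interference_fraction = 0.6))
  n_prev <- Inf
  for (mp in c(0, 0.3, 0.6, 0.8, 0.95)) {
    p <- loose_params(min_purity = mp)
    n <- nrow(simsef_schedule(ds$features, ds$frames, p)$events)
    expect_lte(n, n_prev)
    n_prev <- n
  }
})

test_that("identical inputs give identical schedules", {
  ds <- generate_dataset(synthetic_spec(raster_geometry(14, 14),
                                        n_features = 8, seed = 17))
  p <- schedule_parameters(n_spectra_per_ce = 2,
                           collision_energies = c(20, 40),
                           min_distance_px = 3)
  s1 <- simsef_schedule(ds$features, ds$frames, p)
  s2 <- simsef_schedule(ds$features, ds$frames, p)
  expect_identical(s1$events, s2$events)
})

test_that("geometry mismatch between features and frames is an error", {
  ds <- generate_dataset(synthetic_spec(raster_geometry(8, 8),
                                        n_features = 2, seed = 1))
  fr2 <- ms1_frames(ds$frames$points, raster_geometry(9, 8))
  expect_error(simsef_schedule(ds$features, fr2), "geometr")
})

test_that("the validator flags hand-built violations rule by rule", {
  g <- raster_geometry(10, 10)
  ft <- one_feature(uniform_pixels(g, 1e4), mz = 400, geometry = g)
  fr <- pure_frames(ft)
  p <- loose_params(n_spectra_per_ce = 5, min_distance_px = 20)
  base <- list(params = p, geometry = g)

  mk <- function(rows) {
    s <- base
    s$events <- rows
    class(s) <- "simsef_schedule"
    s
  }
  ev <- function(x, y, ce = 30, lo = 1.185, hi = 1.215) {
    data.frame(feature_id = 1L, x = x, y = y, spot_name = spot_name(x, y),
               collision_energy = ce, isolation_mz = 400,
               isolation_width_da = 1.7, mobility_low = lo,
               mobility_high = hi, purity = 1)
  }
  # two same-energy events 1 px apart: exactly one spatial violation
  v <- validate_schedule(mk(rbind(ev(0, 0), ev(1, 0))), ft, fr, p)
  expect_equal(v$rule, "spatial")
  # overlapping windows in one pixel: exactly one ramp violation
  v <- validate_schedule(mk(rbind(ev(0, 0, ce = 20),
                                  ev(0, 0, ce = 40, lo = 1.20, hi = 1.23))),
                         ft, fr, p)
  expect_equal(v$rule, "ramp")
  # different energies far apart: clean
  v <- validate_schedule(mk(rbind(ev(0, 0, ce = 20), ev(9, 9, ce = 40))),
                         ft, fr, p)
  expect_equal(nrow(v), 0)
  # event below the intensity threshold
  p2 <- loose_params(min_pixel_intensity_abs = 2e4)
  v <- validate_schedule(mk(ev(0, 0)), ft, fr, p2)
  expect_equal(v$rule, "intensity")
  # purity recomputed from frames
  p3 <- loose_params(min_purity = 0.9)
  fr2 <- ms1_frames(rbind(fr$points,
                          data.frame(x = 0, y = 0, mz = 400.4,
                                     mobility = 1.2, intensity = 1e5)), g)
  v <- validate_schedule(mk(ev(0, 0)), ft, fr2, p3)
  expect_equal(v$rule, "purity")
  # replicate cap
  p4 <- loose_params(n_spectra_per_ce = 1, min_distance_px = 0,
                     quad_switch_time_ms = 0)
  v <- validate_schedule(mk(rbind(ev(0, 0), ev(5, 5))), ft, fr, p4)
  expect_equal(v$rule, "count")
})
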