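test_that("MGF files round-trip scans with all metadata", {
  scans <- structure(list(
    toy_scan(c(100, 200.5, 350.123456), c(1000, 50.25, 3),
             spot = "X003Y014", pmz = 701.5121, ce = 40,
             lo = 1.29, hi = 1.33, fid = 7L),
    toy_scan(c(80.1), c(12), spot = "X000Y001", pmz = 250.1, ce = 20)
  ), class = "ms2_scans")
  path <- tempfile(fileext = ".mgf")
  write_mgf(scans, path)
  back <- read_mgf(path)
  expect_length(back, 2)
  expect_equal(back[[1]]$spot_name, "X003Y014")
  expect_equal(back[[1]]$precursor_mz, 701.5121)
  expect_equal(back[[1]]$collision_energy, 40)
  expect_equal(back[[1]]$mobility_low, 1.29)
  expect_equal(back[[1]]$mobility_high, 1.33)
  expect_equal(back[[1]]$feature_id, 7L)
  expect_equal(back[[1]]$peaks$mz, scans[[1]]$peaks$mz, tolerance = 1e-6)
  expect_equal(back[[1]]$peaks$intensity, scans[[1]]$peaks$intensity,
               tolerance = 1e-4)
  expect_true(is.na(back[[2]]$feature_id))
})

test_that("scan assignment requires all three identifiers to match", {
  g <- raster_geometry(8, 8)
  ft <- one_feature(uniform_pixels(g), mz = 400, apex = 1.2, geometry = g)
  sch <- simsef_schedule(ft, pure_frames(ft), loose_params())
  ev <- sch$events[1, ]
  ok <- toy_scan(c(100, 200), c(10, 20), spot = ev$spot_name,
                 pmz = ev$isolation_mz, ce = 30,
                 lo = ev$mobility_low, hi = ev$mobility_high)
  off_mz <- ok
  off_mz$precursor_mz <- ev$isolation_mz + 0.1
  off_spot <- ok
  off_spot$spot_name <- "X007Y007"
  off_mob <- ok
  off_mob$mobility_low <- ev$mobility_low + 0.05
  off_mob$mobility_high <- ev$mobility_high + 0.05
  res <- assign_scans(list(ok, off_mz, off_spot, off_mob), sch)
  expect_equal(res$assignments$scan, 1L)
  expect_equal(res$assignments$feature_id, 1L)
  expect_equal(res$unassigned, c(2L, 3L, 4L))
})

test_that("scans in one spot resolve to features by mobility window", {
  g <- raster_geometry(6, 6)
  # two features sharing the hot pixel with disjoint mobility windows
  tab <- data.frame(feature_id = 1:2, mz = c(300, 308),
                    mobility_apex = c(1.0, 1.4),
                    mobility_low = c(0.985, 1.385),
                    mobility_high = c(1.015, 1.415))
  ints <- data.frame(feature_id = c(1L, 2L), x = 2L, y = 2L,
                     intensity = c(1e4, 2e4))
  ft <- ion_features(tab, ints, g)
  sch <- simsef_schedule(ft, pure_frames(ft), loose_params())
  expect_equal(nrow(sch$events), 2)
  scans <- lapply(seq_len(2), function(i) {
    e <- sch$events[sch$events$feature_id == i, ]
    toy_scan(c(100), c(10), spot = e$spot_name, pmz = e$isolation_mz,
             ce = 30, lo = e$mobility_low, hi = e$mobility_high)
  })
  res <- assign_scans(scans, sch)
  expect_equal(res$assignments$feature_id, c(1L, 2L))
})

test_that("merging a single scan is the identity", {
  a <- toy_scan(c(100, 200, 300), c(5, 50, 10))
  m <- merge_scans(list(a))
  expect_equal(m$peaks$mz, a$peaks$mz)
  expect_equal(m$peaks$intensity, a$peaks$intensity)
  expect_equal(m$n_source_scans, 1)
})

test_that("the worked three-peak merge groups and weights correctly", {
  a <- toy_scan(c(100.000, 200.000), c(50, 10))
  b <- toy_scan(c(100.002, 300.000), c(30, 5))
  m <- merge_scans(list(a, b), mz_tol_da = 0.005, tol_ppm = 0)
  expect_equal(nrow(m$peaks), 3)
  expect_equal(m$peaks$mz, c(100.00075, 200, 300), tolerance = 1e-9)
  expect_equal(m$peaks$intensity, c(50, 10, 5))
})

test_that("merging is independent of scan order", {
  set.seed(33)
  scans <- lapply(1:5, function(i) {
    toy_scan(sort(runif(20, 100, 900)), runif(20, 1, 1e4))
  })
  m1 <- merge_scans(scans)
  for (r in 1:5) {
    m2 <- merge_scans(scans[sample(5)])
    expect_equal(m2$peaks, m1$peaks)
  }
})

test_that("consensus intensities dominate every contributing peak", {
  set.seed(44)
  scans <- lapply(1:4, function(i) {
    mz <- sort(c(150, 250.001 + runif(1, -0.002, 0.002), runif(10, 300, 900)))
    toy_scan(mz, runif(length(mz), 1, 5000))
  })
  m <- merge_scans(scans)
  all_peaks <- do.call(rbind, lapply(scans, function(s) s$peaks))
  # each source peak maps into some consensus group with >= intensity
  for (i in seq_len(nrow(all_peaks))) {
    d <- abs(m$peaks$mz - all_peaks$mz[i])
    j <- which.min(d)
    expect_lte(all_peaks$intensity[i], m$peaks$intensity[j] + 1e-9)
  }
  # every group max is attained by a member
  expect_true(all(m$peaks$intensity %in% all_peaks$intensity))
})

test_that("a low-abundance scan with a new m/z grows the consensus", {
  a <- toy_scan(c(100, 200), c(5000, 3000))
  base <- merge_scans(list(a))
  extra <- toy_scan(c(100, 555.5), c(2, 1)) # weak, but one novel signal
  grown <- merge_scans(list(a, extra))
  expect_equal(nrow(grown$peaks), nrow(base$peaks) + 1)
  expect_true(any(abs(grown$peaks$mz - 555.5) < 1e-9))
})

test_that("merging an empty input is an error", {
  expect_error(merge_scans(list()), "empty")
})

test_that("two-stage consensus keeps per-energy spectra inspectable", {
  ds <- generate_dataset(synthetic_spec(raster_geometry(14, 14),
                                        n_features = 5, seed = 19,
                                        interference_fraction = 0))
  p <- loose_params(n_spectra_per_ce = 2, min_distance_px = 2,
                    collision_energies = c(20, 50))
  sch <- simsef_schedule(ds$features, ds$frames, p)
  scans <- generate_ms2(sch, ds)
  asn <- assign_scans(scans, sch)
  cons <- consensus_spectra(scans, asn)
  per_ce_keys <- vapply(cons$per_ce, function(s)
    paste(s$feature_id, s$collision_energy), "")
  expect_false(any(duplicated(per_ce_keys)))
  expect_true(all(is.na(vapply(cons$across_ce, function(s)
    s$collision_energy, 0))))
  # across-energy consensus covers every fragment of the per-energy ones
  for (fid in vapply(cons$across_ce, function(s) s$feature_id, 0L)) {
    ce_peaks <- do.call(rbind, lapply(
      Filter(function(s) s$feature_id == fid, cons$per_ce),
      function(s) s$peaks))
    acc <- Filter(function(s) s$feature_id == fid, cons$across_ce)[[1]]
    for (i in seq_len(nrow(ce_peaks))) {
      expect_true(min(abs(acc$peaks$mz - ce_peaks$mz[i])) < 0.01)
    }
  }
  # consensus spectra export as MGF
  path <- tempfile(fileext = ".mgf")
  write_mgf(cons$across_ce, path)
  expect_length(read_mgf(path), length(cons$across_ce))
})
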