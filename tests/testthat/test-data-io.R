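# Readers, writers, timestamp conversion and day-period labelling.

test_that("detections round-trip through CSV and come back sorted", {
  det <- make_detections(c("S02", "S01", "S01"), c("deer", "serow", "deer"),
                         c("10:00:00", "12:30:05", "08:15:00"))
  path <- withr::local_tempfile(fileext = ".csv")
  write_detections(det, path)
  back <- read_detections(path)
  expect_equal(nrow(back), 3L)
  expect_true(!is.unsorted(order(back$site_id, back$timestamp)))
  # bit-exact field preservation (after sorting the original the same way)
  det_sorted <- det[order(det$site_id, det$timestamp), ]
  rownames(det_sorted) <- NULL
  expect_identical(back$site_id, det_sorted$site_id)
  expect_identical(back$species, det_sorted$species)
  expect_equal(as.numeric(back$timestamp), as.numeric(det_sorted$timestamp))
})

test_that("unknown species and malformed timestamps are rejected with line numbers", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("site_id,species,timestamp",
               "S01,serow,2012-08-01T10:00:00",
               "S01,wild_boar,2012-08-01T10:00:00"), path)
  expect_error(read_detections(path), "line 3.*wild_boar")
  writeLines(c("site_id,species,timestamp",
               "S01,serow,2012-08-01Tnoon"), path)
  expect_error(read_detections(path), "line 2.*timestamp")
  writeLines("site_id,species,timestamp", path)
  expect_error(read_detections(path), "empty")
})

test_that("deployments enforce one interval per site and positive trap-days", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("site_id,start,end",
               "S01,2012-07-01T00:00:00,2012-07-16T12:00:00"), path)
  dep <- read_deployments(path)
  expect_equal(dep$trap_days, 15.5)
  writeLines(c("site_id,start,end",
               "S01,2012-07-01T00:00:00,2012-07-16T00:00:00",
               "S01,2012-08-01T00:00:00,2012-08-16T00:00:00"), path)
  expect_error(read_deployments(path), "multiple deployment")
  writeLines(c("site_id,start,end",
               "S01,2012-07-16T00:00:00,2012-07-01T00:00:00"), path)
  expect_error(read_deployments(path), "after start")
})

test_that("covariate invariants are enforced on read", {
  cols <- c("site_id,slope_mean_deg,dist_road_km,dist_settlement_km,dist_water_km,area_decid_km2,area_conif_km2,area_grass_km2,area_farm_km2")
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(cols, "S01,12.5,0.4,1.2,0.3,0.05,0.03,0.01,0.01"), path)
  cv <- read_covariates(path)
  expect_equal(cv$slope_mean_deg, 12.5)
  writeLines(c(cols, "S01,12.5,-0.4,1.2,0.3,0.05,0.03,0.01,0.01"), path)
  expect_error(read_covariates(path), "negative")
  writeLines(c(cols, "S01,12.5,0.4,1.2,0.3,0.06,0.05,0.01,0.01"), path)
  expect_error(read_covariates(path), "buffer area")
})

test_that("clock time maps to radians and is periodic in 24 h", {
  expect_equal(to_radians(ts("2012-08-01T00:00:00")), 0)
  expect_equal(to_radians(ts("2012-08-01T12:00:00")), pi)
  expect_equal(to_radians(ts("2012-08-01T06:00:00")), pi / 2)
  set.seed(4)
  any_times <- ts("2012-08-01T00:00:00") + round(runif(50, 0, 86400 * 30))
  expect_equal(to_radians(any_times), to_radians(any_times + 86400),
               tolerance = 1e-9)
})

test_that("day periods classify twilight inclusively and partition 24 h", {
  expect_equal(as.character(day_period("05:30", "05:00", "18:30")), "dawn")
  expect_equal(as.character(day_period("12:00", "05:00", "18:30")), "daytime")
  expect_equal(as.character(day_period("23:00", "05:00", "18:30")), "nighttime")
  expect_equal(as.character(day_period("18:00", "05:00", "18:30")), "dusk")
  # boundary instants belong to the twilight classes
  expect_equal(as.character(day_period("06:00", "05:00", "18:30")), "dawn")
  expect_equal(as.character(day_period("04:00", "05:00", "18:30")), "dawn")
  expect_error(day_period("12:00", "05:00", "06:30"), "degenerate")
  # partition: the four class durations sum to 24 h for random sun times
  set.seed(11)
  for (i in 1:5) {
    sr <- runif(1, 3, 8); ss <- runif(1, sr + 2.5, 22)
    grid_h <- seq(0, 24, length.out = 24 * 60 + 1)[-(24 * 60 + 1)]
    cls <- day_period(grid_h, sr, ss)
    durations <- table(cls) / length(grid_h) * 24
    expect_equal(sum(durations), 24)
    expect_equal(unname(durations[["dawn"]]), 2, tolerance = 0.05)
    expect_equal(unname(durations[["dusk"]]), 2, tolerance = 0.05)
  }
})

test_that("detections outside their deployment are caught by validation", {
  det <- make_detections("S01", "serow", "10:00:00", day = "2012-09-20")
  dep <- data.frame(site_id = "S01",
                    start = ts("2012-07-01T00:00:00"),
                    end = ts("2012-07-16T00:00:00"),
                    trap_days = 15)
  expect_error(validate_detections(det, dep), "outside deployment")
  det_ok <- make_detections("S01", "serow", "10:00:00", day = "2012-07-10")
  expect_true(validate_detections(det_ok, dep))
  det_bad <- make_detections("S99", "serow", "10:00:00", day = "2012-07-10")
  expect_error(validate_detections(det_bad, dep), "no deployment")
})
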