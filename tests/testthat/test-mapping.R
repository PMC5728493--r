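test_that("XYT embedding uses quarter-second time units", {
  cfg <- mapping_config()
  tbl <- data.frame(x_px = c(10, 20), y_px = c(5, 5), start_s = c(0, 0))
  p <- xyt_embed(tbl, cfg, day_offset_s = 43200)  # noon
  expect_equal(unname(p[1, "t"]), 10800)
  expect_equal(sqrt(sum((p[1, ] - p[2, ])^2)), 10)
  expect_error(mapping_config(time_scale = 0), "positive")
})

test_that("dance clustering groups drifting runs and enforces the 4-run minimum", {
  cfg <- mapping_config(cluster_dist = 60)
  # 6 runs, ~2 s gaps, ~15 px drift: one dance
  tbl <- data.frame(x_px = 100 + 15 * (0:5), y_px = 200,
                    start_s = 2 * (0:5))
  cl <- cluster_dances(xyt_embed(tbl, cfg), cfg)
  expect_length(cl, 1)
  expect_length(cl[[1]], 6)
  # 3 tightly packed runs: below the dance minimum
  cl3 <- cluster_dances(xyt_embed(tbl[1:3, ], cfg), cfg)
  expect_length(cl3, 0)
  # same comb spot, 10 minutes apart: t-separation 150 units >> d_max3
  tbl2 <- rbind(tbl, transform(tbl, start_s = start_s + 600))
  cl2 <- cluster_dances(xyt_embed(tbl2, cfg), cfg)
  expect_length(cl2, 2)
})

test_that("circular mean matches worked values, warns on odd counts and is equivariant", {
  expect_equal(circular_mean(c(350, 10), warn_odd = FALSE), 0)
  expect_equal(circular_mean(c(10, 20, 30, 40)), 25)
  for (a in c(0, 77, 359))
    expect_equal(circular_mean(a, warn_odd = FALSE), a)
  expect_warning(circular_mean(c(10, 20, 30)), "odd")
  expect_error(circular_mean(c(0, 180), warn_odd = FALSE), "undefined")
  # rotation equivariance against the complex-arithmetic oracle
  set.seed(1)
  ang <- stats::runif(8, 0, 360)
  for (phi in c(10, 123, 300)) {
    expect_equal(circular_mean((ang + phi) %% 360, warn_odd = FALSE),
                 (circular_mean(ang, warn_odd = FALSE) + phi) %% 360,
                 tolerance = 1e-9)
    expect_equal(circular_mean(ang, warn_odd = FALSE),
                 oracle_circ_mean(ang), tolerance = 1e-9)
  }
})

test_that("RANSAC rejects flips, matches exhaustive consensus and flags weak modes", {
  cfg <- mapping_config(ransac_inlier_deg = 30, ransac_iters = 100)
  r <- ransac_angles(c(40, 42, 44, 38, 222), cfg, seed = 1)
  expect_equal(r$inliers, c(TRUE, TRUE, TRUE, TRUE, FALSE))
  expect_equal(r$mean_deg, 41, tolerance = 0.5)
  expect_true(r$ok)
  expect_false(r$weak_mode)
  r2 <- ransac_angles(rep(77, 6), cfg, seed = 1)
  expect_true(all(r2$inliers))
  expect_equal(r2$mean_deg, 77)
  # 50/50 bimodal flip split: tie broken by circular variance, flagged
  bi <- c(0, 1, -1, 2, 180, 181, 179, 182) %% 360
  r3 <- ransac_angles(bi, cfg, seed = 2)
  expect_equal(r3$n_inliers, 4)
  expect_true(r3$weak_mode)
  # randomized consensus equals exhaustive search for <= 12 angles
  for (rep in 1:10) {
    set.seed(rep + 10)
    ang <- stats::runif(sample(4:12, 1), 0, 360)
    a <- ransac_angles(ang, cfg, seed = rep)
    b <- ransac_angles(ang, cfg, exhaustive = TRUE)
    expect_equal(a$inliers, b$inliers)
    expect_equal(a$mean_deg, b$mean_deg)
  }
})

test_that("duration converts linearly to distance with the feeder calibration", {
  f_d <- 342 / 582.79
  expect_equal(duration_to_distance(582.79, f_d), 342)
  expect_equal(duration_to_distance(2 * 582.79, f_d),
               2 * duration_to_distance(582.79, f_d))
  expect_error(duration_to_distance(0, f_d), "positive")
})

test_that("feeder calibration recovers the generating factor and its CV", {
  expect_equal(
    calibrate_factor(0, 600, 0, 300)$distance_factor, 0.5)
  set.seed(3)
  n <- 200
  ang <- stats::rnorm(n, 225, 5) %% 360
  dur <- stats::rnorm(n, 582.79, 196.10)
  cal <- calibrate_factor(ang, dur, 225, 342)
  expect_equal(cal$distance_factor, 342 / 582.79, tolerance = 0.05)
  set.seed(4)
  big <- stats::rnorm(5000, 582.79, 196.10)
  cv <- calibrate_factor(rep(225, 5000), big, 225, 342)$cv
  expect_equal(cv, 0.34, tolerance = 0.03)
  expect_error(calibrate_factor(10, 500, 200, 342), "window")
})

test_that("profitability is the waggle / return tempo ratio", {
  expect_equal(profitability(500, 500), 1)
  expect_equal(profitability(600, 750), 2 * profitability(600, 1500))
  expect_equal(profitability(600, 1500), 0.4)
  expect_error(profitability(500, 0), "positive")
})

test_that("solar azimuth matches known geometry and rises monotonically", {
  # equinox, equator: sunrise due east
  az <- solar_azimuth(as.POSIXct("2016-03-20 06:00:00", tz = "UTC"), 0, 0)
  expect_equal(as.numeric(az), 90, tolerance = 1)
  # northern mid-latitude local solar noon: due south
  noon <- solar_azimuth(as.POSIXct("2016-06-21 11:03:00", tz = "UTC"),
                        52.457, 13.296)
  expect_equal(as.numeric(noon), 180, tolerance = 2)
  expect_gt(attr(noon, "elevation_deg"), 55)
  expect_false(attr(noon, "low_sun"))
  # monotone through a mid-latitude summer day
  times <- as.POSIXct("2016-06-21 06:00:00", tz = "UTC") +
    3600 * (0 : 10)
  azs <- vapply(times, function(t)
    as.numeric(solar_azimuth(t, 52.457, 13.296)), 0)
  expect_true(all(diff(azs) > 0))
  # polar night: azimuth still defined, flagged
  pol <- solar_azimuth(as.POSIXct("2016-12-21 12:00:00", tz = "UTC"),
                       78, 15)
  expect_true(attr(pol, "low_sun"))
})

test_that("dances project relative to the solar azimuth with compass trigonometry", {
  cfg <- mapping_config(distance_factor = 342 / 582.79)
  up <- project_dance(list(mean_duration_ms = 582.79, comb_angle_deg = 0),
                      cfg, azimuth_deg = 135)
  expect_equal(up$bearing_deg, 135)   # dancing straight up points sunward
  cw <- project_dance(list(mean_duration_ms = 582.79, comb_angle_deg = 90),
                      cfg, azimuth_deg = 135)
  expect_equal(cw$bearing_deg, 225)
  expect_equal(cw$distance_m, 342)
  expect_equal(cw$east_m, -342 / sqrt(2), tolerance = 1e-6)
  expect_equal(cw$north_m, -342 / sqrt(2), tolerance = 1e-6)
})

test_that("map_dances aggregates inliers, return gaps and flags, end to end", {
  cfg <- mapping_config(distance_factor = 342 / 582.79)
  mk_dance <- function(x, t0, angles, dur = 580) {
    data.frame(x_px = x + 2 * seq_along(angles), y_px = 100,
               start_s = t0 + 2.5 * (seq_along(angles) - 1),
               duration_ms = dur, orientation_deg = angles %% 360)
  }
  tbl <- rbind(
    mk_dance(100, 100, c(44, 46, 43, 45, 225, 44)),  # one flipped run
    mk_dance(300, 700, c(120, 122, 118, 121)))
  start <- as.POSIXct("2016-07-15 10:00:00", tz = "UTC")
  dances <- map_dances(tbl, cfg, start, seed = 1)
  expect_equal(nrow(dances), 2)
  d1 <- dances[dances$n_runs == 6, ]
  expect_equal(d1$n_inliers, 5)
  expect_equal(d1$comb_angle_deg, circular_mean(c(44, 46, 43, 45, 44),
                                                warn_odd = FALSE),
               tolerance = 1e-6)
  # return gap: 2.5 s spacing minus 0.58 s waggle = 1.92 s
  expect_equal(d1$mean_return_ms, 1920, tolerance = 1)
  expect_equal(d1$profitability, 580 / 1920, tolerance = 1e-6)
  # timestamps propagate exactly
  expect_equal(d1$start_iso,
               format(start + 100, "%Y-%m-%dT%H:%M:%OS3%z"))
  # projection round-trips the generator geometry: bearing =
  # azimuth(time) + comb angle
  az <- as.numeric(solar_azimuth(start + 100, cfg$hive_lat, cfg$hive_lon))
  expect_equal(d1$bearing_deg, (az + d1$comb_angle_deg) %% 360,
               tolerance = 1e-9)
  # GeoJSON writing
  path <- withr::local_tempfile(fileext = ".geojson")
  write_dances_geojson(dances, cfg, path)
  gj <- jsonlite::read_json(path)
  expect_equal(length(gj$features), 2)
})
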