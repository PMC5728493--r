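#' Mapping-module configuration
#'
#' Groups decoded waggle runs into dances in (x, y, t) space, rejects
#' angular outliers (180-degree direction flips, aberrant runs) with
#' RANSAC, and projects each dance to a field location using the solar
#' azimuth at dance time.
#'
#' @param time_scale data-space units per second of occurrence time; 0.25
#'   represents time in quarter seconds so temporal gaps are commensurate
#'   with the px drift between runs.
#' @param cluster_dist merge threshold d_max3 in data-space units for the
#'   single-linkage clustering of runs.
#' @param min_runs_per_dance clusters (and RANSAC consensus sets) with
#'   fewer runs are not treated as dances.
#' @param ransac_inlier_deg circular distance below which a run angle
#'   counts as an inlier of a candidate direction; 30 degrees safely
#'   excludes a lone 180-degree flip.
#' @param ransac_iters candidate draws per dance.
#' @param distance_factor f_d, meters of foraging distance per millisecond
#'   of waggle duration; comes from [calibrate_factor()]. The default is
#'   the calibration of a feeder 342 m away signalled with 582.79 ms mean
#'   waggle duration.
#' @param hive_lat,hive_lon hive position, degrees (east/north positive).
#' @return object of class `mapping_config`.
#' @export
mapping_config <- function(time_scale = 0.25, cluster_dist = 60,
                           min_runs_per_dance = 4, ransac_inlier_deg = 30,
                           ransac_iters = 100,
                           distance_factor = 342 / 582.79,
                           hive_lat = 52.457, hive_lon = 13.296) {
  if (time_scale <= 0) stop("time_scale must be positive")
  if (min_runs_per_dance < 1) stop("min_runs_per_dance must be >= 1")
  stop_if_not_scalar_pos(distance_factor, "distance_factor")
  structure(list(time_scale = time_scale, cluster_dist = cluster_dist,
                 min_runs_per_dance = as.integer(min_runs_per_dance),
                 ransac_inlier_deg = ransac_inlier_deg,
                 ransac_iters = as.integer(ransac_iters),
                 distance_factor = distance_factor,
                 hive_lat = hive_lat, hive_lon = hive_lon),
            class = "mapping_config")
}

#' Embed waggle runs in (x, y, t) data space
#'
#' Time of occurrence is expressed in seconds since local midnight and
#' scaled by `time_scale` (quarter seconds by default) so that spatial
#' drift and temporal gaps between a dance's runs live on comparable
#' scales.
#'
#' @param tbl run table with columns `x_px`, `y_px`, `start_s`.
#' @param cfg a [mapping_config()].
#' @param day_offset_s seconds since local midnight of the recording's
#'   first frame.
#' @return n x 3 matrix of data-space points.
#' @export
xyt_embed <- function(tbl, cfg, day_offset_s = 0) {
  cbind(x = tbl$x_px, y = tbl$y_px,
        t = (day_offset_s + tbl$start_s) * cfg$time_scale)
}

#' Cluster embedded runs into candidate dances
#'
#' Single-linkage agglomeration cut at `cluster_dist`; clusters with fewer
#' than `min_runs_per_dance` runs are dropped.
#'
#' @param points matrix from [xyt_embed()].
#' @param cfg a [mapping_config()].
#' @return list of integer index vectors, one per retained cluster.
#' @export
cluster_dances <- function(points, cfg) {
  n <- nrow(points)
  if (n == 0) return(list())
  cl <- if (n == 1) 1L
        else cutree(hclust(dist(points), method = "single"),
                    h = cfg$cluster_dist)
  out <- split(seq_len(n), cl)
  out <- out[vapply(out, length, 0L) >= cfg$min_runs_per_dance]
  names(out) <- NULL
  out
}

#' Circular mean of angles in degrees
#'
#' `atan2(sum sin, sum cos)` mapped to [0, 360). Averaging an odd number
#' of consecutive runs is allowed but warned about: the alternating
#' divergence angle of successive waggle runs only cancels over an even
#' count.
#'
#' @param angles_deg numeric vector of angles.
#' @param warn_odd warn when `length(angles_deg)` is odd.
#' @return mean angle in [0, 360).
#' @export
circular_mean <- function(angles_deg, warn_odd = TRUE) {
  if (!length(angles_deg)) stop("no angles")
  r <- deg2rad(angles_deg)
  S <- sum(sin(r)); C <- sum(cos(r))
  if (sqrt(S^2 + C^2) < 1e-9 * length(angles_deg))
    stop("undefined mean: angles are perfectly opposed")
  if (warn_odd && length(angles_deg) %% 2 == 1L)
    warning("averaging an odd number of waggle runs; the divergence ",
            "angle may not cancel", call. = FALSE)
  m <- rad2deg(atan2(S, C)) %% 360
  if (m >= 360 - 1e-9) m <- 0  # guard the floating wrap at 360
  m
}

## circular variance = 1 - mean resultant length
circ_var <- function(angles_deg) {
  r <- deg2rad(angles_deg)
  1 - sqrt(mean(cos(r))^2 + mean(sin(r))^2)
}

consensus_for <- function(angles_deg, center, tol)
  which(circ_dist_deg(angles_deg, center) <= tol)

#' RANSAC over waggle-run orientations
#'
#' Repeatedly picks one run angle as a candidate direction, collects all
#' angles within `ransac_inlier_deg` circular distance, and keeps the
#' largest consensus set (ties resolved toward the smaller circular
#' variance). The robust mean is the circular mean of the consensus.
#'
#' @param angles_deg run orientations of one dance.
#' @param cfg a [mapping_config()].
#' @param seed optional seed for the candidate draws.
#' @param exhaustive try every angle as candidate instead of sampling
#'   (deterministic; used as oracle and for small dances).
#' @return list with `inliers` (logical mask), `mean_deg`, `n_inliers`,
#'   `weak_mode` (consensus no larger than half the runs, e.g. a 50/50
#'   split of flipped directions) and `ok` (consensus reached
#'   `min_runs_per_dance`).
#' @export
ransac_angles <- function(angles_deg, cfg, seed = NULL, exhaustive = FALSE) {
  n <- length(angles_deg)
  cand_idx <- if (exhaustive) seq_len(n)
              else with_seed(seed, sample.int(n, cfg$ransac_iters,
                                              replace = TRUE))
  best <- integer(0); best_var <- Inf
  for (i in cand_idx) {
    cons <- consensus_for(angles_deg, angles_deg[i], cfg$ransac_inlier_deg)
    if (length(cons) > length(best) ||
        (length(cons) == length(best) &&
         circ_var(angles_deg[cons]) < best_var)) {
      best <- cons
      best_var <- circ_var(angles_deg[cons])
    }
  }
  inl <- seq_len(n) %in% best
  list(inliers = inl,
       mean_deg = circular_mean(angles_deg[best], warn_odd = FALSE),
       n_inliers = length(best),
       weak_mode = length(best) <= n / 2,
       ok = length(best) >= cfg$min_runs_per_dance)
}

#' Convert mean waggle duration to foraging distance
#'
#' Linear calibration `r = f_d * d_w` with zero intercept.
#'
#' @param d_w_ms mean waggle-run duration in ms (> 0).
#' @param distance_factor f_d in meters per ms.
#' @return distance in meters.
#' @export
duration_to_distance <- function(d_w_ms, distance_factor) {
  if (any(d_w_ms <= 0)) stop("waggle duration must be positive")
  distance_factor * d_w_ms
}

#' Calibrate the duration-to-distance factor at a known feeder
#'
#' Selects the runs whose orientation lies within `angle_window_deg` of
#' the feeder bearing and divides the feeder distance by their mean
#' waggle duration — the colony's own collective odometer calibration.
#'
#' @param angles_deg decoded run orientations (field bearing frame).
#' @param durations_ms matching waggle durations.
#' @param feeder_bearing_deg compass bearing of the feeder from the hive.
#' @param feeder_distance_m known feeder distance.
#' @param angle_window_deg half-width of the selection window.
#' @return list with `distance_factor` (m/ms), `n`, `mean_duration_ms`
#'   and `cv` (coefficient of variation of the selected durations).
#' @export
calibrate_factor <- function(angles_deg, durations_ms, feeder_bearing_deg,
                             feeder_distance_m, angle_window_deg = 10) {
  sel <- circ_dist_deg(angles_deg, feeder_bearing_deg) <= angle_window_deg
  if (!any(sel)) stop("no runs within the feeder angle window")
  d <- durations_ms[sel]
  list(distance_factor = feeder_distance_m / mean(d),
       n = sum(sel), mean_duration_ms = mean(d),
       cv = stats::sd(d) / mean(d))
}

#' Dance-tempo profitability index
#'
#' Ratio of mean waggle duration to mean return duration; at equal
#' distance, richer resources have shorter return runs and score higher.
#'
#' @param d_w_ms mean waggle duration (ms).
#' @param d_r_ms mean return duration (ms, > 0).
#' @return dimensionless ratio.
#' @export
profitability <- function(d_w_ms, d_r_ms) {
  if (any(d_r_ms <= 0)) stop("return duration must be positive")
  d_w_ms / d_r_ms
}

#' Solar compass azimuth (NOAA solar position)
#'
#' Standard NOAA low-accuracy solar-position algorithm (accurate to well
#' under half a degree for 1900-2100): solar declination and the equation
#' of time give the local hour angle, from which the compass azimuth
#' (0 = true north, clockwise) follows.
#'
#' @param time POSIXct (any timezone; converted to UTC internally).
#' @param lat,lon observer position in degrees; east and north positive.
#' @return azimuth in [0, 360) with attributes `elevation_deg` and
#'   `low_sun` (TRUE when the sun is below the horizon, e.g. polar night;
#'   the azimuth is still returned).
#' @export
solar_azimuth <- function(time, lat, lon) {
  stopifnot(inherits(time, "POSIXt"))
  jd <- as.numeric(time) / 86400 + 2440587.5
  Tc <- (jd - 2451545) / 36525
  L0 <- (280.46646 + Tc * (36000.76983 + 0.0003032 * Tc)) %% 360
  M <- 357.52911 + Tc * (35999.05029 - 0.0001537 * Tc)
  e <- 0.016708634 - Tc * (0.000042037 + 0.0000001267 * Tc)
  Cs <- sin(deg2rad(M)) * (1.914602 - Tc * (0.004817 + 0.000014 * Tc)) +
    sin(deg2rad(2 * M)) * (0.019993 - 0.000101 * Tc) +
    sin(deg2rad(3 * M)) * 0.000289
  true_long <- L0 + Cs
  omega <- 125.04 - 1934.136 * Tc
  app_long <- true_long - 0.00569 - 0.00478 * sin(deg2rad(omega))
  eps0 <- 23 + (26 + (21.448 - Tc * (46.815 + Tc * (0.00059 -
            Tc * 0.001813))) / 60) / 60
  eps <- eps0 + 0.00256 * cos(deg2rad(omega))
  decl <- rad2deg(asin(sin(deg2rad(eps)) * sin(deg2rad(app_long))))
  y <- tan(deg2rad(eps / 2))^2
  eqtime <- 4 * rad2deg(
    y * sin(2 * deg2rad(L0)) - 2 * e * sin(deg2rad(M)) +
      4 * e * y * sin(deg2rad(M)) * cos(2 * deg2rad(L0)) -
      0.5 * y^2 * sin(4 * deg2rad(L0)) -
      1.25 * e^2 * sin(2 * deg2rad(M)))
  mins_utc <- (as.numeric(time) %% 86400) / 60
  tst <- (mins_utc + eqtime + 4 * lon) %% 1440
  ha <- tst / 4 - 180
  latr <- deg2rad(lat); decr <- deg2rad(decl); har <- deg2rad(ha)
  elev <- rad2deg(asin(sin(latr) * sin(decr) +
                         cos(latr) * cos(decr) * cos(har)))
  az <- (rad2deg(atan2(sin(har),
                       cos(har) * sin(latr) - tan(decr) * cos(latr))) +
           180) %% 360
  structure(az, elevation_deg = elev, low_sun = elev < 0)
}

#' Project one dance to field coordinates
#'
#' Field bearing = solar azimuth at dance time + comb angle (up = toward
#' the azimuth); distance from the mean waggle duration via the linear
#' calibration; map offsets east/north of the hive.
#'
#' @param dance list with `mean_duration_ms`, `comb_angle_deg` and either
#'   `start_time` (POSIXct) or nothing if `azimuth_deg` is given.
#' @param cfg a [mapping_config()].
#' @param azimuth_deg solar azimuth to use; computed from
#'   `dance$start_time` and the hive position when `NULL`.
#' @return list with `bearing_deg`, `distance_m`, `east_m`, `north_m` and
#'   `azimuth_deg`.
#' @export
project_dance <- function(dance, cfg, azimuth_deg = NULL) {
  if (is.null(azimuth_deg))
    azimuth_deg <- as.numeric(solar_azimuth(dance$start_time,
                                            cfg$hive_lat, cfg$hive_lon))
  bearing <- (azimuth_deg + dance$comb_angle_deg) %% 360
  distance <- duration_to_distance(dance$mean_duration_ms,
                                   cfg$distance_factor)
  list(bearing_deg = bearing, distance_m = distance,
       east_m = distance * sin(deg2rad(bearing)),
       north_m = distance * cos(deg2rad(bearing)),
       azimuth_deg = azimuth_deg %% 360)
}

#' Cluster, aggregate and map a table of decoded waggle runs
#'
#' The complete mapping module. Runs are embedded in (x, y, t), clustered
#' into dances, each dance's orientations are RANSAC-cleaned, waggle and
#' return durations averaged over inliers (returns only between
#' consecutive inlier runs), and the dance projected to the field.
#'
#' @param tbl run table with columns `x_px`, `y_px`, `start_s`,
#'   `duration_ms`, `orientation_deg` (from [run_table()] after decoding).
#' @param cfg a [mapping_config()].
#' @param recording_start POSIXct of the first video frame.
#' @param seed seed for the RANSAC draws.
#' @return data.frame with one row per dance: identifiers, run counts,
#'   mean durations, comb angle, field bearing/distance/position and
#'   profitability (NA when no return gap is available).
#' @export
map_dances <- function(tbl, cfg, recording_start, seed = NULL) {
  day_offset <- as.numeric(recording_start) -
    as.numeric(trunc(recording_start, "days"))
  pts <- xyt_embed(tbl, cfg, day_offset_s = day_offset)
  clusters <- cluster_dances(pts, cfg)
  rows <- list()
  did <- 0L
  for (idx in clusters) {
    idx <- idx[order(tbl$start_s[idx])]
    rr <- ransac_angles(tbl$orientation_deg[idx], cfg,
                        seed = if (is.null(seed)) NULL else seed + did)
    if (!rr$ok) next  # no strong orientation mode: not a usable dance
    did <- did + 1L
    inl <- idx[rr$inliers]
    d_w <- mean(tbl$duration_ms[inl])
    # return durations: gaps between consecutive inlier runs only
    gaps <- numeric(0)
    if (length(inl) > 1) {
      consec <- which(diff(match(inl, idx)) == 1)
      for (j in consec) {
        a <- inl[j]; b <- inl[j + 1]
        gap <- (tbl$start_s[b] - tbl$start_s[a]) * 1000 - tbl$duration_ms[a]
        if (gap > 0) gaps <- c(gaps, gap)
      }
    }
    d_r <- if (length(gaps)) mean(gaps) else NA_real_
    start_time <- recording_start + tbl$start_s[idx[1]]
    proj <- project_dance(list(mean_duration_ms = d_w,
                               comb_angle_deg = rr$mean_deg,
                               start_time = start_time), cfg)
    rows[[did]] <- data.frame(
      dance_id = did,
      start_iso = format(start_time, "%Y-%m-%dT%H:%M:%OS3%z"),
      n_runs = length(idx), n_inliers = rr$n_inliers,
      mean_duration_ms = d_w, mean_return_ms = d_r,
      comb_angle_deg = rr$mean_deg,
      bearing_deg = proj$bearing_deg, distance_m = proj$distance_m,
      profitability = if (is.na(d_r)) NA_real_ else profitability(d_w, d_r),
      east_m = proj$east_m, north_m = proj$north_m,
      weak_mode = rr$weak_mode)
  }
  if (!length(rows))
    return(data.frame(dance_id = integer(0), start_iso = character(0),
                      n_runs = integer(0), n_inliers = integer(0),
                      mean_duration_ms = numeric(0),
                      mean_return_ms = numeric(0),
                      comb_angle_deg = numeric(0), bearing_deg = numeric(0),
                      distance_m = numeric(0), profitability = numeric(0),
                      east_m = numeric(0), north_m = numeric(0),
                      weak_mode = logical(0)))
  do.call(rbind, rows)
}

#' GeoJSON of mapped dances
#'
#' Converts the east/north offsets to WGS84 via a local equirectangular
#' approximation around the hive.
#'
#' @param dances data.frame from [map_dances()].
#' @param cfg a [mapping_config()].
#' @param path output file.
#' @export
write_dances_geojson <- function(dances, cfg, path) {
  R_earth <- 6378137
  lat <- cfg$hive_lat + rad2deg(dances$north_m / R_earth)
  lon <- cfg$hive_lon +
    rad2deg(dances$east_m / (R_earth * cos(deg2rad(cfg$hive_lat))))
  feats <- lapply(seq_len(nrow(dances)), function(i) list(
    type = "Feature",
    geometry = list(type = "Point",
                    coordinates = c(lon[i], lat[i])),
    properties = list(dance_id = dances$dance_id[i],
                      n_runs = dances$n_runs[i],
                      bearing_deg = dances$bearing_deg[i],
                      distance_m = dances$distance_m[i])))
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
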