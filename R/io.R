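#' Recording metadata
#'
#' Per-recording facts the pipeline needs: when frame 0 happened, the
#' frame rate and scale, where the hive stands, and the four comb-corner
#' correspondences used to rectify perspective distortion.
#'
#' @param start_time POSIXct (or ISO-8601 string with zone) of the first
#'   frame.
#' @param frame_rate Hz.
#' @param px_per_mm scale of the rectified image.
#' @param hive_lat,hive_lon hive position in degrees.
#' @param corner_px 4 x 2 matrix of comb-corner image coordinates.
#' @param corner_mm 4 x 2 matrix of the same corners in comb millimetres.
#' @return object of class `recording_meta`.
#' @export
recording_meta <- function(start_time, frame_rate = 100, px_per_mm = 1.7,
                           hive_lat = 52.457, hive_lon = 13.296,
                           corner_px = NULL, corner_mm = NULL) {
  if (is.character(start_time))
    start_time <- as.POSIXct(start_time, format = "%Y-%m-%dT%H:%M:%S",
                             tz = "UTC")
  stopifnot(inherits(start_time, "POSIXt"), frame_rate > 0)
  if (!is.null(corner_px)) {
    corner_px <- as.matrix(corner_px); corner_mm <- as.matrix(corner_mm)
    if (nrow(corner_px) != 4 || nrow(corner_mm) != 4)
      stop("exactly 4 corner correspondences are required")
  }
  structure(list(start_time = start_time, frame_rate = frame_rate,
                 px_per_mm = px_per_mm, hive_lat = hive_lat,
                 hive_lon = hive_lon, corner_px = corner_px,
                 corner_mm = corner_mm), class = "recording_meta")
}

#' Read a frame directory as a grayscale video array
#'
#' PNG frames are read in lexicographic name order; colour frames are
#' converted with the fixed luma weights 0.299/0.587/0.114.
#'
#' @param source directory of `.png` frames, or a character vector of
#'   frame files.
#' @return height x width x T array of grey values in 0-255.
#' @export
read_frames <- function(source) {
  files <- if (length(source) == 1 && dir.exists(source))
    sort(list.files(source, pattern = "\\.png$", full.names = TRUE))
  else source
  if (!length(files) || !all(file.exists(files)))
    stop("no frames found in ", source[1])
  frames <- lapply(files, function(f) {
    img <- png::readPNG(f)
    if (length(dim(img)) == 3)
      img <- 0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
    img * 255
  })
  d <- dim(frames[[1]])
  if (!all(vapply(frames, function(f) identical(dim(f), d), TRUE)))
    stop("inconsistent frame sizes in ", source)
  array(unlist(frames), dim = c(d, length(frames)))
}

#' Write a video array as 8-bit grayscale PNG frames
#' @param dir output directory (created if missing).
#' @param frames height x width x T array of grey values in 0-255.
#' @export
write_frames <- function(dir, frames) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (t in seq_len(dim(frames)[3]))
    png::writePNG(pmin(pmax(frames[, , t], 0), 255) / 255,
                  file.path(dir, sprintf("frame_%06d.png", t)))
  invisible(dir)
}

## 4-point direct linear transform; maps (x, y) -> (x', y')
homography_from_points <- function(src, dst) {
  src <- as.matrix(src); dst <- as.matrix(dst)
  # reject degenerate configurations (any 3 source points collinear)
  for (tri in utils::combn(4, 3, simplify = FALSE)) {
    p <- src[tri, ]
    a <- abs((p[2, 1] - p[1, 1]) * (p[3, 2] - p[1, 2]) -
             (p[3, 1] - p[1, 1]) * (p[2, 2] - p[1, 2]))
    if (a < 1e-9) stop("degenerate corner correspondences (collinear)")
  }
  A <- matrix(0, 8, 8); b <- numeric(8)
  for (i in 1:4) {
    x <- src[i, 1]; y <- src[i, 2]; u <- dst[i, 1]; v <- dst[i, 2]
    A[2 * i - 1, ] <- c(x, y, 1, 0, 0, 0, -u * x, -u * y)
    A[2 * i, ] <- c(0, 0, 0, x, y, 1, -v * x, -v * y)
    b[2 * i - 1] <- u; b[2 * i] <- v
  }
  h <- solve(A, b)
  matrix(c(h, 1), 3, 3, byrow = TRUE)
}

apply_homography <- function(H, xy) {
  xy1 <- cbind(xy, 1) %*% t(H)
  xy1[, 1:2] / xy1[, 3]
}

#' Rectify a frame using the comb-corner correspondences
#'
#' Estimates the homography taking the four observed corner positions to
#' the rectangular comb reference (at `px_per_mm` scale) and inversely
#' warps the frame with bilinear interpolation. Pixels mapping outside
#' the source are zero.
#'
#' @param frame height x width grey matrix.
#' @param meta a [recording_meta()] with corner correspondences.
#' @return rectified matrix of size `diff(range(corner_mm)) * px_per_mm`.
#' @export
rectify <- function(frame, meta) {
  if (is.null(meta$corner_px)) stop("meta has no corner correspondences")
  mm <- meta$corner_mm
  tgt <- cbind((mm[, 1] - min(mm[, 1])) * meta$px_per_mm + 1,
               (mm[, 2] - min(mm[, 2])) * meta$px_per_mm + 1)
  W <- round(max(tgt[, 1])); H <- round(max(tgt[, 2]))
  Hmat <- homography_from_points(meta$corner_px, tgt)
  Hinv <- solve(Hmat)
  grid <- cbind(rep(seq_len(W), each = H), rep(seq_len(H), times = W))
  src <- apply_homography(Hinv, grid)
  bilinear_sample(frame, src[, 1], src[, 2], W, H)
}

bilinear_sample <- function(img, x, y, W, H) {
  h <- nrow(img); w <- ncol(img)
  x0 <- floor(x); y0 <- floor(y)
  fx <- x - x0; fy <- y - y0
  ok <- x0 >= 1 & x0 <= w - 1 & y0 >= 1 & y0 <= h - 1
  val <- numeric(length(x))
  i00 <- (x0 - 1) * h + y0
  v00 <- img[i00[ok]]; v01 <- img[i00[ok] + h]
  v10 <- img[i00[ok] + 1]; v11 <- img[i00[ok] + h + 1]
  val[ok] <- v00 * (1 - fx[ok]) * (1 - fy[ok]) +
    v01 * fx[ok] * (1 - fy[ok]) + v10 * (1 - fx[ok]) * fy[ok] +
    v11 * fx[ok] * fy[ok]
  matrix(val, nrow = H, ncol = W)
}

#' Write / read detected runs as snippet directories plus a run table
#'
#' Each run gets a `wr_<id>/` directory with `frame_%04d.png` snippets and
#' a `meta.json` (frame indices and centroids); `runs.csv` summarises all
#' runs.
#'
#' @param dir output directory.
#' @param runs list of `waggle_run`s carrying `$snippet`.
#' @param sample_rate Hz for the run table.
#' @export
write_detections <- function(dir, runs, sample_rate = 100) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (r in runs) {
    sub <- file.path(dir, sprintf("wr_%04d", r$id))
    dir.create(sub, showWarnings = FALSE)
    sn <- r$snippet
    for (t in seq_len(dim(sn$frames)[3]))
      png::writePNG(pmin(pmax(sn$frames[, , t], 0), 255) / 255,
                    file.path(sub, sprintf("frame_%04d.png", t)))
    jsonlite::write_json(sn$meta, file.path(sub, "meta.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  write.csv(run_table(runs, sample_rate), file.path(dir, "runs.csv"),
            row.names = FALSE)
  invisible(dir)
}

#' @rdname write_detections
#' @export
read_detections <- function(dir) {
  tbl <- read.csv(file.path(dir, "runs.csv"))
  runs <- lapply(seq_len(nrow(tbl)), function(i) {
    sub <- file.path(dir, sprintf("wr_%04d", tbl$id[i]))
    meta <- jsonlite::read_json(file.path(sub, "meta.json"),
                                simplifyVector = TRUE)
    meta$centroids <- matrix(unlist(meta$centroids), ncol = 2,
                             dimnames = list(NULL, c("x", "y")))
    frames <- read_frames(sub)
    structure(list(
      id = tbl$id[i], start_frame = min(meta$frames),
      end_frame = max(meta$frames),
      duration_ms = tbl$duration_ms[i],
      positions = data.frame(frame = meta$frames,
                             x = meta$centroids[, 1],
                             y = meta$centroids[, 2]),
      comb_xy = c(tbl$x_px[i], tbl$y_px[i]),
      orientation_deg = tbl$orientation_deg[i],
      confidence = tbl$confidence[i],
      snippet = list(frames = frames, meta = meta)
    ), class = "waggle_run")
  })
  runs
}

#' Pipeline configuration bundle
#'
#' @param attention,orientation,mapping,filter,scene the per-stage
#'   configurations.
#' @param seed master seed for the pipeline run.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(attention = attention_config(),
                            orientation = orientation_config(),
                            mapping = mapping_config(),
                            filter = filter_config(),
                            scene = scene_config(), seed = NULL) {
  if (!isTRUE(all.equal(orientation$frame_rate, attention$sample_rate)))
    stop("orientation frame_rate must equal attention sample_rate")
  structure(list(attention = attention, orientation = orientation,
                 mapping = mapping, filter = filter, scene = scene,
                 seed = seed), class = "pipeline_config")
}

#' Write / read a pipeline configuration as YAML
#'
#' Serialisation is a fixed point: write-read-write reproduces the file.
#'
#' @param cfg a [pipeline_config()].
#' @param path YAML file path.
#' @export
write_pipeline_config <- function(cfg, path) {
  plain <- lapply(unclass(cfg)[c("attention", "orientation", "mapping",
                                 "filter", "scene")], unclass)
  plain$seed <- cfg$seed
  yaml::write_yaml(plain, path)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  pipeline_config(
    attention = do.call(attention_config, y$attention),
    orientation = do.call(orientation_config, y$orientation),
    mapping = do.call(mapping_config, y$mapping),
    filter = do.call(filter_config,
                     y$filter[setdiff(names(y$filter), "optimizer")]),
    scene = do.call(scene_config,
                    stats::setNames(y$scene[c("frame_rate", "width",
                      "height", "px_per_mm", "bee_length_mm",
                      "waggle_freq_hz", "lateral_amplitude_px",
                      "forward_speed_px_per_frame", "noise_sd",
                      "n_distractors", "bee_intensity", "background",
                      "gradient", "edge_sigma_px")],
                      c("frame_rate", "width", "height", "px_per_mm",
                        "bee_length_mm", "waggle_freq_hz",
                        "lateral_amplitude_px",
                        "forward_speed_px_per_frame", "noise_sd",
                        "n_distractors", "bee_intensity", "background",
                        "gradient", "edge_sigma_px"))),
    seed = y$seed)
}

#' Run the full pipeline on a video
#'
#' Detect (attention module), optionally filter (network), decode
#' orientations, and map dances. Artifacts (run table, dance table,
#' manifest) are written when `out_dir` is given; stage failures are
#' recorded in the manifest and later stages skipped.
#'
#' @param source video array or frame directory.
#' @param cfg a [pipeline_config()].
#' @param meta a [recording_meta()].
#' @param out_dir optional artifact directory.
#' @param filter_model optional trained [build_filternet()] model; `NULL`
#'   skips the filtering stage.
#' @return list with `runs`, `run_table`, `dances` and `manifest`.
#' @export
run_pipeline <- function(source, cfg, meta, out_dir = NULL,
                         filter_model = NULL) {
  frames <- if (is.character(source)) read_frames(source) else source
  manifest <- list(package_version = as.character(
    utils::packageVersion("beewaggle")), seed = cfg$seed,
    filtered = !is.null(filter_model), stages = list())
  runs <- list(); dances <- NULL; tbl <- NULL
  ok <- TRUE
  stage <- function(name, expr) {
    if (!ok) {
      manifest$stages[[name]] <<- list(status = "skipped")
      return(NULL)
    }
    tryCatch(expr, error = function(e) {
      manifest$stages[[name]] <<- list(status = "error",
                                       message = conditionMessage(e))
      ok <<- FALSE
      NULL
    })
  }
  # stage expressions are promises evaluated in this frame, so plain
  # assignment updates run_pipeline's locals
  stage("detect", {
    runs <- detect_waggle_runs(frames, cfg$attention)
    manifest$stages$detect <- list(status = "ok", n_runs = length(runs))
  })
  if (!is.null(filter_model)) stage("filter", {
    runs <- filter_runs(runs, filter_model)
    manifest$stages$filter <- list(
      status = "ok",
      n_rejected = sum(vapply(runs, function(r) isTRUE(r$rejected), TRUE)))
  })
  stage("decode", {
    runs <- lapply(runs, decode_run, cfg = cfg$orientation)
    manifest$stages$decode <- list(status = "ok", n_decoded = length(runs))
  })
  stage("map", {
    tbl <- run_table(runs, cfg$attention$sample_rate)
    keep <- if (!is.null(filter_model))
      !vapply(runs, function(r) isTRUE(r$rejected), TRUE)
    else rep(TRUE, length(runs))
    dances <- map_dances(tbl[keep, , drop = FALSE], cfg$mapping,
                         meta$start_time, seed = cfg$seed)
    manifest$stages$map <- list(status = "ok", n_dances = nrow(dances))
  })
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!is.null(tbl))
      write.csv(tbl, file.path(out_dir, "runs.csv"), row.names = FALSE)
    if (!is.null(dances))
      write.csv(dances, file.path(out_dir, "dances.csv"),
                row.names = FALSE)
    cfg_path <- file.path(out_dir, "config.yaml")
    write_pipeline_config(cfg, cfg_path)
    manifest$config_md5 <- unname(tools::md5sum(cfg_path))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  list(runs = runs, run_table = tbl, dances = dances, manifest = manifest)
}
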