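#' Scene configuration for the synthetic dance renderer
#'
#' The renderer draws honey bees as bright, textureless ellipsoidal blobs
#' (axis ratio 2.5:1) on a darker comb background, the way low-resolution
#' observation-hive footage shows them. During a waggle run the blob advances
#' along its body axis while oscillating perpendicular to it as a pure
#' sinusoid at `waggle_freq_hz`.
#'
#' Defaults reproduce the recording conditions the pipeline is designed for:
#' 100 Hz frame rate, 1.7 px/mm, a 14 mm bee and a 13 Hz waggle whose lateral
#' sweep peaks at about 6 px/frame. Forward progress is much slower than the
#' lateral sweep; a dancer advances roughly one body length per run.
#'
#' @param frame_rate frames per second (Hz). Must exceed twice the waggle
#'   frequency so the oscillation is sampleable.
#' @param width,height frame size in px.
#' @param px_per_mm spatial scale.
#' @param bee_length_mm body length; the blob is `bee_length_mm * px_per_mm`
#'   px long and 2.5 times shorter across.
#' @param waggle_freq_hz lateral oscillation frequency during waggle runs.
#' @param lateral_amplitude_px peak lateral displacement from the run axis.
#' @param forward_speed_px_per_frame advance along the run axis per frame.
#' @param noise_sd additive Gaussian sensor noise (8-bit intensity units).
#' @param n_distractors number of non-dancing bees doing a slow random walk.
#' @param bee_intensity,background blob and comb grey levels (0-255).
#' @param gradient peak-to-peak amplitude of a static horizontal
#'   illumination gradient added to the background.
#' @param edge_sigma_px Gaussian softness of the blob edge.
#' @param seed integer seed for all randomness of a render call; `NULL`
#'   uses the current RNG stream.
#' @return object of class `scene_config`.
#' @export
scene_config <- function(frame_rate = 100, width = 120, height = 120,
                         px_per_mm = 1.7, bee_length_mm = 14,
                         waggle_freq_hz = 13, lateral_amplitude_px = 7,
                         forward_speed_px_per_frame = 0.5,
                         noise_sd = 3, n_distractors = 0,
                         bee_intensity = 200, background = 40,
                         gradient = 0, edge_sigma_px = 1.2, seed = NULL) {
  if (frame_rate <= 2 * waggle_freq_hz)
    stop("frame_rate must exceed twice waggle_freq_hz (Nyquist)")
  for (nm in c("frame_rate", "width", "height", "px_per_mm", "bee_length_mm",
               "waggle_freq_hz", "forward_speed_px_per_frame", "edge_sigma_px"))
    stop_if_not_scalar_pos(get(nm), nm)
  if (lateral_amplitude_px < 0 || noise_sd < 0 || n_distractors < 0)
    stop("lateral_amplitude_px, noise_sd and n_distractors must be >= 0")
  structure(list(
    frame_rate = frame_rate, width = width, height = height,
    px_per_mm = px_per_mm, bee_length_mm = bee_length_mm,
    waggle_freq_hz = waggle_freq_hz,
    lateral_amplitude_px = lateral_amplitude_px,
    forward_speed_px_per_frame = forward_speed_px_per_frame,
    noise_sd = noise_sd, n_distractors = n_distractors,
    bee_intensity = bee_intensity, background = background,
    gradient = gradient, edge_sigma_px = edge_sigma_px, seed = seed
  ), class = "scene_config")
}

#' @export
print.scene_config <- function(x, ...) {
  cat("Synthetic scene:", x$width, "x", x$height, "px @", x$frame_rate, "Hz,",
      x$px_per_mm, "px/mm\n")
  cat("  waggle:", x$waggle_freq_hz, "Hz, lateral amplitude",
      x$lateral_amplitude_px, "px, forward", x$forward_speed_px_per_frame,
      "px/frame\n")
  cat("  noise sd", x$noise_sd, ", distractors:", x$n_distractors, "\n")
  invisible(x)
}

#' Ground-truth record for one rendered waggle run
#'
#' @param start_frame 1-based index of the first waggle frame in the
#'   rendered sequence.
#' @param n_frames number of waggle frames.
#' @param start_xy numeric c(x, y): blob center at the start of the run.
#' @param orientation_deg body heading, degrees clockwise from image up.
#' @param label `"waggle"` or `"non_waggle"`.
#' @return object of class `ground_truth_run`.
#' @export
ground_truth_run <- function(start_frame, n_frames, start_xy,
                             orientation_deg, label = "waggle") {
  if (n_frames < 1) stop("n_frames must be >= 1")
  structure(list(
    start_frame = as.integer(start_frame), n_frames = as.integer(n_frames),
    start_xy = as.numeric(start_xy),
    orientation_deg = orientation_deg %% 360,
    label = match.arg(label, c("waggle", "non_waggle"))
  ), class = "ground_truth_run")
}

bee_semi_axes <- function(cfg) {
  len <- cfg$bee_length_mm * cfg$px_per_mm
  c(a = len / 2, b = len / 5)  # 2.5:1 full-axis ratio
}

## Evaluate the scene (background + composited bee blobs, no noise) on the
## pixel grid xs (columns) x ys (rows). `bees` is a list of
## list(xy = c(x, y), heading_deg =) entries. Returns length(ys) x length(xs).
scene_values <- function(cfg, xs, ys, bees) {
  ax <- bee_semi_axes(cfg)
  img <- matrix(cfg$background, nrow = length(ys), ncol = length(xs))
  if (cfg$gradient != 0)
    img <- img + matrix(rep(cfg$gradient * (xs / cfg$width - 0.5),
                            each = length(ys)), nrow = length(ys))
  X <- matrix(rep(xs, each = length(ys)), nrow = length(ys))
  Y <- matrix(rep(ys, times = length(xs)), nrow = length(ys))
  for (bee in bees) {
    h <- heading_vector(bee$heading_deg)
    p <- c(-h[2], h[1])  # perpendicular (right of heading)
    dx <- X - bee$xy[1]; dy <- Y - bee$xy[2]
    u <- dx * h[1] + dy * h[2]
    v <- dx * p[1] + dy * p[2]
    d <- sqrt((u / ax["a"])^2 + (v / ax["b"])^2)
    s <- stats::pnorm((1 - d) * ax["b"] / cfg$edge_sigma_px)
    img <- img * (1 - s) + cfg$bee_intensity * s
  }
  img
}

finish_frame <- function(cfg, img) {
  if (cfg$noise_sd > 0)
    img <- img + matrix(rnorm(length(img), sd = cfg$noise_sd), nrow = nrow(img))
  round(pmin(pmax(img, 0), 255))
}

## Waggle-run center path (base path + lateral sinusoid), frames t = 1..n.
waggle_path <- function(cfg, start_xy, orientation_deg, n_frames,
                        phase = 0) {
  h <- heading_vector(orientation_deg)
  p <- c(-h[2], h[1])
  t <- seq_len(n_frames) - 1
  base <- cbind(start_xy[1] + h[1] * cfg$forward_speed_px_per_frame * t,
                start_xy[2] + h[2] * cfg$forward_speed_px_per_frame * t)
  off <- cfg$lateral_amplitude_px *
    sin(2 * pi * cfg$waggle_freq_hz * t / cfg$frame_rate + phase)
  list(base = base, center = cbind(base[, 1] + off * p[1],
                                   base[, 2] + off * p[2]))
}

new_distractors <- function(cfg) {
  if (cfg$n_distractors == 0) return(list())
  lapply(seq_len(cfg$n_distractors), function(i)
    list(xy = c(runif(1, 10, cfg$width - 10), runif(1, 10, cfg$height - 10)),
         heading_deg = runif(1, 0, 360)))
}

## slow random walk, never faster than 3 px/frame (stays out of the
## waggle band by construction)
step_distractors <- function(dstr) {
  lapply(dstr, function(b) {
    st <- pmin(pmax(rnorm(2, sd = 1), -3), 3) / sqrt(2)
    b$xy <- b$xy + st
    b$heading_deg <- (b$heading_deg + rnorm(1, sd = 3)) %% 360
    b
  })
}

check_in_frame <- function(cfg, centers, offset = 0L) {
  bad <- which(centers[, 1] < 1 | centers[, 1] > cfg$width |
               centers[, 2] < 1 | centers[, 2] > cfg$height)
  if (length(bad))
    stop(sprintf("bee trajectory leaves the frame at frame %d",
                 bad[1] + offset))
}

#' Render a single waggle run
#'
#' Renders a full-frame grayscale sequence containing one dancer. Frames
#' before `truth$start_frame` and after the run show the bee standing still
#' at the path endpoints, which mimics a dancer pausing before and after the
#' waggle phase and gives detectors a warm-up period.
#'
#' @param cfg a [scene_config()].
#' @param truth a [ground_truth_run()] with `label = "waggle"`.
#' @param tail_frames extra stationary frames after the run ends.
#' @param seed overrides `cfg$seed`.
#' @return list with `frames` (height x width x T array, 8-bit grey values)
#'   and `truth` (the input record).
#' @export
render_waggle_run <- function(cfg, truth, tail_frames = 0L, seed = cfg$seed) {
  stopifnot(inherits(cfg, "scene_config"), inherits(truth, "ground_truth_run"))
  if (truth$label != "waggle") stop("truth$label must be 'waggle'")
  with_seed(seed, {
    path <- waggle_path(cfg, truth$start_xy, truth$orientation_deg,
                        truth$n_frames)
    check_in_frame(cfg, path$center, offset = truth$start_frame - 1L)
    n_total <- truth$start_frame - 1L + truth$n_frames + as.integer(tail_frames)
    frames <- array(0, dim = c(cfg$height, cfg$width, n_total))
    dstr <- new_distractors(cfg)
    for (t in seq_len(n_total)) {
      k <- t - truth$start_frame + 1L
      xy <- if (k < 1) path$center[1, ]
            else if (k > truth$n_frames) path$center[truth$n_frames, ]
            else path$center[k, ]
      bees <- c(list(list(xy = xy, heading_deg = truth$orientation_deg)), dstr)
      frames[, , t] <- finish_frame(cfg,
        scene_values(cfg, seq_len(cfg$width), seq_len(cfg$height), bees))
      dstr <- step_distractors(dstr)
    }
    list(frames = frames, truth = truth)
  })
}

#' Render a waggle run as a tracked 50x50 snippet
#'
#' Produces the view the attention module exports: a small window riding
#' along the dancer's mean path, so the lateral 13 Hz oscillation stays
#' visible inside the crop. Also returns the absolute blob positions used
#' later for direction disambiguation.
#'
#' @inheritParams render_waggle_run
#' @param orientation_deg true body heading of the run.
#' @param n_frames run length in frames.
#' @param size crop side length in px.
#' @param position_noise_sd Gaussian jitter added to the reported per-frame
#'   positions, emulating detector centroid noise.
#' @return list with `frames` (size x size x n_frames), `positions`
#'   (n_frames x 2 absolute xy of the tracked window center, jittered) and
#'   `truth`.
#' @export
render_run_snippet <- function(cfg, orientation_deg, n_frames, size = 50,
                               position_noise_sd = 1, seed = cfg$seed) {
  stopifnot(inherits(cfg, "scene_config"))
  with_seed(seed, {
    phase <- runif(1, 0, 2 * pi)
    path <- waggle_path(cfg, c(0, 0), orientation_deg, n_frames, phase = phase)
    frames <- array(0, dim = c(size, size, n_frames))
    half <- (size - 1) / 2
    for (t in seq_len(n_frames)) {
      xs <- path$base[t, 1] + seq(-half, half)
      ys <- path$base[t, 2] + seq(-half, half)
      bees <- list(list(xy = path$center[t, ], heading_deg = orientation_deg))
      frames[, , t] <- finish_frame(cfg, scene_values(cfg, xs, ys, bees))
    }
    pos <- path$base
    if (position_noise_sd > 0)
      pos <- pos + matrix(rnorm(2 * n_frames, sd = position_noise_sd),
                          ncol = 2)
    truth <- ground_truth_run(1L, n_frames, path$base[1, ], orientation_deg)
    list(frames = frames, positions = pos, truth = truth)
  })
}

#' Render a full dance (alternating waggle and return phases)
#'
#' Waggle-phase orientations are drawn from a circular normal around
#' `base_orientation_deg`; return phases follow a semicircular arc back to
#' the neighbourhood of the previous start, with clockwise and
#' counter-clockwise returns alternating so the path traces a figure eight.
#'
#' @inheritParams render_waggle_run
#' @param n_runs number of waggle phases (>= 1).
#' @param base_orientation_deg dance direction on the comb.
#' @param run_angle_sd_deg SD of per-run orientation draws (waggle-level
#'   angular spread).
#' @param run_duration_frames,return_duration_frames phase lengths.
#' @param start_xy first waggle start position; defaults to frame center.
#' @param start_drift_sd_px SD of the drift of successive waggle start
#'   points.
#' @param render if `FALSE`, skip rasterisation and return geometry plus
#'   ground truth only (fast path for large experiments).
#' @return list with `frames` (array, or `NULL` when `render = FALSE`) and
#'   `truth` (list of [ground_truth_run()] records, one per waggle phase).
#' @export
render_dance <- function(cfg, n_runs, base_orientation_deg,
                         run_angle_sd_deg = 14.37,
                         run_duration_frames = 58,
                         return_duration_frames = 150,
                         start_xy = c(cfg$width / 2, cfg$height / 2),
                         start_drift_sd_px = 2, render = TRUE,
                         seed = cfg$seed) {
  stopifnot(inherits(cfg, "scene_config"), n_runs >= 1)
  with_seed(seed, {
    ori <- (base_orientation_deg + rnorm(n_runs, sd = run_angle_sd_deg)) %% 360
    dur <- rep_len(run_duration_frames, n_runs)
    starts <- matrix(0, n_runs, 2)
    starts[1, ] <- start_xy
    if (n_runs > 1)
      for (i in 2:n_runs)
        starts[i, ] <- starts[1, ] + rnorm(2, sd = start_drift_sd_px)
    truth <- vector("list", n_runs)
    segs <- list()
    frame_at <- 1L
    for (i in seq_len(n_runs)) {
      path <- waggle_path(cfg, starts[i, ], ori[i], dur[i])
      truth[[i]] <- ground_truth_run(frame_at, dur[i], starts[i, ], ori[i])
      segs[[length(segs) + 1L]] <- list(centers = path$center,
                                        headings = rep(ori[i], dur[i]))
      frame_at <- frame_at + dur[i]
      if (i < n_runs) {
        arc <- return_arc(path$center[dur[i], ], starts[i + 1, ],
                          clockwise = (i %% 2 == 1L),
                          n = return_duration_frames)
        segs[[length(segs) + 1L]] <- arc
        frame_at <- frame_at + nrow(arc$centers)
      }
    }
    centers <- do.call(rbind, lapply(segs, `[[`, "centers"))
    headings <- unlist(lapply(segs, `[[`, "headings"))
    frames <- NULL
    if (render) {
      check_in_frame(cfg, centers)
      frames <- array(0, dim = c(cfg$height, cfg$width, nrow(centers)))
      dstr <- new_distractors(cfg)
      for (t in seq_len(nrow(centers))) {
        bees <- c(list(list(xy = centers[t, ], heading_deg = headings[t])),
                  dstr)
        frames[, , t] <- finish_frame(cfg,
          scene_values(cfg, seq_len(cfg$width), seq_len(cfg$height), bees))
        dstr <- step_distractors(dstr)
      }
    }
    list(frames = frames, truth = truth, centers = centers,
         headings = headings)
  })
}

## Semicircular arc from a to b, bulging to the chosen side; bee heading
## follows the tangent.
return_arc <- function(a, b, clockwise, n) {
  mid <- (a + b) / 2
  r <- sqrt(sum((b - a)^2)) / 2
  phi_a <- atan2(a[2] - mid[2], a[1] - mid[1])
  dphi <- if (clockwise) pi else -pi
  phis <- phi_a + dphi * seq_len(n) / n
  centers <- cbind(mid[1] + r * cos(phis), mid[2] + r * sin(phis))
  # tangent of the parametrisation; heading from consecutive points
  tang <- rbind(centers[2, ] - centers[1, ],
                diff(centers))
  headings <- vector_heading(tang[, 1], tang[, 2])
  list(centers = centers, headings = headings)
}

#' Render a non-dancing 50x50 snippet
#'
#' Negative examples for the filter network: behaviours that lack a
#' sustained 10-16 Hz lateral oscillation.
#'
#' @inheritParams render_run_snippet
#' @param kind `"walking"` (straight walk through the window, no
#'   oscillation), `"stationary"` (still bee, sensor noise only) or
#'   `"grooming_jitter"` (a brief oscillation pulse shorter than 200 ms).
#' @param walk_speed_px_per_frame walking speed.
#' @param pulse_ms duration of the grooming oscillation pulse.
#' @return list with `frames` (size x size x n_frames) and `label`
#'   (`"non_waggle"`).
#' @export
render_non_waggle_snippet <- function(cfg, kind = c("walking", "stationary",
                                                    "grooming_jitter"),
                                      n_frames = 128, size = 50,
                                      walk_speed_px_per_frame = 3,
                                      pulse_ms = 150, seed = cfg$seed) {
  kind <- match.arg(kind)
  stopifnot(inherits(cfg, "scene_config"))
  with_seed(seed, {
    half <- (size - 1) / 2
    ctr <- c(half + 1, half + 1)
    heading <- runif(1, 0, 360)
    h <- heading_vector(heading)
    p <- c(-h[2], h[1])
    frames <- array(0, dim = c(size, size, n_frames))
    pulse_n <- round(pulse_ms / 1000 * cfg$frame_rate)
    pulse_start <- if (n_frames > pulse_n + 1)
      sample.int(n_frames - pulse_n, 1) else 1L
    for (t in seq_len(n_frames)) {
      xy <- switch(kind,
        walking = ctr + h * walk_speed_px_per_frame * (t - 1 - n_frames / 2),
        stationary = ctr,
        grooming_jitter = {
          k <- t - pulse_start
          off <- if (k >= 0 && k < pulse_n)
            cfg$lateral_amplitude_px *
              sin(2 * pi * cfg$waggle_freq_hz * k / cfg$frame_rate)
          else 0
          ctr + off * p
        })
      bees <- list(list(xy = xy, heading_deg = heading))
      frames[, , t] <- finish_frame(cfg,
        scene_values(cfg, seq_len(size), seq_len(size), bees))
    }
    list(frames = frames, label = "non_waggle", kind = kind)
  })
}

#' Render a balanced labeled corpus for filter-network training
#'
#' Waggle examples are tracked run snippets with uniform random
#' orientations and run lengths; non-waggle examples cycle through the
#' walking / stationary / grooming-jitter behaviours.
#'
#' @param n_waggle,n_non_waggle class sizes.
#' @param cfg a [scene_config()]; its noise and motion settings apply to
#'   both classes.
#' @param frame_range run/clip lengths are drawn uniformly from this
#'   range (frames).
#' @param size snippet side length in px.
#' @param seed master seed for the whole corpus.
#' @return list of [labeled_clip()]s, waggle first.
#' @export
render_filter_corpus <- function(n_waggle, n_non_waggle, cfg,
                                 frame_range = c(40, 140), size = 50,
                                 seed = cfg$seed) {
  with_seed(seed, {
    kinds <- c("walking", "stationary", "grooming_jitter")
    wag <- lapply(seq_len(n_waggle), function(i) {
      sn <- render_run_snippet(cfg, runif(1, 0, 360),
                               sample(frame_range[1]:frame_range[2], 1),
                               size = size, seed = NULL)
      labeled_clip(sn$frames, "waggle")
    })
    non <- lapply(seq_len(n_non_waggle), function(i) {
      sn <- render_non_waggle_snippet(
        cfg, kinds[(i - 1) %% 3 + 1],
        n_frames = sample(frame_range[1]:frame_range[2], 1),
        size = size, seed = NULL)
      labeled_clip(sn$frames, "non_waggle")
    })
    c(wag, non)
  })
}

#' Write a rendered scene to a frame directory with its ground-truth log
#'
#' Frames go to `frame_%06d.png` (8-bit grayscale) and the run records to
#' `ground_truth.json`.
#'
#' @param dir output directory (created if missing).
#' @param frames height x width x T array of grey values in 0-255.
#' @param truth list of [ground_truth_run()] records (or a single record).
#' @export
write_scene <- function(dir, frames, truth = list()) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_frames(dir, frames)
  if (inherits(truth, "ground_truth_run")) truth <- list(truth)
  recs <- lapply(truth, function(tr)
    list(start_frame = tr$start_frame, n_frames = tr$n_frames,
         start_xy = tr$start_xy, orientation_deg = tr$orientation_deg,
         label = tr$label))
  jsonlite::write_json(recs, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a ground-truth log written by [write_scene()]
#' @param path a scene directory or the json file itself.
#' @return list of [ground_truth_run()] records.
#' @export
read_ground_truth <- function(path) {
  if (dir.exists(path)) path <- file.path(path, "ground_truth.json")
  recs <- jsonlite::read_json(path, simplifyVector = FALSE)
  lapply(recs, function(r)
    ground_truth_run(r$start_frame, r$n_frames, unlist(r$start_xy),
                     r$orientation_deg, r$label))
}
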