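#' Attention-module configuration
#'
#' Parameters of the real-time waggle detector: per-pixel spectral scoring
#' in the waggle band, spatial clustering of activated detectors, and
#' assembly of per-frame dancer positions into waggle runs.
#'
#' @param window_len sliding-window length b in frames. 32 frames at 100 Hz
#'   is 0.32 s, roughly four waggle cycles.
#' @param sample_rate video sample rate s_r in Hz.
#' @param waggle_band frequencies (Hz) probed by every dot detector; each
#'   must lie below the Nyquist frequency.
#' @param score_threshold activation threshold t_h on the waggle-band
#'   periodogram score. Because of the min-max normalisation the score of
#'   pure sensor noise follows one fixed null distribution whatever the
#'   noise level; the default 130 sits at that null's ~1e-6 tail, so
#'   chance activations are rare even over millions of pixel windows,
#'   while bee-edge pixels in a real waggle score several times higher
#'   (a full-range pure tone scores (b/2)^2 = 256). Use
#'   [calibrate_threshold()] to re-derive it for other window lengths.
#' @param cluster_dist merge threshold d_max1 (px) for single-linkage
#'   clustering of activated pixels; half a bee body length.
#' @param min_cluster_size clusters with fewer activated detectors than
#'   c_min1 are discarded as noise.
#' @param link_dist max distance d_max2 (px) between successive positions
#'   of one run.
#' @param max_gap frames g_max2 a run candidate may go without new
#'   detections before it is closed.
#' @param min_run_detections minimum detections c_min2 per emitted run.
#' @param min_run_ms minimum run duration; 200 ms corresponds to about
#'   three body oscillations and suppresses non-dance body shaking.
#' @param snippet_size side length of exported image snippets (px).
#' @param px_per_mm spatial scale used for the `cluster_dist` default.
#' @return object of class `attention_config`.
#' @export
attention_config <- function(window_len = 32, sample_rate = 100,
                             waggle_band = 10:16, score_threshold = 130,
                             cluster_dist = 0.5 * 14 * px_per_mm,
                             min_cluster_size = 4, link_dist = 12,
                             max_gap = 10, min_run_detections = 10,
                             min_run_ms = 200, snippet_size = 50,
                             px_per_mm = 1.7) {
  if (window_len < 2) stop("window_len must be >= 2")
  if (any(waggle_band >= sample_rate / 2))
    stop("every waggle-band frequency must be below sample_rate / 2")
  if (cluster_dist <= 0 || link_dist <= 0)
    stop("cluster_dist and link_dist must be positive")
  if (min_cluster_size < 1 || min_run_detections < 1)
    stop("min_cluster_size and min_run_detections must be >= 1")
  structure(list(
    window_len = as.integer(window_len), sample_rate = sample_rate,
    waggle_band = as.numeric(waggle_band),
    score_threshold = score_threshold, cluster_dist = cluster_dist,
    min_cluster_size = as.integer(min_cluster_size), link_dist = link_dist,
    max_gap = as.integer(max_gap),
    min_run_detections = as.integer(min_run_detections),
    min_run_ms = min_run_ms, snippet_size = as.integer(snippet_size),
    px_per_mm = px_per_mm
  ), class = "attention_config")
}

#' Min-max normalise a full pixel window to [-1, 1]
#'
#' Maps the window's minimum to -1 and maximum to +1, which makes the
#' detector invariant to illumination gain and offset. A constant window
#' returns all zeros, so flat pixels can never activate.
#'
#' @param B numeric vector of the last `window_len` intensity values.
#' @param window_len expected window length; an incomplete buffer signals
#'   a warm-up error rather than a score.
#' @return numeric vector in [-1, 1].
#' @export
normalize_window <- function(B, window_len = length(B)) {
  if (length(B) < window_len)
    stop("warm-up: pixel buffer not yet full", call. = FALSE)
  mn <- min(B); mx <- max(B)
  if (mx == mn) return(rep(0, length(B)))
  2 * (B - mn) / (mx - mn) - 1
}

#' Dot-detector score at one frequency
#'
#' Squared magnitude of the projection of a normalised pixel window onto
#' the complex exponential at frequency `r`: the periodogram ordinate
#' `(sum B(m) cos(2 pi r m / s_r))^2 + (sum B(m) sin(...))^2`.
#'
#' @param B_norm normalised window (see [normalize_window()]).
#' @param r probe frequency in Hz; must be below `s_r / 2`.
#' @param s_r sample rate in Hz.
#' @return nonnegative scalar; about `(b/2)^2` for a full-range pure tone
#'   at `r`.
#' @export
dd_score <- function(B_norm, r, s_r) {
  if (r >= s_r / 2) stop("probe frequency r must be below s_r / 2")
  m <- seq_along(B_norm)
  w <- 2 * pi * r * m / s_r
  sum(B_norm * cos(w))^2 + sum(B_norm * sin(w))^2
}

#' Activated dot detectors for every frame of a video
#'
#' Runs the sliding-window waggle-band scoring over all pixels. A pixel is
#' activated at frame n when the maximum score over the waggle band of its
#' window ending at n reaches `score_threshold`.
#'
#' @param frames height x width x T array of grey values.
#' @param cfg an [attention_config()].
#' @return list of length T; element n is a k x 2 integer matrix of
#'   activated positions (columns x, y). Warm-up frames give empty
#'   matrices.
#' @export
activate_detectors <- function(frames, cfg) {
  stopifnot(inherits(cfg, "attention_config"), length(dim(frames)) == 3)
  acts <- cpp_dd_activations(frames, cfg$window_len, cfg$waggle_band,
                             cfg$sample_rate, cfg$score_threshold)
  lapply(acts, function(m) {
    colnames(m) <- c("x", "y")
    m
  })
}

#' Calibrate the activation threshold on a bee-free clip
#'
#' Chooses t_h as the (1 - fp_rate) quantile of the max-over-band scores
#' of a recording that contains no bees, so at most `fp_rate` of
#' noise-driven pixel windows activate. The default rate keeps the
#' expected number of chance activations per frame far below one pixel
#' even at full-frame resolution (a few spurious pixels per frame would
#' chain into fake clusters under single linkage).
#'
#' @param frames bee-free video array.
#' @param cfg an [attention_config()] (its threshold is ignored).
#' @param fp_rate tolerated per-window false-positive activation rate.
#' @return calibrated threshold value.
#' @export
calibrate_threshold <- function(frames, cfg, fp_rate = 1e-6) {
  sc <- cpp_dd_maxscores(frames, cfg$window_len, cfg$waggle_band,
                         cfg$sample_rate)
  as.numeric(quantile(sc, 1 - fp_rate, names = FALSE))
}

#' Cluster activated detectors into potential dancer positions
#'
#' Single-linkage agglomerative clustering of activated pixel positions
#' with merge threshold `cluster_dist`; clusters smaller than
#' `min_cluster_size` are dropped as noise-induced, the rest are reported
#' by their centroid.
#'
#' @param positions k x 2 matrix of activated positions (x, y).
#' @param cfg an [attention_config()].
#' @return data.frame with columns `x`, `y` (centroid) and `n_detectors`,
#'   plus a `members` attribute listing each cluster's pixel positions.
#'   Zero rows when nothing survives.
#' @export
cluster_dancers <- function(positions, cfg) {
  empty <- data.frame(x = numeric(0), y = numeric(0),
                      n_detectors = integer(0))
  if (is.null(positions) || nrow(positions) == 0) return(empty)
  # lexicographic order makes merges (and centroids) order-invariant
  positions <- positions[order(positions[, 1], positions[, 2]), ,
                         drop = FALSE]
  if (nrow(positions) == 1) {
    cl <- 1L
  } else {
    cl <- cutree(hclust(dist(positions), method = "single"),
                 h = cfg$cluster_dist)
  }
  keep <- which(tabulate(cl) >= cfg$min_cluster_size)
  if (!length(keep)) return(empty)
  members <- lapply(keep, function(k) positions[cl == k, , drop = FALSE])
  out <- data.frame(
    x = vapply(members, function(m) mean(m[, 1]), 0),
    y = vapply(members, function(m) mean(m[, 2]), 0),
    n_detectors = vapply(members, nrow, 0L)
  )
  ord <- order(out$x, out$y)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "members") <- members[ord]
  out
}

#' Assemble per-frame dancer positions into waggle runs
#'
#' Positions in successive frames within `link_dist` of an open candidate's
#' last position extend that candidate (nearest candidate wins, ties go to
#' the older one); otherwise a new candidate is opened. Candidates starved
#' of detections for more than `max_gap` frames are closed. Closed
#' candidates need at least `min_run_detections` detections and
#' `min_run_ms` of duration to be emitted.
#'
#' @param detections data.frame with columns `frame`, `x`, `y` (and
#'   optionally `n_detectors`), ordered by frame.
#' @param cfg an [attention_config()].
#' @return list of `waggle_run` objects (id, start/end frame, duration in
#'   ms, per-frame positions, comb position = median of centroids).
#' @export
assemble_runs <- function(detections, cfg) {
  runs <- list()
  open <- list()
  next_id <- 1L
  finalize <- function(cand) {
    n <- nrow(cand$pos)
    dur <- (cand$pos$frame[n] - cand$pos$frame[1] + 1) /
      cfg$sample_rate * 1000
    if (n >= cfg$min_run_detections && dur >= cfg$min_run_ms) {
      run <- structure(list(
        id = next_id, start_frame = cand$pos$frame[1],
        end_frame = cand$pos$frame[n], duration_ms = dur,
        positions = cand$pos,
        comb_xy = c(stats::median(cand$pos$x), stats::median(cand$pos$y)),
        orientation_deg = NA_real_, confidence = NA_real_
      ), class = "waggle_run")
      runs[[length(runs) + 1L]] <<- run
      next_id <<- next_id + 1L
    }
  }
  if (nrow(detections) > 0) {
    detections <- detections[order(detections$frame), , drop = FALSE]
    for (fr in unique(detections$frame)) {
      # close candidates that exceeded the allowed gap
      if (length(open)) {
        stale <- vapply(open, function(c) fr - c$last_frame > cfg$max_gap,
                        TRUE)
        for (c in open[stale]) finalize(c)
        open <- open[!stale]
      }
      rows <- which(detections$frame == fr)
      for (ri in rows) {
        px <- detections$x[ri]; py <- detections$y[ri]
        best <- 0L
        if (length(open)) {
          d <- vapply(open, function(c)
            sqrt((c$last_xy[1] - px)^2 + (c$last_xy[2] - py)^2), 0)
          ok <- which(d <= cfg$link_dist)
          if (length(ok)) {
            dm <- min(d[ok])
            cand <- ok[d[ok] == dm]       # ties: oldest candidate
            best <- cand[which.min(vapply(open[cand],
                                          function(c) c$born, 0L))]
          }
        }
        row <- data.frame(frame = fr, x = px, y = py)
        if (best > 0L) {
          open[[best]]$pos <- rbind(open[[best]]$pos, row)
          open[[best]]$last_xy <- c(px, py)
          open[[best]]$last_frame <- fr
        } else {
          open[[length(open) + 1L]] <-
            list(pos = row, last_xy = c(px, py), last_frame = fr,
                 born = length(open) + next_id)
        }
      }
    }
  }
  for (c in open) finalize(c)
  runs
}

#' @export
print.waggle_run <- function(x, ...) {
  cat(sprintf(
    "Waggle run %d: frames %d-%d (%.0f ms), %d detections at (%.1f, %.1f)",
    x$id, x$start_frame, x$end_frame, x$duration_ms, nrow(x$positions),
    x$comb_xy[1], x$comb_xy[2]))
  if (!is.na(x$orientation_deg))
    cat(sprintf(", orientation %.1f deg", x$orientation_deg))
  cat("\n")
  invisible(x)
}

#' Crop the snippet sequence of a waggle run
#'
#' Per detection frame, a `snippet_size` square crop centred on that
#' frame's dancer position; crops reaching past the image border are
#' zero-padded.
#'
#' @param frames full video array.
#' @param run a `waggle_run`.
#' @param cfg an [attention_config()].
#' @return list with `frames` (snippet_size x snippet_size x k array) and
#'   `meta` (frame indices and centroids, needed later for direction
#'   disambiguation).
#' @export
export_snippet <- function(frames, run, cfg) {
  sz <- cfg$snippet_size
  half <- (sz - 1) %/% 2
  k <- nrow(run$positions)
  out <- array(0, dim = c(sz, sz, k))
  H <- dim(frames)[1]; W <- dim(frames)[2]
  for (t in seq_len(k)) {
    cx <- round(run$positions$x[t]); cy <- round(run$positions$y[t])
    xs <- (cx - half):(cx - half + sz - 1)
    ys <- (cy - half):(cy - half + sz - 1)
    vx <- xs >= 1 & xs <= W
    vy <- ys >= 1 & ys <= H
    out[which(vy), which(vx), t] <-
      frames[ys[vy], xs[vx], run$positions$frame[t]]
  }
  list(frames = out,
       meta = list(id = run$id, frames = run$positions$frame,
                   centroids = as.matrix(run$positions[, c("x", "y")])))
}

#' Detect waggle runs in a video
#'
#' The full attention module: per-pixel waggle-band scoring, per-frame
#' clustering of activated detectors, and run assembly.
#'
#' @param frames height x width x T array of grey values.
#' @param cfg an [attention_config()].
#' @param snippets if `TRUE`, attach the cropped snippet sequence to each
#'   run (`$snippet`).
#' @return list of `waggle_run` objects.
#' @export
detect_waggle_runs <- function(frames, cfg, snippets = TRUE) {
  acts <- activate_detectors(frames, cfg)
  dets <- list()
  for (fr in seq_along(acts)) {
    if (nrow(acts[[fr]]) == 0) next
    cl <- cluster_dancers(acts[[fr]], cfg)
    if (nrow(cl) > 0)
      dets[[length(dets) + 1L]] <-
        data.frame(frame = fr, x = cl$x, y = cl$y,
                   n_detectors = cl$n_detectors)
  }
  dets <- if (length(dets)) do.call(rbind, dets)
          else data.frame(frame = integer(0), x = numeric(0), y = numeric(0))
  runs <- assemble_runs(dets, cfg)
  if (snippets)
    runs <- lapply(runs, function(r) {
      r$snippet <- export_snippet(frames, r, cfg)
      r
    })
  runs
}

#' Run table of a list of waggle runs
#'
#' @param runs list of `waggle_run` objects.
#' @param sample_rate Hz, used for the start time in seconds.
#' @return data.frame with one row per run.
#' @export
run_table <- function(runs, sample_rate = 100) {
  if (!length(runs))
    return(data.frame(id = integer(0), start_frame = integer(0),
                      start_s = numeric(0), x_px = numeric(0),
                      y_px = numeric(0), duration_ms = numeric(0),
                      n_detections = integer(0),
                      orientation_deg = numeric(0),
                      confidence = numeric(0)))
  data.frame(
    id = vapply(runs, `[[`, 0L, "id"),
    start_frame = vapply(runs, `[[`, 0, "start_frame"),
    start_s = vapply(runs, function(r) (r$start_frame - 1) / sample_rate, 0),
    x_px = vapply(runs, function(r) r$comb_xy[1], 0),
    y_px = vapply(runs, function(r) r$comb_xy[2], 0),
    duration_ms = vapply(runs, `[[`, 0, "duration_ms"),
    n_detections = vapply(runs, function(r) nrow(r$positions), 0L),
    orientation_deg = vapply(runs, `[[`, 0, "orientation_deg"),
    confidence = vapply(runs, `[[`, 0, "confidence")
  )
}
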