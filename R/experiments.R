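#' Validation experiments on synthetic ground truth
#'
#' These functions run the pipeline's modules against the synthetic
#' renderer at the scales used for validation and return per-item results,
#' so error statistics are always recomputed from scratch.
#'
#' @name experiments
NULL

#' Orientation decoding error over random synthetic runs
#'
#' Renders tracked waggle-run snippets at uniform random true
#' orientations and decodes each with the orientation module.
#'
#' @param n_runs number of runs.
#' @param scene a [scene_config()] (noise, motion parameters).
#' @param ocfg an [orientation_config()].
#' @param n_frames run length in frames.
#' @param seed master seed.
#' @return data.frame with `true_deg`, `decoded_deg`, `error_deg`
#'   (signed circular), `flipped` (error closer to 180 than to 0) and
#'   `degenerate`.
#' @export
experiment_orientation_error <- function(n_runs = 200,
                                         scene = scene_config(noise_sd = 3),
                                         ocfg = orientation_config(),
                                         n_frames = 58, seed = NULL) {
  with_seed(seed, {
    res <- lapply(seq_len(n_runs), function(i) {
      true <- runif(1, 0, 360)
      sn <- render_run_snippet(scene, true, n_frames, seed = NULL)
      dec <- decode_orientation(sn$frames, sn$positions, ocfg)
      data.frame(true_deg = true, decoded_deg = dec$direction_deg,
                 error_deg = circ_diff_deg(dec$direction_deg, true),
                 flipped = circ_dist_deg(dec$direction_deg, true) > 90,
                 degenerate = dec$degenerate)
    })
    do.call(rbind, res)
  })
}

#' Attention-module duration error over random synthetic runs
#'
#' Renders one waggle run of known duration per scene (uniform 300-900 ms)
#' with stationary lead-in/out, runs the attention module, and compares
#' emitted durations against ground truth. Scenes where the module does
#' not report exactly one run are returned with `detected = FALSE`.
#'
#' @param n_scenes number of scenes.
#' @param scene a [scene_config()]; width/height should leave room for
#'   the longest run.
#' @param acfg an [attention_config()].
#' @param duration_range_ms true durations are drawn uniformly from this
#'   range.
#' @param seed master seed.
#' @return data.frame with `true_ms`, `detected`, `decoded_ms`,
#'   `error_ms`.
#' @export
experiment_duration_error <- function(n_scenes = 200,
                                      scene = scene_config(width = 140,
                                                           height = 140,
                                                           noise_sd = 3),
                                      acfg = attention_config(),
                                      duration_range_ms = c(300, 900),
                                      seed = NULL) {
  with_seed(seed, {
    res <- lapply(seq_len(n_scenes), function(i) {
      dur_f <- round(runif(1, duration_range_ms[1], duration_range_ms[2]) /
                       1000 * scene$frame_rate)
      true_ms <- dur_f / scene$frame_rate * 1000
      th <- runif(1, 0, 360)
      h <- heading_vector(th)
      start <- c(scene$width / 2, scene$height / 2) -
        h * scene$forward_speed_px_per_frame * dur_f / 2
      sc <- render_waggle_run(scene,
                              ground_truth_run(41L, dur_f, start, th),
                              tail_frames = 40, seed = NULL)
      runs <- detect_waggle_runs(sc$frames, acfg, snippets = FALSE)
      if (length(runs) != 1)
        return(data.frame(true_ms = true_ms, detected = FALSE,
                          decoded_ms = NA_real_, error_ms = NA_real_))
      data.frame(true_ms = true_ms, detected = TRUE,
                 decoded_ms = runs[[1]]$duration_ms,
                 error_ms = runs[[1]]$duration_ms - true_ms)
    })
    do.call(rbind, res)
  })
}

#' Filter-network held-out accuracy on a balanced synthetic corpus
#'
#' Generates a balanced waggle / non-waggle corpus, trains the 3D conv
#' network with the standard protocol (random 128-frame subsequences,
#' zero padding, flip augmentation, Adam, 20% held-out split) and
#' returns the trained model with its validation metrics.
#'
#' @param n_per_class clips per class.
#' @param scene a [scene_config()].
#' @param fcfg a [filter_config()]; its seed is overridden by `seed`.
#' @param seed master seed (corpus and training).
#' @return the trained `filternet` (see `$val$accuracy`).
#' @export
experiment_filter_accuracy <- function(n_per_class = 400,
                                       scene = scene_config(noise_sd = 3),
                                       fcfg = filter_config(),
                                       seed = NULL) {
  corpus <- render_filter_corpus(n_per_class, n_per_class, scene,
                                 seed = seed)
  fcfg$seed <- if (is.null(seed)) fcfg$seed else seed + 1L
  train_filternet(corpus, fcfg)
}

#' Feeder-bearing recovery over many synthetic dances
#'
#' Emulates the feeder experiment: dances whose per-run comb angles are
#' drawn around a fixed feeder angle with waggle-level spread, rendered
#' as snippets, decoded with the orientation module, clustered and
#' RANSAC-averaged with the mapping module, and projected with a fixed
#' solar azimuth.
#'
#' @param n_dances number of dances.
#' @param comb_angle_deg true comb angle of the feeder direction.
#' @param run_angle_sd_deg per-run angular spread.
#' @param runs_per_dance function(n) drawing run counts; the default is
#'   4 + Poisson(1.8), truncated at 17 (range 4-17, mean about 5.8 runs).
#' @param duration_mean_ms,duration_sd_ms run-duration draw (truncated at
#'   300 ms / 1200 ms).
#' @param azimuth_deg fixed solar azimuth used for projection.
#' @param scene a [scene_config()].
#' @param ocfg an [orientation_config()].
#' @param mcfg a [mapping_config()].
#' @param seed master seed.
#' @return list with `dances` (the mapped dance table), `true_bearing_deg`
#'   and `mean_bearing_deg` (circular mean over dances).
#' @export
experiment_feeder_mapping <- function(n_dances = 571, comb_angle_deg = 225,
                                      run_angle_sd_deg = 14.37,
                                      runs_per_dance = function(n)
                                        pmin(4 + stats::rpois(n, 1.8), 17),
                                      duration_mean_ms = 582.79,
                                      duration_sd_ms = 196.10,
                                      azimuth_deg = 135,
                                      scene = scene_config(noise_sd = 3),
                                      ocfg = orientation_config(),
                                      mcfg = mapping_config(),
                                      seed = NULL) {
  with_seed(seed, {
    n_runs <- runs_per_dance(n_dances)
    rows <- list()
    for (d in seq_len(n_dances)) {
      center <- c(runif(1, 100, 500), runif(1, 100, 500))
      t0 <- (d - 1) * 60  # dances a minute apart: distinct XYT clusters
      t_run <- t0
      for (j in seq_len(n_runs[d])) {
        ang <- (comb_angle_deg + rnorm(1, sd = run_angle_sd_deg)) %% 360
        dur_f <- round(pmin(pmax(rnorm(1, duration_mean_ms,
                                       duration_sd_ms), 300), 1200) /
                         1000 * scene$frame_rate)
        sn <- render_run_snippet(scene, ang, dur_f, seed = NULL)
        dec <- decode_orientation(sn$frames, sn$positions, ocfg)
        rows[[length(rows) + 1L]] <- data.frame(
          dance = d, x_px = center[1] + rnorm(1, sd = 2),
          y_px = center[2] + rnorm(1, sd = 2), start_s = t_run,
          duration_ms = dur_f * 1000 / scene$frame_rate,
          orientation_deg = dec$direction_deg)
        t_run <- t_run + dur_f / scene$frame_rate +
          runif(1, 1.5, 2.5)  # return-phase gap
      }
    }
    tbl <- do.call(rbind, rows)
    # midnight start so start_s doubles as seconds since midnight
    dances <- map_dances(tbl, mcfg,
                         as.POSIXct("2016-07-15 00:00:00", tz = "UTC"),
                         seed = 1L)
    # replace the per-dance solar azimuth with the fixed experimental one
    dances$bearing_deg <- (azimuth_deg + dances$comb_angle_deg) %% 360
    true_bearing <- (azimuth_deg + comb_angle_deg) %% 360
    list(dances = dances, true_bearing_deg = true_bearing,
         mean_bearing_deg = circular_mean(dances$bearing_deg,
                                          warn_odd = FALSE),
         run_table = tbl)
  })
}
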