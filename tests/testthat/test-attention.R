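test_that("window normalisation maps extremes to +-1 and guards degenerate input", {
  B <- rep(c(0, 255), 16)
  expect_equal(normalize_window(B), rep(c(-1, 1), 16))
  expect_equal(normalize_window(rep(7, 32)), rep(0, 32))
  expect_error(normalize_window(1:10, window_len = 32), "warm-up")
  # affine illumination invariance of the normalised series
  B2 <- stats::rnorm(32)
  expect_equal(normalize_window(3.7 * B2 + 42), normalize_window(B2))
})

test_that("dd_score matches the closed form and the naive DFT oracle", {
  b <- 100; sr <- 100
  tone <- cos(2 * pi * 13 * (1:b) / sr)
  expect_equal(dd_score(tone, 13, sr), (b / 2)^2, tolerance = 1e-3)
  expect_equal(dd_score(rep(0, b), 13, sr), 0)
  expect_lt(dd_score(tone, 30, sr), 0.01 * dd_score(tone, 13, sr))
  expect_error(dd_score(tone, 50, sr), "below")
  # naive double-loop oracle at 1e-9 relative
  set.seed(1)
  x <- normalize_window(stats::rnorm(32))
  for (r in c(10, 13, 16)) {
    cs <- 0; sn <- 0
    for (m in seq_along(x)) {
      cs <- cs + x[m] * cos(2 * pi * r * m / sr)
      sn <- sn + x[m] * sin(2 * pi * r * m / sr)
    }
    expect_equal(dd_score(x, r, sr), cs^2 + sn^2, tolerance = 1e-9)
  }
})

test_that("the literal per-term-squared score reading cannot detect periodicity", {
  # rejected alternative: squaring each summand before summing makes the
  # score blind to phase coherence - a pure tone and its random
  # permutation become indistinguishable, unlike the periodogram reading
  literal <- function(x, r, sr) {
    m <- seq_along(x)
    sum((x * cos(2 * pi * r * m / sr))^2 + (x * sin(2 * pi * r * m / sr))^2)
  }
  b <- 32; sr <- 100
  tone <- normalize_window(cos(2 * pi * 13 * (1:b) / sr))
  set.seed(2)
  scram <- sample(tone)
  expect_equal(literal(tone, 13, sr), literal(scram, 13, sr),
               tolerance = 1e-12)  # sum x^2 regardless of order
  expect_gt(dd_score(tone, 13, sr) / dd_score(scram, 13, sr), 10)
})

test_that("the compiled activation map equals per-window R scoring", {
  set.seed(3)
  cfg <- attention_config(score_threshold = 40)
  video <- array(stats::runif(6 * 5 * 40, 0, 255), dim = c(6, 5, 40))
  acts <- activate_detectors(video, cfg)
  b <- cfg$window_len
  for (n in c(b, 36, 40)) {
    ref <- matrix(0L, 0, 2)
    for (j in 1:5) for (i in 1:6) {
      w <- normalize_window(video[i, j, (n - b + 1):n])
      sc <- max(vapply(cfg$waggle_band, function(r)
        dd_score(w, r, cfg$sample_rate), 0))
      if (sc >= cfg$score_threshold) ref <- rbind(ref, c(j, i))
    }
    expect_equal(unname(acts[[n]][order(acts[[n]][, 1], acts[[n]][, 2]), ,
                                  drop = FALSE]),
                 ref[order(ref[, 1], ref[, 2]), , drop = FALSE])
  }
  expect_equal(nrow(acts[[b - 1]]), 0L)  # warm-up frames never activate
})

test_that("activations are invariant to illumination gain and offset", {
  sn <- fixture_snippet(orientation = 80, n_frames = 70, noise_sd = 2)
  cfg <- attention_config()
  a1 <- activate_detectors(sn$frames, cfg)
  a2 <- activate_detectors(0.5 * sn$frames + 60, cfg)
  expect_equal(a1, a2)
})

test_that("waggle snippets activate near the bee; threshold zero activates everything", {
  sn <- fixture_snippet(orientation = 10, n_frames = 70, noise_sd = 2)
  cfg <- attention_config()
  acts <- activate_detectors(sn$frames, cfg)
  n_act <- vapply(acts, nrow, 0L)
  expect_gt(sum(n_act), 0)
  # all activated pixels near the crop centre (bee is tracked), i.e.
  # inside a generously dilated bee mask
  pts <- do.call(rbind, acts[n_act > 0])
  expect_true(all(sqrt((pts[, 1] - 25.5)^2 + (pts[, 2] - 25.5)^2) < 25))
  all_on <- activate_detectors(sn$frames[, , 1:40],
                               attention_config(score_threshold = 0))
  expect_equal(nrow(all_on[[40]]), 50 * 50)
})

test_that("dancer clustering matches a single-linkage oracle and drops small clusters", {
  cfg <- attention_config(cluster_dist = 10, min_cluster_size = 5)
  # two well-separated blobs
  blob <- function(cx, cy) cbind(cx + rep(0:2, 3), cy + rep(0:2, each = 3))
  det <- cluster_dancers(rbind(blob(10, 10), blob(80, 80)), cfg)
  expect_equal(nrow(det), 2)
  expect_equal(det$n_detectors, c(9L, 9L))
  expect_equal(det$x, c(11, 81))
  # a lone pixel is discarded as noise
  expect_equal(nrow(cluster_dancers(matrix(c(5, 5), 1), cfg)), 0)
  # order invariance + oracle partition on random sets of <= 20 points
  for (rep in 1:10) {
    set.seed(rep)
    pts <- matrix(stats::runif(2 * sample(5:20, 1), 0, 40), ncol = 2)
    cfg2 <- attention_config(cluster_dist = 8, min_cluster_size = 1)
    d1 <- cluster_dancers(pts, cfg2)
    d2 <- cluster_dancers(pts[sample(nrow(pts)), ], cfg2)
    expect_equal(d1, d2, ignore_attr = TRUE)
    oracle <- oracle_single_linkage(pts, 8)
    expect_equal(nrow(d1), length(unique(oracle)))
    # centroid multiset must match the oracle's
    oc <- t(sapply(split(seq_len(nrow(pts)), oracle), function(ix)
      colMeans(pts[ix, , drop = FALSE])))
    ord_o <- order(oc[, 1], oc[, 2])
    ord_d <- order(d1$x, d1$y)
    expect_equal(unname(cbind(d1$x, d1$y)[ord_d, , drop = FALSE]),
                 unname(oc[ord_o, , drop = FALSE]), tolerance = 1e-12)
  }
})

test_that("run assembly links tracks, tolerates gaps and enforces minimum duration", {
  cfg <- attention_config(link_dist = 10, max_gap = 4,
                          min_run_detections = 10, min_run_ms = 200)
  track <- data.frame(frame = 1:60, x = 10 + 3 * (0:59) * 0.5, y = 20)
  runs <- assemble_runs(track, cfg)
  expect_length(runs, 1)
  expect_equal(nrow(runs[[1]]$positions), 60)
  expect_equal(runs[[1]]$duration_ms, 600)
  # a 2-frame hole within the gap allowance keeps the run open
  holed <- track[-(30:31), ]
  runs <- assemble_runs(holed, cfg)
  expect_length(runs, 1)
  expect_equal(runs[[1]]$start_frame, 1)
  expect_equal(runs[[1]]$end_frame, 60)
  # a 120 ms pulse is dropped by the duration filter
  pulse <- data.frame(frame = 1:12, x = 10, y = 10)
  expect_length(assemble_runs(pulse, cfg), 0)
  # exceeding the gap splits the track
  split2 <- rbind(track[1:25, ], transform(track[36:60, ], x = x + 0))
  runs <- assemble_runs(split2, cfg)
  expect_length(runs, 2)
})

test_that("snippet export crops centred, zero-pads at borders and keeps metadata", {
  cfg <- attention_config()
  frames <- array(100, dim = c(80, 80, 20))
  corner_run <- structure(list(
    id = 1L, start_frame = 1L, end_frame = 10L, duration_ms = 100,
    positions = data.frame(frame = 1:10, x = 2, y = 2),
    comb_xy = c(2, 2)), class = "waggle_run")
  sn <- export_snippet(frames, corner_run, cfg)
  expect_equal(dim(sn$frames), c(50, 50, 10))
  expect_equal(sn$frames[1, 1, 1], 0)    # padded region
  expect_equal(sn$frames[30, 30, 1], 100)
  # tracked synthetic run: blob centroid stays near the crop centre
  fx <- fixture_snippet(orientation = 135, n_frames = 60, noise_sd = 2)
  runs <- detect_waggle_runs(fx$frames, cfg)
  expect_length(runs, 1)
  crop <- runs[[1]]$snippet$frames
  for (t in c(1, 10, 20)) {
    m <- pmax(crop[, , t] - 40, 0)
    cx <- sum(col(m) * m) / sum(m); cy <- sum(row(m) * m) / sum(m)
    expect_lt(sqrt((cx - 25.5)^2 + (cy - 25.5)^2), 8)
  }
  # metadata serialisation round-trip
  path <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(runs[[1]]$snippet$meta, path, auto_unbox = TRUE,
                       digits = NA)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(back$frames, runs[[1]]$snippet$meta$frames)
  expect_equal(unname(back$centroids),
               unname(runs[[1]]$snippet$meta$centroids))
})

test_that("detection is causal: truncating the video preserves earlier activations", {
  sn <- fixture_snippet(orientation = 300, n_frames = 80, noise_sd = 2)
  cfg <- attention_config()
  full <- activate_detectors(sn$frames, cfg)
  part <- activate_detectors(sn$frames[, , 1:50], cfg)
  expect_equal(full[1:50], part)
  # and re-running the whole batch is bit-identical
  expect_identical(detect_waggle_runs(sn$frames, cfg, snippets = FALSE),
                   detect_waggle_runs(sn$frames, cfg, snippets = FALSE))
})

test_that("threshold calibration bounds the noise false-positive rate", {
  set.seed(5)
  noise <- array(40 + stats::rnorm(40 * 40 * 120, sd = 3),
                 dim = c(40, 40, 120))
  cfg <- attention_config()
  th <- calibrate_threshold(noise, cfg, fp_rate = 0.01)
  sc <- beewaggle:::cpp_dd_maxscores(noise, cfg$window_len,
                                     cfg$waggle_band, cfg$sample_rate)
  expect_lte(mean(sc >= th), 0.011)
  expect_gt(th, 0)
})
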