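test_that("difference images are signed, linear and need two frames", {
  a <- array(c(1, 2, 3, 4, 5, 6, 7, 8), dim = c(2, 2, 2))
  d <- difference_images(a)
  expect_equal(dim(d), c(2, 2, 1))
  expect_equal(d[, , 1], a[, , 2] - a[, , 1])
  same <- array(3, dim = c(4, 4, 2))
  expect_true(all(difference_images(same) == 0))
  expect_error(difference_images(array(0, dim = c(4, 4, 1))), "2 frames")
  expect_equal(difference_images(2.5 * a), 2.5 * difference_images(a))
})

test_that("a laterally stepping blob leaves side-by-side opposite lobes", {
  # vertical body (0 deg) stepping image-right: positive and negative
  # difference lobes sit beside each other along the horizontal axis
  cfg <- quiet_scene()
  f1 <- beewaggle:::scene_values(cfg, 1:50, 1:50,
    list(list(xy = c(22, 25), heading_deg = 0)))
  f2 <- beewaggle:::scene_values(cfg, 1:50, 1:50,
    list(list(xy = c(28, 25), heading_deg = 0)))
  d <- f2 - f1
  imax <- which(d == max(d), arr.ind = TRUE)[1, ]
  imin <- which(d == min(d), arr.ind = TRUE)[1, ]
  expect_gt(abs(imax["col"] - imin["col"]), 3)  # horizontally separated
  expect_lt(abs(imax["row"] - imin["row"]), 3)  # same height
})

test_that("accumulated spectra are additive, symmetric and orient with a Gabor patch", {
  z <- array(0, dim = c(50, 50, 3))
  expect_true(all(accumulate_spectrum(z) == 0))
  set.seed(1)
  one <- array(stats::rnorm(50 * 50), dim = c(50, 50, 1))
  five <- array(rep(one, 5), dim = c(50, 50, 5))
  expect_equal(accumulate_spectrum(five), 5 * accumulate_spectrum(one),
               tolerance = 1e-12)
  # point symmetry about the origin bin
  s <- accumulate_spectrum(one)
  c0 <- 26
  for (off in list(c(3, 7), c(-5, 2), c(10, -4)))
    expect_equal(s[c0 + off[1], c0 + off[2]], s[c0 - off[1], c0 - off[2]],
                 tolerance = 1e-9)
  # analytic Gabor patch at angle phi: spectral maxima on the line at phi
  for (phi in c(0, 30, 60, 120)) {
    x <- matrix(rep(1:50 - 25.5, each = 50), 50)
    y <- matrix(rep(1:50 - 25.5, times = 50), 50)
    k <- heading_vector(phi)  # wave vector direction
    u <- x * k[1] + y * k[2]
    g <- exp(-(x^2 + y^2) / (2 * 6^2)) * sin(2 * pi * u / 10)
    sp <- accumulate_spectrum(array(g, dim = c(50, 50, 1)))
    pk <- which(sp == max(sp), arr.ind = TRUE)[1, ]
    ang <- vector_heading(pk["col"] - c0, pk["row"] - c0) %% 180
    expect_lt(circ_dist_deg(2 * ang, 2 * (phi %% 180)) / 2, 8)
  }
})

test_that("the DoG ring sits at k = I/(2x) and attenuates off-ring energy", {
  expect_equal(beewaggle:::dog_ring_radius(50, 5), 5)
  expect_equal(beewaggle:::dog_ring_radius(50, 7), 50 / 14, tolerance = 1e-12)
  ring <- beewaggle:::dog_ring(50, 5)
  c0 <- 26
  gain_at <- function(r) ring[c0, c0 + r]
  expect_gt(gain_at(5), 0.9)              # near-peak on the ring
  expect_gt(gain_at(5) / gain_at(15), 10) # impulse at 3k attenuated >= 10x
  expect_equal(ring[c0, c0], 0)           # DC suppressed
  cfg_bad <- orientation_config(lateral_step = 0.9)
  expect_error(dog_bandpass(matrix(1, 50, 50), cfg_bad), "Nyquist")
})

test_that("PCA axis follows spectral anisotropy and flags isotropy", {
  s <- matrix(0, 50, 50)
  s[26, 26 + c(-8, 8)] <- 1  # two point masses on the horizontal freq axis
  ax <- pca_axis(s)
  expect_equal(ax$lateral_deg, 90)  # frequency axis horizontal
  expect_equal(ax$axis_deg, 0)      # body axis vertical
  expect_false(ax$degenerate)
  iso <- beewaggle:::dog_ring(50, 5)  # perfectly isotropic ring
  expect_true(pca_axis(iso)$degenerate)
  expect_error(pca_axis(matrix(0, 50, 50)), "zero")
})

test_that("disambiguation follows the dominant displacement direction", {
  cfg <- orientation_config()
  right <- cbind(seq(0, 30, length.out = 40), rep(0, 40))
  d <- disambiguate(90, right, cfg)
  expect_equal(d$direction_deg, 90)
  expect_gt(d$margin, 0.9)
  d2 <- disambiguate(90, -right, cfg)
  expect_equal(d2$direction_deg, 270)
  same <- matrix(5, nrow = 20, ncol = 2)
  d3 <- disambiguate(40, same, cfg)
  expect_true(d3$degenerate)
  expect_equal(d3$margin, 0)
  expect_equal(d3$direction_deg, 40)
})

test_that("noise-free synthetic runs decode within 5 degrees", {
  cfg <- orientation_config()
  for (truth in c(123, 11, 250)) {
    sn <- render_run_snippet(quiet_scene(), truth, 58, seed = truth)
    dec <- decode_orientation(sn$frames, sn$positions, cfg)
    expect_lt(circ_dist_deg(dec$direction_deg, truth), 5)
    expect_equal(dec$direction_deg %% 180, dec$axis_deg, tolerance = 1e-6)
  }
})

test_that("the recovered axis is equivariant under scene rotation", {
  cfg <- orientation_config()
  base <- 20
  sn0 <- render_run_snippet(quiet_scene(), base, 58, seed = 5)
  ax0 <- decode_orientation(sn0$frames, sn0$positions, cfg)$axis_deg
  for (phi in c(25, 70, 110)) {
    sn <- render_run_snippet(quiet_scene(), base + phi, 58, seed = 5)
    ax <- decode_orientation(sn$frames, sn$positions, cfg)$axis_deg
    err <- circ_dist_deg(2 * ax, 2 * ((ax0 + phi) %% 180)) / 2
    expect_lt(err, 2)
  }
})

test_that("mirroring frames horizontally maps direction d to 360 - d", {
  cfg <- orientation_config()
  sn <- fixture_snippet(orientation = 63, n_frames = 58, noise_sd = 0,
                        seed = 8)
  d1 <- decode_orientation(sn$frames, sn$positions, cfg)$direction_deg
  mirrored <- sn$frames[, 50:1, , drop = FALSE]
  pos <- cbind(-sn$positions[, 1], sn$positions[, 2])
  d2 <- decode_orientation(mirrored, pos, cfg)$direction_deg
  expect_lt(circ_dist_deg(d2, (360 - d1) %% 360), 2)
})

test_that("runs without forward motion are flagged degenerate but still decoded", {
  cfg <- orientation_config()
  # amplitude-only oscillation under a tracking crop: the reported
  # dancer position never moves
  scene <- scene_config(noise_sd = 0, forward_speed_px_per_frame = 1e-9)
  sn <- render_run_snippet(scene, 45, 58, position_noise_sd = 0, seed = 9)
  frozen <- matrix(5, nrow = 58, ncol = 2)
  dec <- decode_orientation(sn$frames, frozen, cfg)
  expect_true(dec$degenerate)
  expect_equal(dec$margin, 0)
  expect_lt(circ_dist_deg(dec$axis_deg, 45), 5)
})

test_that("magnitude accumulation is robust to the pattern's shifting position", {
  # rejected alternative: summing complex transforms before taking the
  # magnitude lets identical patterns at different positions (pure phase
  # shifts in frequency space) cancel, while magnitudes add coherently
  x <- matrix(rep(1:50 - 25.5, each = 50), 50)
  y <- matrix(rep(1:50 - 25.5, times = 50), 50)
  gabor_at <- function(cx, cy)
    exp(-((x - cx)^2 + (y - cy)^2) / (2 * 5^2)) * sin(2 * pi * (x - cx) / 10)
  stack <- array(0, dim = c(50, 50, 4))
  shifts <- cbind(c(0, 5, -5, 2.5), c(0, 0, 0, 0))
  for (t in 1:4) stack[, , t] <- gabor_at(shifts[t, 1], shifts[t, 2])
  s_mag <- accumulate_spectrum(stack)
  cplx <- matrix(0 + 0i, 50, 50)
  for (t in 1:4) {
    d <- stack[, , t]
    cplx <- cplx + stats::fft(d - mean(d))
  }
  s_complex <- beewaggle:::fftshift2(Mod(cplx))
  expect_lt(max(s_complex), 0.6 * max(s_mag))  # destructive interference
  # and the magnitude accumulation still orients correctly
  ax <- pca_axis(dog_bandpass(s_mag, orientation_config()))
  expect_equal(ax$lateral_deg, 90, tolerance = 3)  # wave along x
})

test_that("decode_run writes the orientation back onto detected runs", {
  fx <- fixture_snippet(orientation = 320, n_frames = 60, noise_sd = 2,
                        seed = 12)
  runs <- detect_waggle_runs(fx$frames, attention_config())
  expect_length(runs, 1)
  run <- decode_run(runs[[1]], orientation_config())
  expect_false(is.na(run$orientation_deg))
  # tracked-crop detections: centroids hover near the window centre, so
  # the axis is trustworthy even if heading needs the absolute track
  expect_lt(circ_dist_deg(2 * run$orientation$axis_deg, 2 * (320 %% 180)) / 2,
            6)
  bad <- runs[[1]]; bad$snippet <- NULL
  expect_error(decode_run(bad, orientation_config()), "no snippet")
})
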