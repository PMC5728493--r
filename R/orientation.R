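#' Orientation-module configuration
#'
#' Decoding a run's body orientation works on the exported snippet
#' sequence: consecutive frames are differenced, each difference image is
#' Fourier transformed, magnitudes are accumulated over the run, a
#' ring-shaped difference-of-Gaussians bandpass keeps the frequencies of
#' the Gabor-like lateral-motion pattern, and PCA of the filtered spectrum
#' yields the movement axis (body axis = movement axis + 90 degrees).
#'
#' @param image_size snippet side length I_size in px.
#' @param frame_rate video frame rate in Hz.
#' @param px_per_mm spatial scale.
#' @param lateral_step expected lateral displacement x per frame in px
#'   (field measurements give 5-7 px/frame at this scale); sets the
#'   bandpass ring radius k = I_size / (2 x).
#' @param anchor_fraction fraction of the run's first frames averaged into
#'   the anchor point for forward-motion disambiguation.
#' @param histogram_bins bins of the displacement-direction histogram.
#' @return object of class `orientation_config`.
#' @export
orientation_config <- function(image_size = 50, frame_rate = 100,
                               px_per_mm = 1.7, lateral_step = 6,
                               anchor_fraction = 0.1, histogram_bins = 36) {
  stop_if_not_scalar_pos(image_size, "image_size")
  stop_if_not_scalar_pos(lateral_step, "lateral_step")
  if (anchor_fraction <= 0 || anchor_fraction > 1)
    stop("anchor_fraction must be in (0, 1]")
  structure(list(image_size = as.integer(image_size),
                 frame_rate = frame_rate, px_per_mm = px_per_mm,
                 lateral_step = lateral_step,
                 anchor_fraction = anchor_fraction,
                 histogram_bins = as.integer(histogram_bins)),
            class = "orientation_config")
}

#' Consecutive-frame difference images
#'
#' A laterally waggling blob leaves a signed two-lobe pattern (one positive,
#' one negative peak side by side) in these images, oriented along the
#' motion direction like a 2D Gabor patch.
#'
#' @param frames h x w x n array, n >= 2.
#' @return h x w x (n-1) signed array, `frames[,,t+1] - frames[,,t]`.
#' @export
difference_images <- function(frames) {
  if (length(dim(frames)) != 3 || dim(frames)[3] < 2)
    stop("need at least 2 frames")
  n <- dim(frames)[3]
  frames[, , 2:n, drop = FALSE] - frames[, , 1:(n - 1), drop = FALSE]
}

## swap quadrants so the zero-frequency bin sits at (n/2 + 1, n/2 + 1)
fftshift2 <- function(m) {
  h <- nrow(m); w <- ncol(m)
  ri <- c((floor(h / 2) + 1):h, 1:floor(h / 2))
  ci <- c((floor(w / 2) + 1):w, 1:floor(w / 2))
  m[ri, ci]
}

#' Accumulated magnitude spectrum of the difference images
#'
#' Element-wise sum over frames of the magnitude of each centred 2D Fourier
#' transform. Magnitudes (not complex values) are summed: the pattern's
#' phase moves with the dancer, so complex sums would cancel across frames
#' while magnitudes add coherently. Each difference image has its mean
#' removed first to suppress a spurious DC peak.
#'
#' @param diffs h x w x m array of signed difference images (m >= 1).
#' @return h x w accumulated magnitude spectrum, zero frequency at the
#'   center, symmetric under point reflection.
#' @export
accumulate_spectrum <- function(diffs) {
  if (length(dim(diffs)) != 3) diffs <- array(diffs, dim = c(dim(diffs), 1))
  acc <- matrix(0, dim(diffs)[1], dim(diffs)[2])
  for (t in seq_len(dim(diffs)[3])) {
    d <- diffs[, , t]
    acc <- acc + Mod(stats::fft(d - mean(d)))
  }
  fftshift2(acc)
}

## ring radius (frequency bins) of the expected Gabor pattern:
## k = I_size / T with period T = 2 x
dog_ring_radius <- function(image_size, lateral_step)
  image_size / (2 * lateral_step)

#' Ring-shaped difference-of-Gaussians bandpass
#'
#' Multiplies the centred spectrum by the radial profile
#' `exp(-rho^2 / (2 k^2)) - exp(-rho^2 / (2 (k/2)^2))` (surround sigma k,
#' center sigma k/2), normalised to peak gain 1. The profile is zero at the
#' origin, peaks near radius `k = I_size / (2 x)` and suppresses energy far
#' from the ring — a Mexican-hat-type annulus around the lateral-motion
#' frequency.
#'
#' @param spectrum square centred magnitude spectrum.
#' @param cfg an [orientation_config()].
#' @return filtered spectrum of the same size.
#' @export
dog_bandpass <- function(spectrum, cfg) {
  I <- nrow(spectrum)
  if (ncol(spectrum) != I) stop("spectrum must be square")
  k <- dog_ring_radius(I, cfg$lateral_step)
  if (k >= I / 2)
    stop("bandpass ring radius k = I_size/(2x) lies outside Nyquist; ",
         "increase lateral_step or image size")
  spectrum * dog_ring(I, k)
}

dog_ring <- function(I, k) {
  c0 <- floor(I / 2) + 1
  u <- matrix(rep(seq_len(I) - c0, each = I), nrow = I)
  v <- matrix(rep(seq_len(I) - c0, times = I), nrow = I)
  rho2 <- u^2 + v^2
  D <- exp(-rho2 / (2 * k^2)) - exp(-rho2 / (2 * (k / 2)^2))
  D / max(D)
}

#' Movement axis of the filtered spectrum via weighted PCA
#'
#' The filtered spectrum is treated as a weighted point cloud of frequency
#' coordinates; its principal axis is the lateral-movement direction, and
#' the body axis is that direction plus 90 degrees (mod 180).
#'
#' @param spectrum filtered, centred, nonnegative spectrum.
#' @return list with `axis_deg` (body axis, degrees in [0, 180)),
#'   `lateral_deg`, `eigen_ratio` and `degenerate` (TRUE when the spectrum
#'   is near-isotropic, eigenvalue ratio < 1.05).
#' @export
pca_axis <- function(spectrum) {
  I <- nrow(spectrum)
  if (all(spectrum == 0)) stop("spectrum is all zero")
  c0 <- floor(I / 2) + 1
  u <- matrix(rep(seq_len(I) - c0, each = I), nrow = I)   # freq-x
  v <- matrix(rep(seq_len(I) - c0, times = I), nrow = I)  # freq-y
  w <- pmax(spectrum, 0)
  sw <- sum(w)
  # second moments about the origin (spectrum is point-symmetric)
  C <- matrix(c(sum(w * u * u), sum(w * u * v),
                sum(w * u * v), sum(w * v * v)) / sw, 2, 2)
  e <- eigen(C, symmetric = TRUE)
  ratio <- e$values[1] / max(e$values[2], .Machine$double.eps)
  vec <- e$vectors[, 1]
  lateral <- vector_heading(vec[1], vec[2]) %% 180
  list(axis_deg = (lateral + 90) %% 180, lateral_deg = lateral,
       eigen_ratio = ratio, degenerate = ratio < 1.05)
}

#' Disambiguate the two possible headings using forward motion
#'
#' The dot-detector positions of a run trace the dancer's path. Positions
#' are referenced to the average of the first `anchor_fraction` of frames,
#' their directions are histogrammed, and the modal direction (ties
#' averaged circularly) picks whichever of `axis_deg` / `axis_deg + 180`
#' it is circularly closer to.
#'
#' @param axis_deg body axis in [0, 180).
#' @param positions n x 2 matrix of per-frame dancer positions (x, y),
#'   frame order.
#' @param cfg an [orientation_config()].
#' @return list with `direction_deg` in [0, 360), `margin` =
#'   |cos(angle between modal heading and chosen direction)| in [0, 1],
#'   and `degenerate` (TRUE when there is no usable forward motion, in
#'   which case `direction_deg = axis_deg` and `margin = 0`).
#' @export
disambiguate <- function(axis_deg, positions, cfg) {
  positions <- as.matrix(positions)
  n <- nrow(positions)
  if (n < 1) stop("positions must be non-empty")
  n_anchor <- max(1L, ceiling(cfg$anchor_fraction * n))
  anchor <- colMeans(positions[seq_len(n_anchor), , drop = FALSE])
  dx <- positions[, 1] - anchor[1]
  dy <- positions[, 2] - anchor[2]
  keep <- sqrt(dx^2 + dy^2) > 1e-9
  if (!any(keep))
    return(list(direction_deg = axis_deg %% 360, margin = 0,
                degenerate = TRUE))
  ang <- vector_heading(dx[keep], dy[keep])
  width <- 360 / cfg$histogram_bins
  counts <- tabulate(pmin(floor(ang / width) + 1L, cfg$histogram_bins),
                     nbins = cfg$histogram_bins)
  modal <- which(counts == max(counts))
  centers <- (modal - 0.5) * width
  heading <- rad2deg(atan2(mean(sin(deg2rad(centers))),
                           mean(cos(deg2rad(centers))))) %% 360
  cand <- c(axis_deg %% 360, (axis_deg + 180) %% 360)
  d <- circ_dist_deg(heading, cand)
  direction <- cand[which.min(d)]
  list(direction_deg = direction,
       margin = abs(cos(deg2rad(min(d)))),
       degenerate = FALSE, heading_deg = heading)
}

#' Decode the orientation of one waggle run
#'
#' Full orientation pipeline: difference images, accumulated magnitude
#' spectrum, ring bandpass, PCA axis, forward-motion disambiguation.
#'
#' @param frames snippet sequence (h x w x n array).
#' @param positions per-frame dancer positions (n x 2), same run.
#' @param cfg an [orientation_config()].
#' @return object of class `orientation_result`: `axis_deg` in [0, 180),
#'   `direction_deg` in [0, 360) with `direction_deg %% 180 == axis_deg`,
#'   `margin`, and `degenerate` (axis PCA near-isotropic or no forward
#'   motion; such runs are still returned so the mapping stage can reject
#'   them as outliers).
#' @export
decode_orientation <- function(frames, positions, cfg) {
  spec <- accumulate_spectrum(difference_images(frames))
  filt <- dog_bandpass(spec, cfg)
  ax <- pca_axis(filt)
  dis <- disambiguate(ax$axis_deg, positions, cfg)
  structure(list(
    axis_deg = ax$axis_deg,
    direction_deg = dis$direction_deg,
    margin = if (ax$degenerate) 0 else dis$margin,
    degenerate = ax$degenerate || dis$degenerate,
    eigen_ratio = ax$eigen_ratio
  ), class = "orientation_result")
}

#' @export
print.orientation_result <- function(x, ...) {
  cat(sprintf("Orientation: %.1f deg (axis %.1f deg, margin %.2f%s)\n",
              x$direction_deg, x$axis_deg, x$margin,
              if (x$degenerate) ", degenerate" else ""))
  invisible(x)
}

#' Decode orientation for a detected run and write it back
#'
#' @param run a `waggle_run` carrying its `$snippet` (from
#'   [export_snippet()] or [detect_waggle_runs()]).
#' @param cfg an [orientation_config()].
#' @return the run with `orientation_deg` set and the full
#'   `orientation_result` attached as `$orientation`.
#' @export
decode_run <- function(run, cfg) {
  if (is.null(run$snippet))
    stop(sprintf("run %s has no snippet sequence", run$id))
  res <- tryCatch(
    decode_orientation(run$snippet$frames, run$snippet$meta$centroids, cfg),
    error = function(e)
      stop(sprintf("run %s: %s", run$id, conditionMessage(e)), call. = FALSE))
  run$orientation_deg <- res$direction_deg
  run$orientation <- res
  run
}
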