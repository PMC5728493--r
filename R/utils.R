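#' @useDynLib beewaggle, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm runif sd hclust cutree dist fft quantile
#' @importFrom utils read.csv write.csv
NULL

## Angle conventions used throughout:
##   image coordinates: x = column (rightwards), y = row (downwards)
##   headings/axes in degrees, 0 = image "up", increasing clockwise
##   (so 90 points image-right), matching the comb convention where
##   "up" corresponds to the solar azimuth.

deg2rad <- function(d) d * pi / 180
rad2deg <- function(r) r * 180 / pi

#' Unit vector for a clockwise-from-up heading
#'
#' @param deg heading in degrees (0 = image up, clockwise positive).
#' @return numeric c(dx, dy) in image coordinates (y down).
#' @export
heading_vector <- function(deg) {
  r <- deg2rad(deg)
  c(sin(r), -cos(r))
}

#' Heading of an image-space vector
#'
#' @param dx,dy displacement in image coordinates (y down).
#' @return degrees in [0, 360), clockwise from image up.
#' @export
vector_heading <- function(dx, dy) {
  (rad2deg(atan2(dx, -dy))) %% 360
}

#' Signed circular difference a - b in (-180, 180]
#' @param a,b angles in degrees.
#' @export
circ_diff_deg <- function(a, b) {
  d <- (a - b) %% 360
  ifelse(d > 180, d - 360, d)
}

#' Absolute circular distance in [0, 180]
#' @param a,b angles in degrees.
#' @export
circ_dist_deg <- function(a, b) abs(circ_diff_deg(a, b))

## circular SD (degrees) from the mean resultant length
circ_sd_deg <- function(angles_deg) {
  r <- deg2rad(angles_deg)
  R <- sqrt(mean(cos(r))^2 + mean(sin(r))^2)
  rad2deg(sqrt(-2 * log(max(R, .Machine$double.eps))))
}

## Evaluate `code` under a fixed RNG seed without disturbing the caller's
## RNG stream. seed = NULL leaves the current stream untouched.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

stop_if_not_scalar_pos <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
    stop(sprintf("'%s' must be a positive finite scalar", name), call. = FALSE)
}
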