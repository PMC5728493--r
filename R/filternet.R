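#' Filter-network configuration
#'
#' A compact 3D convolutional classifier scores exported snippet sequences
#' so non-waggle detections can be discarded: two stacked 3D convolution
#' layers with SELU nonlinearities, average pooling over all three
#' dimensions (time, height, width), dropout after the pooling, and a
#' fully connected layer with a sigmoid output. The convolutions are
#' strided, which takes the role of intermediate downsampling and keeps
#' training tractable on a single CPU.
#'
#' @param clip_len training subsequence length in frames; shorter
#'   detections are zero-padded, longer ones are randomly subsampled per
#'   batch.
#' @param input_size snippet side length in px.
#' @param conv_channels channels of the two conv layers.
#' @param kernel_size cubic kernel side.
#' @param conv_stride per-layer stride (time = space).
#' @param dropout_rate dropout probability on the pooled features.
#' @param threshold decision threshold on the sigmoid output.
#' @param lr Adam learning rate.
#' @param epochs,batch_size training schedule.
#' @param val_fraction held-out fraction of the labeled data.
#' @param seed seed fixing the split, initialisation, subsequence
#'   sampling, augmentation and dropout.
#' @return object of class `filter_config`.
#' @export
filter_config <- function(clip_len = 128, input_size = 50,
                          conv_channels = c(8, 16), kernel_size = 3,
                          conv_stride = c(2, 2), dropout_rate = 0.1,
                          threshold = 0.5, lr = 3e-3, epochs = 10,
                          batch_size = 16, val_fraction = 0.2,
                          seed = NULL) {
  if (clip_len < 1) stop("clip_len must be >= 1")
  if (val_fraction <= 0 || val_fraction >= 1)
    stop("val_fraction must be in (0, 1)")
  if (dropout_rate < 0 || dropout_rate >= 1)
    stop("dropout_rate must be in [0, 1)")
  structure(list(clip_len = as.integer(clip_len),
                 input_size = as.integer(input_size),
                 conv_channels = as.integer(conv_channels),
                 kernel_size = as.integer(kernel_size),
                 conv_stride = as.integer(conv_stride),
                 dropout_rate = dropout_rate, threshold = threshold,
                 optimizer = "adam", lr = lr, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 val_fraction = val_fraction, seed = seed),
            class = "filter_config")
}

#' A labeled clip for filter-network training
#' @param frames h x w x n array of grey values (0-255).
#' @param label `"waggle"` or `"non_waggle"`.
#' @export
labeled_clip <- function(frames, label = c("waggle", "non_waggle")) {
  structure(list(frames = frames, label = match.arg(label)),
            class = "labeled_clip")
}

#' Initialise the network parameters
#'
#' The architecture is a pure function of the configuration; the returned
#' untrained model reports its parameter count.
#'
#' @param cfg a [filter_config()].
#' @param seed overrides `cfg$seed` for the weight draw.
#' @return object of class `filternet` with flat parameter vector
#'   `$params`.
#' @export
build_filternet <- function(cfg, seed = cfg$seed) {
  K <- cfg$kernel_size
  c1 <- cfg$conv_channels[1]; c2 <- cfg$conv_channels[2]
  n <- cpp_filternet_nparam(cfg$input_size, cfg$input_size, cfg$clip_len,
                            K, c1, c2, cfg$conv_stride[1],
                            cfg$conv_stride[2])
  params <- with_seed(seed, {
    # LeCun-normal initialisation (the SELU self-normalising choice)
    p <- numeric(n)
    nW1 <- K^3 * c1
    p[seq_len(nW1)] <- rnorm(nW1, sd = 1 / sqrt(K^3))
    oW2 <- nW1 + c1
    nW2 <- K^3 * c1 * c2
    p[oW2 + seq_len(nW2)] <- rnorm(nW2, sd = 1 / sqrt(K^3 * c1))
    ow3 <- oW2 + nW2 + c2
    p[ow3 + seq_len(c2)] <- rnorm(c2, sd = 1 / sqrt(c2))
    p
  })
  structure(list(cfg = cfg, params = params, n_params = n,
                 trained = FALSE), class = "filternet")
}

#' @export
print.filternet <- function(x, ...) {
  cfg <- x$cfg
  cat(sprintf(
    "3D conv filter net: %d->%d channels, %d^3 kernels, stride %d/%d, %d parameters (%s)\n",
    cfg$conv_channels[1], cfg$conv_channels[2], cfg$kernel_size,
    cfg$conv_stride[1], cfg$conv_stride[2], x$n_params,
    if (x$trained) "trained" else "untrained"))
  if (!is.null(x$val))
    cat(sprintf("  validation accuracy %.4f (n = %d) at threshold %.2f\n",
                x$val$accuracy, x$val$n, cfg$threshold))
  invisible(x)
}

#' Random horizontal/vertical flip augmentation
#'
#' Independently flips the clip along the image-horizontal and
#' image-vertical axes with probability 0.5 each (no temporal flip);
#' labels are unaffected.
#'
#' @param clip h x w x n array.
#' @param flip_h,flip_v force a specific flip (for tests); `NULL` draws
#'   from the current RNG stream.
#' @return the (possibly) flipped clip.
#' @export
augment_clip <- function(clip, flip_h = NULL, flip_v = NULL) {
  if (is.null(flip_h)) flip_h <- runif(1) < 0.5
  if (is.null(flip_v)) flip_v <- runif(1) < 0.5
  if (flip_h) clip <- clip[, dim(clip)[2]:1, , drop = FALSE]
  if (flip_v) clip <- clip[dim(clip)[1]:1, , , drop = FALSE]
  clip
}

## exactly clip_len frames: zero-pad at the end, or take a window
## (random start while training, first window otherwise)
fit_clip_length <- function(frames, clip_len, random_start = FALSE) {
  n <- dim(frames)[3]
  if (n == clip_len) return(frames)
  if (n < clip_len) {
    out <- array(0, dim = c(dim(frames)[1], dim(frames)[2], clip_len))
    out[, , seq_len(n)] <- frames
    return(out)
  }
  s <- if (random_start) sample.int(n - clip_len + 1L, 1L) else 1L
  frames[, , s:(s + clip_len - 1L), drop = FALSE]
}

filternet_eval <- function(model, clip01) {
  cfg <- model$cfg
  cpp_filternet_sample(clip01, model$params, cfg$kernel_size,
                       cfg$conv_channels[1], cfg$conv_channels[2],
                       cfg$conv_stride[1], cfg$conv_stride[2],
                       rep(1, cfg$conv_channels[2]), 0, FALSE)$prob
}

## standardise a clip to zero mean / unit variance over its real frames;
## zero-padding frames (all-zero by construction) are set to the mean, so
## classifying a short clip equals classifying its zero-padded version
normalize_clip <- function(clip) {
  nz <- apply(clip, 3, function(f) any(f != 0))
  if (!any(nz)) return(clip)
  v <- clip[, , nz, drop = FALSE]
  s <- stats::sd(v)
  if (!is.finite(s) || s < 1e-9) s <- 1
  out <- (clip - mean(v)) / s
  out[, , !nz] <- 0
  out
}

#' Classify clips with a filter network
#'
#' Dropout is disabled; clips shorter than `clip_len` are zero-padded
#' (identical output to their padded version by construction), longer
#' clips are scored on their first `clip_len` frames. Inputs are
#' standardised per clip (zero mean, unit variance over the real frames),
#' which makes the classifier invariant to illumination gain/offset and
#' keeps activations in the range the SELU nonlinearity self-normalises.
#'
#' @param object a trained or untrained `filternet`.
#' @param clips a single h x w x n array, a list of such arrays, or a list
#'   of [labeled_clip()]s.
#' @param ... unused.
#' @return numeric vector of waggle probabilities in (0, 1).
#' @export
predict.filternet <- function(object, clips, ...) {
  if (is.array(clips)) clips <- list(clips)
  vapply(clips, function(cl) {
    if (inherits(cl, "labeled_clip")) cl <- cl$frames
    clip <- normalize_clip(fit_clip_length(cl, object$cfg$clip_len))
    filternet_eval(object, clip)
  }, 0)
}

#' Train the filter network
#'
#' Adam on binary cross-entropy. Per batch, a random `clip_len`-frame
#' subsequence is drawn from each longer detection, shorter ones are
#' zero-padded, and clips are randomly flipped horizontally/vertically.
#' A `val_fraction` split (fixed by the seed) is held out and scored
#' after training.
#'
#' @param clips list of [labeled_clip()]s; both labels must be present.
#' @param cfg a [filter_config()].
#' @param verbose print per-epoch loss.
#' @return a trained `filternet` with `$val` metrics (accuracy at the
#'   configured threshold, precision-recall curve over thresholds) and
#'   `$history` of epoch losses.
#' @export
train_filternet <- function(clips, cfg, verbose = FALSE) {
  labels <- vapply(clips, function(c) c$label, "")
  if (length(unique(labels)) < 2)
    stop("training data must contain both labels")
  y <- as.numeric(labels == "waggle")
  with_seed(cfg$seed, {
    model <- build_filternet(cfg, seed = NULL)
    n <- length(clips)
    val_idx <- sample.int(n, max(1L, round(cfg$val_fraction * n)))
    train_idx <- setdiff(seq_len(n), val_idx)
    p <- model$params
    m <- numeric(length(p)); v <- numeric(length(p))
    b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
    step <- 0L
    c2 <- cfg$conv_channels[2]
    history <- numeric(cfg$epochs)
    for (ep in seq_len(cfg$epochs)) {
      ord <- sample(train_idx)
      ep_loss <- 0
      for (bs in split(ord, ceiling(seq_along(ord) / cfg$batch_size))) {
        g <- numeric(length(p))
        bl <- 0
        for (i in bs) {
          clip <- fit_clip_length(clips[[i]]$frames, cfg$clip_len,
                                  random_start = TRUE)
          clip <- normalize_clip(augment_clip(clip))
          mask <- if (cfg$dropout_rate > 0)
            (runif(c2) >= cfg$dropout_rate) / (1 - cfg$dropout_rate)
          else rep(1, c2)
          r <- cpp_filternet_sample(clip, p, cfg$kernel_size,
                                    cfg$conv_channels[1], c2,
                                    cfg$conv_stride[1], cfg$conv_stride[2],
                                    mask, y[i], TRUE)
          if (!is.finite(r$loss))
            stop("non-finite training loss; lower the learning rate")
          g <- g + r$grad
          bl <- bl + r$loss
        }
        g <- g / length(bs)
        step <- step + 1L
        m <- b1 * m + (1 - b1) * g
        v <- b2 * v + (1 - b2) * g^2
        mh <- m / (1 - b1^step)
        vh <- v / (1 - b2^step)
        p <- p - cfg$lr * mh / (sqrt(vh) + eps)
        ep_loss <- ep_loss + bl
      }
      history[ep] <- ep_loss / length(ord)
      if (verbose)
        message(sprintf("epoch %d/%d: loss %.4f", ep, cfg$epochs,
                        history[ep]))
    }
    model$params <- p
    model$trained <- TRUE
    model$history <- history
    probs <- predict(model, clips[val_idx])
    model$val <- c(list(n = length(val_idx), probs = probs,
                        labels = y[val_idx]),
                   threshold_metrics(probs, y[val_idx], cfg$threshold))
    model
  })
}

## accuracy/precision/recall at one threshold plus the whole realized
## precision-recall curve
threshold_metrics <- function(probs, y, threshold) {
  pred <- as.numeric(probs >= threshold)
  acc <- mean(pred == y)
  prec <- if (any(pred == 1)) mean(y[pred == 1] == 1) else NA_real_
  rec <- if (any(y == 1)) mean(pred[y == 1] == 1) else NA_real_
  ths <- sort(unique(c(0, probs, 1)))
  curve <- data.frame(
    threshold = ths,
    precision = vapply(ths, function(t) {
      pr <- probs >= t
      if (!any(pr)) NA_real_ else mean(y[pr] == 1)
    }, 0),
    recall = vapply(ths, function(t) mean(probs[y == 1] >= t), 0),
    accuracy = vapply(ths, function(t)
      mean((probs >= t) == (y == 1)), 0))
  list(accuracy = acc, precision = prec, recall = rec, curve = curve)
}

#' Save / load a filter-network checkpoint
#'
#' A plain-JSON checkpoint holding the flat parameter vector with its
#' embedded configuration.
#'
#' @param model a `filternet`.
#' @param path checkpoint file.
#' @export
save_filternet <- function(model, path) {
  cfg <- unclass(model$cfg)
  cfg$conv_channels <- as.list(cfg$conv_channels)
  cfg$conv_stride <- as.list(cfg$conv_stride)
  jsonlite::write_json(list(config = cfg, params = model$params,
                            trained = model$trained,
                            accuracy = model$val$accuracy),
                       path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname save_filternet
#' @export
load_filternet <- function(path) {
  ck <- jsonlite::read_json(path, simplifyVector = TRUE)
  args <- ck$config[setdiff(names(ck$config), "optimizer")]
  args$conv_channels <- unlist(args$conv_channels)
  args$conv_stride <- unlist(args$conv_stride)
  cfg <- do.call(filter_config, args)
  model <- build_filternet(cfg, seed = 0)
  model$params <- as.numeric(ck$params)
  model$trained <- isTRUE(ck$trained)
  model
}

#' Score detected runs and flag rejections
#'
#' Every run gets a `confidence` (the network output on its snippet);
#' runs below the threshold are flagged `rejected = TRUE` but kept, never
#' silently dropped. Runs without a snippet get a per-run error record
#' and processing continues.
#'
#' @param runs list of `waggle_run`s carrying `$snippet`.
#' @param model a trained `filternet`.
#' @param threshold defaults to the model's configured threshold.
#' @return the runs, annotated.
#' @export
filter_runs <- function(runs, model, threshold = model$cfg$threshold) {
  lapply(runs, function(r) {
    if (is.null(r$snippet)) {
      r$filter_error <- "missing snippet sequence"
      r$rejected <- NA
      return(r)
    }
    r$confidence <- predict(model, r$snippet$frames)
    r$rejected <- r$confidence < threshold
    r
  })
}
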