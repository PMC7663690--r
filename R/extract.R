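#' Build 10 Hz key frames from a frame stack
#'
#' Key frame k is the elementwise mean of raw frames `[10k, 10k+10)`;
#' a trailing remainder of fewer than 10 frames is dropped. Segmentation,
#' centroid tracking and mask bookkeeping all operate at this 10 Hz cadence.
#'
#' @param stack A `frame_stack` (at least 10 frames).
#' @return List of class `keyframes`: `images` (list of matrices),
#'   `t` (block start times, `10 * index / fps` for 0-based index), `fps_key`.
#' @export
make_keyframes <- function(stack) {
  stopifnot(inherits(stack, "frame_stack"))
  n <- dim(stack$counts)[1]
  if (n < 10L) stop("need at least 10 frames")
  K <- n %/% 10L
  images <- vector("list", K)
  for (k in seq_len(K)) {
    idx <- (10L * (k - 1L) + 1L):(10L * k)
    images[[k]] <- colMeans(stack$counts[idx, , , drop = FALSE], dims = 1)
  }
  structure(list(images = images,
                 t = 10 * (seq_len(K) - 1L) / stack$fps + stack$t0,
                 fps_key = stack$fps / 10),
            class = "keyframes")
}

#' Percentile-trimmed mean of masked pixels
#'
#' Masked pixel values below the `p_low` percentile or above the `p_high`
#' percentile (linear-interpolation convention, strict inequality) are
#' discarded before averaging, excluding outliers caused by segmentation
#' errors at the mask border.
#'
#' @param frame Numeric matrix.
#' @param mask Logical matrix of the same shape with at least 10 TRUE pixels.
#' @param p_low,p_high Percentile cuts (defaults 10 and 90).
#' @return Scalar mean intensity.
#' @export
trimmed_masked_mean <- function(frame, mask, p_low = 10, p_high = 90) {
  stopifnot(p_low >= 0, p_high <= 100, p_low < p_high)
  v <- frame[mask]
  if (length(v) < 10L)
    stop(structure(class = c("spadppg_mask_unusable", "error", "condition"),
                   list(message = "mask unusable: fewer than 10 skin pixels",
                        call = sys.call(-1))))
  q <- stats::quantile(v, c(p_low, p_high) / 100, names = FALSE, type = 7)
  mean(v[v >= q[1] & v <= q[2]])
}

#' Extract the raw pulse signal from a frame stack
#'
#' Every raw frame is reduced to the trimmed mean of its skin pixels, using
#' the mask of its own 10-frame key block. At each key-frame boundary where
#' the mask changes, the step between the first sample under the new mask
#' and the last sample under the old one is subtracted from all subsequent
#' samples, so mask-induced level jumps do not enter the signal. The result
#' is kept in a FIFO buffer capped at `capacity` samples (default 6000,
#' one minute at 100 Hz). Unusable masks (fewer than 10 pixels) hold the
#' previous value and set the `held` flag.
#'
#' @param stack A `frame_stack`.
#' @param masks List of logical matrices, one per key frame (at least
#'   `floor(n_frames / 10)` of them).
#' @param p_low,p_high Trimming percentiles (defaults 10, 90).
#' @param capacity Buffer capacity in samples (default 6000).
#' @return Object of class `pulse_signal`: `samples`, `t` (seconds),
#'   `fs`, `held` (logical), `mask_pixels` (per-sample mask size),
#'   `capacity`, `t_last`.
#' @export
extract_pulse_signal <- function(stack, masks, p_low = 10, p_high = 90,
                                 capacity = 6000L) {
  stopifnot(inherits(stack, "frame_stack"))
  n <- dim(stack$counts)[1]
  K <- n %/% 10L
  if (length(masks) < K) stop("need one mask per key frame")
  samples <- numeric(K * 10L)
  held <- logical(K * 10L)
  npix <- integer(K * 10L)
  offset <- 0
  last_emitted <- NA_real_
  prev_mask <- NULL
  for (k in seq_len(K)) {
    mask <- masks[[k]]
    frames_k <- (10L * (k - 1L) + 1L):(10L * k)
    usable <- sum(mask) >= 10L
    if (!usable) {
      hold <- if (is.na(last_emitted)) 0 else last_emitted
      samples[frames_k] <- hold
      held[frames_k] <- TRUE
      npix[frames_k] <- sum(mask)
      # an unusable block does not update prev_mask: the offset is taken
      # against the last mask that actually produced samples
      next
    }
    sub <- matrix(stack$counts[frames_k, , , drop = FALSE],
                  nrow = 10L)[, as.vector(mask), drop = FALSE]
    raw <- apply(sub, 1L, function(v) {
      q <- stats::quantile(v, c(p_low, p_high) / 100, names = FALSE, type = 7)
      mean(v[v >= q[1] & v <= q[2]])
    })
    if (!is.null(prev_mask) && !identical(mask, prev_mask) &&
        !is.na(last_emitted)) {
      offset <- offset + (raw[1L] - offset - last_emitted)
    }
    samples[frames_k] <- raw - offset
    npix[frames_k] <- sum(mask)
    last_emitted <- samples[frames_k[10L]]
    prev_mask <- mask
  }
  t <- (seq_len(K * 10L) - 1L) / stack$fps + stack$t0
  if (length(samples) > capacity) {
    keep <- (length(samples) - capacity + 1L):length(samples)
    samples <- samples[keep]; held <- held[keep]
    npix <- npix[keep]; t <- t[keep]
  }
  structure(list(samples = samples, t = t, fs = stack$fps, held = held,
                 mask_pixels = npix, capacity = capacity,
                 t_last = t[length(t)]),
            class = "pulse_signal")
}

#' @export
print.pulse_signal <- function(x, ...) {
  cat(sprintf(
    "Pulse signal: %d samples at %g Hz (%.1f s, buffer capacity %d)\n",
    length(x$samples), x$fs, length(x$samples) / x$fs, x$capacity))
  if (any(x$held))
    cat(sprintf("  %d samples held over unusable masks\n", sum(x$held)))
  invisible(x)
}
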