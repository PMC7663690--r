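#' Track the skin-mask centroid at 10 Hz
#'
#' The head position proxy: per key frame, the mean (row, col) coordinate
#' of the mask's skin pixels. Empty masks hold the previous centroid and
#' are flagged; if every mask is empty there is no track.
#'
#' @param masks List of per-key-frame logical matrices.
#' @param fps_key Key-frame rate in Hz (default 10).
#' @return List: `t`, `row`, `col`, `held` (logical).
#' @export
track_centroid <- function(masks, fps_key = 10) {
  K <- length(masks)
  if (K == 0L || all(vapply(masks, function(m) sum(m) == 0L, logical(1))))
    stop("no track: all masks empty")
  row <- col <- numeric(K)
  held <- logical(K)
  last <- NULL
  for (k in seq_len(K)) {
    m <- masks[[k]]
    if (sum(m) == 0L) {
      if (is.null(last)) { row[k] <- NA; col[k] <- NA }
      else { row[k] <- last[1]; col[k] <- last[2] }
      held[k] <- TRUE
    } else {
      w <- which(m, arr.ind = TRUE)
      row[k] <- mean(w[, 1]); col[k] <- mean(w[, 2])
      last <- c(row[k], col[k])
    }
  }
  # leading empties (before any valid centroid) take the first valid one
  if (anyNA(row)) {
    first <- which(!is.na(row))[1L]
    row[seq_len(first - 1L)] <- row[first]
    col[seq_len(first - 1L)] <- col[first]
  }
  list(t = (seq_len(K) - 1L) / fps_key, row = row, col = col, held = held)
}

#' Project a 2D centroid track onto its principal component
#'
#' Mean-centers the (row, col) points and projects them onto the leading
#' eigenvector of their 2 x 2 covariance, collapsing the head movement into
#' one signal. Sign convention: the first non-zero displacement projects
#' positively. Zero covariance (a perfectly static track) yields an
#' all-zero signal flagged `static`.
#'
#' @param x,y Numeric coordinate series (at least 20 samples).
#' @return Numeric 1D movement signal with attribute `static` (logical).
#' @export
pca_project <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 20L)
  pts <- cbind(x - mean(x), y - mean(y))
  cv <- crossprod(pts) / (nrow(pts) - 1L)
  if (all(abs(cv) < 1e-30))
    return(structure(numeric(nrow(pts)), static = TRUE))
  ev <- eigen(cv, symmetric = TRUE)
  proj <- as.numeric(pts %*% ev$vectors[, 1L])
  nz <- which(proj != 0)[1L]
  if (!is.na(nz) && proj[nz] < 0) proj <- -proj
  structure(proj, static = FALSE)
}

#' Spectral peak-area dependability score
#'
#' Locates the global maximum of a (DC-excluded) power spectrum, walks left
#' and right to the first bins at or below `frac` (default 25%) of the peak
#' value (or the band edges), and integrates the spectrum between them by
#' the trapezoid rule. The score is that area as a fraction of the total
#' band area: near 1 when one periodic component dominates, much lower for
#' broadband noise. A flatness guard additionally requires the peak to
#' exceed `flatness_factor` times the band median before the score can
#' raise a flag, because a flat spectrum would otherwise degenerate to a
#' full-band "peak" with score 1.
#'
#' @param power Nonnegative spectrum values.
#' @param f Frequencies (Hz) matching `power`; bins at `f == 0` are
#'   excluded from the peak search.
#' @param frac Flank level as a fraction of the peak (default 0.25).
#' @param threshold Flag threshold on the score (default 0.5).
#' @param flatness_factor Peak-to-median guard factor (default 3).
#' @return Object of class `dependability_score`: `score`, `peak_freq`,
#'   `flagged`, `threshold`, `flat`.
#' @export
peak_area_score <- function(power, f = seq_along(power), frac = 0.25,
                            threshold = 0.5, flatness_factor = 3) {
  stopifnot(length(power) == length(f), all(power >= 0))
  use <- f != 0
  if (!any(use) || all(power[use] == 0)) stop("all-zero spectrum")
  pw <- power[use]; fq <- f[use]
  ipk <- which.max(pw)
  pk <- pw[ipk]
  lev <- frac * pk
  lo <- ipk
  while (lo > 1L && pw[lo] > lev) lo <- lo - 1L
  hi <- ipk
  n <- length(pw)
  while (hi < n && pw[hi] > lev) hi <- hi + 1L
  total <- trapz(fq, pw)
  peak_area <- if (hi > lo) trapz(fq[lo:hi], pw[lo:hi]) else 0
  score <- if (total > 0) peak_area / total else 0
  flat <- pk <= flatness_factor * stats::median(pw)
  structure(list(score = score, peak_freq = fq[ipk],
                 flagged = (score > threshold) && !flat,
                 threshold = threshold, flat = flat),
            class = "dependability_score")
}

#' @export
print.dependability_score <- function(x, ...) {
  cat(sprintf(
    "Dependability score %.3f (peak %.2f Hz, threshold %.2f): %s%s\n",
    x$score, x$peak_freq, x$threshold,
    if (x$flagged) "FLAGGED" else "not flagged",
    if (x$flat) " [flat spectrum guard]" else ""))
  invisible(x)
}

#' Detect periodic head movement from the mask centroid
#'
#' Centroid track (10 Hz) -> principal-component projection -> mean-removed
#' Hann-windowed spectrum restricted to the 0.4--4 Hz heart-rate band ->
#' peak-area score. Periodic motion in the band concentrates spectral area
#' under one peak and raises the flag.
#'
#' @param masks List of per-key-frame logical masks covering >= 30 s.
#' @param fps_key Key-frame rate in Hz (default 10).
#' @param threshold Flag threshold (default 0.5).
#' @param band Analysis band in Hz (default `c(0.4, 4)`).
#' @param frac Peak flank fraction (default 0.25).
#' @return A `dependability_score`.
#' @export
check_periodic_movement <- function(masks, fps_key = 10, threshold = 0.5,
                                    band = c(0.4, 4), frac = 0.25) {
  if (length(masks) < 30 * fps_key)
    stop("need at least 30 s of key frames")
  tr <- track_centroid(masks, fps_key)
  proj <- pca_project(tr$row, tr$col)
  if (isTRUE(attr(proj, "static"))) {
    return(structure(list(score = 0, peak_freq = NA_real_, flagged = FALSE,
                          threshold = threshold, flat = TRUE),
                     class = "dependability_score"))
  }
  pg <- periodogram(as.numeric(proj), fps_key, "hann")
  sel <- pg$f >= band[1] & pg$f <= band[2]
  peak_area_score(pg$power[sel], pg$f[sel], frac = frac,
                  threshold = threshold)
}

#' Extract the background (environmental) light signal
#'
#' Per raw frame, the mean of pixels outside the frame's key mask, at the
#' full frame rate.
#'
#' @param stack A `frame_stack`.
#' @param masks List of per-key-frame logical masks.
#' @return Numeric vector, one value per raw frame (trailing frames beyond
#'   the last key block are dropped).
#' @export
background_signal <- function(stack, masks) {
  stopifnot(inherits(stack, "frame_stack"))
  n <- dim(stack$counts)[1]
  K <- min(n %/% 10L, length(masks))
  out <- numeric(K * 10L)
  for (k in seq_len(K)) {
    bg <- !masks[[k]]
    if (sum(bg) == 0L) stop("no background: mask covers the whole frame")
    frames_k <- (10L * (k - 1L) + 1L):(10L * k)
    sub <- matrix(stack$counts[frames_k, , , drop = FALSE],
                  nrow = 10L)[, as.vector(bg), drop = FALSE]
    out[frames_k] <- rowMeans(sub)
  }
  out
}

#' Detect pulsating background light
#'
#' The background light signal is bandpassed with the same heart-rate-band
#' filter as the pulse, its post-transient spectrum restricted to the
#' analysis band, and scored with [peak_area_score()]. Sinusoidal ambient
#' light inside the band concentrates the spectral area and raises the
#' flag.
#'
#' @param stack A `frame_stack` covering >= 30 s.
#' @param masks List of per-key-frame logical masks.
#' @param threshold Flag threshold (default 0.5).
#' @param band Analysis band in Hz (default `c(0.4, 4)`).
#' @param frac Peak flank fraction (default 0.25).
#' @param spec Bandpass design (defaults to [design_bandpass()]).
#' @return A `dependability_score`.
#' @export
check_pulsating_light <- function(stack, masks, threshold = 0.5,
                                  band = c(0.4, 4), frac = 0.25,
                                  spec = design_bandpass()) {
  n <- dim(stack$counts)[1]
  if (n < 30 * stack$fps) stop("need at least 30 s of frames")
  bg <- background_signal(stack, masks)
  fsig <- apply_filter(bg, spec, fs = stack$fps)
  pt <- post_transient(fsig)
  pg <- periodogram(pt$samples, pt$fs, "hann")
  sel <- pg$f >= band[1] & pg$f <= band[2]
  peak_area_score(pg$power[sel], pg$f[sel], frac = frac,
                  threshold = threshold)
}

#' First flag time of a dependability check under streaming evaluation
#'
#' Emulates the real-time system: the check re-runs every `update` seconds
#' on the most recent (up to `buffer`-second) window, starting once
#' `min_window` seconds are available. Returns the signal time at which the
#' check first flags, or `Inf` if it never does — the detection latency is
#' bounded by the buffer length plus one update interval.
#'
#' @param stack A `frame_stack`.
#' @param masks Per-key-frame masks.
#' @param check `"light"` or `"movement"`.
#' @param threshold Flag threshold (default 0.5).
#' @param update Update interval in seconds (default 1).
#' @param min_window Shortest analyzed window in seconds (default 30).
#' @param buffer Longest analyzed window in seconds (default 60).
#' @return First flag time in seconds (`Inf` when never flagged).
#' @export
dependability_latency <- function(stack, masks, check = c("light", "movement"),
                                  threshold = 0.5, update = 1,
                                  min_window = 30, buffer = 60) {
  check <- match.arg(check)
  n <- dim(stack$counts)[1]
  dur <- n / stack$fps
  for (t_end in seq(min_window, dur, by = update)) {
    t_start <- max(0, t_end - buffer)
    k_range <- (floor(t_start * stack$fps / 10) + 1L):floor(t_end * stack$fps / 10)
    sc <- if (check == "movement") {
      check_periodic_movement(masks[k_range], fps_key = stack$fps / 10,
                              threshold = threshold)
    } else {
      f_range <- (10L * (k_range[1L] - 1L) + 1L):(10L * k_range[length(k_range)])
      sub <- structure(list(counts = stack$counts[f_range, , , drop = FALSE],
                            fps = stack$fps, t0 = 0),
                       class = "frame_stack")
      check_pulsating_light(sub, masks[k_range], threshold = threshold)
    }
    if (sc$flagged) return(t_end)
  }
  Inf
}
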