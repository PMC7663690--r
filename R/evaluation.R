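#' Pan-Tompkins QRS detection
#'
#' The classic reference detector used to anchor the evaluation: zero-phase
#' 5--15 Hz bandpass, five-point derivative, squaring, 150 ms
#' moving-window integration, then adaptive dual-threshold peak
#' classification with search-back for missed beats. R-peak times are
#' refined to the local maximum of the raw trace near each accepted
#' integration peak.
#'
#' @param ecg Numeric single-lead trace, or the list from
#'   [synthesize_ecg()].
#' @param fs Sampling rate in Hz (>= 200; unnecessary when `ecg` carries
#'   its own).
#' @return Numeric vector of R-peak times in seconds.
#' @export
pan_tompkins_qrs <- function(ecg, fs = NULL) {
  if (is.list(ecg)) { fs <- ecg$fs; ecg <- ecg$trace }
  if (is.null(fs) || fs < 200) stop("fs must be at least 200 Hz")
  n <- length(ecg)
  if (n < 10 * fs) stop("need at least 10 s of ECG")
  if (max(ecg) - min(ecg) < 1e-12) stop("no QRS found: flat trace")
  bp <- signal::butter(2, c(5, 15) / (fs / 2), type = "pass")
  xf <- as.numeric(signal::filtfilt(bp, ecg))
  d <- (fs / 8) * c(1, 2, 0, -2, -1)
  xd <- as.numeric(stats::filter(xf, d, sides = 2))
  xd[is.na(xd)] <- 0
  xs <- xd^2
  wl <- max(3L, round(0.15 * fs))
  xi <- as.numeric(stats::filter(xs, rep(1 / wl, wl), sides = 2))
  xi[is.na(xi)] <- 0
  t <- (seq_len(n) - 1L) / fs

  # candidate integration peaks, 200 ms refractory
  cand <- local_maxima(xi)
  if (length(cand) == 0L) stop("no QRS found")
  refr <- round(0.2 * fs)
  keep <- logical(length(cand))
  last <- -Inf
  ord <- order(xi[cand], decreasing = TRUE)
  sel <- rep(FALSE, length(cand))
  for (j in ord) {
    if (all(abs(cand[j] - cand[sel]) >= refr)) sel[j] <- TRUE
  }
  cand <- sort(cand[sel])

  spki <- max(xi[seq_len(min(n, 2 * fs))]) / 3
  npki <- mean(xi[seq_len(min(n, 2 * fs))]) / 2
  thr1 <- function() npki + 0.25 * (spki - npki)
  qrs <- integer(0)
  rr_hist <- numeric(0)
  for (i in cand) {
    p <- xi[i]
    if (p > thr1()) {
      qrs <- c(qrs, i)
      spki <- 0.125 * p + 0.875 * spki
      if (length(qrs) >= 2L)
        rr_hist <- utils::tail(c(rr_hist, diff(utils::tail(qrs, 2L))), 8L)
    } else {
      npki <- 0.125 * p + 0.875 * npki
      # search-back: a long gap re-examines this candidate at half threshold
      if (length(qrs) >= 2L && length(rr_hist) > 0L) {
        if ((i - qrs[length(qrs)]) > 1.66 * mean(rr_hist) &&
            p > 0.5 * thr1()) {
          qrs <- c(qrs, i)
          spki <- 0.25 * p + 0.75 * spki
          rr_hist <- utils::tail(c(rr_hist, diff(utils::tail(qrs, 2L))), 8L)
        }
      }
    }
  }
  if (length(qrs) == 0L) stop("no QRS found")
  # refine each R time on the raw trace (integration window is centered,
  # so the search is symmetric around the integration peak)
  half <- round(0.1 * fs)
  r_idx <- vapply(qrs, function(i) {
    a <- max(1L, i - half); b <- min(n, i + half)
    as.integer(a + which.max(ecg[a:b]) - 1L)
  }, integer(1))
  r_idx <- sort(unique(r_idx))
  # drop refined duplicates closer than the refractory period
  if (length(r_idx) > 1L) {
    ok <- c(TRUE, diff(r_idx) >= refr)
    r_idx <- r_idx[ok]
  }
  t[r_idx]
}

#' Match detected beat times against a reference
#'
#' Greedy one-to-one matching within a tolerance; the standard
#' recall/precision bookkeeping for beat detectors.
#'
#' @param detected,reference Numeric times in seconds.
#' @param tol Matching tolerance in seconds (default 0.05).
#' @return List: `recall`, `precision`, `n_matched`, `matched_ref`
#'   (logical per reference beat).
#' @export
match_beats <- function(detected, reference, tol = 0.05) {
  matched_ref <- logical(length(reference))
  matched_det <- logical(length(detected))
  for (i in seq_along(reference)) {
    d <- abs(detected - reference[i])
    d[matched_det] <- Inf
    j <- which.min(d)
    if (length(j) && d[j] <= tol) {
      matched_ref[i] <- TRUE
      matched_det[j] <- TRUE
    }
  }
  list(recall = if (length(reference)) mean(matched_ref) else NA_real_,
       precision = if (length(detected)) mean(matched_det) else NA_real_,
       n_matched = sum(matched_ref), matched_ref = matched_ref)
}

#' Segment a pulse signal into per-beat rows
#'
#' The pulse between consecutive R times (shifted by the pulse transit lag,
#' default 200 ms) is resampled to `n_points` samples by linear
#' interpolation and L2-normalized, one row per beat. Spans with fewer
#' than 4 raw samples, or extending beyond the record, are dropped.
#'
#' @param pulse Numeric pulse series, a `pulse_signal`, or a
#'   `filtered_signal`.
#' @param r_times Reference R-peak times in seconds (>= 6, giving >= 5
#'   complete RR spans).
#' @param fs Sampling rate for a bare numeric `pulse`.
#' @param n_points Samples per resampled beat (default 100).
#' @param lag Pulse transit lag added to the R times in seconds
#'   (default 0.2; set 0 to disable).
#' @return Object of class `beat_matrix`: numeric matrix
#'   (n_beats x n_points), every row unit-norm.
#' @export
segment_beats <- function(pulse, r_times, fs = NULL, n_points = 100,
                          lag = 0.2) {
  if (inherits(pulse, "pulse_signal") || inherits(pulse, "filtered_signal")) {
    tt <- pulse$t; x <- pulse$samples
  } else {
    x <- as.numeric(pulse)
    if (is.null(fs)) stop("fs required")
    tt <- (seq_along(x) - 1L) / fs
  }
  if (length(r_times) < 6L) stop("need at least 5 complete RR spans")
  rows <- list()
  for (i in seq_len(length(r_times) - 1L)) {
    a <- r_times[i] + lag
    b <- r_times[i + 1L] + lag
    if (a < tt[1L] || b > tt[length(tt)]) next
    if (sum(tt >= a & tt < b) < 4L) next
    xi <- seq(a, b, length.out = n_points)
    v <- stats::approx(tt, x, xout = xi)$y
    nrm <- sqrt(sum(v^2))
    if (nrm == 0) next
    rows[[length(rows) + 1L]] <- v / nrm
  }
  if (length(rows) < 2L) stop("fewer than 2 usable beats")
  structure(do.call(rbind, rows), class = "beat_matrix")
}

#' Per-point standard deviation of segmented beats
#'
#' Column-wise sample (n-1 denominator) standard deviation of the
#' L2-normalized beat matrix; small values mean a reproducible beat shape.
#'
#' @param matrix A `beat_matrix` with at least 2 rows.
#' @return List: `per_point` (numeric vector), `mean_std` (scalar summary).
#' @export
beat_shape_std <- function(matrix) {
  if (nrow(matrix) < 2L) stop("need at least 2 beats")
  per_point <- apply(unclass(matrix), 2L, stats::sd)
  list(per_point = per_point, mean_std = mean(per_point))
}

#' Estimation-error metrics
#'
#' `hr_error()`: absolute heart-rate difference in beats/min.
#' `respiration_error()`: absolute respiration-rate difference in
#' breaths/min. `lf_hf_error()`: percent and absolute error of the LF/HF
#' ratio against a positive reference.
#'
#' @param est,ref Estimated and reference values.
#' @return `hr_error`/`respiration_error`: nonnegative scalar;
#'   `lf_hf_error`: list `percent`, `absolute`.
#' @export
hr_error <- function(est, ref) abs(est - ref)

#' @rdname hr_error
#' @export
respiration_error <- function(est, ref) abs(est - ref)

#' @rdname hr_error
#' @export
lf_hf_error <- function(est, ref) {
  if (ref <= 0) stop("reference ratio must be positive")
  list(percent = 100 * abs(est - ref) / ref, absolute = abs(est - ref))
}

#' RMSE between two tachograms
#'
#' Both tachograms are interpolated onto a common uniform grid (default
#' 4 Hz) over their overlap (>= 30 s required) and compared by
#' root-mean-squared error.
#'
#' @param est,ref `tachogram` objects.
#' @param rate Comparison grid rate in Hz (default 4).
#' @return RMSE in seconds.
#' @export
tachogram_rmse <- function(est, ref, rate = 4) {
  stopifnot(inherits(est, "tachogram"), inherits(ref, "tachogram"))
  lo <- max(min(est$t_rr), min(ref$t_rr))
  hi <- min(max(est$t_rr), max(ref$t_rr))
  if (hi - lo < 30) stop("tachogram overlap shorter than 30 s")
  grid <- seq(lo, hi, by = 1 / rate)
  e <- stats::spline(est$t_rr, est$rr, xout = grid)$y
  r <- stats::spline(ref$t_rr, ref$rr, xout = grid)$y
  sqrt(mean((e - r)^2))
}
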