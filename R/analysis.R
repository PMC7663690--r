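#' Estimate the average heart rate from the signal spectrum
#'
#' Magnitude FFT of the mean-removed, Hann-windowed post-transient signal;
#' the heart rate is 60 times the frequency of the spectral peak restricted
#' to the 0.4--4 Hz band. No zero padding is applied, so on a full
#' one-minute buffer the frequency resolution is 1/60 Hz, i.e. 1 bpm.
#'
#' @param filtered A `filtered_signal`, or numeric vector with `fs`.
#' @param fs Sampling rate when `filtered` is a bare vector.
#' @param band Search band in Hz (default `c(0.4, 4)`).
#' @param window `"hann"` (default) or `"rect"`.
#' @return Heart rate in beats/min, with attribute `peak_freq` (Hz).
#' @export
estimate_hr_fft <- function(filtered, fs = NULL, band = c(0.4, 4),
                            window = c("hann", "rect")) {
  window <- match.arg(window)
  if (inherits(filtered, "filtered_signal")) {
    pt <- post_transient(filtered)
    x <- pt$samples; fs <- pt$fs
  } else {
    x <- as.numeric(filtered)
    if (is.null(fs)) stop("fs required")
  }
  if (length(x) < 30 * fs) stop("need at least 30 s of post-transient signal")
  pg <- periodogram(x, fs, window)
  sel <- pg$f >= band[1] & pg$f <= band[2]
  if (!any(sel) || all(pg$power[sel] == 0)) stop("degenerate spectrum")
  fpk <- pg$f[sel][which.max(pg$power[sel])]
  structure(60 * fpk, peak_freq = fpk)
}

#' Detect beat peaks with non-maximal suppression
#'
#' Local maxima of the filtered pulse are screened by two criteria: a
#' minimal temporal distance — within any window of width
#' `0.5 * (60 / hr_hint)` seconds only the largest-amplitude maximum
#' survives — and an amplitude cut discarding survivors below
#' `amp_frac` times the 90th percentile of surviving peak amplitudes.
#'
#' @param filtered A `filtered_signal` (transient excluded automatically)
#'   or numeric vector with `fs`.
#' @param fs Sampling rate for a bare vector.
#' @param hr_hint Prior heart rate in beats/min (from [estimate_hr_fft()]).
#' @param amp_frac Amplitude-criterion fraction (default 0.3).
#' @return Numeric vector of peak times in seconds (absolute, i.e. offset
#'   by the transient when a `filtered_signal` is given).
#' @export
detect_beat_peaks <- function(filtered, fs = NULL, hr_hint, amp_frac = 0.3) {
  if (inherits(filtered, "filtered_signal")) {
    pt <- post_transient(filtered)
    x <- pt$samples; fs <- pt$fs; t <- pt$t
  } else {
    x <- as.numeric(filtered)
    if (is.null(fs)) stop("fs required")
    t <- (seq_along(x) - 1L) / fs
  }
  stopifnot(hr_hint > 0)
  cand <- local_maxima(x)
  if (length(cand) == 0L) stop("unanalyzable window: no peaks found")
  w <- 0.5 * 60 / hr_hint
  ord <- cand[order(x[cand], decreasing = TRUE)]
  acc_t <- numeric(0)
  acc_i <- integer(0)
  for (i in ord) {
    if (all(abs(t[i] - acc_t) >= w)) {
      acc_t <- c(acc_t, t[i])
      acc_i <- c(acc_i, i)
    }
  }
  amps <- x[acc_i]
  thr <- amp_frac * stats::quantile(amps, 0.9, names = FALSE, type = 7)
  keep <- amps >= thr
  if (!any(keep)) stop("unanalyzable window: no peaks found")
  sort(acc_t[keep])
}

#' Recover missing beat peaks
#'
#' Wherever the inter-peak gap exceeds `gap_factor` times the mean RR of
#' the current peak set, the local maximum inside the window centered at
#' (previous peak + mean RR) with half-width half the mean RR is inserted.
#' Passes repeat until no gap remains or a pass inserts nothing. Clean
#' inputs pass through unchanged (the operation is idempotent).
#'
#' @param peaks Numeric peak times in seconds (at least 5).
#' @param filtered The `filtered_signal` (or numeric vector with `fs`) the
#'   peaks came from.
#' @param fs Sampling rate for a bare vector.
#' @param gap_factor Gap threshold as a multiple of the mean RR
#'   (default 1.5).
#' @return Augmented, sorted peak times.
#' @export
recover_missing_peaks <- function(peaks, filtered, fs = NULL,
                                  gap_factor = 1.5) {
  if (inherits(filtered, "filtered_signal")) {
    x <- filtered$samples; fs <- filtered$fs; t <- filtered$t
  } else {
    x <- as.numeric(filtered)
    if (is.null(fs)) stop("fs required")
    t <- (seq_along(x) - 1L) / fs
  }
  stopifnot(length(peaks) >= 5L)
  peaks <- sort(peaks)
  for (pass in seq_len(50L)) {
    mrr <- mean(diff(peaks))
    gaps <- which(diff(peaks) > gap_factor * mrr)
    inserted <- numeric(0)
    for (gi in gaps) {
      center <- peaks[gi] + mrr
      lo <- max(center - 0.5 * mrr, peaks[gi] + 1 / fs)
      hi <- min(center + 0.5 * mrr, peaks[gi + 1L] - 1 / fs)
      sel <- which(t >= lo & t <= hi)
      if (length(sel) == 0L) next
      inserted <- c(inserted, t[sel[which.max(x[sel])]])
    }
    if (length(inserted) == 0L) break
    peaks <- sort(unique(c(peaks, inserted)))
  }
  peaks
}

#' Tachogram from beat-peak times
#'
#' RR interval i is `peaks[i+1] - peaks[i]`, timestamped at `peaks[i+1]`.
#'
#' @param peaks Numeric peak times in seconds (at least 2).
#' @return Object of class `tachogram`: `beat_times`, `rr`, `t_rr`.
#' @export
compute_tachogram <- function(peaks) {
  peaks <- sort(as.numeric(peaks))
  if (length(peaks) < 2L) stop("need at least 2 peaks")
  structure(list(beat_times = peaks, rr = diff(peaks), t_rr = peaks[-1L],
                 even_series = NULL, even_t = NULL, resample_rate = NULL),
            class = "tachogram")
}

#' Resample a tachogram onto a uniform grid
#'
#' Cubic-spline interpolation of the (time, RR) points evaluated on a
#' uniform grid (default 4 Hz) restricted to the observed span, the
#' standard preparation for spectral HRV analysis of unevenly sampled RR
#' series.
#'
#' @param tach A `tachogram` with at least 4 RR points spanning >= 10 s.
#' @param rate Resampling rate in Hz (default 4).
#' @return The `tachogram` with `even_series`, `even_t`, `resample_rate`
#'   filled in.
#' @export
resample_tachogram <- function(tach, rate = 4) {
  stopifnot(inherits(tach, "tachogram"))
  if (length(tach$rr) < 4L) stop("need at least 4 RR points")
  span <- range(tach$t_rr)
  if (diff(span) < 10) stop("tachogram span shorter than 10 s")
  grid <- seq(span[1], span[2], by = 1 / rate)
  tach$even_series <- stats::spline(tach$t_rr, tach$rr, xout = grid)$y
  tach$even_t <- grid
  tach$resample_rate <- rate
  tach
}

#' Power spectral density of the evenly resampled tachogram
#'
#' Mean-removed, Hann-windowed one-sided periodogram, scaled so the
#' trapezoid integral of `power` over `f` approximates the RR-series
#' variance (a sinusoidal RR modulation of amplitude A in seconds carries
#' band power A^2/2 s^2).
#'
#' @param tach A resampled `tachogram`, or a numeric even series with
#'   `rate`.
#' @param rate Sampling rate of a bare even series, Hz.
#' @param window `"hann"` (default) or `"rect"`.
#' @return Object of class `tachogram_psd`: `f` (Hz), `power` (s^2/Hz).
#' @export
tachogram_psd <- function(tach, rate = NULL, window = c("hann", "rect")) {
  window <- match.arg(window)
  if (inherits(tach, "tachogram")) {
    if (is.null(tach$even_series)) tach <- resample_tachogram(tach)
    x <- tach$even_series; rate <- tach$resample_rate
  } else {
    x <- as.numeric(tach)
    if (is.null(rate)) stop("rate required")
  }
  if (length(x) < 60 * rate)
    warning("tachogram shorter than 60 s; spectral estimates are coarse")
  pg <- periodogram(x, rate, window)
  structure(list(f = pg$f, power = pg$power, rate = rate, window = window),
            class = "tachogram_psd")
}

#' LF and HF band powers of a tachogram PSD
#'
#' LF is the trapezoid area under the PSD between 0.04 and 0.15 Hz, HF the
#' area from 0.15 to 0.4 Hz; the LF/HF ratio indexes sympathovagal balance.
#' A zero HF power flags the ratio as undefined (`NA` with attribute).
#'
#' @param psd A `tachogram_psd`.
#' @param lf_band,hf_band Band limits in Hz.
#' @return List: `lf_power`, `hf_power` (s^2), `ratio`,
#'   `ratio_defined` (logical).
#' @export
lf_hf <- function(psd, lf_band = c(0.04, 0.15), hf_band = c(0.15, 0.4)) {
  stopifnot(inherits(psd, "tachogram_psd"))
  band_area <- function(band) {
    sel <- psd$f >= band[1] & psd$f <= band[2]
    if (sum(sel) < 2L) return(0)
    trapz(psd$f[sel], psd$power[sel])
  }
  lf <- band_area(lf_band)
  hf <- band_area(hf_band)
  defined <- hf > 0
  list(lf_power = lf, hf_power = hf,
       ratio = if (defined) lf / hf else NA_real_,
       ratio_defined = defined)
}

#' Respiration rate from the tachogram PSD
#'
#' Respiratory sinus arrhythmia concentrates tachogram power at the
#' breathing frequency; the respiration rate is 60 times the frequency of
#' the PSD maximum within the HF band (0.15--0.4 Hz).
#'
#' @param psd A `tachogram_psd`.
#' @param band HF search band in Hz (default `c(0.15, 0.4)`).
#' @param flatness_factor The estimate is flagged low-confidence when the
#'   band maximum is below this multiple of the band median (default 3).
#' @return Breaths/min, with attributes `peak_freq` (Hz) and
#'   `low_confidence` (logical).
#' @export
respiration_rate <- function(psd, band = c(0.15, 0.4), flatness_factor = 3) {
  stopifnot(inherits(psd, "tachogram_psd"))
  sel <- psd$f >= band[1] & psd$f <= band[2]
  if (!any(sel)) stop("PSD does not resolve the HF band")
  p <- psd$power[sel]
  fpk <- psd$f[sel][which.max(p)]
  structure(60 * fpk, peak_freq = fpk,
            low_confidence = max(p) < flatness_factor * stats::median(p))
}
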