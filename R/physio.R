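#' Physiological parameters for the beat-timeline generator
#'
#' Bundles and validates the parameters of the two-sinusoid instantaneous-RR
#' model used to simulate heart-rate variability. The instantaneous RR
#' interval is
#' \deqn{RR(t) = 60/\mathrm{mean\_hr} + a_{LF}\sin(2\pi f_{LF} t)
#'              + a_{HF}\sin(2\pi f_{HF} t),}
#' with the low-frequency term in the 0.04--0.15 Hz sympathovagal band and
#' the respiratory (high-frequency) term in 0.15--0.4 Hz, so the LF/HF band
#' power ratio of the resulting tachogram has the analytic ground truth
#' \eqn{(a_{LF}/a_{HF})^2}.
#'
#' @param mean_hr Mean heart rate in beats/min, within the 24--240 bpm
#'   analysis band.
#' @param lf_freq Low-frequency modulation in Hz, in [0.04, 0.15).
#' @param lf_amp Amplitude of the LF RR modulation in seconds.
#' @param resp_freq Respiratory modulation in Hz, in [0.15, 0.4].
#' @param resp_amp Amplitude of the respiratory RR modulation in seconds.
#' @param duration Record length in seconds.
#' @param rr_jitter_sd Standard deviation in seconds of optional white
#'   beat-to-beat jitter (0 disables it, the default).
#' @param seed Integer seed used only when `rr_jitter_sd > 0`.
#' @return An object of class `physio_params` (a validated list).
#' @export
physio_params <- function(mean_hr = 72, lf_freq = 0.1, lf_amp = 0,
                          resp_freq = 0.25, resp_amp = 0, duration = 60,
                          rr_jitter_sd = 0, seed = NULL) {
  stopifnot(mean_hr >= 24, mean_hr <= 240,
            lf_freq >= 0.04, lf_freq < 0.15,
            resp_freq >= 0.15, resp_freq <= 0.4,
            lf_amp >= 0, resp_amp >= 0, duration > 0, rr_jitter_sd >= 0)
  if (60 / mean_hr - (lf_amp + resp_amp) <= 0.25)
    stop("modulation amplitudes too large: minimum RR would fall below 0.25 s")
  structure(list(mean_hr = mean_hr, lf_freq = lf_freq, lf_amp = lf_amp,
                 resp_freq = resp_freq, resp_amp = resp_amp,
                 duration = duration, rr_jitter_sd = rr_jitter_sd,
                 seed = seed),
            class = "physio_params")
}

#' Generate a beat timeline from an instantaneous-RR model
#'
#' Beats are placed iteratively: \eqn{t_0 = 0} and
#' \eqn{t_{k+1} = t_k + RR(t_k)} with the two-sinusoid instantaneous RR of
#' [physio_params()], until `duration` is exceeded. With both modulation
#' amplitudes at zero every interval equals `60/mean_hr` exactly. Optional
#' white jitter (off by default) adds `rnorm(sd = rr_jitter_sd)` per
#' interval under `seed`.
#'
#' @param params A `physio_params` object.
#' @return An object of class `beat_timeline`: list with `beat_times`
#'   (strictly increasing, seconds, within `[0, duration)`) and
#'   `rr_intervals` (their first differences).
#' @export
generate_rr_series <- function(params) {
  stopifnot(inherits(params, "physio_params"))
  rr_of <- function(t) {
    60 / params$mean_hr +
      params$lf_amp * sin(2 * pi * params$lf_freq * t) +
      params$resp_amp * sin(2 * pi * params$resp_freq * t)
  }
  n_max <- ceiling(params$duration * params$mean_hr / 60) + 16L
  jitter <- if (params$rr_jitter_sd > 0) {
    with_seed(params$seed, stats::rnorm(n_max, 0, params$rr_jitter_sd))
  } else rep(0, n_max)
  times <- numeric(n_max)
  t <- 0
  k <- 1L
  while (t < params$duration) {
    times[k] <- t
    rr <- rr_of(t) + jitter[k]
    if (rr <= 0.25 || rr >= 2.5)
      stop("RR interval outside (0.25, 2.5) s; adjust parameters")
    t <- t + rr
    k <- k + 1L
    if (k > n_max) {  # jitter shortened intervals beyond the preallocation
      times <- c(times, numeric(n_max))
      jitter <- c(jitter, if (params$rr_jitter_sd > 0)
        stats::rnorm(n_max, 0, params$rr_jitter_sd) else rep(0, n_max))
      n_max <- length(times)
    }
  }
  times <- times[seq_len(k - 1L)]
  structure(list(beat_times = times, rr_intervals = diff(times)),
            class = "beat_timeline")
}

#' Synthesize a unit-amplitude pulse waveform from a beat timeline
#'
#' Each beat contributes a stereotyped kernel with the sharp systolic
#' upstroke seen in photoplethysmographic beats: a fast rise over
#' `0.15 * RR`, an exponential decay, and an optional dicrotic bump at
#' `0.4 * RR` of 30% amplitude. The waveform is normalized to zero mean and
#' unit peak amplitude. An empty timeline yields an all-zero signal.
#'
#' @param timeline A `beat_timeline`.
#' @param fps Sampling rate in Hz (default 100, the camera frame rate).
#' @param duration Record length in seconds.
#' @param dicrotic Logical; include the dicrotic bump (default TRUE).
#' @return Numeric vector of length `round(duration * fps)`.
#' @export
synthesize_pulse_signal <- function(timeline, fps = 100, duration,
                                    dicrotic = TRUE) {
  stopifnot(inherits(timeline, "beat_timeline"))
  n <- round(duration * fps)
  x <- numeric(n)
  bt <- timeline$beat_times
  if (length(bt) == 0L) return(x)
  rr <- timeline$rr_intervals
  rr_last <- if (length(rr)) rr[length(rr)] else 60 / 75
  rr_k <- c(rr, rr_last)  # kernel span of the final beat reuses the last RR
  for (k in seq_along(bt)) {
    i0 <- floor(bt[k] * fps) + 1L
    i1 <- min(n, floor((bt[k] + rr_k[k]) * fps))
    if (i0 > n) break
    idx <- i0:i1
    u <- ((idx - 1L) / fps - bt[k]) / rr_k[k]  # beat phase in [0, 1)
    kern <- ifelse(u < 0.15,
                   sin(pi / 2 * u / 0.15)^2,
                   exp(-(u - 0.15) / 0.25))
    if (dicrotic) kern <- kern + 0.3 * exp(-(u - 0.4)^2 / (2 * 0.05^2))
    x[idx] <- x[idx] + kern
  }
  x <- x - mean(x)
  m <- max(abs(x))
  if (m > 0) x <- x / m
  x
}

#' Synthesize an ECG-like reference trace for a beat timeline
#'
#' Builds a single-lead surrogate ECG: narrow Gaussian R spikes (sigma
#' 10 ms, amplitude 1) at the beat times, over smaller P- and T-wave bumps,
#' plus additive white Gaussian noise. The true R-peak sample indices are
#' returned for use as evaluation ground truth.
#'
#' @param timeline A `beat_timeline`.
#' @param fs Sampling rate in Hz, at least 100 (default 250).
#' @param duration Record length in seconds; defaults to covering the
#'   timeline plus one final interval.
#' @param noise_sd Standard deviation of the additive noise (default 0.02).
#' @param seed Integer seed for the noise.
#' @return List with `trace` (numeric), `fs`, `t` (seconds),
#'   `r_indices` (1-based sample indices of the true R peaks) and
#'   `r_times` (seconds).
#' @export
synthesize_ecg <- function(timeline, fs = 250, duration = NULL,
                           noise_sd = 0.02, seed = NULL) {
  stopifnot(inherits(timeline, "beat_timeline"), fs >= 100)
  bt <- timeline$beat_times
  if (is.null(duration)) {
    rr <- timeline$rr_intervals
    duration <- if (length(bt)) max(bt) + (if (length(rr)) rr[length(rr)] else 1) else 1
  }
  n <- round(duration * fs)
  t <- (seq_len(n) - 1L) / fs
  trace <- numeric(n)
  rr <- c(timeline$rr_intervals,
          if (length(timeline$rr_intervals))
            timeline$rr_intervals[length(timeline$rr_intervals)] else 0.8)
  gauss <- function(center, sd, amp) {
    i0 <- max(1L, floor((center - 5 * sd) * fs))
    i1 <- min(n, ceiling((center + 5 * sd) * fs))
    if (i0 > n || i1 < 1L) return(invisible(NULL))
    idx <- i0:i1
    trace[idx] <<- trace[idx] + amp * exp(-(t[idx] - center)^2 / (2 * sd^2))
    invisible(NULL)
  }
  for (k in seq_along(bt)) {
    gauss(bt[k], 0.010, 1)                       # R spike
    gauss(bt[k] - 0.16 * rr[k], 0.025, 0.12)     # P wave
    gauss(bt[k] + 0.30 * rr[k], 0.050, 0.25)     # T wave
  }
  if (noise_sd > 0)
    trace <- trace + with_seed(seed, stats::rnorm(n, 0, noise_sd))
  r_idx <- round(bt * fs) + 1L
  r_idx <- r_idx[r_idx >= 1L & r_idx <= n]
  list(trace = trace, fs = fs, t = t, r_indices = r_idx,
       r_times = (r_idx - 1L) / fs)
}
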