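#' Design the heart-rate-band bandpass filter
#'
#' A fixed biquad with real zeros at \eqn{z = \pm 1} and real poles at
#' \eqn{z = 0.824} and \eqn{z = 0.966} (at 100 Hz sampling):
#' \deqn{H(z) = g\,\frac{(z-1)(z+1)}{(z-0.824)(z-0.966)}.}
#' The zeros null DC and the Nyquist frequency exactly; the passband covers
#' the 0.4--4 Hz heart-rate band (24--240 bpm). The gain `g` normalizes the
#' peak in-band magnitude response to 1.
#'
#' @param zeros Real z-plane zeros (default `c(1, -1)`).
#' @param poles Real z-plane poles, magnitudes < 1 (default
#'   `c(0.824, 0.966)`).
#' @param fs Sampling rate in Hz (default 100).
#' @param band Passband in Hz (default `c(0.4, 4)`), used only for gain
#'   normalization and downstream band restriction.
#' @return Object of class `bandpass_spec`: `b`, `a` (difference-equation
#'   coefficients), `zeros`, `poles`, `fs`, `band`, `gain`.
#' @export
design_bandpass <- function(zeros = c(1, -1), poles = c(0.824, 0.966),
                            fs = 100, band = c(0.4, 4)) {
  stopifnot(length(zeros) == 2L, length(poles) == 2L, all(abs(poles) < 1))
  b <- c(1, -sum(zeros), prod(zeros))
  a <- c(1, -sum(poles), prod(poles))
  f <- seq(band[1], band[2], length.out = 4001L)
  resp <- function(fq) {
    z <- exp(1i * 2 * pi * fq / fs)
    (z^2 * b[1] + z * b[2] + b[3]) / (z^2 * a[1] + z * a[2] + a[3])
  }
  g <- 1 / max(Mod(resp(f)))
  structure(list(b = g * b, a = a, zeros = zeros, poles = poles,
                 fs = fs, band = band, gain = g),
            class = "bandpass_spec")
}

#' Magnitude response of a bandpass design
#'
#' @param spec A `bandpass_spec`.
#' @param f Frequencies in Hz.
#' @return Numeric vector `|H(e^{j 2 pi f / fs})|`.
#' @export
bandpass_response <- function(spec, f) {
  stopifnot(inherits(spec, "bandpass_spec"))
  z <- exp(1i * 2 * pi * f / spec$fs)
  num <- spec$b[1] * z^2 + spec$b[2] * z + spec$b[3]
  den <- spec$a[1] * z^2 + spec$a[2] * z + spec$a[3]
  Mod(num / den)
}

#' Apply the bandpass filter to a pulse signal
#'
#' Causal difference-equation filtering. The first `transient` seconds
#' (default 5) of output are flagged and excluded from downstream peak and
#' spectral analysis while the filter state settles.
#'
#' @param x A `pulse_signal` or numeric vector (then `fs` is required).
#' @param spec A `bandpass_spec` (defaults to [design_bandpass()]).
#' @param fs Sampling rate when `x` is a bare vector.
#' @param transient Transient length in seconds flagged at the start.
#' @return Object of class `filtered_signal`: `samples`, `t`, `fs`,
#'   `transient` (logical flags), `spec`.
#' @export
apply_filter <- function(x, spec = design_bandpass(), fs = NULL,
                         transient = 5) {
  if (inherits(x, "pulse_signal")) {
    v <- x$samples; fs <- x$fs; t <- x$t
  } else {
    v <- as.numeric(x)
    if (is.null(fs)) stop("fs required for a bare numeric signal")
    t <- (seq_along(v) - 1L) / fs
  }
  if (length(v) < 10 * fs) stop("need at least 10 s of signal")
  y <- as.numeric(signal::filter(spec$b, spec$a, v))
  trans <- t < t[1L] + transient
  structure(list(samples = y, t = t, fs = fs, transient = trans,
                 spec = spec),
            class = "filtered_signal")
}

# post-transient view of a filtered signal
post_transient <- function(fsig) {
  keep <- !fsig$transient
  list(samples = fsig$samples[keep], t = fsig$t[keep], fs = fsig$fs)
}
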