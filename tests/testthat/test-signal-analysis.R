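test_that("bandpass nulls DC and Nyquist exactly and passes the HR band", {
  spec <- design_bandpass()
  peak <- max(bandpass_response(spec, seq(0.4, 4, 0.01)))
  expect_lt(bandpass_response(spec, 0) / peak, 1e-12)
  expect_lt(bandpass_response(spec, 50) / peak, 1e-12)
  # band edges attenuated, mid-band nearly at peak gain
  expect_lt(bandpass_response(spec, 0.05) / peak, 0.15)
  expect_gt(bandpass_response(spec, 2) / peak, 0.9)
  # out-of-band power rejection at 0.05 Hz is over an order of magnitude
  expect_gt((bandpass_response(spec, 2) / bandpass_response(spec, 0.05))^2, 10)
  expect_equal(peak, 1, tolerance = 1e-3)
})

test_that("transfer function agrees with direct pole-zero evaluation", {
  spec <- design_bandpass()
  f <- c(0.05, 0.4, 1, 2, 4, 10, 25)
  z <- exp(1i * 2 * pi * f / 100)
  ref <- spec$gain * Mod((z - 1) * (z + 1) / ((z - 0.824) * (z - 0.966)))
  expect_equal(bandpass_response(spec, f), ref, tolerance = 1e-12)
})

test_that("filtering rejects DC and keeps in-band sinusoids", {
  y <- apply_filter(rep(3, 3000), fs = 100)
  expect_lt(max(abs(spadppg:::post_transient(y)$samples)), 1e-6 * 3)
  t <- (0:5999) / 100
  y2 <- apply_filter(sin(2 * pi * 1.2 * t), fs = 100)
  amp <- max(abs(spadppg:::post_transient(y2)$samples))
  expect_gt(amp, 0.5)
  expect_lte(amp, 1.0 + 1e-6)
  # energy of DC + in-band + out-of-band mixture concentrates in-band
  x <- 5 + sin(2 * pi * 1.2 * t) + 0.8 * sin(2 * pi * 30 * t)
  pt <- spadppg:::post_transient(apply_filter(x, fs = 100))
  pg <- spadppg:::periodogram(pt$samples, 100, "rect")
  inband <- pg$f > 1.0 & pg$f < 1.4
  expect_gt(sum(pg$power[inband]) / sum(pg$power), 0.9)
  expect_error(apply_filter(rep(1, 100), fs = 100), "10 s")
})

test_that("FFT heart rate is exact on-bin and picks the dominant tone", {
  t <- (0:5999) / 100
  hr <- estimate_hr_fft(sin(2 * pi * 1.2 * t), fs = 100)
  expect_equal(as.numeric(hr), 72)
  two <- sin(2 * pi * 1.0 * t) + 0.5 * sin(2 * pi * 2.0 * t)
  expect_equal(as.numeric(estimate_hr_fft(two, fs = 100)), 60)
})

test_that("simulated pulse recovers the set mean heart rate", {
  std <- std_recording()
  fit <- rppg(std$stack, std$truth$true_masks, dependability = FALSE)
  expect_lt(abs(fit$hr - 72), 1)
})

test_that("peak detection on a pure sinusoid finds every cycle", {
  t <- (0:1499) / 100
  pk <- detect_beat_peaks(apply_filter(sin(2 * pi * t), fs = 100),
                          hr_hint = 60)
  expect_equal(length(pk), 10)
  expect_equal(diff(pk), rep(1, 9), tolerance = 0.02)
})

test_that("clean pulse train yields correctly spaced beats", {
  filt <- constant_filtered()
  hr <- estimate_hr_fft(filt)
  pk <- detect_beat_peaks(filt, hr_hint = as.numeric(hr))
  expect_true(length(pk) %in% c(68, 69))  # 55 s post-transient at rr 0.8
  expect_equal(diff(pk), rep(0.8, length(pk) - 1), tolerance = 0.02)
})

test_that("a halved-amplitude beat still clears the amplitude criterion", {
  filt <- constant_filtered()
  weak <- filt
  # halve one beat's neighbourhood in the filtered signal
  sel <- weak$t >= 20.0 & weak$t < 20.8
  weak$samples[sel] <- weak$samples[sel] * 0.5
  pk <- detect_beat_peaks(weak, hr_hint = 75)
  expect_true(any(pk >= 20 & pk < 20.8))
})

test_that("missing peaks are recovered and recovery is idempotent", {
  filt <- constant_filtered()
  pk <- detect_beat_peaks(filt, hr_hint = 75)
  expect_identical(recover_missing_peaks(pk, filt), pk)
  # delete one interior peak
  del <- pk[-10]
  rec <- recover_missing_peaks(del, filt)
  expect_equal(length(rec), length(pk))
  expect_lt(min(abs(rec - pk[10])), 0.05)
  # two consecutive deletions need two passes
  del2 <- pk[-c(10, 11)]
  rec2 <- recover_missing_peaks(del2, filt)
  expect_equal(length(rec2), length(pk))
  expect_lt(max(abs(sort(rec2) - sort(pk))), 0.05)
})

test_that("tachogram construction takes first differences", {
  tach <- compute_tachogram(c(0, 0.8, 1.6))
  expect_equal(tach$rr, c(0.8, 0.8))
  expect_equal(tach$t_rr, c(0.8, 1.6))
  expect_equal(length(compute_tachogram(seq(0, 10, 0.5))$rr), 20)
  expect_error(compute_tachogram(1), "at least 2")
})

test_that("tachogram resampling reproduces constants and sinusoids", {
  t <- seq(0, 60, 0.8)
  tach <- resample_tachogram(compute_tachogram(t))
  expect_equal(unique(round(diff(tach$even_t), 10)), 0.25)
  expect_equal(tach$even_series, rep(0.8, length(tach$even_t)),
               tolerance = 1e-9)
  # sinusoidally modulated RR: spline recovers the closed form
  tl <- generate_rr_series(physio_params(mean_hr = 75, lf_amp = 0.05,
                                         lf_freq = 0.1, duration = 120))
  tach2 <- resample_tachogram(compute_tachogram(tl$beat_times))
  # RR(t) is attached at the interval end; compare against the generator's
  # instantaneous RR at the preceding beat time
  ref <- approx(tl$beat_times[-1],
                tl$rr_intervals, xout = tach2$even_t)$y
  expect_lt(sqrt(mean((tach2$even_series - ref)^2, na.rm = TRUE)), 0.005)
})

test_that("tachogram PSD satisfies Parseval within tolerance", {
  rate <- 4
  t <- seq(0, 300, 1 / rate)
  x <- 0.05 * sin(2 * pi * 0.1 * t)
  psd <- tachogram_psd(x, rate = rate, window = "rect")
  sel <- psd$f > 0.05 & psd$f < 0.15
  band <- spadppg:::trapz(psd$f[sel], psd$power[sel])
  expect_equal(band, 0.05^2 / 2, tolerance = 0.1)
  set.seed(40)
  w <- rnorm(1200, 0, 0.03)
  psd2 <- tachogram_psd(w, rate = rate, window = "rect")
  expect_equal(spadppg:::trapz(psd2$f, psd2$power), var(w),
               tolerance = 0.1)
  psd3 <- tachogram_psd(rep(0.8, 400), rate = rate)
  expect_lt(max(psd3$power), 1e-20)
})

test_that("LF/HF separates band-pure modulations", {
  mk_psd <- function(lf_amp, hf_amp, lf_f = 0.1, hf_f = 0.3) {
    tl <- generate_rr_series(physio_params(mean_hr = 75, lf_amp = lf_amp,
                                           lf_freq = lf_f, resp_amp = hf_amp,
                                           resp_freq = hf_f, duration = 300))
    tachogram_psd(resample_tachogram(compute_tachogram(tl$beat_times)))
  }
  pure_lf <- lf_hf(mk_psd(0.05, 0))
  expect_gt(pure_lf$lf_power / (pure_lf$lf_power + pure_lf$hf_power), 0.9)
  pure_hf <- lf_hf(mk_psd(0, 0.05))
  expect_lt(pure_hf$lf_power / (pure_hf$lf_power + pure_hf$hf_power), 0.1)
  both <- lf_hf(mk_psd(0.06, 0.03))
  expect_equal(both$ratio, 4, tolerance = 0.3 * 4)
  expect_true(both$ratio_defined)
})

test_that("respiration rate reads the HF peak", {
  tl <- generate_rr_series(physio_params(mean_hr = 75, resp_amp = 0.04,
                                         resp_freq = 0.25, duration = 180))
  psd <- tachogram_psd(resample_tachogram(compute_tachogram(tl$beat_times)))
  expect_equal(as.numeric(respiration_rate(psd)), 15, tolerance = 0.5)
  # synthetic two-tone HF spectrum: argmax wins
  f <- seq(0, 2, 0.01)
  p <- numeric(length(f))
  p[abs(f - 0.2) < 0.005] <- 5
  p[abs(f - 0.35) < 0.005] <- 2
  psd2 <- structure(list(f = f, power = p, rate = 4, window = "rect"),
                    class = "tachogram_psd")
  expect_equal(as.numeric(respiration_rate(psd2)), 12)
})

test_that("band powers are nonnegative and bounded by total variance", {
  tl <- generate_rr_series(physio_params(mean_hr = 70, lf_amp = 0.04,
                                         resp_amp = 0.03, duration = 240))
  tach <- resample_tachogram(compute_tachogram(tl$beat_times))
  psd <- tachogram_psd(tach)
  bands <- lf_hf(psd)
  expect_gte(bands$lf_power, 0)
  expect_gte(bands$hf_power, 0)
  expect_lte(bands$lf_power + bands$hf_power,
             var(tach$even_series) * 1.05)
})
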