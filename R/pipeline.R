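#' Analysis configuration
#'
#' All tunables of the pipeline with their defaults, validated on
#' construction and serializable to flat YAML.
#'
#' @param p_low,p_high Trimming percentiles of the masked average (10, 90).
#' @param capacity Pulse buffer capacity in samples (6000 = one minute at
#'   100 Hz).
#' @param band Heart-rate analysis band in Hz (`c(0.4, 4)`).
#' @param poles,zeros Bandpass pole/zero placement (see
#'   [design_bandpass()]).
#' @param transient Filter transient excluded from analysis, seconds (5).
#' @param amp_frac Peak amplitude-criterion fraction (0.3).
#' @param gap_factor Missing-peak gap threshold, multiples of mean RR (1.5).
#' @param resample_rate Tachogram resampling rate in Hz (4).
#' @param lf_band,hf_band HRV bands in Hz.
#' @param dependability_threshold Flag threshold of both checks (0.5).
#' @param peak_frac Peak-area flank fraction (0.25).
#' @param mask_threshold Binarization cut of probability maps (0.5).
#' @param alpha Asymmetric-loss weight (0.4).
#' @param beat_lag Pulse transit lag for beat segmentation, seconds (0.2).
#' @return Object of class `rppg_config` (a validated list).
#' @export
rppg_config <- function(p_low = 10, p_high = 90, capacity = 6000L,
                        band = c(0.4, 4), poles = c(0.824, 0.966),
                        zeros = c(1, -1), transient = 5, amp_frac = 0.3,
                        gap_factor = 1.5, resample_rate = 4,
                        lf_band = c(0.04, 0.15), hf_band = c(0.15, 0.4),
                        dependability_threshold = 0.5, peak_frac = 0.25,
                        mask_threshold = 0.5, alpha = 0.4, beat_lag = 0.2) {
  stopifnot(p_low >= 0, p_high <= 100, p_low < p_high,
            capacity >= 1000, band[1] > 0, band[2] > band[1],
            all(abs(poles) < 1), transient >= 0,
            amp_frac > 0, amp_frac < 1, gap_factor > 1,
            resample_rate > 0,
            lf_band[1] < lf_band[2], hf_band[1] < hf_band[2],
            dependability_threshold > 0, dependability_threshold < 1,
            peak_frac > 0, peak_frac < 1,
            mask_threshold > 0, mask_threshold < 1,
            alpha > 0, alpha < 0.5, beat_lag >= 0)
  structure(as.list(environment()), class = "rppg_config")
}

#' Read / write an analysis configuration as YAML
#' @param path YAML file path.
#' @param config An `rppg_config`.
#' @return `read_config()` an `rppg_config`; `write_config()` `path`
#'   invisibly.
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(rppg_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown))
    stop("unknown config fields: ", paste(unknown, collapse = ", "))
  do.call(rppg_config, vals)
}

#' @rdname read_config
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "rppg_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Fit the full remote-photoplethysmography analysis to a frame stack
#'
#' The central estimator: converts photon-count video plus per-key-frame
#' skin masks into heart rate, tachogram, LF/HF balance, respiration rate
#' and the two optical dependability scores. Masks may be given directly
#' (a list of logical matrices), produced by a trained [skin_net] applied
#' to the 10 Hz key frames, or taken from simulator ground truth.
#'
#' @param stack A `frame_stack`.
#' @param masks List of per-key-frame logical masks, or a trained
#'   `skin_net` used to segment the key frames.
#' @param config An `rppg_config`.
#' @param dependability Run the movement/light checks (default TRUE;
#'   requires >= 30 s).
#' @return Object of class `rppg` with components `signal`
#'   (`pulse_signal`), `filtered`, `hr` (bpm), `peaks` (s), `tachogram`,
#'   `psd`, `lf_power`, `hf_power`, `lf_hf_ratio`, `resp_rate`
#'   (breaths/min), `movement`, `light` (dependability scores or NULL),
#'   `masks`, `config`.
#' @export
rppg <- function(stack, masks, config = rppg_config(), dependability = TRUE) {
  stopifnot(inherits(stack, "frame_stack"))
  if (inherits(masks, "skin_net")) {
    kf <- make_keyframes(stack)
    maps <- predict(masks, kf$images)
    masks <- lapply(maps, binarize, threshold = config$mask_threshold)
  }
  sig <- extract_pulse_signal(stack, masks, config$p_low, config$p_high,
                              config$capacity)
  spec <- design_bandpass(config$zeros, config$poles, stack$fps, config$band)
  filt <- apply_filter(sig, spec, transient = config$transient)
  hr <- estimate_hr_fft(filt, band = config$band)
  # beats must point upward for sharp-peak detection: blood-volume influx
  # darkens the skin, so the systolic event is a counts dip; orient by the
  # sign of the post-transient skewness (sharp excursions dominate it)
  pt <- post_transient(filt)
  sk <- mean((pt$samples - mean(pt$samples))^3) / stats::sd(pt$samples)^3
  dfilt <- filt
  if (is.finite(sk) && sk < 0) dfilt$samples <- -dfilt$samples
  peaks <- detect_beat_peaks(dfilt, hr_hint = as.numeric(hr),
                             amp_frac = config$amp_frac)
  peaks <- recover_missing_peaks(peaks, dfilt, gap_factor = config$gap_factor)
  tach <- compute_tachogram(peaks)
  tach <- tryCatch(resample_tachogram(tach, config$resample_rate),
                   error = function(e) tach)
  psd <- if (!is.null(tach$even_series))
    suppressWarnings(tachogram_psd(tach)) else NULL
  bands <- if (!is.null(psd)) lf_hf(psd, config$lf_band, config$hf_band)
    else list(lf_power = NA_real_, hf_power = NA_real_, ratio = NA_real_,
              ratio_defined = FALSE)
  resp <- if (!is.null(psd)) as.numeric(respiration_rate(psd, config$hf_band))
    else NA_real_
  movement <- light <- NULL
  if (dependability && dim(stack$counts)[1] >= 30 * stack$fps) {
    movement <- tryCatch(
      check_periodic_movement(masks, stack$fps / 10,
                              config$dependability_threshold, config$band,
                              config$peak_frac),
      error = function(e) NULL)
    light <- tryCatch(
      check_pulsating_light(stack, masks, config$dependability_threshold,
                            config$band, config$peak_frac, spec),
      error = function(e) NULL)
  }
  structure(list(signal = sig, filtered = filt, hr = as.numeric(hr),
                 peaks = peaks, tachogram = tach, psd = psd,
                 lf_power = bands$lf_power, hf_power = bands$hf_power,
                 lf_hf_ratio = bands$ratio, resp_rate = resp,
                 movement = movement, light = light, masks = masks,
                 polarity = if (is.finite(sk) && sk < 0) -1 else 1,
                 config = config),
            class = "rppg")
}

#' @export
print.rppg <- function(x, ...) {
  cat("Remote photoplethysmography analysis\n")
  cat(sprintf("  signal: %.1f s at %g Hz, %d beats detected\n",
              length(x$signal$samples) / x$signal$fs, x$signal$fs,
              length(x$peaks)))
  cat(sprintf("  heart rate: %.1f bpm\n", x$hr))
  if (!is.na(x$lf_hf_ratio))
    cat(sprintf("  LF/HF: %.2f (LF %.2e, HF %.2e s^2)\n",
                x$lf_hf_ratio, x$lf_power, x$hf_power))
  if (!is.na(x$resp_rate))
    cat(sprintf("  respiration: %.1f breaths/min\n", x$resp_rate))
  for (nm in c("movement", "light")) {
    if (!is.null(x[[nm]]))
      cat(sprintf("  %s score: %.3f%s\n", nm, x[[nm]]$score,
                  if (x[[nm]]$flagged) " [FLAGGED]" else ""))
  }
  invisible(x)
}

#' @export
summary.rppg <- function(object, ...) {
  rr <- object$tachogram$rr
  out <- list(hr_bpm = object$hr, n_beats = length(object$peaks),
              mean_rr_s = mean(rr), sd_rr_s = stats::sd(rr),
              lf_power = object$lf_power, hf_power = object$hf_power,
              lf_hf_ratio = object$lf_hf_ratio,
              resp_rate_bpm = object$resp_rate,
              movement_score = if (!is.null(object$movement))
                object$movement$score else NA_real_,
              movement_flag = if (!is.null(object$movement))
                object$movement$flagged else NA,
              light_score = if (!is.null(object$light))
                object$light$score else NA_real_,
              light_flag = if (!is.null(object$light))
                object$light$flagged else NA,
              held_fraction = mean(object$signal$held))
  class(out) <- "summary.rppg"
  out
}

#' @export
print.summary.rppg <- function(x, ...) {
  cat("rPPG estimates\n")
  cat(sprintf("  heart rate      %8.1f bpm   (%d beats, RR %.3f +/- %.3f s)\n",
              x$hr_bpm, x$n_beats, x$mean_rr_s, x$sd_rr_s))
  if (!is.na(x$lf_hf_ratio))
    cat(sprintf("  LF/HF ratio     %8.2f\n", x$lf_hf_ratio))
  if (!is.na(x$resp_rate_bpm))
    cat(sprintf("  respiration     %8.1f breaths/min\n", x$resp_rate_bpm))
  if (!is.na(x$movement_score))
    cat(sprintf("  movement score  %8.3f %s\n", x$movement_score,
                if (isTRUE(x$movement_flag)) "[FLAGGED]" else ""))
  if (!is.na(x$light_score))
    cat(sprintf("  light score     %8.3f %s\n", x$light_score,
                if (isTRUE(x$light_flag)) "[FLAGGED]" else ""))
  if (x$held_fraction > 0)
    cat(sprintf("  held samples    %8.1f %%\n", 100 * x$held_fraction))
  invisible(x)
}

#' @export
coef.rppg <- function(object, ...) {
  c(hr_bpm = object$hr, lf_power = object$lf_power,
    hf_power = object$hf_power, lf_hf_ratio = object$lf_hf_ratio,
    resp_rate_bpm = object$resp_rate)
}

#' @export
plot.rppg <- function(x, ...) {
  op <- graphics::par(mfrow = c(2, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  graphics::plot(x$signal$t, x$signal$samples, type = "l",
                 xlab = "time (s)", ylab = "counts", main = "raw pulse signal")
  pt <- post_transient(x$filtered)
  graphics::plot(pt$t, pt$samples, type = "l", xlab = "time (s)",
                 ylab = "filtered", main = "filtered + beats")
  graphics::abline(v = x$peaks, col = "red", lty = 3)
  graphics::plot(x$tachogram$t_rr, x$tachogram$rr, pch = 20,
                 xlab = "time (s)", ylab = "RR (s)", main = "tachogram")
  if (!is.null(x$tachogram$even_series))
    graphics::lines(x$tachogram$even_t, x$tachogram$even_series, col = "blue")
  if (!is.null(x$psd)) {
    sel <- x$psd$f <= 0.5
    graphics::plot(x$psd$f[sel], x$psd$power[sel], type = "l",
                   xlab = "frequency (Hz)", ylab = "PSD (s^2/Hz)",
                   main = "tachogram PSD")
    graphics::abline(v = c(0.04, 0.15, 0.4), lty = 3, col = "grey")
  }
  invisible(x)
}

#' Run the full simulate -> segment -> extract -> analyze -> evaluate
#' pipeline
#'
#' Batch driver over the package's stages: simulate a recording, obtain
#' masks (ground truth, morphologically degraded, or a trained network),
#' fit [rppg()], and score the estimates against the simulator's ground
#' truth via the surrogate ECG and Pan-Tompkins reference.
#'
#' @param physio A `physio_params`.
#' @param scene A `scene_params`.
#' @param masks `"truth"`, a trained `skin_net`, or a list of masks.
#' @param config An `rppg_config`.
#' @param out_dir Optional directory for CSV/JSON outputs.
#' @return List: `fit` (the `rppg` object), `truth`, `ecg`, `metrics`
#'   (hr_error_bpm, tachogram_rmse_s, lf_hf_percent_error, resp_error_bpm,
#'   mean_beat_std, plus the underlying estimates and references).
#' @export
run_pipeline <- function(physio, scene = scene_params(), masks = "truth",
                         config = rppg_config(), out_dir = NULL) {
  sim <- simulate_recording(physio, scene)
  mask_list <- if (identical(masks, "truth")) sim$truth$true_masks
    else if (inherits(masks, "skin_net")) masks
    else masks
  fit <- rppg(sim$stack, mask_list, config)

  # reference side: Pan-Tompkins on the surrogate ECG
  r_times <- pan_tompkins_qrs(sim$ecg)
  ref_tach <- compute_tachogram(r_times)
  ref_hr <- 60 / mean(ref_tach$rr)
  metrics <- list(hr_est_bpm = fit$hr, hr_ref_bpm = ref_hr,
                  hr_error_bpm = hr_error(fit$hr, ref_hr))
  metrics$tachogram_rmse_s <- tryCatch(
    tachogram_rmse(fit$tachogram, ref_tach, config$resample_rate),
    error = function(e) NA_real_)
  ref_fit <- tryCatch({
    rt <- resample_tachogram(ref_tach, config$resample_rate)
    psd <- suppressWarnings(tachogram_psd(rt))
    list(bands = lf_hf(psd, config$lf_band, config$hf_band),
         resp = as.numeric(respiration_rate(psd, config$hf_band)))
  }, error = function(e) NULL)
  if (!is.null(ref_fit) && isTRUE(ref_fit$bands$ratio_defined) &&
      !is.na(fit$lf_hf_ratio)) {
    err <- lf_hf_error(fit$lf_hf_ratio, ref_fit$bands$ratio)
    metrics$lf_hf_est <- fit$lf_hf_ratio
    metrics$lf_hf_ref <- ref_fit$bands$ratio
    metrics$lf_hf_percent_error <- err$percent
  }
  if (!is.null(ref_fit) && !is.na(fit$resp_rate)) {
    metrics$resp_est_bpm <- fit$resp_rate
    metrics$resp_ref_bpm <- ref_fit$resp
    metrics$resp_error_bpm <- respiration_error(fit$resp_rate, ref_fit$resp)
  }
  metrics$mean_beat_std <- tryCatch({
    bm <- segment_beats(fit$filtered, r_times, n_points = 100,
                        lag = config$beat_lag)
    beat_shape_std(bm)$mean_std
  }, error = function(e) NA_real_)

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_signal_csv(fit$signal, file.path(out_dir, "signal.csv"))
    utils::write.csv(data.frame(t = fit$tachogram$t_rr,
                                rr = fit$tachogram$rr),
                     file.path(out_dir, "tachogram.csv"), row.names = FALSE)
    if (!is.null(fit$psd))
      utils::write.csv(data.frame(f = fit$psd$f, power = fit$psd$power),
                       file.path(out_dir, "psd.csv"), row.names = FALSE)
    jsonlite::write_json(metrics, file.path(out_dir, "metrics.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  list(fit = fit, truth = sim$truth, ecg = sim$ecg, metrics = metrics)
}
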