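#' Scene parameters for the photon-count video simulator
#'
#' Describes the simulated acquisition: an elliptical skin region over a
#' static background, photon-count levels, pulse modulation depth, and the
#' two optical-artifact generators (periodic horizontal head motion and
#' sinusoidally pulsating illumination). Defaults match the 64 x 32 pixel,
#' 100 Hz photon-counting camera geometry.
#'
#' @param rows,cols Frame size in pixels (defaults 32, 64).
#' @param fps Frame rate in Hz (default 100).
#' @param skin_center Numeric (row, col) center of the skin ellipse.
#' @param skin_axes Numeric (row, col) semi-axes of the skin ellipse, pixels.
#' @param skin_mean_counts Expected photon count per skin pixel per frame.
#' @param bg_mean_counts Expected photon count per background pixel per frame.
#' @param modulation_depth Fractional pulse modulation of the skin counts,
#'   in [0, 0.2). The default 2% stands in for the unreported modulation at
#'   the optimal green wavelength.
#' @param motion_amp Amplitude of the left-right head motion, pixels.
#' @param motion_freq Frequency of the head motion, Hz.
#' @param light_amp Fractional amplitude of the pulsating illumination.
#' @param light_freq Frequency of the pulsating illumination, Hz.
#' @param seed Integer seed for the Poisson photon noise.
#' @return An object of class `scene_params`.
#' @export
scene_params <- function(rows = 32, cols = 64, fps = 100,
                         skin_center = c(16.5, 32.5), skin_axes = c(10, 16),
                         skin_mean_counts = 500, bg_mean_counts = 50,
                         modulation_depth = 0.02,
                         motion_amp = 0, motion_freq = 0,
                         light_amp = 0, light_freq = 0, seed = 1L) {
  stopifnot(rows >= 8, cols >= 8, fps > 0,
            length(skin_center) == 2L, length(skin_axes) == 2L,
            all(skin_axes > 0),
            skin_mean_counts >= 0, bg_mean_counts >= 0,
            modulation_depth >= 0, modulation_depth < 0.2,
            motion_amp >= 0, light_amp >= 0, light_amp < 1)
  # the ellipse must stay inside the frame at maximum motion excursion
  if (skin_center[1] - skin_axes[1] < 1 || skin_center[1] + skin_axes[1] > rows ||
      skin_center[2] - skin_axes[2] - motion_amp < 1 ||
      skin_center[2] + skin_axes[2] + motion_amp > cols)
    stop("skin ellipse (with motion excursion) exits the frame")
  structure(list(rows = rows, cols = cols, fps = fps,
                 skin_center = skin_center, skin_axes = skin_axes,
                 skin_mean_counts = skin_mean_counts,
                 bg_mean_counts = bg_mean_counts,
                 modulation_depth = modulation_depth,
                 motion_amp = motion_amp, motion_freq = motion_freq,
                 light_amp = light_amp, light_freq = light_freq,
                 seed = seed),
            class = "scene_params")
}

# Logical skin mask for the ellipse at a given time (column-axis motion).
ellipse_mask_at <- function(scene, t) {
  cc <- scene$skin_center[2] +
    scene$motion_amp * sin(2 * pi * scene$motion_freq * t)
  rterm <- ((seq_len(scene$rows) - scene$skin_center[1]) / scene$skin_axes[1])^2
  cterm <- ((seq_len(scene$cols) - cc) / scene$skin_axes[2])^2
  outer(rterm, cterm, `+`) <= 1
}

#' Render a photon-count frame stack with ground truth
#'
#' Draws every pixel of every frame from a Poisson law. At frame time
#' \eqn{t}, skin pixels have expectation
#' \eqn{\lambda = \mu_{skin}(1 - d\,p(t))L(t)} and background pixels
#' \eqn{\lambda = \mu_{bg}L(t)}, where \eqn{p(t)} is the unit pulse
#' waveform, \eqn{d} the modulation depth and
#' \eqn{L(t) = 1 + a\sin(2\pi f_L t)} the pulsating-illumination factor.
#' The skin ellipse center is displaced horizontally by
#' \eqn{A\sin(2\pi f_m t)} pixels. Ground truth records the exact skin
#' mask of every 10-frame key frame (evaluated at the block's mid-time).
#'
#' @param scene A `scene_params` object.
#' @param pulse Unit pulse waveform sampled at `scene$fps`
#'   (see [synthesize_pulse_signal()]).
#' @param timeline The `beat_timeline` that generated `pulse` (stored in the
#'   ground truth).
#' @param physio Optional `physio_params` stored in the ground truth.
#' @return List with `stack` (class `frame_stack`: integer `counts` array of
#'   dimension n_frames x rows x cols, `fps`, `t0`) and `truth` (class
#'   `ground_truth`: `timeline`, `pulse_waveform`, `true_masks` — one logical
#'   matrix per key frame — `scene`, `physio`).
#' @export
render_frames <- function(scene, pulse, timeline = NULL, physio = NULL) {
  stopifnot(inherits(scene, "scene_params"), is.numeric(pulse))
  n <- length(pulse)
  rows <- scene$rows; cols <- scene$cols
  counts <- array(0L, dim = c(n, rows, cols))
  rterm <- ((seq_len(rows) - scene$skin_center[1]) / scene$skin_axes[1])^2
  colpos <- seq_len(cols)
  with_seed(scene$seed, {
    for (i in seq_len(n)) {
      t <- (i - 1L) / scene$fps
      L <- 1 + scene$light_amp * sin(2 * pi * scene$light_freq * t)
      cc <- scene$skin_center[2] +
        scene$motion_amp * sin(2 * pi * scene$motion_freq * t)
      cterm <- ((colpos - cc) / scene$skin_axes[2])^2
      mask <- outer(rterm, cterm, `+`) <= 1
      lam <- matrix(scene$bg_mean_counts * L, rows, cols)
      lam[mask] <- scene$skin_mean_counts *
        (1 - scene$modulation_depth * pulse[i]) * L
      lam[lam < 0] <- 0
      counts[i, , ] <- stats::rpois(rows * cols, lam)
    }
  })
  n_key <- floor(n / 10)
  true_masks <- vector("list", n_key)
  for (k in seq_len(n_key)) {
    t_mid <- (10 * (k - 1L) + 4.5) / scene$fps
    true_masks[[k]] <- ellipse_mask_at(scene, t_mid)
  }
  stack <- structure(list(counts = counts, fps = scene$fps, t0 = 0),
                     class = "frame_stack")
  truth <- structure(list(timeline = timeline, pulse_waveform = pulse,
                          true_masks = true_masks, scene = scene,
                          physio = physio),
                     class = "ground_truth")
  list(stack = stack, truth = truth)
}

#' Simulate a complete recording scenario
#'
#' Convenience wrapper tying the physiological and scene generators
#' together: beat timeline, pulse waveform, rendered photon-count video and
#' a matching surrogate ECG, all sharing one ground truth.
#'
#' @param physio A `physio_params` object.
#' @param scene A `scene_params` object (its `fps` samples the pulse).
#' @param ecg_fs Sampling rate of the surrogate ECG in Hz (default 250).
#' @param ecg_noise_sd ECG noise standard deviation (default 0.02).
#' @return List with `stack`, `truth` (as [render_frames()]) and `ecg`
#'   (as [synthesize_ecg()]).
#' @export
simulate_recording <- function(physio, scene = scene_params(),
                               ecg_fs = 250, ecg_noise_sd = 0.02) {
  stopifnot(inherits(physio, "physio_params"))
  timeline <- generate_rr_series(physio)
  pulse <- synthesize_pulse_signal(timeline, fps = scene$fps,
                                   duration = physio$duration)
  out <- render_frames(scene, pulse, timeline = timeline, physio = physio)
  out$ecg <- synthesize_ecg(timeline, fs = ecg_fs, duration = physio$duration,
                            noise_sd = ecg_noise_sd,
                            seed = (scene$seed %||% 1L) + 1L)
  out
}

#' Generate randomized key-frame / mask training pairs
#'
#' Draws scenes with randomized skin-ellipse geometry and count levels,
#' renders 10 raw frames each, and returns the 10 Hz key frame together
#' with its exact skin mask — the supervision for the skin-detection
#' network.
#'
#' @param n Number of pairs.
#' @param rows,cols Frame shape (defaults 32, 64).
#' @param seed Integer seed.
#' @return List of `list(frame, mask)` pairs.
#' @export
simulate_training_pairs <- function(n, rows = 32, cols = 64, seed = 1L) {
  with_seed(seed, {
    lapply(seq_len(n), function(i) {
      ax <- c(stats::runif(1, 5, 12), stats::runif(1, 7, 20))
      ctr <- c(stats::runif(1, 1 + ax[1], rows - ax[1]),
               stats::runif(1, 1 + ax[2], cols - ax[2]))
      sc <- scene_params(rows = rows, cols = cols,
                         skin_center = ctr, skin_axes = ax,
                         skin_mean_counts = stats::runif(1, 150, 800),
                         bg_mean_counts = stats::runif(1, 10, 100),
                         modulation_depth = 0.02,
                         seed = sample.int(.Machine$integer.max, 1))
      out <- render_frames(sc, rep(0, 10))
      kf <- make_keyframes(out$stack)
      list(frame = kf$images[[1L]], mask = out$truth$true_masks[[1L]])
    })
  })
}
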