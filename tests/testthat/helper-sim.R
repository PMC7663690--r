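# Shared simulation fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixture_cache[[name]]))
    .fixture_cache[[name]] <- builder()
  .fixture_cache[[name]]
}

# standard 60 s modulated recording with Poisson noise, true masks
std_recording <- function() fixture("std60", function() {
  ph <- physio_params(mean_hr = 72, lf_freq = 0.1, lf_amp = 0.03,
                      resp_freq = 0.25, resp_amp = 0.03, duration = 60)
  tl <- generate_rr_series(ph)
  pulse <- synthesize_pulse_signal(tl, fps = 100, duration = 60)
  out <- render_frames(scene_params(seed = 7), pulse, tl, ph)
  list(physio = ph, tl = tl, pulse = pulse,
       stack = out$stack, truth = out$truth)
})

# noise-free constant-rate pulse train (rr = 0.8 s), 60 s at 100 Hz
constant_pulse <- function() fixture("const_pulse", function() {
  tl <- generate_rr_series(physio_params(mean_hr = 75, duration = 60))
  list(tl = tl, pulse = synthesize_pulse_signal(tl, 100, 60))
})

# clean filtered signal with upright beats from the constant-rate pulse
constant_filtered <- function() fixture("const_filt", function() {
  cp <- constant_pulse()
  apply_filter(cp$pulse, fs = 100)
})
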