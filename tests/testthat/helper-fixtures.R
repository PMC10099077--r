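# shared fixtures: quiet acquisition (no hum / drift / noise) and small
# helpers used across the test files

quiet_noise <- function(dc = 0)
  noise_model(hum_harmonic_amplitudes = numeric(0), drift_rms = 0,
              white_noise_density = 0, dc_offset = dc)

# a pure tone packaged as a raw_trace
tone_trace <- function(freq, amp = 1, fs = 25600, dur = 2, units = "V",
                       phase = 0) {
  t <- (seq_len(dur * fs) - 1) / fs
  raw_trace(amp * sin(2 * pi * freq * t + phase), fs,
            list(actuator_channel("A", resonance_freq = freq)), units)
}

# steady-state amplitude of a (possibly filtered) sinusoid: RMS over the
# central half of the samples, away from filter transients
mid_amplitude <- function(x) {
  n <- length(x)
  sqrt(2) * sqrt(mean(x[seq(n %/% 4, 3 * n %/% 4)]^2))
}

clean_pulse_trial <- function(seed = 1, peak = 0.8, width = 0.26,
                              center = 3, noise = quiet_noise(2.5),
                              freq = 1397, duration = 6) {
  generate_trial(actuator_channel("A", resonance_freq = freq),
                 swallow_kinematics(center, peak, width),
                 noise, seed = seed, duration = duration)
}

make_event <- function(x, rate = 256, subject = "a", task = "water",
                       trial = 1L) {
  env <- envelope_signal(pmax(x, 0), rate)
  ev <- segment_event(env, 1.5, subject, task, trial)
  ev$magnitude <- x[seq_len(round(3 * rate))]
  ev
}
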