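causal_cfg <- enhancement_config(mode = "causal")
offline_cfg <- enhancement_config()

test_that("highpass rejects DC and passes the carrier band", {
  dc <- raw_trace(rep(1, 25600), 25600)
  out <- highpass_reject(dc, offline_cfg)
  expect_lt(max(abs(out$samples[5000:20000])), 1e-6)
  # Butterworth cutoff definition: -3 dB at 800 Hz for a single pass
  g800 <- mid_amplitude(highpass_reject(tone_trace(800), causal_cfg)$samples)
  expect_equal(20 * log10(g800), -3.01, tolerance = 0.05)
  g1397 <- mid_amplitude(highpass_reject(tone_trace(1397), causal_cfg)$samples)
  expect_gt(20 * log10(g1397), -1)
})

test_that("comb design requires an integer notch spacing", {
  expect_error(comb_design(25600, 511), "notch spacing")
  d <- comb_design(25600, 512, 3)
  expect_equal(d$spacing, 50)
})

test_that("comb response: deep notches at 50 Hz multiples, unity between, carrier spared", {
  d <- comb_design(25600, 512, 3)
  # notch attenuation and -3 dB bandwidth
  expect_gt(-20 * log10(comb_response(d, 50)), 40)
  expect_gt(-20 * log10(comb_response(d, 1400)), 40)
  expect_equal(20 * log10(comb_response(d, 50 + 1.5)), -3.01, tolerance = 0.05)
  # mid-band gain within 0.5 dB of unity
  expect_lt(abs(20 * log10(comb_response(d, 25))), 0.5)
  # the 1397 Hz carrier sits 3 Hz from the 1400 Hz notch: loss below 1 dB
  expect_gt(20 * log10(comb_response(d, 1397)), -1)
  # adjacent response minima exactly 50 Hz apart on a 0.01 Hz grid
  f <- seq(25, 175, by = 0.01)
  r <- comb_response(d, f)
  mins <- f[which(diff(sign(diff(r))) == 2) + 1]
  expect_equal(diff(mins), c(50, 50), tolerance = 1e-8)
})

test_that("comb filtering attenuates a 50 Hz tone and passes 25 Hz", {
  out50 <- comb_suppress(tone_trace(50, dur = 4), causal_cfg)
  n <- length(out50$samples)
  steady <- out50$samples[seq(3 * n %/% 4, n)]  # after the IIR settles
  expect_lt(20 * log10(sqrt(2) * sqrt(mean(steady^2))), -40)
  out25 <- comb_suppress(tone_trace(25, dur = 4), causal_cfg)
  expect_equal(mid_amplitude(out25$samples), 1, tolerance = 0.06)
})

test_that("voltage-to-tesla conversion divides by the 5 V/uT sensitivity", {
  tr <- raw_trace(c(1, 0, -2.5), 25600)
  out <- to_magnetic(tr, offline_cfg)
  expect_equal(out$samples, c(0.2e-6, 0, -0.5e-6))
  expect_identical(out$units, "T")
  expect_warning(to_magnetic(out, offline_cfg), "already in tesla")
})

test_that("channel bandpass isolates the carrier and rejects the other actuator", {
  g_c <- mid_amplitude(channel_bandpass(tone_trace(1397), 1397,
                                        causal_cfg)$samples)
  expect_gt(20 * log10(g_c), -1)
  # single-pass rejection of the 1039 Hz carrier through the A band: the
  # 2nd-order Butterworth gives 12.3 dB per pass (24.5 dB zero-phase)
  g_b1 <- mid_amplitude(channel_bandpass(tone_trace(1039), 1397,
                                         causal_cfg)$samples)
  expect_lt(20 * log10(g_b1), -12)
  g_b2 <- mid_amplitude(channel_bandpass(tone_trace(1039), 1397,
                                         offline_cfg)$samples)
  expect_lt(20 * log10(g_b2), -20)
  expect_error(channel_bandpass(tone_trace(100), 100, offline_cfg),
               "Nyquist")
  # band-limited output on white input
  set.seed(1)
  wn <- raw_trace(rnorm(25600), 25600)
  out <- channel_bandpass(wn, 1397, offline_cfg)
  sp <- Mod(stats::fft(out$samples))^2
  f <- (seq_along(sp) - 1)
  inband <- mean(sp[f > 1197 & f < 1597])
  outband <- mean(sp[f > 3000 & f < 6000])
  expect_gt(inband / outband, 1e3)
})

test_that("demodulation is calibrated at the carrier with a 10 Hz first null", {
  cfg <- enhancement_config(equalize = FALSE)
  tone <- tone_trace(1397, amp = 1e-9, units = "T")
  env <- demodulate_envelope(tone, 1397, cfg)
  n <- length(env$magnitude)
  mid <- env$magnitude[seq(n %/% 4, 3 * n %/% 4)]
  expect_equal(mean(mid), 1, tolerance = 1e-3)   # 1 nT in -> 1 nT out
  expect_equal(env$bandwidth, 10)
  expect_true(all(env$magnitude >= 0))
  # offsets: sinc response of the 100 ms integrator
  off_resp <- function(df) {
    e <- demodulate_envelope(tone_trace(1397 + df, amp = 1e-9, units = "T"),
                             1397, cfg)
    m <- e$magnitude
    mean(m[seq(length(m) %/% 4, 3 * length(m) %/% 4)])
  }
  expect_lt(off_resp(10), 5e-3)                    # first integrator null
  expect_equal(off_resp(5), abs(sin(pi * 0.5) / (pi * 0.5)),
               tolerance = 0.02)                   # |sinc(0.5)| = 0.637
})

test_that("offline enhancement has zero group delay on a symmetric pulse", {
  tr <- clean_pulse_trial(seed = 2, center = 3)
  env <- enhance(tr$trace)$A
  t <- (seq_along(env$magnitude) - 1) / env$sample_rate
  expect_equal(t[which.max(env$magnitude)], 3, tolerance = 1.01 / env$sample_rate)
})

test_that("hum suppression keeps low-frequency AM sidebands intact", {
  # 2 Hz amplitude modulation on the 1039 Hz carrier (clear of comb
  # notches); after sinc correction the recovered modulation depth matches
  fs <- 25600
  t <- (seq_len(4 * fs) - 1) / fs
  depth <- 0.3
  x <- 5e6 * 1e-9 * (1 + depth * sin(2 * pi * 2 * t)) * sin(2 * pi * 1039 * t)
  tr <- raw_trace(x, fs, list(actuator_channel("B", 1039)))
  env <- enhance(tr, cfg = enhancement_config(equalize = FALSE))$B
  m <- env$magnitude[seq(256, length(env$magnitude) - 256)]
  rec_depth <- (max(m) - min(m)) / (max(m) + min(m))
  sinc2 <- sin(pi * 0.2) / (pi * 0.2)   # integrator response at 2 Hz
  expect_equal(rec_depth / sinc2, depth, tolerance = 0.05 * depth)
})

test_that("equalized offline chain recovers pulse amplitude without bias", {
  tr <- clean_pulse_trial(seed = 4, peak = 0.8, width = 0.26)
  env <- enhance(tr$trace)$A
  r <- recover_swallow(env)
  expect_equal(r$amplitude, 0.8, tolerance = 0.03)
  expect_equal(r$width, 0.26, tolerance = 0.05)
})

test_that("FDMA separation: modulation on one channel leaves the other flat", {
  chans <- list(actuator_channel("A", 1397, 1),
                actuator_channel("B", 1039, 0.5))
  kin <- list(B = list(swallow_kinematics(3, 0.8, 0.26)))  # only B moves
  tr <- generate_trial(chans, kin, quiet_noise(2.5), seed = 9, duration = 6)
  env <- enhance(tr$trace)
  edge <- 256
  a <- env$A$magnitude[seq(edge, length(env$A$magnitude) - edge)]
  b <- env$B$magnitude[seq(edge, length(env$B$magnitude) - edge)]
  expect_equal(max(b) - min(b), 0.8, tolerance = 0.08)
  crosstalk <- (max(a) - min(a)) / 0.8
  expect_lt(crosstalk, 0.01)
})

test_that("causal mode runs single-pass and zero input stays at the noise floor", {
  tr <- clean_pulse_trial(seed = 6)
  env_c <- enhance(tr$trace, cfg = causal_cfg)$A
  expect_true(all(env_c$magnitude >= 0))
  # causal chain still sees the pulse (delayed, slightly attenuated)
  expect_gt(max(env_c$magnitude) - stats::median(env_c$magnitude), 0.5)
  zero <- raw_trace(numeric(25600), 25600, list(actuator_channel("A")))
  env_z <- enhance(zero)$A
  expect_lt(max(env_z$magnitude), 1e-9)
})

test_that("pipeline linearity: doubling the injected pulse doubles the excursion", {
  excursion <- function(peak) {
    tr <- clean_pulse_trial(seed = 13, peak = peak)
    env <- enhance(tr$trace)$A
    m <- env$magnitude[seq(128, length(env$magnitude) - 128)]
    max(m) - stats::median(m)
  }
  e1 <- excursion(0.4)
  e2 <- excursion(0.8)
  expect_equal(e2 / e1, 2, tolerance = 0.03)
})
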