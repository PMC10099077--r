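pulse_env <- function(center = 3, amp = 1, width = 0.2, dur = 6, rate = 256,
                      base = 1) {
  t <- (seq_len(dur * rate) - 1) / rate
  kin <- swallow_kinematics(center, amp, width)
  envelope_signal(base + swallow_envelope(kin, t), rate)
}

test_that("center detection finds an injected pulse and breaks ties earliest", {
  env <- pulse_env(center = 3.2)
  c0 <- detect_center(env)
  expect_equal(as.numeric(c0), 3.2, tolerance = 1.01 / (3.2 * 256))
  expect_identical(attr(c0, "confidence"), "ok")
  # two equal maxima: the earliest is returned
  rate <- 256
  m <- rep(1, 6 * rate)
  m[2 * rate] <- 2
  m[4 * rate] <- 2
  c2 <- detect_center(envelope_signal(m, rate))
  expect_equal(as.numeric(c2), (2 * rate - 1) / rate)
  # a monotone ramp peaks at the search boundary and is flagged
  ramp <- envelope_signal(seq(0, 1, length.out = 6 * rate), rate)
  c3 <- detect_center(ramp)
  expect_identical(attr(c3, "confidence"), "low")
  expect_error(detect_center(env, search = c(2, 3)), "shorter")
})

test_that("segmentation cuts exact 3 s windows and zero-pads edge events", {
  env <- pulse_env()
  ev <- segment_event(env, 3, "a", "water", 1)
  expect_equal(length(ev$magnitude), 3 * 256)
  expect_false(ev$padded)
  # the window is centered: peak lands mid-window
  expect_equal(which.max(ev$magnitude), round(1.5 * 256) + 1, tolerance = 2)
  edge <- segment_event(env, 1.0, "a", "water", 1)
  expect_true(edge$padded)
  expect_equal(length(edge$magnitude), 3 * 256)
  expect_equal(edge$magnitude[seq_len(100)], rep(0, 100))
})

test_that("initial-50 ms demeaning subtracts the reference level and is idempotent", {
  ev <- make_event(rep(0.3, 768))
  out <- demean_initial(ev)
  expect_equal(out$magnitude, rep(0, 768))
  ev2 <- make_event(c(rep(0.2, 13), rnorm(755)))
  once <- demean_initial(ev2)
  expect_equal(mean(once$magnitude[1:13]), 0, tolerance = 1e-12)
  twice <- demean_initial(once)
  expect_equal(twice$magnitude, once$magnitude, tolerance = 1e-12)
})

test_that("detrending removes ramps, preserves the swallow band, and zeroes the mean", {
  rate <- 256
  t <- (seq_len(3 * rate) - 1) / rate
  ramp <- make_event(0.7 + 0.4 * t)
  out <- detrend_event(ramp)
  expect_lt(max(abs(out$magnitude)), 1e-10)
  # a 2 Hz oscillation passes essentially unchanged
  sine <- make_event(sin(2 * pi * 2 * t))
  outs <- detrend_event(sine)
  expect_equal(max(abs(outs$magnitude - sine$magnitude)), 0, tolerance = 0.05)
  expect_equal(mean(outs$magnitude), 0, tolerance = 0.02)
  # FIR variant also captures a ramp
  outf <- detrend_event(ramp, method = "fir")
  expect_lt(max(abs(outf$magnitude[100:668])), 0.05)
})

test_that("pulse metrics: FWHM of known shapes, undefined flags, scale equivariance", {
  rate <- 256
  t <- (seq_len(3 * rate) - 1) / rate
  # Gaussian with sigma 0.0425 s -> half-amplitude width 0.100 s
  g <- exp(-(t - 1.5)^2 / (2 * 0.0425^2))
  pm <- pulse_metrics(make_event(g))
  expect_equal(pm$pulse_width, 2 * sqrt(2 * log(2)) * 0.0425, tolerance = 0.01)
  expect_equal(pm$peak_to_peak, 1, tolerance = 1e-3)
  # symmetric triangle, height 1, base 0.2 s -> width 0.1 s
  tri <- pmax(0, 1 - abs(t - 1.5) / 0.1)
  pmt <- pulse_metrics(make_event(tri))
  expect_equal(pmt$pulse_width, 0.1, tolerance = 0.01)
  # flat event: undefined width, zero amplitude
  pmf <- pulse_metrics(make_event(rep(0, 768)))
  expect_false(pmf$width_defined)
  expect_equal(pmf$peak_to_peak, 0)
  # scaling the event scales p2p, leaves the width unchanged
  for (a in c(0.5, 3)) {
    pma <- pulse_metrics(make_event(a * g))
    expect_equal(pma$peak_to_peak, a * pm$peak_to_peak, tolerance = 1e-9)
    expect_equal(pma$pulse_width, pm$pulse_width, tolerance = 1e-9)
  }
})

test_that("prototype averaging aligns on maxima", {
  rate <- 256
  t <- (seq_len(3 * rate) - 1) / rate
  g <- exp(-(t - 1.5)^2 / (2 * 0.05^2))
  e1 <- make_event(g)
  # identical events average to themselves
  p <- prototype_event(list(e1, e1, e1))
  expect_equal(p$magnitude, g)
  # x and -x cancel (alignment off to keep phases)
  p0 <- prototype_event(list(make_event(g), make_event(-g)), align = FALSE)
  expect_equal(p0$magnitude, rep(0, 768))
  # shifted copies collapse back onto the pulse after max-alignment
  sh <- function(k) make_event(c(rep(0, k), g[seq_len(768 - k)]))
  pa <- prototype_event(list(sh(0), sh(12), sh(24)))
  i <- 200:568  # central region, away from shift padding
  expect_equal(pa$magnitude[i], sh(12)$magnitude[i], tolerance = 1e-8)
  expect_error(prototype_event(list()), "empty")
})

test_that("end-to-end segmentation recovers injected ground truth at study noise", {
  errs <- t(vapply(1:20, function(s) {
    set.seed(s)
    amp <- runif(1, 0.4, 1.2)
    wid <- runif(1, 0.2, 0.3)
    tr <- generate_trial(actuator_channel("A"),
                         swallow_kinematics(3, amp, wid),
                         noise_model(), seed = s, duration = 6)
    env <- enhance(tr$trace)$A
    r <- recover_swallow(env)
    c(amp = (r$amplitude - amp) / amp, wid = (r$width - wid) / wid)
  }, numeric(2)))
  expect_lt(stats::median(abs(errs[, "amp"])), 0.10)
  expect_lt(stats::median(abs(errs[, "wid"])), 0.15)
  joint <- mean(abs(errs[, "amp"]) <= 0.10 & abs(errs[, "wid"]) <= 0.15)
  expect_gte(joint, 0.8)
})
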