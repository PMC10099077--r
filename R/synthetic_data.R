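# Synthetic raw-trace generator.
#
# Emulates the statistical structure of the swallowing recordings: a DC
# sensor offset, one or two resonance-frequency carriers whose amplitude is
# modulated by a swallow-shaped displacement envelope, 50 Hz power hum with
# harmonics, low-frequency geomagnetic motion drift, and broadband sensor
# noise.  Every trial carries its injected ground truth so the full
# enhancement/segmentation chain can be scored against known parameters.

#' Actuator channel description
#'
#' One frequency-division-multiplexed actuator: its resonance frequency and
#' the carrier flux amplitude seen by the sensor when the subject is at rest.
#'
#' @param label Channel label, e.g. `"A"`.
#' @param resonance_freq Resonance frequency in Hz (0 < f < Nyquist).  The
#'   study actuators resonate at 1397 Hz (A) and 1039 Hz (B).
#' @param baseline_flux Carrier amplitude at rest in nT (> 0).
#' @return An object of class `actuator_channel`.
#' @export
actuator_channel <- function(label = "A", resonance_freq = 1397,
                             baseline_flux = 1) {
  if (resonance_freq <= 0) stop("resonance_freq must be > 0")
  if (baseline_flux <= 0) stop("baseline_flux must be > 0")
  structure(list(label = as.character(label),
                 resonance_freq = resonance_freq,
                 baseline_flux = baseline_flux),
            class = "actuator_channel")
}

#' Swallow kinematics (injected ground truth)
#'
#' Parameters of one swallow-shaped carrier-amplitude excursion: where it
#' happens, how large it is, how wide it is, and its shape.  Two shapes are
#' supported: a symmetric Gaussian lobe and an asymmetric variant with a
#' small secondary lobe right before the main one (20 % of the main-lobe
#' amplitude by default), as seen for one of the study subjects.
#'
#' @param center_time Pulse center, s from trial start.
#' @param peak_delta Signed change of the carrier amplitude at the pulse
#'   peak, nT.  Observed swallow amplitudes lie between 0.25 and 1.8 nT.
#' @param width_half Full width at half amplitude, s (> 0); observed widths
#'   are roughly 0.1 to 0.3 s.
#' @param shape `"gaussian"` or `"asymmetric"` (pre-lobe variant).
#' @param task_label One of `"saliva"`, `"water"`, `"yogurt"`.
#' @param prelobe_frac Amplitude of the pre-lobe relative to the main lobe
#'   (asymmetric shape only).
#' @return An object of class `swallow_kinematics`.
#' @export
swallow_kinematics <- function(center_time, peak_delta, width_half,
                               shape = c("gaussian", "asymmetric"),
                               task_label = "water",
                               prelobe_frac = 0.2) {
  shape <- match.arg(shape)
  if (width_half <= 0) stop("width_half must be > 0")
  structure(list(center_time = center_time, peak_delta = peak_delta,
                 width_half = width_half, shape = shape,
                 task_label = task_label, prelobe_frac = prelobe_frac),
            class = "swallow_kinematics")
}

#' Noise and interference model of the acquisition chain
#'
#' @param hum_fundamental Power-line fundamental, Hz.
#' @param hum_harmonic_amplitudes Voltage amplitudes of the hum harmonics
#'   (element k is the amplitude at `k * hum_fundamental`).  The default is a
#'   50 mV fundamental (ten times the carrier voltage of a 1 nT carrier at
#'   5 V/uT) with 1/k rolloff up to 1 kHz; hum dominates the raw spectrum.
#' @param drift_rms RMS of the low-frequency geomagnetic motion drift, nT.
#' @param drift_bandwidth Drift bandwidth, Hz (< 10).
#' @param white_noise_density Sensor noise density, T/sqrt(Hz).  The default
#'   10 pT/sqrt(Hz) reproduces the envelope quality of the recordings; the
#'   sensor datasheet bound is 100 pT/sqrt(Hz).
#' @param dc_offset Sensor DC offset, V (single-ended supply).
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(hum_fundamental = 50,
                        hum_harmonic_amplitudes = 0.05 / (1:20),
                        drift_rms = 20,
                        drift_bandwidth = 2,
                        white_noise_density = 10e-12,
                        dc_offset = 2.5) {
  if (any(hum_harmonic_amplitudes < 0)) stop("hum amplitudes must be >= 0")
  if (drift_bandwidth >= 10) stop("drift_bandwidth must be < 10 Hz")
  if (white_noise_density < 0) stop("white_noise_density must be >= 0")
  structure(list(hum_fundamental = hum_fundamental,
                 hum_harmonic_amplitudes = hum_harmonic_amplitudes,
                 drift_rms = drift_rms,
                 drift_bandwidth = drift_bandwidth,
                 white_noise_density = white_noise_density,
                 dc_offset = dc_offset),
            class = "noise_model")
}

#' Swallow displacement envelope on a time grid
#'
#' Evaluates the carrier-amplitude modulation (nT) produced by one swallow.
#' The Gaussian shape has its peak `peak_delta` at `center_time` and full
#' width `width_half` at half amplitude (`sigma = width_half / (2 sqrt(2 ln 2))`).
#' The asymmetric shape adds a pre-lobe of `prelobe_frac` amplitude and half
#' the width, centered 1.25 widths before the main lobe.
#'
#' @param kin A [swallow_kinematics()] object.
#' @param time Monotone numeric vector of times, s.
#' @return Numeric vector of envelope values, nT.
#' @export
swallow_envelope <- function(kin, time) {
  stopifnot(inherits(kin, "swallow_kinematics"))
  if (is.unsorted(time)) stop("time grid must be monotone increasing")
  sigma <- kin$width_half / (2 * sqrt(2 * log(2)))
  env <- kin$peak_delta * exp(-(time - kin$center_time)^2 / (2 * sigma^2))
  if (kin$shape == "asymmetric") {
    c2 <- kin$center_time - 1.25 * kin$width_half
    s2 <- sigma / 2
    env <- env + kin$prelobe_frac * kin$peak_delta *
      exp(-(time - c2)^2 / (2 * s2^2))
  }
  env
}

#' Raw sensor trace container
#'
#' @param samples Voltage samples, V.
#' @param sample_rate Hz (default 25600, the acquisition rate of the study).
#' @param channels List of [actuator_channel()] present in the trace.
#' @param units `"V"` for raw voltage or `"T"` after conversion.
#' @param metadata Free-form list (seed, labels, ...).
#' @return An object of class `raw_trace`.
#' @export
raw_trace <- function(samples, sample_rate = 25600, channels = list(),
                      units = "V", metadata = list()) {
  if (!all(is.finite(samples))) stop("samples must be finite")
  structure(list(samples = as.numeric(samples), sample_rate = sample_rate,
                 channels = channels, units = units, metadata = metadata),
            class = "raw_trace")
}

#' @export
print.raw_trace <- function(x, ...) {
  cat(sprintf("<raw_trace> %d samples @ %g Hz (%.3g s), units %s, %d channel(s)\n",
              length(x$samples), x$sample_rate,
              length(x$samples) / x$sample_rate, x$units, length(x$channels)))
  invisible(x)
}

.lowpass_noise <- function(n, fs, bandwidth, rms) {
  # band-limited Gaussian drift; zero-phase so trials have no filter skew
  if (rms <= 0) return(numeric(n))
  lp <- signal::butter(2, bandwidth / (fs / 2), type = "low")
  x <- signal::filtfilt(lp, stats::rnorm(n))
  s <- stats::sd(x)
  if (s == 0) return(numeric(n))
  x / s * rms
}

#' Generate one synthetic trial with ground truth
#'
#' Builds a raw voltage trace: DC offset plus, per channel, the sensitivity-
#' scaled carrier `(baseline_flux + envelope(t)) sin(2 pi f t + phi)` with a
#' random phase, plus power hum, additive low-frequency drift and white
#' sensor noise.  A trace generated twice with the same seed is identical.
#'
#' @param channels List of [actuator_channel()] (or a single one).
#' @param kinematics Named list mapping channel labels to lists of
#'   [swallow_kinematics()] (or a single kinematics applied to the first
#'   channel).  May be empty for an event-free trial.
#' @param noise A [noise_model()].
#' @param seed Integer seed; required for reproducibility.
#' @param duration Trial length, s.
#' @param sample_rate Hz.
#' @param sensitivity Sensor sensitivity, V/T.
#' @return A list with `trace` (a [raw_trace()]) and `truth` (class
#'   `ground_truth`: injected kinematics per channel, baselines, seed).
#' @export
generate_trial <- function(channels, kinematics = list(),
                           noise = noise_model(), seed,
                           duration = 6, sample_rate = 25600,
                           sensitivity = 5e6) {
  if (inherits(channels, "actuator_channel")) channels <- list(channels)
  stopifnot(length(channels) >= 1, inherits(noise, "noise_model"))
  if (missing(seed)) stop("an explicit seed is required")
  if (inherits(kinematics, "swallow_kinematics"))
    kinematics <- stats::setNames(list(list(kinematics)), channels[[1]]$label)
  labs <- vapply(channels, function(ch) ch$label, character(1))
  freqs <- vapply(channels, function(ch) ch$resonance_freq, numeric(1))
  if (any(freqs >= sample_rate / 2))
    stop("channel frequency at or above Nyquist")
  if (length(freqs) > 1 && min(dist(freqs)) < 200)
    warning("carrier spacing < 200 Hz: FDMA separation will fail")

  set.seed(seed)
  n <- round(duration * sample_rate)
  t <- (seq_len(n) - 1) / sample_rate
  v <- rep(noise$dc_offset, n)
  for (ch in channels) {
    kin_list <- kinematics[[ch$label]]
    env <- ch$baseline_flux
    if (!is.null(kin_list)) {
      if (inherits(kin_list, "swallow_kinematics")) kin_list <- list(kin_list)
      for (k in kin_list) {
        if (k$center_time <= 0 || k$center_time >= duration)
          stop("event center_time must lie inside the trial")
        env <- env + swallow_envelope(k, t)
      }
    }
    phi <- stats::runif(1, 0, 2 * pi)
    v <- v + sensitivity * env * 1e-9 * sin(2 * pi * ch$resonance_freq * t + phi)
  }
  for (k in seq_along(noise$hum_harmonic_amplitudes)) {
    a <- noise$hum_harmonic_amplitudes[k]
    if (a > 0)
      v <- v + a * sin(2 * pi * noise$hum_fundamental * k * t +
                         stats::runif(1, 0, 2 * pi))
  }
  v <- v + sensitivity * 1e-9 *
    .lowpass_noise(n, sample_rate, noise$drift_bandwidth, noise$drift_rms)
  if (noise$white_noise_density > 0)
    v <- v + stats::rnorm(n, sd = noise$white_noise_density * sensitivity *
                            sqrt(sample_rate / 2))

  trace <- raw_trace(v, sample_rate, channels, "V",
                     metadata = list(seed = seed, duration = duration,
                                     sensitivity = sensitivity))
  truth <- structure(list(kinematics = kinematics,
                          baseline_flux = stats::setNames(
                            vapply(channels, function(ch) ch$baseline_flux,
                                   numeric(1)), labs),
                          seed = seed),
                     class = "ground_truth")
  list(trace = trace, truth = truth)
}

#' Default 27-trial study protocol
#'
#' Three subjects x three tasks (saliva, water, yogurt) x three trials, the
#' layout of the single-actuator experiment.
#'
#' @return A data.frame with columns `subject`, `task`, `trial`.
#' @export
default_protocol <- function() {
  expand.grid(trial = 1:3,
              task = c("saliva", "water", "yogurt"),
              subject = c("a", "b", "c"),
              KEEP.OUT.ATTRS = FALSE,
              stringsAsFactors = FALSE)[, c("subject", "task", "trial")]
}

# Per-task amplitude / width distributions (nT, s): means follow the
# single-actuator study statistics, spreads their reported trial scatter.
.task_params <- list(
  saliva = list(amp = c(0.67, 0.08), width = c(0.28, 0.01)),
  water  = list(amp = c(0.66, 0.13), width = c(0.26, 0.03)),
  yogurt = list(amp = c(0.85, 0.13), width = c(0.29, 0.04))
)

.draw_kin <- function(task, subject, duration) {
  p <- .task_params[[task]]
  if (is.null(p)) p <- .task_params$water
  amp <- max(0.1, stats::rnorm(1, p$amp[1], p$amp[2]))
  wid <- max(0.12, stats::rnorm(1, p$width[1], p$width[2]))
  swallow_kinematics(center_time = duration / 2 + stats::runif(1, -0.5, 0.5),
                     peak_delta = amp, width_half = wid,
                     shape = if (identical(subject, "c")) "asymmetric" else "gaussian",
                     task_label = task)
}

#' Generate a full synthetic session
#'
#' Draws per-trial swallow parameters from task-specific distributions and
#' generates one trial per protocol row.  Subject "c" swallows with the
#' asymmetric (pre-lobe) shape, subjects "a" and "b" with the Gaussian one.
#' Per-trial seeds are derived from `seed` by counter, so any subset of the
#' session is reproducible.
#'
#' @param plan Protocol data.frame with columns `subject`, `task`, `trial`
#'   (default [default_protocol()]).  A zero-row plan yields an empty session
#'   with a valid manifest.
#' @param channels List of [actuator_channel()] used in every trial.
#' @param noise A [noise_model()].
#' @param seed Session seed (integer).
#' @param duration,sample_rate Trial geometry.
#' @param dir Optional directory: when given, every trial is written as
#'   32-bit float WAV + JSON sidecar (see [write_trace()]) and the manifest
#'   as `manifest.csv`.
#' @return A list with `trials` (list of `generate_trial()` results) and
#'   `manifest` (data.frame with labels, seeds, injected amplitude/width and
#'   file names).
#' @export
generate_session <- function(plan = default_protocol(),
                             channels = list(actuator_channel("A")),
                             noise = noise_model(), seed = 1,
                             duration = 6, sample_rate = 25600,
                             dir = NULL) {
  if (inherits(channels, "actuator_channel")) channels <- list(channels)
  trials <- vector("list", nrow(plan))
  manifest <- plan
  manifest$seed <- rep(NA_integer_, nrow(plan))
  manifest$peak_delta <- rep(NA_real_, nrow(plan))
  manifest$width_half <- rep(NA_real_, nrow(plan))
  manifest$file <- rep(NA_character_, nrow(plan))
  if (!is.null(dir) && !dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (i in seq_len(nrow(plan))) {
    trial_seed <- (seed * 1000L + i) %% .Machine$integer.max
    set.seed(trial_seed)
    kin <- .draw_kin(plan$task[i], plan$subject[i], duration)
    kins <- stats::setNames(
      lapply(channels, function(ch) list(kin)),
      vapply(channels, function(ch) ch$label, character(1)))
    tr <- generate_trial(channels, kins, noise, seed = trial_seed,
                         duration = duration, sample_rate = sample_rate)
    tr$labels <- list(subject = plan$subject[i], task = plan$task[i],
                      trial = plan$trial[i])
    trials[[i]] <- tr
    manifest$seed[i] <- trial_seed
    manifest$peak_delta[i] <- kin$peak_delta
    manifest$width_half[i] <- kin$width_half
    if (!is.null(dir)) {
      fn <- sprintf("trial_%s_%s_%d.wav", plan$subject[i], plan$task[i],
                    plan$trial[i])
      write_trace(tr$trace, file.path(dir, fn), truth = tr$truth)
      manifest$file[i] <- fn
    }
  }
  if (!is.null(dir))
    utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                     row.names = FALSE)
  list(trials = trials, manifest = manifest)
}
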