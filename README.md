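# magswallow

Active magnetic motion sensing of swallowing, as an R package.  A
permanent-magnet MEMS cantilever actuator worn on the throat emits a weak
AC magnetic field at its mechanical resonance (Actuator A: 1397 Hz;
optionally a second actuator B at 1039 Hz under the jaw).  A stationary
uniaxial magnetoimpedance sensor (5 V/µT, sampled at 25.6 kHz) records the
field; laryngeal motion during deglutition modulates the carrier
amplitude by 0.25–1.8 nT over 0.1–0.3 s.  The package is for signal
processing researchers who want a tested, ground-truth-capable
re-implementation of this measurement chain: it simulates raw recordings,
recovers per-actuator motion envelopes, segments swallow events, extracts
the standard feature battery, and quantifies event similarity.  Its
intended consumers are methodologists studying non-invasive dysphagia
screening and anyone who needs a calibrated reference pipeline for
carrier-amplitude motion sensing.

## The method

* **Actuator model** — a magnetic dipole whose moment tilts by ±1° about
  the y-axis: the AC moment is `2 sin(0.5°) ≈ 1.745 %` of the DC moment,
  perpendicular to it, and by linearity the AC field is itself a dipole
  field (`dipole_source()`, `ac_dc_decompose()`, `sensor_reading()`).
* **Synthetic recordings** — carriers with swallow-shaped amplitude
  modulation plus 50 Hz hum and harmonics, low-frequency geomagnetic
  drift, and white sensor noise, with per-trial ground truth
  (`generate_trial()`, `generate_session()`).
* **Enhancement** — Butterworth highpass (2nd order, 800 Hz) → IIR comb
  (order 512, 3 Hz notch bandwidth, 50 Hz notch spacing) → division by
  5 V/µT → per-actuator bandpass (carrier ± 200 Hz) → complex demodulation
  with 100 ms sliding integration, magnitude only (10 Hz envelope
  bandwidth).  Offline mode is zero-phase and equalizes the known chain
  response so recovered pulse parameters are unbiased (`enhance()`).
* **Segmentation** — ±1.5 s window at the envelope maximum, demeaning
  against the first 50 ms, baseline detrending, peak-to-peak amplitude and
  half-amplitude pulse width (`recover_swallow()`, `pulse_metrics()`).
* **Features & similarity** — RMS, VAR, MNF, MDF, MNP, PKF, −3 dB power
  bandwidth, 4-level db3 wavelet band energies; maximum power-normalized
  cross-correlation matrices with 3 × 3 cluster reports
  (`feature_vector()`, `build_matrix()`, `cluster_report()`).

The methods vignette (`vignettes/magnetic-swallow-pipeline.Rmd`) documents
every model, parameter and design decision.

## Worked example

```r
library(magswallow)

# one synthetic trial: a 0.8 nT, 0.26 s swallow at t = 3 s on Actuator A
tr  <- generate_trial(actuator_channel("A", 1397, baseline_flux = 1),
                      swallow_kinematics(center_time = 3, peak_delta = 0.8,
                                         width_half = 0.26),
                      noise_model(), seed = 42, duration = 6)
env <- enhance(tr$trace)$A     # motion envelope, nT at 256 Hz
rec <- recover_swallow(env)
cat(sprintf("amplitude %.3f nT, width %.3f s, center %.2f s\n",
            rec$amplitude, rec$width, rec$center))
#> amplitude 0.790 nT, width 0.265 s, center 3.02 s
```

The recovered amplitude (0.790 nT vs 0.8 injected), half-amplitude width
(0.265 s vs 0.26) and center (3.02 s vs 3.0) show the calibrated chain
working at the default sensor noise of 10 pT/√Hz.  A full study — 27
trials in the 3-subjects × 3-tasks × 3-trials layout, envelopes, events,
the grouped feature table and the 27 × 27 correlation matrix — runs as

```r
res <- run_pipeline(run_config(seed = 1, output_dir = "out"))
res$feature_table   # per-task mean ± sd of every feature
res$matrix          # task-major correlation matrix
```

A thin command-line front end with `simulate`, `enhance` and `run-all`
subcommands is installed at `inst/cli/magswallow`.

Real recordings are accepted in the same dialect the simulator writes:
32-bit float WAV (volts, 25.6 kHz) plus a JSON sidecar naming the sample
rate and actuator channels (`read_trace()` / `write_trace()`).

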