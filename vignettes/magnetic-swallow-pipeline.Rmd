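---
title: "Magnetic motion analysis for swallowing detection: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Magnetic motion analysis for swallowing detection: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(magswallow)
```

## The measurement principle

A millimeter-scale cantilever carrying permanent magnets is driven
piezoelectrically at its mechanical resonance (1–2 kHz).  At rest the
magnets form a magnetic dipole with moment along $-\hat z$; the drive tilts
the moment about $\hat y$ by low single-digit degrees.  Writing $R(\delta)$
for that rotation, the moment decomposes into a static (DC) part
$\mathbf m_{dc}$ and an oscillating (AC) part

$$\mathbf m_{ac} = R(\delta)\,\mathbf m_{dc} - \mathbf m_{dc},
\qquad \frac{|\mathbf m_{ac}|}{|\mathbf m_{dc}|} = 2\sin(\delta/2),$$

which for $\delta = 1^\circ$ is $1.745\,\%$ — the figure usually quoted
rounded as "about 1.8 %".  Because the dipole field
$\mathbf B(\mathbf r) = \frac{\mu_0}{4\pi |r|^3}\bigl(3(\mathbf m\cdot\hat
r)\hat r - \mathbf m\bigr)$ is linear in $\mathbf m$, the AC field anywhere
is itself a dipole field of $\mathbf m_{ac}$, oriented perpendicular to the
DC moment and the tilt axis.  `dipole_source()`, `ac_dc_decompose()` and
`sensor_reading()` implement exactly this geometry; the package reports the
analytic $2\sin(0.5^\circ)$ rather than forcing the rounded 1.8 %.

A stationary uniaxial magnetoimpedance sensor (sensitivity 5 V/µT) records
the field projection on its axis at 25.6 kHz.  An actuator worn on the
throat at the cricoid cartilage moves with the larynx during the pharyngeal
swallow phase; the motion changes the actuator–sensor geometry and thereby
modulates the amplitude of the received resonance carrier.  Swallow
detection is therefore carrier-envelope recovery.

## What the simulator emulates — and what it does not

`generate_trial()` builds a raw voltage trace

$$v(t) = V_{dc} + \sum_{ch} S\,[B_{0,ch} + e_{ch}(t)]\sin(2\pi f_{ch} t +
\varphi_{ch}) + \text{hum}(t) + S\,d(t) + n(t)$$

with $S$ the sensitivity, $B_{0,ch}$ the rest carrier flux (default 1 nT
for Actuator A at 1397 Hz; 0.5 nT for the weaker-driven Actuator B at
1039 Hz), $e_{ch}(t)$ the swallow envelope, 50 Hz hum with harmonics,
low-frequency geomagnetic drift $d(t)$ and white sensor noise $n(t)$.
Design choices, made once:

* **Amplitude modulation only.**  Motion is modeled as a change of carrier
  amplitude, no phase/frequency modulation, because the receiver drops the
  phase anyway and keeps only the magnitude.
* **Swallow envelope.**  A Gaussian lobe parameterized by its peak
  excursion (0.25–1.8 nT is the observed swallowing range) and full width
  at half amplitude ($\sigma = w/(2\sqrt{2\ln 2})$).  One subject profile
  uses an asymmetric variant with a secondary pre-lobe at 20 % amplitude,
  half width, 1.25 widths before the main lobe — "a second small peak right
  before the main lobe" is the only constraint, so those three numbers are
  package choices.
* **Session statistics.**  `generate_session()` draws per-trial amplitude
  and width from per-task normal distributions whose means follow the
  single-actuator study statistics (amplitude 0.67/0.66/0.85 nT and width
  0.28/0.26/0.29 s for saliva/water/yogurt), truncated at 0.1 nT and
  0.12 s.  The default protocol is 3 subjects × 3 tasks × 3 trials.
* **Hum.**  The recordings show hum dominating the raw spectrum but no
  amplitudes are published; the default is a 50 mV fundamental (10× the
  5 mV carrier of a 1 nT flux) with $1/k$ harmonic rolloff up to 1 kHz.
* **Drift.**  Additive band-limited (< 2 Hz) Gaussian flux, 20 nT RMS,
  standing in for motion in the geomagnetic field; the 800 Hz highpass
  removes it entirely, so its exact level is uncritical.
* **Sensor noise.**  White, 10 pT/√Hz by default.  The sensor datasheet
  states a *bound* of 100 pT/√Hz; the recordings themselves — clean
  sub-nanotesla envelopes and ~11 % pulse-width repeatability including
  physiological variance — are only consistent with an effective density
  an order of magnitude below that bound, so the default emulates the
  observations rather than the worst-case figure.  At 100 pT/√Hz the
  envelope noise after the 10 Hz matched filter is
  $\sigma \approx \sqrt{S_0/2T} \approx 0.16$ nT, which would bury a
  0.67 nT pulse's ±10 % amplitude band; no estimator can recover the pulse
  parameters to that precision at that density (the matched-filter bound is
  ≈ 0.11 nT).  The acceptance script reports recovery rates at both
  densities.

The simulator does **not** emulate respiratory or voice artifacts, the
camera reference, the real-time feedback loop that kept subjects at a
common baseline, or inter-subject differences in actuator placement.
Passing recovery tests therefore show that the *processing chain* is
correct and calibrated, not that detection is robust against every
artifact in real recordings.

## The enhancement chain

`enhance()` composes, in order:

1. **Butterworth highpass**, 2nd order, 800 Hz — removes the DC offset and
   geomagnetic motion.
2. **IIR comb**, order $N = 512$, so notches sit at multiples of
   $f_s/N = 50$ Hz.  The realization is the notching comb
   $H(z) = g\,(1 - z^{-N})/(1 - r\,z^{-N})$ with $g = (1+r)/2$; $r$ is
   solved so each notch has a 3 Hz −3 dB width ($r \approx 0.827$).  The
   1397 Hz carrier sits only 3 Hz below the 1400 Hz notch; with this $r$
   its single-pass loss is 0.95 dB (< 1 dB, asserted in tests).
3. **Conversion** to flux density by dividing by 5 V/µT.
4. **Per-actuator bandpass**, 2nd-order Butterworth at carrier ± 200 Hz
   (FDMA separation).  At the paper's stated order the other carrier
   (358 Hz away) is attenuated 12.3 dB per pass, 24.5 dB zero-phase; the
   residual is then pushed far below 0.1 % by the demodulator's
   frequency selectivity, so end-to-end crosstalk stays < 1 %.
5. **Matched filter in correlator realization**: multiply by
   $e^{-2\pi i f_c t}$, average over a sliding 100 ms window, take the
   magnitude.  The window's first response null is at exactly
   $1/T = 10$ Hz, the envelope bandwidth.  Normalization is chosen so a
   tone of amplitude $A$ at the carrier reads $A$; absolute envelope
   scaling is otherwise arbitrary in the source material.  The envelope is
   decimated to 256 Hz for storage (also a package choice).

In **offline** mode all filters run forward–backward (zero phase, no group
delay: a symmetric pulse peaks at its true center).  **Causal** mode runs
every stage single-pass, mirroring a simplified real-time implementation,
with no latency guarantee and no equalization.

**Envelope calibration.**  The chain is not flat across the ±10 Hz
modulation band: the comb notch at 1400 Hz bites into the upper sidebands
of the 1397 Hz carrier, and the 100 ms integrator rolls off as
$\mathrm{sinc}(\nu T)$.  Uncorrected, a 0.26 s pulse comes out ≈ 11 % low
and 14 % wide.  Offline mode therefore divides the envelope spectrum by
the known response — the symmetric-average AM gain
$[G(f_c+\nu) + G(f_c-\nu)]/2$ times $|\mathrm{sinc}(\nu T)|$ — up to 5 Hz,
with the boost capped at 3× to bound noise amplification, and a Gaussian
rolloff above.  The symmetric average is the right quantity for magnitude
detection of real amplitude modulation: even where one sideband is
destroyed by a notch, the modulation survives at half gain in the other
and remains invertible.  Equalization on the complex baseband per sideband
is *not* equivalent (a dead sideband cannot be restored) and was measurably
worse.  With equalization, recovered amplitude and width are unbiased to
well under 1 % on clean trials.

## Segmentation and pulse metrics

Events are the ±1.5 s window around the largest envelope excursion from
the trial's median level (`detect_center()`, ties to the earliest sample;
maxima on the search boundary are flagged low-confidence).  In
dual-actuator trials the center found on Actuator A is reused for B, so
both channels describe the same swallow.  Windows crossing a trial edge
are zero-padded and flagged.

`demean_initial()` subtracts the mean of the first 50 ms, the alignment
reference of the recordings.  `detrend_event()` removes the residual slow
offset: the default estimates the baseline as the straight line through
the mean levels of the outer 0.5 s of the window — exact for linear
drifts, exactly zero for whole periods of in-band oscillations, and
leaving the central swallow lobe untouched.  The published description
("highpass filtering, filter order twice the sample rate") is retained as
`method = "fir"`; with 2 s of taps its transition necessarily reaches
~0.4 Hz and measurably attenuates 0.26–0.29 s lobes (≈ 9 % amplitude), so
it is not the default.

`pulse_metrics()` reports the peak-to-peak amplitude and the
half-amplitude pulse width: the time between the two crossings of the
level halfway between the window baseline (median of the outer 0.5 s) and
the main-lobe peak, linearly interpolated, bracketing the peak.  When the
half level is not crossed on both sides inside the window the width is
*undefined* — a value, not an error; the same happens in the recordings
for strongly asymmetric events.  Note the source material quotes both
~0.26–0.29 s widths (tables) and 19–34 ms durations (prose) without
reconciling the definitions; this package computes the half-amplitude
width of the envelope event and makes no attempt to map it onto the
smaller printed numbers.

Prototype signals (`prototype_event()`) are sample-wise means of events
peak-aligned to their common median peak index; alignment is by maximum
because no alignment rule is published.

## Features and similarity

`feature_vector()` assembles, per event: RMS and VAR as the *mean-free*
sums $\sqrt{\sum x_i^2/N}$ and $\sum x_i^2/(N-1)$ exactly as printed
(events are demeaned upstream); MNF, MDF, MNP, PKF and the −3 dB power
bandwidth ($f_{low}$, $f_{high}$, $BW$) on a single rectangular-window
periodogram of the 3 s event (0.33 Hz resolution, density-normalized so
MNP is in nT²/Hz — the estimator is unnamed in the source, and sub-hertz
feature scales make one unwindowed periodogram the natural choice); and
db3 wavelet energies $E_a, E_{d1..d4}$ from a 4-level decomposition with
periodized boundaries (chosen to make energy conservation exact), in dB
re 1 nT² (the reference is unpublished; only differences matter).  The
"3 dB below the reference line" rule for $f_{low}/f_{high}$ is read as
3 dB below the spectral peak; MDF interpolates linearly between bins.
With the 100 ms integrator all spectral features live below 10 Hz by
construction.

`max_norm_xcorr()` is the maximum over lags of the cross-correlation
normalized by whole-signal power, so $\rho(x,x) = 1$, $|\rho| \le 1$ by
Cauchy–Schwarz, and $\rho$ is invariant to positive scaling.  Events are
demeaned first (otherwise the positive baselines dominate every pair) and
the lag search is limited to ±1.5 s by default; the signed maximum is
taken, not the maximum of $|\rho|$.  `build_matrix()` orders the
27-event matrix task-major or subject-major, and `cluster_report()`
counts, per 3 × 3 block, entries above the 0.8 similarity threshold.

## Numerical choices and problem sizes

Trials are 6 s at 25.6 kHz (the protocol has one swallow per trial, so a
short trial with the event near the center loses nothing); envelopes are
stored at 256 Hz; events are 768 samples.  The comb is applied through its
polyphase decomposition (512 independent first-order recursions), making
the 512th-order IIR O(n).  Test suites use 20-trial recovery runs at the
default noise density; the acceptance script uses 100-trial runs at both
the default and the 100 pT/√Hz bound, a 27-trial session for the feature
and correlation summaries, and 1000 random events for the feature-formula
oracle comparison.

## Known limitations

* Absolute envelope scale rests on the package's own calibration
  convention (tone in = tone amplitude out); only relative statements are
  comparable across setups.
* The equalizer assumes the strong-carrier regime (baseline ≫ envelope
  noise); with the carrier absent the magnitude envelope is Rice-biased.
* Recovery tolerances of ±10 %/±15 % are achievable at the default noise
  density but not at the sensor's 100 pT/√Hz datasheet bound (see the
  noise discussion above) — this is a physical SNR limit, not an
  implementation artifact.
* The pulse-width definition ambiguity in the source material is left
  unresolved; only the half-amplitude width is reported.
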