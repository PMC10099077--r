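# Swallow event segmentation.
#
# Events are located at the local maximum of the envelope excursion during
# swallowing, cut to a +-1.5 s window, demeaned against the first 50 ms,
# detrended, and summarized by peak-to-peak amplitude and half-amplitude
# pulse width.  Prototype signals are peak-aligned averages of events.

#' Locate the swallow center in an envelope
#'
#' Returns the time of the global maximum of `|magnitude - baseline|`
#' (baseline = median of the search range) within `search`.  Ties break to
#' the earliest time.  If the maximum sits on a boundary of the search range
#' (e.g. a monotone ramp) the result carries `attr(, "confidence") = "low"`.
#' For dual-actuator trials the center detected on Actuator A is reused for
#' Actuator B (see [run_pipeline()]).
#'
#' @param envelope An [envelope_signal()].
#' @param search Numeric `c(t0, t1)`, s; defaults to the largest range whose
#'   +-1.5 s event window stays inside the trial.  Must span at least the
#'   3 s window.
#' @return Center time in s, with attribute `confidence`.
#' @export
detect_center <- function(envelope, search = NULL) {
  stopifnot(inherits(envelope, "envelope_signal"))
  er <- envelope$sample_rate
  t <- (seq_along(envelope$magnitude) - 1) / er
  dur <- length(envelope$magnitude) / er
  if (is.null(search)) search <- c(1.5, dur - 1.5)
  if (diff(search) < 3 - 1 / er)
    stop("search range is shorter than the 3 s segmentation window")
  sel <- which(t >= search[1] & t <= search[2])
  if (!length(sel)) stop("search range contains no envelope samples")
  base <- stats::median(envelope$magnitude[sel])
  dev <- abs(envelope$magnitude[sel] - base)
  i <- sel[which.max(dev)]  # which.max returns the first (earliest) maximum
  conf <- if (i == sel[1] || i == sel[length(sel)]) "low" else "ok"
  structure(t[i], confidence = conf)
}

#' Cut a 3 s swallow event around a center time
#'
#' Extracts `center +- 1.5 s` (3 x envelope rate samples).  Events whose
#' window crosses a trial edge are zero-padded and flagged.
#'
#' @param envelope An [envelope_signal()].
#' @param center Center time, s.
#' @param subject,task,trial Labels attached to the event.
#' @return An object of class `swallow_event` with fields `magnitude`,
#'   `sample_rate`, `center_time_in_trial`, `actuator_label`, `labels`,
#'   `padded`, `detrended`.
#' @export
segment_event <- function(envelope, center, subject = "s", task = "water",
                          trial = 1L) {
  stopifnot(inherits(envelope, "envelope_signal"))
  er <- envelope$sample_rate
  n <- round(3 * er)
  i0 <- round((center - 1.5) * er) + 1
  idx <- seq(i0, length.out = n)
  inside <- idx >= 1 & idx <= length(envelope$magnitude)
  mag <- numeric(n)
  mag[inside] <- envelope$magnitude[idx[inside]]
  structure(list(magnitude = mag, sample_rate = er,
                 center_time_in_trial = as.numeric(center),
                 actuator_label = envelope$actuator_label,
                 labels = list(subject = subject, task = task,
                               trial = as.integer(trial)),
                 padded = !all(inside), detrended = FALSE),
            class = "swallow_event")
}

#' @export
print.swallow_event <- function(x, ...) {
  cat(sprintf("<swallow_event> %s/%s/%d (actuator %s), %d samples @ %g Hz%s\n",
              x$labels$subject, x$labels$task, x$labels$trial,
              x$actuator_label, length(x$magnitude), x$sample_rate,
              if (x$padded) ", padded" else ""))
  invisible(x)
}

#' Demean an event against its first 50 ms
#'
#' Subtracts the mean of the first 50 ms from the whole event, the reference
#' convention used for visual alignment of the recordings.  Idempotent up to
#' numerical precision.
#'
#' @param event A `swallow_event` of at least 50 ms.
#' @return The demeaned event.
#' @export
demean_initial <- function(event) {
  stopifnot(inherits(event, "swallow_event"))
  k <- max(1L, round(0.05 * event$sample_rate))
  if (length(event$magnitude) < k) stop("event shorter than 50 ms")
  event$magnitude <- event$magnitude - mean(event$magnitude[seq_len(k)])
  event
}

#' Remove the slow offset trend from an event
#'
#' The default method estimates the baseline level in the first and last
#' `edge` seconds of the window (where the swallow lobe is absent) as the
#' mean of each region, draws the straight line through the two region
#' centers and subtracts it: a linear ramp is removed exactly while the
#' 0.1-10 Hz swallow band is untouched (a whole period of an in-band tone
#' averages to zero in each region).  `method = "fir"` instead subtracts
#' a zero-phase windowed-sinc lowpass trend estimate of order
#' `2 * sample_rate` with the given cutoff; note its 2 s support makes the
#' effective highpass corner ~0.4 Hz, which visibly bites into wide swallow
#' lobes.
#'
#' @param event A `swallow_event`.
#' @param method `"baseline"` (default) or `"fir"`.
#' @param cutoff FIR trend cutoff, Hz.
#' @param edge Width of each baseline-fit region, s.
#' @return The detrended event (`detrended = TRUE`).
#' @export
detrend_event <- function(event, method = c("baseline", "fir"),
                          cutoff = 0.05, edge = 0.5) {
  stopifnot(inherits(event, "swallow_event"))
  method <- match.arg(method)
  x <- event$magnitude
  n <- length(x)
  t <- (seq_len(n) - 1) / event$sample_rate
  if (method == "baseline") {
    lo <- t < edge
    hi <- t > t[n] - edge
    m1 <- mean(x[lo])
    m2 <- mean(x[hi])
    t1 <- mean(t[lo])
    t2 <- mean(t[hi])
    slope <- (m2 - m1) / (t2 - t1)
    trend <- m1 + slope * (t - t1)
  } else {
    ord <- 2 * round(event$sample_rate)
    m <- ord / 2
    k <- seq(-m, m)
    h <- 2 * cutoff / event$sample_rate *
      .sinc(2 * cutoff / event$sample_rate * k)
    h <- h * (0.54 + 0.46 * cos(pi * k / m))  # Hamming
    h <- h / sum(h)
    xp <- c(rev(x), x, rev(x))  # reflect to tame edge transients
    trend <- stats::convolve(xp, h, type = "open")[(n + m) + seq_len(n)]
  }
  event$magnitude <- as.numeric(x - trend)
  event$detrended <- TRUE
  attr(event, "baseline_edge") <- edge
  event
}

.sinc <- function(x) ifelse(x == 0, 1, sin(pi * x) / (pi * x))

#' Peak-to-peak amplitude and half-amplitude pulse width
#'
#' `peak_to_peak` is max - min of the (detrended) event.  The pulse width is
#' the time between the two crossings of the half-amplitude level that
#' bracket the main-lobe peak, where the amplitude reference is the peak
#' height above the baseline (median of the outer 0.5 s of the window) and
#' crossing times are linearly interpolated.  When the level is not crossed
#' exactly once on each side of the peak inside the window, the width is
#' undefined (`NA` with `width_defined = FALSE`) -- a value, not an error;
#' the same happens on the recordings for strongly asymmetric events.
#'
#' @param event A detrended `swallow_event`.
#' @return An object of class `pulse_metrics`: list with `peak_to_peak`
#'   (nT), `amplitude` (peak above baseline, nT), `pulse_width` (s or NA),
#'   `width_defined`, `peak_time` (s, within the window).
#' @export
pulse_metrics <- function(event) {
  stopifnot(inherits(event, "swallow_event"))
  x <- event$magnitude
  n <- length(x)
  t <- (seq_len(n) - 1) / event$sample_rate
  edge <- attr(event, "baseline_edge")
  if (is.null(edge)) edge <- 0.5
  outer <- t < edge | t > t[n] - edge
  base <- stats::median(x[outer])
  ipk <- which.max(x)
  p2p <- max(x) - min(x)
  amp <- x[ipk] - base
  if (amp <= 0 || p2p == 0) {
    return(structure(list(peak_to_peak = p2p, amplitude = max(amp, 0),
                          pulse_width = NA_real_, width_defined = FALSE,
                          peak_time = t[ipk]),
                     class = "pulse_metrics"))
  }
  half <- base + amp / 2
  above <- x > half
  lo <- ipk
  while (lo > 1 && above[lo - 1]) lo <- lo - 1
  hi <- ipk
  while (hi < n && above[hi + 1]) hi <- hi + 1
  defined <- lo > 1 && hi < n
  width <- NA_real_
  if (defined) {
    cross <- function(i1, i2)
      t[i1] + (half - x[i1]) / (x[i2] - x[i1]) * (t[i2] - t[i1])
    width <- cross(hi, hi + 1) - cross(lo, lo - 1)
  }
  structure(list(peak_to_peak = p2p, amplitude = amp, pulse_width = width,
                 width_defined = defined, peak_time = t[ipk]),
            class = "pulse_metrics")
}

#' @export
print.pulse_metrics <- function(x, ...) {
  cat(sprintf("<pulse_metrics> p2p %.3g nT, amplitude %.3g nT, width %s\n",
              x$peak_to_peak, x$amplitude,
              if (x$width_defined) sprintf("%.3g s", x$pulse_width)
              else "undefined"))
  invisible(x)
}

#' Average events into a prototype signal
#'
#' Aligns equal-length events on their maxima (circular shift to the common
#' median peak index) and averages sample-wise; the per-subject prototype of
#' the study is the average over that subject's tasks.
#'
#' @param events Non-empty list of `swallow_event`s of equal length.
#' @param align Peak-align before averaging (default `TRUE`).
#' @return A `swallow_event` holding the prototype (labels from the first
#'   event, task `"prototype"`).
#' @export
prototype_event <- function(events, align = TRUE) {
  if (!length(events)) stop("cannot average an empty event list")
  lens <- vapply(events, function(e) length(e$magnitude), integer(1))
  if (length(unique(lens)) != 1) stop("events must have equal lengths")
  mags <- lapply(events, function(e) e$magnitude)
  if (align && length(events) > 1) {
    peaks <- vapply(mags, which.max, integer(1))
    target <- round(stats::median(peaks))
    mags <- Map(function(m, p) {
      s <- p - target
      if (s == 0) m
      else if (s > 0) c(m[-seq_len(s)], numeric(s))
      else c(numeric(-s), m[seq_len(length(m) + s)])
    }, mags, peaks)
  }
  out <- events[[1]]
  out$magnitude <- Reduce(`+`, mags) / length(mags)
  out$labels$task <- "prototype"
  out
}
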