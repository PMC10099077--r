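# Feature battery per swallow event.
#
# Time domain: RMS and VAR (both mean-free sums of squares, exactly as the
# printed formulas; events are demeaned/detrended upstream).  Frequency
# domain: mean / median / peak frequency, mean power and the -3 dB power
# bandwidth of a density-normalized periodogram.  Time-frequency: energies
# of a 4-level Daubechies-3 wavelet decomposition, in dB re 1 nT^2.

#' Time-domain features
#'
#' `RMS = sqrt(sum(x^2) / N)` and `VAR = sum(x^2) / (N - 1)` -- the mean-free
#' conventions of the feature battery (input is demeaned upstream).
#'
#' @param x Numeric vector (an event's samples) or a `swallow_event`.
#' @return List with `RMS` (nT) and `VAR` (nT^2).
#' @export
time_features <- function(x) {
  if (inherits(x, "swallow_event")) x <- x$magnitude
  n <- length(x)
  if (n < 2) stop("at least two samples are required for VAR")
  list(RMS = sqrt(sum(x^2) / n), VAR = sum(x^2) / (n - 1))
}

# one-sided density-normalized periodogram (rectangular window)
.periodogram <- function(x, fs) {
  n <- length(x)
  X <- stats::fft(x)
  m <- floor(n / 2) + 1
  p <- (abs(X[seq_len(m)])^2) / (n * fs)
  scale <- rep(2, m)
  scale[1] <- 1
  if (n %% 2 == 0) scale[m] <- 1
  list(f = (seq_len(m) - 1) * fs / n, p = p * scale)
}

#' Frequency-domain features
#'
#' Computes, on a single rectangular-window periodogram (density-normalized,
#' resolution `fs / N`): the power-weighted mean frequency MNF, the median
#' frequency MDF (half-cumulative-power point, linearly interpolated between
#' bins), the mean power MNP, the peak frequency PKF, and the power
#' bandwidth: `f_low` / `f_high` are the first and last crossings of the
#' level 3 dB below the spectral peak (linearly interpolated), `BW = f_high
#' - f_low`.  An all-zero event yields `NA` features.
#'
#' @param x Numeric vector or `swallow_event`.
#' @param sample_rate Hz (taken from the event if one is given).
#' @return List with `MNF`, `MDF`, `MNP`, `PKF`, `f_low`, `f_high`, `BW`.
#' @export
spectral_features <- function(x, sample_rate = NULL) {
  if (inherits(x, "swallow_event")) {
    sample_rate <- x$sample_rate
    x <- x$magnitude
  }
  if (is.null(sample_rate)) stop("sample_rate is required")
  pg <- .periodogram(x, sample_rate)
  f <- pg$f
  p <- pg$p
  tot <- sum(p)
  if (tot == 0 || !any(p > 0)) {
    na <- NA_real_
    return(list(MNF = na, MDF = na, MNP = na, PKF = na,
                f_low = na, f_high = na, BW = na))
  }
  mnf <- sum(f * p) / tot
  cum <- cumsum(p)
  j <- which(cum >= tot / 2)[1]
  mdf <- if (j == 1) f[1] else {
    prev <- cum[j - 1]
    f[j - 1] + (tot / 2 - prev) / (cum[j] - prev) * (f[j] - f[j - 1])
  }
  mnp <- mean(p)
  ipk <- which.max(p)
  lev <- p[ipk] / 10^(3 / 10)  # 3 dB below the spectral peak
  above <- p >= lev
  first <- which(above)[1]
  last <- utils::tail(which(above), 1)
  interp_cross <- function(i_out, i_in) {
    # crossing between adjacent bins i_out (below level) and i_in (above)
    f[i_out] + (lev - p[i_out]) / (p[i_in] - p[i_out]) * (f[i_in] - f[i_out])
  }
  f_low <- if (first == 1) f[1] else interp_cross(first - 1, first)
  f_high <- if (last == length(p)) f[last] else interp_cross(last + 1, last)
  list(MNF = mnf, MDF = mdf, MNP = mnp, PKF = f[ipk],
       f_low = f_low, f_high = f_high, BW = f_high - f_low)
}

# Daubechies-3 decomposition filters (orthonormal, 6 taps)
.DB3_LO <- c(0.035226291885709533, -0.085441273882026658,
             -0.13501102001025458, 0.45987750211849154,
             0.80689150931109255, 0.33267055295008263)
.DB3_HI <- c(-0.33267055295008263, 0.80689150931109255,
             -0.45987750211849154, -0.13501102001025458,
             0.085441273882026658, 0.035226291885709533)

# one periodized analysis step; x length must be even.
# y_a[k] = sum_i lo[L-1-i] x[(2k + i - 2) mod n], the periodization
# convention of the common discrete wavelet toolboxes.
.dwt_step <- function(x) {
  n <- length(x)
  L <- 6L
  half <- n / 2
  idx <- outer(2 * seq_len(half) - 2, seq_len(L) - 3L, `+`)
  xi <- x[(idx %% n) + 1]
  dim(xi) <- dim(idx)
  list(a = as.numeric(xi %*% rev(.DB3_LO)),
       d = as.numeric(xi %*% rev(.DB3_HI)))
}

#' Periodized Daubechies-3 wavelet decomposition
#'
#' Orthonormal multilevel DWT with periodic boundary handling, so the total
#' coefficient energy equals the signal energy exactly.  The input length
#' must be divisible by `2^levels` (3 s events at 256 Hz are).
#'
#' @param x Numeric vector.
#' @param levels Number of decomposition levels.
#' @return List with approximation coefficients `cA` and details `cD` (list,
#'   level 1 = finest).
#' @export
db3_dwt <- function(x, levels = 4) {
  n <- length(x)
  if (n %% 2^levels != 0)
    stop("signal length must be divisible by 2^levels for periodized DWT")
  details <- vector("list", levels)
  a <- x
  for (lev in seq_len(levels)) {
    s <- .dwt_step(a)
    a <- s$a
    details[[lev]] <- s$d
  }
  list(cA = a, cD = details)
}

#' Wavelet energy features
#'
#' Energies of the level-4 approximation and of each detail band of the db3
#' decomposition, `Ea = sum cA^2`, `Edj = sum cDj^2`, reported in dB re
#' 1 nT^2 (`10 log10(E)`).  A zero-energy band is floored at -120 dB.
#' Periodization makes `Ea + sum(Edj)` equal the signal energy to machine
#' precision.
#'
#' @param x Numeric vector or `swallow_event` (length divisible by 16).
#' @param levels Decomposition depth (default 4).
#' @return List with `Ea`, `Ed1` .. `Ed4` in dB.
#' @export
wavelet_features <- function(x, levels = 4) {
  if (inherits(x, "swallow_event")) x <- x$magnitude
  if (length(x) < 2^levels * 6)
    stop("event too short for the level-4 db3 filter support")
  w <- db3_dwt(x, levels)
  to_db <- function(e) if (e <= 0) -120 else max(10 * log10(e), -120)
  out <- c(list(Ea = to_db(sum(w$cA^2))),
           stats::setNames(lapply(rev(seq_len(levels)), function(l)
             to_db(sum(w$cD[[l]]^2))),
             paste0("Ed", seq_len(levels))))
  out
}

#' Full feature vector for one event
#'
#' Assembles time, frequency and wavelet features plus the pulse metrics
#' (peak-to-peak amplitude and half-amplitude width) into one row.
#'
#' @param event A detrended `swallow_event`.
#' @param metrics Optional precomputed [pulse_metrics()].
#' @return A one-row data.frame (class keeps labels as columns).
#' @export
feature_vector <- function(event, metrics = NULL) {
  stopifnot(inherits(event, "swallow_event"))
  if (is.null(metrics)) metrics <- pulse_metrics(event)
  tf <- time_features(event)
  sf <- spectral_features(event)
  wf <- wavelet_features(event)
  data.frame(subject = event$labels$subject, task = event$labels$task,
             trial = event$labels$trial, actuator = event$actuator_label,
             amplitude = metrics$peak_to_peak,
             pulse_width = metrics$pulse_width,
             RMS = tf$RMS, VAR = tf$VAR,
             MNF = sf$MNF, MDF = sf$MDF, PKF = sf$PKF,
             f_low = sf$f_low, f_high = sf$f_high, BW = sf$BW,
             MNP = sf$MNP,
             Ea = wf$Ea, Ed1 = wf$Ed1, Ed2 = wf$Ed2, Ed3 = wf$Ed3,
             Ed4 = wf$Ed4,
             stringsAsFactors = FALSE)
}

#' Grouped feature table (mean and standard deviation)
#'
#' Summarizes per-event feature rows into the study's grouped layout: one
#' row per feature, one `mean +- sd` pair of columns per group (swallowing
#' task by default, or actuator for the dual-actuator comparison).
#' Undefined pulse widths are dropped from that feature's statistics, as in
#' the study tables.
#'
#' @param features data.frame of [feature_vector()] rows.
#' @param group_by Grouping column, e.g. `"task"`, `"subject"`, `"actuator"`.
#' @return A data.frame with columns `feature`, then `<group>_mean` and
#'   `<group>_sd` per group.
#' @export
feature_table <- function(features, group_by = "task") {
  stopifnot(is.data.frame(features), nrow(features) >= 1,
            group_by %in% names(features))
  feats <- setdiff(names(features),
                   c("subject", "task", "trial", "actuator"))
  groups <- unique(features[[group_by]])
  out <- data.frame(feature = feats, stringsAsFactors = FALSE)
  for (g in groups) {
    sub <- features[features[[group_by]] == g, feats, drop = FALSE]
    mu <- vapply(sub, function(v) mean(v, na.rm = TRUE), numeric(1))
    sdv <- vapply(sub, function(v) {
      v <- v[!is.na(v)]
      if (length(v) < 2) 0 else stats::sd(v)
    }, numeric(1))
    out[[paste0(g, "_mean")]] <- unname(mu)
    out[[paste0(g, "_sd")]] <- unname(sdv)
  }
  out
}
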