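# independent brute-force oracle: direct evaluation of the printed feature
# sums on a plain DFT periodogram (no shared code with the implementation)
oracle_psd <- function(x, fs) {
  n <- length(x)
  m <- floor(n / 2) + 1
  j <- seq_len(m) - 1
  p <- vapply(j, function(k) {
    e <- exp(-2i * pi * k * (seq_len(n) - 1) / n)
    abs(sum(x * e))^2 / (n * fs)
  }, numeric(1))
  sc <- rep(2, m)
  sc[1] <- 1
  if (n %% 2 == 0) sc[m] <- 1
  list(f = j * fs / n, p = p * sc)
}

oracle_features <- function(x, fs) {
  ps <- oracle_psd(x, fs)
  tot <- sum(ps$p)
  cum <- cumsum(ps$p)
  j <- which(cum >= tot / 2)[1]
  mdf <- if (j == 1) ps$f[1] else
    ps$f[j - 1] + (tot / 2 - cum[j - 1]) / (cum[j] - cum[j - 1]) *
      (ps$f[j] - ps$f[j - 1])
  list(RMS = sqrt(sum(x^2) / length(x)),
       VAR = sum(x^2) / (length(x) - 1),
       MNF = sum(ps$f * ps$p) / tot,
       MDF = mdf,
       MNP = mean(ps$p),
       PKF = ps$f[which.max(ps$p)])
}

test_that("time features evaluate the printed sums", {
  tf <- time_features(c(1, -1))
  expect_equal(tf$RMS, 1)
  expect_equal(tf$VAR, 2)
  expect_equal(time_features(rep(0, 10)), list(RMS = 0, VAR = 0))
  x <- rnorm(50)
  for (a in c(-2, 0.3)) {
    ta <- time_features(a * x)
    t1 <- time_features(x)
    expect_equal(ta$RMS, abs(a) * t1$RMS, tolerance = 1e-12)
    expect_equal(ta$VAR, a^2 * t1$VAR, tolerance = 1e-12)
  }
  expect_error(time_features(1), "two samples")
})

test_that("spectral features of tones land on the expected lines", {
  fs <- 64
  t <- (seq_len(512) - 1) / fs
  sf <- spectral_features(sin(2 * pi * 2 * t), fs)
  bin <- fs / 512
  expect_equal(sf$MNF, 2, tolerance = bin / 2)
  expect_equal(sf$MDF, 2, tolerance = bin)
  expect_equal(sf$PKF, 2, tolerance = bin / 2)
  # two equal tones at 1 and 3 Hz average to 2 Hz
  sf2 <- spectral_features(sin(2 * pi * t) + sin(2 * pi * 3 * t), fs)
  expect_equal(sf2$MNF, 2, tolerance = bin)
  # all-zero event: undefined
  expect_true(all(is.na(unlist(spectral_features(rep(0, 64), fs)))))
})

test_that("spectral features agree with the brute-force oracle", {
  set.seed(42)
  for (rep in 1:40) {
    n <- sample(c(96, 128, 250, 768), 1)
    x <- rnorm(n) * stats::filter(rnorm(n), rep(1, 5), circular = TRUE)
    sf <- spectral_features(as.numeric(x), 256)
    or <- oracle_features(as.numeric(x), 256)
    for (k in c("MNF", "MDF", "MNP", "PKF"))
      expect_equal(sf[[k]], or[[k]], tolerance = 1e-9)
    tf <- time_features(as.numeric(x))
    expect_equal(tf$RMS, or$RMS, tolerance = 1e-12)
    expect_equal(tf$VAR, or$VAR, tolerance = 1e-12)
  }
})

test_that("median frequency splits the cumulative spectrum in half", {
  set.seed(7)
  for (rep in 1:10) {
    x <- rnorm(256)
    sf <- spectral_features(x, 256)
    ps <- oracle_psd(x, 256)
    frac <- sum(ps$p[ps$f < sf$MDF]) / sum(ps$p)
    expect_gte(frac, 0.49 - 0.02)
    expect_lte(frac, 0.51 + 0.02)
  }
})

test_that("power bandwidth brackets the -3 dB region around the peak", {
  fs <- 256
  t <- (seq_len(768) - 1) / fs
  # narrowband pulse: bandwidth must straddle its center frequency
  x <- exp(-(t - 1.5)^2 / (2 * 0.2^2)) * sin(2 * pi * 2 * t)
  sf <- spectral_features(x, fs)
  expect_lte(sf$f_low, sf$PKF)
  expect_gte(sf$f_high, sf$PKF)
  expect_equal(sf$BW, sf$f_high - sf$f_low)
  expect_gt(sf$BW, 0)
})

test_that("db3 decomposition is orthonormal: energies conserved exactly", {
  set.seed(3)
  for (n in c(768, 256, 64)) {
    x <- rnorm(n)
    w <- db3_dwt(x, 4)
    e <- sum(w$cA^2) + sum(vapply(w$cD, function(v) sum(v^2), numeric(1)))
    expect_equal(e, sum(x^2), tolerance = 1e-10)
  }
  # unit impulse carries unit energy through the transform
  imp <- c(1, rep(0, 63))
  wi <- db3_dwt(imp, 4)
  expect_equal(sum(wi$cA^2) +
                 sum(vapply(wi$cD, function(v) sum(v^2), numeric(1))),
               1, tolerance = 1e-12)
  expect_error(db3_dwt(rnorm(100), 4), "divisible")
})

test_that("db3 decomposition matches the reference toolbox on a frozen fixture", {
  # expected energies computed once with an independent wavelet toolbox
  # (periodization mode) and frozen here
  x <- sin(2 * pi * (0:31) / 32) + 0.5 * cos(2 * pi * 3 * (0:31) / 32)
  w <- db3_dwt(x, 4)
  expect_equal(sum(w$cA^2), 1.08829583559312, tolerance = 1e-10)
  expect_equal(sum(w$cD[[4]]^2), 16.8022327799533, tolerance = 1e-10)
  expect_equal(sum(w$cD[[3]]^2), 1.3847785169609, tolerance = 1e-10)
  expect_equal(sum(w$cD[[2]]^2), 0.703542771594169, tolerance = 1e-10)
  expect_equal(sum(w$cD[[1]]^2), 0.021150095898527, tolerance = 1e-9)
})

test_that("wavelet energy features are in dB with a floor for silent bands", {
  z <- wavelet_features(rep(0, 768))
  expect_true(all(unlist(z) == -120))
  set.seed(5)
  x <- rnorm(768)
  wf <- wavelet_features(x)
  lin <- sum(10^(unlist(wf) / 10))
  expect_equal(lin, sum(x^2), tolerance = 1e-9)
})

test_that("feature vectors and grouped tables keep the study layout", {
  rate <- 256
  t <- (seq_len(3 * rate) - 1) / rate
  mk <- function(subject, task, trial, amp)
    make_event(amp * exp(-(t - 1.5)^2 / (2 * 0.11^2)), subject = subject,
               task = task, trial = trial)
  evs <- list(mk("a", "water", 1L, 0.6), mk("a", "water", 2L, 0.7),
              mk("a", "saliva", 1L, 0.9))
  rows <- do.call(rbind, lapply(evs, feature_vector))
  expect_equal(nrow(rows), 3)
  expect_true(all(c("RMS", "VAR", "MNF", "MDF", "PKF", "f_low", "f_high",
                    "BW", "MNP", "Ea", "Ed1", "Ed2", "Ed3", "Ed4",
                    "amplitude", "pulse_width") %in% names(rows)))
  tab <- feature_table(rows, "task")
  expect_true(all(c("water_mean", "water_sd", "saliva_mean", "saliva_sd")
                  %in% names(tab)))
  # single-event group: sd 0
  expect_true(all(tab$saliva_sd == 0))
  # permuting events leaves the table unchanged
  tab2 <- feature_table(rows[c(3, 1, 2), ], "task")
  cols <- sort(names(tab))
  expect_equal(tab[order(tab$feature), cols],
               tab2[order(tab2$feature), cols], ignore_attr = TRUE)
  # the group means reproduce the injected amplitudes
  amp_row <- tab[tab$feature == "amplitude", ]
  expect_equal(amp_row$water_mean, mean(c(0.6, 0.7)), tolerance = 0.02)
})
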