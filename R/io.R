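# Trace file I/O: 32-bit float RIFF/WAVE for the samples plus a JSON
# sidecar carrying the acquisition metadata (sample rate, channels, seed,
# injected ground truth).  The same dialect is the input contract for real
# recordings.  The writer/reader is a deliberately small single-chunk
# implementation (format tag 3 = IEEE float, mono).

.sidecar_path <- function(path) paste0(path, ".json")

#' Write a raw trace as WAV + JSON sidecar
#'
#' Samples are stored verbatim (volts) as 32-bit IEEE float; metadata --
#' sample rate, actuator channels, units and optionally the injected ground
#' truth -- goes to `<path>.json`.
#'
#' @param trace A [raw_trace()].
#' @param path Output WAV path.
#' @param truth Optional `ground_truth` to embed in the sidecar.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path, truth = NULL) {
  stopifnot(inherits(trace, "raw_trace"))
  n <- length(trace$samples)
  fs <- as.integer(round(trace$sample_rate))
  con <- file(path, "wb")
  on.exit(close(con))
  data_bytes <- 4L * n
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_bytes), con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(3L, con, size = 2, endian = "little")   # IEEE float
  writeBin(1L, con, size = 2, endian = "little")   # mono
  writeBin(fs, con, size = 4, endian = "little")
  writeBin(fs * 4L, con, size = 4, endian = "little")
  writeBin(4L, con, size = 2, endian = "little")
  writeBin(32L, con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(data_bytes, con, size = 4, endian = "little")
  writeBin(trace$samples, con, size = 4, endian = "little")

  side <- list(sample_rate = trace$sample_rate,
               n_samples = n,
               units = trace$units,
               channels = lapply(trace$channels, function(ch)
                 list(label = ch$label, resonance_freq = ch$resonance_freq,
                      baseline_flux = ch$baseline_flux)),
               metadata = trace$metadata)
  if (!is.null(truth)) {
    side$ground_truth <- list(
      seed = truth$seed,
      baseline_flux = as.list(truth$baseline_flux),
      kinematics = lapply(truth$kinematics, function(kl)
        lapply(kl, function(k) k[c("center_time", "peak_delta",
                                   "width_half", "shape", "task_label",
                                   "prelobe_frac")])))
  }
  jsonlite::write_json(side, .sidecar_path(path), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a raw trace from WAV + JSON sidecar
#'
#' Validates that the sidecar exists, that its sample rate matches the WAV
#' header, and that the file is complete; errors leave no partial object.
#'
#' @param path WAV path written by [write_trace()] (or real data in the same
#'   dialect).
#' @param expected_rate Sample rate the caller requires (default 25600);
#'   `NULL` skips the check.
#' @return A [raw_trace()]; any embedded ground truth is attached as
#'   attribute `"truth"`.
#' @export
read_trace <- function(path, expected_rate = 25600) {
  if (!file.exists(path)) stop("no such file: ", path)
  sp <- .sidecar_path(path)
  if (!file.exists(sp))
    stop("missing metadata sidecar: ", sp)
  side <- jsonlite::read_json(sp, simplifyVector = FALSE)
  con <- file(path, "rb")
  on.exit(close(con))
  if (!identical(readChar(con, 4), "RIFF")) stop("not a RIFF file: ", path)
  readBin(con, integer(), size = 4, endian = "little")
  if (!identical(readChar(con, 4), "WAVE")) stop("not a WAVE file: ", path)
  fmt_tag <- NULL
  fs <- NULL
  bits <- NULL
  samples <- NULL
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0 || nchar(id) < 4) break
    sz <- readBin(con, integer(), size = 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmt_tag <- readBin(con, integer(), size = 2, endian = "little")
      readBin(con, integer(), size = 2, endian = "little")
      fs <- readBin(con, integer(), size = 4, endian = "little")
      readBin(con, integer(), size = 4, endian = "little")
      readBin(con, integer(), size = 2, endian = "little")
      bits <- readBin(con, integer(), size = 2, endian = "little")
      if (sz > 16) readBin(con, raw(), n = sz - 16)
    } else if (identical(id, "data")) {
      samples <- readBin(con, numeric(), n = sz %/% 4, size = 4,
                         endian = "little")
      if (length(samples) < sz %/% 4)
        stop("truncated WAV data chunk in ", path)
      break
    } else {
      readBin(con, raw(), n = sz)
    }
  }
  if (is.null(fs) || is.null(samples))
    stop("incomplete WAV file (missing fmt or data chunk): ", path)
  if (!identical(fmt_tag, 3L) || !identical(bits, 32L))
    stop("only 32-bit float WAV is supported")
  if (!is.null(side$sample_rate) && side$sample_rate != fs)
    stop("sidecar sample rate (", side$sample_rate,
         ") disagrees with WAV header (", fs, ")")
  if (!is.null(expected_rate) && fs != expected_rate)
    stop("sample rate ", fs, " differs from expected ", expected_rate)
  if (!is.null(side$n_samples) && side$n_samples != length(samples))
    stop("sidecar sample count disagrees with WAV data: ", path)
  channels <- lapply(side$channels, function(ch)
    actuator_channel(ch$label, ch$resonance_freq, ch$baseline_flux))
  tr <- raw_trace(samples, fs, channels,
                  units = if (is.null(side$units)) "V" else side$units,
                  metadata = if (is.null(side$metadata)) list()
                  else side$metadata)
  if (!is.null(side$ground_truth)) {
    gt <- side$ground_truth
    kin <- lapply(gt$kinematics, function(kl)
      lapply(kl, function(k)
        swallow_kinematics(k$center_time, k$peak_delta, k$width_half,
                           shape = k$shape, task_label = k$task_label,
                           prelobe_frac = k$prelobe_frac)))
    attr(tr, "truth") <- structure(
      list(kinematics = kin,
           baseline_flux = unlist(gt$baseline_flux),
           seed = gt$seed),
      class = "ground_truth")
  }
  tr
}

#' Write an envelope or event as a two-column CSV
#'
#' @param x An `envelope_signal` or `swallow_event`.
#' @param path Output CSV (`time` s, `magnitude` nT).
#' @return `path`, invisibly.
#' @export
write_envelope_csv <- function(x, path) {
  mag <- x$magnitude
  t <- (seq_along(mag) - 1) / x$sample_rate
  utils::write.csv(data.frame(time = t, magnitude = mag), path,
                   row.names = FALSE)
  invisible(path)
}
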