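# End-to-end driver: synthetic session (or recorded trials) -> enhancement
# -> segmentation -> features -> correlation, with all stage parameters
# logged and every output written as CSV.  Time is seconds from trial
# start; windows are half-open [start, end).

#' Pipeline run configuration
#'
#' Bundles every stage's options plus the global seed and output directory.
#' Serializes to/from YAML via [write_run_config()] / [read_run_config()];
#' unknown keys in a config file are rejected.
#'
#' @param seed Global seed; all per-trial randomness derives from it.
#' @param output_dir Where [run_pipeline()] writes its results (`NULL` keeps
#'   everything in memory).
#' @param protocol Trial plan data.frame (see [default_protocol()]).
#' @param channels List of [actuator_channel()].
#' @param noise A [noise_model()].
#' @param enhancement An [enhancement_config()].
#' @param duration Trial duration, s.
#' @param sample_rate Acquisition rate, Hz.
#' @param correlation_ordering `"task"` or `"subject"` major matrix order.
#' @param correlation_threshold Cluster threshold on rho.
#' @return An object of class `run_config`.
#' @export
run_config <- function(seed = 1, output_dir = NULL,
                       protocol = default_protocol(),
                       channels = list(actuator_channel("A")),
                       noise = noise_model(),
                       enhancement = enhancement_config(),
                       duration = 6, sample_rate = 25600,
                       correlation_ordering = "task",
                       correlation_threshold = 0.8) {
  structure(list(seed = seed, output_dir = output_dir, protocol = protocol,
                 channels = channels, noise = noise,
                 enhancement = enhancement, duration = duration,
                 sample_rate = sample_rate,
                 correlation_ordering = correlation_ordering,
                 correlation_threshold = correlation_threshold),
            class = "run_config")
}

.cfg_scalar_keys <- c("seed", "output_dir", "duration", "sample_rate",
                      "correlation_ordering", "correlation_threshold")

#' Serialize a run configuration to YAML
#'
#' @param config A [run_config()].
#' @param path Output YAML file.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  out <- list(
    seed = config$seed, output_dir = config$output_dir,
    duration = config$duration, sample_rate = config$sample_rate,
    correlation_ordering = config$correlation_ordering,
    correlation_threshold = config$correlation_threshold,
    protocol = as.list(config$protocol),
    channels = lapply(config$channels, unclass),
    noise = unclass(config$noise),
    enhancement = unclass(config$enhancement))
  yaml::write_yaml(out, path)
  invisible(path)
}

#' Read a run configuration from YAML
#'
#' Unknown keys (top level or inside a section) are an error, so typos in a
#' config file cannot silently fall back to defaults.
#'
#' @param path YAML file written by [write_run_config()] or by hand.
#' @return A [run_config()].
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- c(.cfg_scalar_keys, "protocol", "channels", "noise", "enhancement")
  bad <- setdiff(names(raw), known)
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
  check_section <- function(given, template, what) {
    extra <- setdiff(names(given), names(template))
    if (length(extra))
      stop("unknown ", what, " keys: ", paste(extra, collapse = ", "))
  }
  cfg <- run_config()
  for (k in intersect(.cfg_scalar_keys, names(raw))) cfg[[k]] <- raw[[k]]
  if (!is.null(raw$protocol))
    cfg$protocol <- as.data.frame(raw$protocol, stringsAsFactors = FALSE)
  if (!is.null(raw$channels))
    cfg$channels <- lapply(raw$channels, function(ch) {
      check_section(ch, unclass(actuator_channel()), "channel")
      do.call(actuator_channel, ch)
    })
  if (!is.null(raw$noise)) {
    check_section(raw$noise, unclass(noise_model()), "noise")
    cfg$noise <- do.call(noise_model, raw$noise)
  }
  if (!is.null(raw$enhancement)) {
    check_section(raw$enhancement, unclass(enhancement_config()),
                  "enhancement")
    cfg$enhancement <- do.call(enhancement_config, raw$enhancement)
  }
  cfg
}

.log_line <- function(lines, ...) c(lines, sprintf(...))

#' Run the full analysis pipeline
#'
#' Generates (or loads) every trial of the protocol, runs the enhancement
#' chain, detects and segments one swallow event per trial and actuator
#' (for dual-actuator trials the center found on the first channel --
#' Actuator A -- is reused for the others), demeans, detrends, extracts
#' pulse metrics and the feature battery, builds the grouped feature table
#' and the correlation matrix with its cluster report.  Deterministic for a
#' fixed `config$seed`; when `config$output_dir` is set, envelopes, events,
#' features, matrices and a parameter log are written as CSV/text.
#'
#' @param config A [run_config()].
#' @param trials Optional list of pre-loaded trials (each a list with
#'   `trace`, and optionally `truth` and `labels`) to analyze instead of
#'   generating synthetic ones.
#' @return A list (class `pipeline_result`) with `envelopes`, `events`,
#'   `features`, `feature_table`, `matrix` (first actuator), `clusters`,
#'   `manifest`, `log`.
#' @export
run_pipeline <- function(config = run_config(), trials = NULL) {
  stopifnot(inherits(config, "run_config"))
  log <- character()
  log <- .log_line(log, "magswallow pipeline, seed %d", config$seed)
  log <- .log_line(log, "enhancement: hp %g Hz (order %d), comb order %d / %g Hz bw, sens %g V/T, band +-%g Hz, Tint %g s, mode %s",
                   config$enhancement$highpass_cutoff,
                   config$enhancement$highpass_order,
                   config$enhancement$comb_order,
                   config$enhancement$comb_bandwidth,
                   config$enhancement$sensitivity,
                   config$enhancement$band_halfwidth,
                   config$enhancement$integration_time,
                   config$enhancement$mode)
  manifest <- NULL
  if (is.null(trials)) {
    ses <- generate_session(config$protocol, config$channels, config$noise,
                            seed = config$seed, duration = config$duration,
                            sample_rate = config$sample_rate)
    trials <- ses$trials
    manifest <- ses$manifest
    log <- .log_line(log, "generated %d synthetic trial(s)", length(trials))
  }
  envelopes <- list()
  events <- list()
  feats <- NULL
  for (i in seq_along(trials)) {
    tr <- trials[[i]]
    labs <- tr$labels
    if (is.null(labs))
      labs <- list(subject = "s", task = "water", trial = i)
    env <- enhance(tr$trace, cfg = config$enhancement)
    envelopes[[i]] <- env
    center <- detect_center(env[[1]])
    for (ch in names(env)) {
      ev <- segment_event(env[[ch]], center, subject = labs$subject,
                          task = labs$task, trial = labs$trial)
      ev <- demean_initial(ev)
      ev <- detrend_event(ev)
      events[[length(events) + 1]] <- ev
      fv <- feature_vector(ev)
      feats <- rbind(feats, fv)
    }
  }
  ftab <- if (!is.null(feats)) feature_table(feats, "task") else NULL
  first_lab <- events[[1]]$actuator_label
  first_events <- Filter(function(e) e$actuator_label == first_lab, events)
  cm <- if (length(first_events) >= 2)
    build_matrix(first_events, config$correlation_ordering)
  else NULL
  clusters <- if (!is.null(cm) && nrow(cm) %% 3 == 0)
    cluster_report(cm, config$correlation_threshold, 3)
  else NULL
  log <- .log_line(log, "%d event(s), %d feature row(s)",
                   length(events), if (is.null(feats)) 0L else nrow(feats))
  res <- structure(list(envelopes = envelopes, events = events,
                        features = feats, feature_table = ftab,
                        matrix = cm, clusters = clusters,
                        manifest = manifest, log = log),
                   class = "pipeline_result")
  if (!is.null(config$output_dir)) .write_results(res, config)
  res
}

.write_results <- function(res, config) {
  dir <- config$output_dir
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  if (!is.null(res$features))
    utils::write.csv(res$features, file.path(dir, "features.csv"),
                     row.names = FALSE)
  if (!is.null(res$feature_table))
    utils::write.csv(res$feature_table, file.path(dir, "feature_table.csv"),
                     row.names = FALSE)
  if (!is.null(res$matrix))
    utils::write.csv(as.data.frame(unclass(res$matrix)),
                     file.path(dir, "correlation_matrix.csv"))
  if (!is.null(res$clusters))
    utils::write.csv(res$clusters, file.path(dir, "clusters.csv"),
                     row.names = FALSE)
  if (!is.null(res$manifest))
    utils::write.csv(res$manifest, file.path(dir, "manifest.csv"),
                     row.names = FALSE)
  for (i in seq_along(res$events)) {
    e <- res$events[[i]]
    write_envelope_csv(e, file.path(dir, sprintf(
      "event_%02d_%s_%s_%d_%s.csv", i, e$labels$subject, e$labels$task,
      e$labels$trial, e$actuator_label)))
  }
  writeLines(res$log, file.path(dir, "run_log.txt"))
  invisible(dir)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  cat(" ", length(x$events), "event(s);",
      if (!is.null(x$matrix)) sprintf("%dx%d correlation matrix", nrow(x$matrix),
                                      ncol(x$matrix)) else "no matrix", "\n")
  invisible(x)
}

#' Recover swallow parameters from one envelope
#'
#' Convenience wrapper used for ground-truth scoring: detects the event
#' center, segments, demeans, detrends and returns the recovered center
#' time, pulse amplitude (main-lobe peak above the window baseline) and
#' half-amplitude width.
#'
#' @param envelope An [envelope_signal()].
#' @param search Optional search range passed to [detect_center()].
#' @return List with `center`, `amplitude`, `width`, `width_defined`,
#'   `event` (the detrended `swallow_event`).
#' @export
recover_swallow <- function(envelope, search = NULL) {
  center <- detect_center(envelope, search)
  ev <- segment_event(envelope, as.numeric(center))
  ev <- demean_initial(ev)
  ev <- detrend_event(ev)
  pm <- pulse_metrics(ev)
  list(center = as.numeric(center) - 1.5 + pm$peak_time,
       amplitude = pm$amplitude, width = pm$pulse_width,
       width_defined = pm$width_defined, event = ev)
}
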