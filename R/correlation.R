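# Similarity analysis: maximum power-normalized cross-correlation between
# event pairs, assembled into grouped matrices and block (cluster) reports.

#' Maximum power-normalized cross-correlation
#'
#' `rho = max over lags of sum x(t) y(t + tau) / sqrt(sum x^2 sum y^2)`.
#' Normalization is by whole-signal power (not per-overlap), so
#' `rho(x, x) = 1` at zero lag and shifted copies are slightly penalized by
#' edge truncation; `|rho| <= 1` always (Cauchy-Schwarz).  Events are
#' demeaned before correlating so offsets do not dominate.  The maximum of
#' the signed correlation is taken (not of its absolute value).
#'
#' @param x,y Numeric vectors or `swallow_event`s at the same sample rate.
#' @param max_lag Lag search range in samples; `NULL` searches all lags.
#'   For 3 s events at 256 Hz the default pipeline limits it to +-1.5 s.
#' @param demean Subtract each signal's mean first (default `TRUE`).
#' @return Scalar rho in [-1, 1], or `NA` for a zero-power input.
#' @export
max_norm_xcorr <- function(x, y, max_lag = NULL, demean = TRUE) {
  rate_x <- if (inherits(x, "swallow_event")) x$sample_rate else NULL
  rate_y <- if (inherits(y, "swallow_event")) y$sample_rate else NULL
  if (!is.null(rate_x) && !is.null(rate_y) && rate_x != rate_y)
    stop("events must share a sample rate")
  if (inherits(x, "swallow_event")) x <- x$magnitude
  if (inherits(y, "swallow_event")) y <- y$magnitude
  if (demean) {
    x <- x - mean(x)
    y <- y - mean(y)
  }
  px <- sum(x^2)
  py <- sum(y^2)
  if (px == 0 || py == 0) return(NA_real_)
  n <- length(x) + length(y) - 1
  nfft <- stats::nextn(n, 2)
  cc <- Re(stats::fft(stats::fft(c(x, numeric(nfft - length(x)))) *
                        Conj(stats::fft(c(y, numeric(nfft - length(y))))),
                      inverse = TRUE)) / nfft
  # element k (0-based) of cc is sum_t x[t] y[t - k]; positive lags tau of
  # r(tau) = sum x(t) y(t + tau) therefore sit at k = nfft - tau
  k <- seq(0, nfft - 1)
  tau <- ifelse(k <= nfft / 2, -k, nfft - k)
  lag_cap <- min(length(y) - 1,
                 if (is.null(max_lag)) Inf else max_lag)
  lag_cap_neg <- min(length(x) - 1,
                     if (is.null(max_lag)) Inf else max_lag)
  keep <- (tau >= 0 & tau <= lag_cap) | (tau < 0 & -tau <= lag_cap_neg)
  max(cc[keep]) / sqrt(px * py)
}

#' Correlation matrix over a set of events
#'
#' All-pairs maximum power-normalized cross-correlation, with rows ordered
#' by the requested grouping (task-major or subject-major), mirroring the
#' study's 27 x 27 similarity plots.
#'
#' @param events List (>= 2) of `swallow_event`s of equal sample rate.
#' @param ordering `"task"` or `"subject"` major order; within the major key
#'   events sort by the other key, then trial.
#' @param max_lag Lag limit in samples; default +-1.5 s.
#' @return An object of class `correlation_matrix`: the symmetric
#'   unit-diagonal matrix with `subject/task/trial` row labels and the
#'   grouping recorded in attributes.
#' @export
build_matrix <- function(events, ordering = c("task", "subject"),
                         max_lag = NULL) {
  ordering <- match.arg(ordering)
  if (length(events) < 2) stop("at least two events are required")
  sub <- vapply(events, function(e) e$labels$subject, character(1))
  tsk <- vapply(events, function(e) e$labels$task, character(1))
  tri <- vapply(events, function(e) e$labels$trial, integer(1))
  ord <- if (ordering == "task") order(tsk, sub, tri)
  else order(sub, tsk, tri)
  events <- events[ord]
  if (is.null(max_lag))
    max_lag <- round(1.5 * events[[1]]$sample_rate)
  k <- length(events)
  m <- diag(1, k)
  for (i in seq_len(k - 1)) {
    for (j in seq(i + 1, k)) {
      m[i, j] <- m[j, i] <- max_norm_xcorr(events[[i]], events[[j]],
                                           max_lag = max_lag)
    }
  }
  labels <- sprintf("%s.%s.%d", sub[ord], tsk[ord], tri[ord])
  dimnames(m) <- list(labels, labels)
  structure(m, class = c("correlation_matrix", "matrix"),
            ordering = ordering,
            subject = sub[ord], task = tsk[ord], trial = tri[ord])
}

#' @export
print.correlation_matrix <- function(x, ...) {
  cat(sprintf("<correlation_matrix> %d x %d, %s-major ordering\n",
              nrow(x), ncol(x), attr(x, "ordering")))
  print(round(unclass(x)[, , drop = FALSE], 2), ...)
  invisible(x)
}

#' Heat-map display of a correlation matrix
#'
#' @param x A `correlation_matrix`.
#' @param ... Passed to [graphics::image()].
#' @export
plot.correlation_matrix <- function(x, ...) {
  k <- nrow(x)
  graphics::image(seq_len(k), seq_len(k),
                  t(unclass(x)[k:1, , drop = FALSE]),
                  zlim = c(-1, 1), xlab = "", ylab = "", axes = FALSE,
                  col = grDevices::hcl.colors(64, "Blue-Red 3"), ...)
  graphics::axis(1, at = seq_len(k), labels = colnames(x), las = 2,
                 cex.axis = 0.6)
  graphics::axis(2, at = seq_len(k), labels = rev(rownames(x)), las = 2,
                 cex.axis = 0.6)
  graphics::box()
  invisible(x)
}

#' Block (cluster) report on a correlation matrix
#'
#' Partitions the matrix into `block x block` cells following its grouping
#' order and, for each cell, counts the entries with `rho > threshold` and
#' flags full cells (all `block^2` entries above threshold) -- the "3 x 3
#' cluster" summary used to read the study's similarity plots.
#'
#' @param mat A `correlation_matrix` (or plain matrix) whose size is a
#'   multiple of `block`.
#' @param threshold Correlation threshold (default 0.8).
#' @param block Cell edge length (default 3 = trials per condition).
#' @return data.frame with `row_block`, `col_block`, `n_above`, `full`.
#' @export
cluster_report <- function(mat, threshold = 0.8, block = 3) {
  k <- nrow(mat)
  if (k %% block != 0)
    stop("matrix size is not a multiple of the block size")
  nb <- k / block
  blk_name <- function(i) {
    idx <- (i - 1) * block + 1
    nm <- rownames(mat)
    if (is.null(nm)) as.character(i)
    else sub("\\.[0-9]+$", "", nm[idx])
  }
  out <- expand.grid(row_block = seq_len(nb), col_block = seq_len(nb),
                     KEEP.OUT.ATTRS = FALSE)
  out$row_group <- vapply(out$row_block, blk_name, character(1))
  out$col_group <- vapply(out$col_block, blk_name, character(1))
  out$n_above <- NA_integer_
  out$full <- NA
  for (r in seq_len(nrow(out))) {
    ri <- (out$row_block[r] - 1) * block + seq_len(block)
    ci <- (out$col_block[r] - 1) * block + seq_len(block)
    cell <- unclass(mat)[ri, ci, drop = FALSE]
    out$n_above[r] <- sum(cell > threshold, na.rm = TRUE)
    out$full[r] <- all(cell > threshold, na.rm = FALSE)
  }
  out
}
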