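# window width in hours -> odd number of samples, centered
window_samples <- function(window_h, dt) {
  k <- max(1L, round(window_h / dt))
  if (k %% 2L == 0L) k <- k + 1L
  as.integer(k)
}

# centered running statistic with shrinking windows at the edges
running_stat <- function(x, half, fun) {
  n <- length(x)
  vapply(seq_len(n), function(i) {
    lo <- max(1L, i - half)
    hi <- min(n, i + half)
    fun(x[lo:hi])
  }, numeric(1L))
}

# centered running mean with shrinking edge windows, O(n) via cumulative sums
running_mean <- function(x, half) {
  n <- length(x)
  cs <- c(0, cumsum(x))
  lo <- pmax(1L, seq_len(n) - half)
  hi <- pmin(n, seq_len(n) + half)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# restrict a trace to [from, to] (inclusive), keeping events inside
crop_trace <- function(trace, from, to) {
  idx <- trace$time_h >= from & trace$time_h <= to
  out <- trace
  out$time_h <- trace$time_h[idx]
  out$value <- trace$value[idx]
  if (!is.null(trace$events)) {
    ev <- trace$events[trace$events$time_h >= from & trace$events$time_h <= to, ,
                       drop = FALSE]
    out$events <- if (nrow(ev)) ev else NULL
  }
  out
}

#' Running-average baseline subtraction
#'
#' Detrends a raw luminescence trace by subtracting, at each sample, the mean
#' over a centered window (24 h by default, i.e. one full circadian cycle, so
#' the running mean tracks the slow baseline while the oscillation averages
#' out). At the edges the window shrinks symmetrically rather than dropping
#' samples, keeping early pre-treatment cycles usable.
#'
#' @param trace A [lumi_trace].
#' @param window_h Window width in hours (converted to an odd sample count).
#'   Default 24.
#' @return A `detrended_trace` (inherits `lumi_trace`) whose `value` is raw
#'   minus running mean; carries `window_h` and a `baseline` element with the
#'   subtracted running mean.
#' @export
baseline_subtract <- function(trace, window_h = 24) {
  stopifnot(inherits(trace, "lumi_trace"), window_h > 0)
  dt <- sampling_interval(trace)
  span <- trace$time_h[length(trace$time_h)] - trace$time_h[1L]
  if (span < window_h) stop("trace shorter than the detrending window")
  k <- window_samples(window_h, dt)
  half <- (k - 1L) %/% 2L
  bl <- running_mean(trace$value, half)
  out <- trace
  out$value <- trace$value - bl
  out$baseline <- bl
  out$window_h <- window_h
  out$detrend_half <- half
  class(out) <- c("detrended_trace", "lumi_trace")
  out
}

#' Moving-median smoothing
#'
#' Centered moving median used to stabilise extrema detection before trough
#' calling. Removes isolated spikes while preserving monotone segments;
#' idempotent on constants. Edges use shrinking centered windows.
#'
#' @param trace A [lumi_trace] (raw or detrended).
#' @param window_h Window width in hours (> 0, and should be well below half
#'   the period). Default 2.
#' @return A trace of the same class with smoothed values.
#' @export
smooth_trace <- function(trace, window_h = 2) {
  stopifnot(inherits(trace, "lumi_trace"))
  if (window_h <= 0) stop("window_h must be > 0")
  dt <- sampling_interval(trace)
  k <- window_samples(window_h, dt)
  half <- (k - 1L) %/% 2L
  out <- trace
  out$value <- running_stat(trace$value, half, stats::median)
  out
}

#' @export
print.detrended_trace <- function(x, ...) {
  NextMethod()
  cat(sprintf("  detrended (running mean, window %.1f h)\n", x$window_h))
  invisible(x)
}
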