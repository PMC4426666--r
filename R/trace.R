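#' Luminescence trace objects
#'
#' A `lumi_trace` holds one sample's uniformly sampled bioluminescence time
#' series (counts/s against hours since the start of recording) together with
#' its treatment events and, for synthetic traces, the generator's ground
#' truth (injected phase shifts and true period).
#'
#' @param sample_id Character scalar identifying the sample.
#' @param time_h Numeric vector of sampling times in hours, strictly
#'   increasing on a uniform grid.
#' @param value Numeric vector of luminescence values (counts/s), same length
#'   as `time_h`, all finite.
#' @param events Optional data frame of treatment events with columns
#'   `time_h`, `peptide`, `concentration_nM`. Vehicle is encoded as peptide
#'   `"PBS"` with concentration 0.
#' @param ground_truth Optional data frame (synthetic traces only) with one
#'   row per event: `time_h`, `phase_deg` (oscillator phase at treatment, in
#'   degrees), `shift_h` (injected phase shift, delays negative).
#' @param true_period_h Optional true oscillator period in hours (synthetic
#'   traces only).
#'
#' @return An object of class `lumi_trace`: a list with elements
#'   `sample_id`, `time_h`, `value`, `events`, `ground_truth`,
#'   `true_period_h`.
#' @export
#' @examples
#' tr <- lumi_trace("s1", seq(0, 96, by = 1/6),
#'                  100 * cos(2 * pi * (seq(0, 96, by = 1/6) - 20) / 24))
#' print(tr)
lumi_trace <- function(sample_id, time_h, value, events = NULL,
                       ground_truth = NULL, true_period_h = NULL) {
  stopifnot(is.character(sample_id), length(sample_id) == 1L)
  time_h <- as.numeric(time_h)
  value <- as.numeric(value)
  if (length(time_h) != length(value))
    stop("time_h and value must have the same length")
  if (length(time_h) < 2L) stop("a trace needs at least two samples")
  dt <- diff(time_h)
  if (any(dt <= 0)) stop("times must be strictly increasing")
  if (max(dt) - min(dt) > 1e-8 * stats::median(dt))
    stop("times must lie on a uniform grid")
  if (!all(is.finite(value))) stop("values must be finite")
  if (!is.null(events)) {
    events <- as.data.frame(events)
    req <- c("time_h", "peptide", "concentration_nM")
    if (!all(req %in% names(events)))
      stop("events needs columns time_h, peptide, concentration_nM")
    if (any(events$concentration_nM < 0)) stop("concentrations must be >= 0")
    if (any(events$time_h < time_h[1L] | events$time_h > time_h[length(time_h)]))
      stop("event outside trace duration")
    events <- events[order(events$time_h), , drop = FALSE]
  }
  structure(list(sample_id = sample_id, time_h = time_h, value = value,
                 events = events, ground_truth = ground_truth,
                 true_period_h = true_period_h),
            class = "lumi_trace")
}

#' @export
print.lumi_trace <- function(x, ...) {
  n <- length(x$time_h)
  cat(sprintf("<lumi_trace> %s: %d samples, %.1f-%.1f h (dt = %.3f h)\n",
              x$sample_id, n, x$time_h[1L], x$time_h[n],
              x$time_h[2L] - x$time_h[1L]))
  if (!is.null(x$events) && nrow(x$events)) {
    for (i in seq_len(nrow(x$events)))
      cat(sprintf("  event: %s %g nM at %.2f h\n", x$events$peptide[i],
                  x$events$concentration_nM[i], x$events$time_h[i]))
  }
  invisible(x)
}

#' @export
plot.lumi_trace <- function(x, ...) {
  graphics::plot(x$time_h, x$value, type = "l", xlab = "time (h)",
                 ylab = "luminescence (counts/s)", main = x$sample_id, ...)
  if (!is.null(x$events) && nrow(x$events))
    graphics::abline(v = x$events$time_h, lty = 2, col = "red")
  invisible(x)
}

#' @export
as.data.frame.lumi_trace <- function(x, ...) {
  data.frame(sample_id = x$sample_id, time_h = x$time_h,
             luminescence = x$value)
}

sampling_interval <- function(trace) trace$time_h[2L] - trace$time_h[1L]

#' Read and write trace tables
#'
#' Long-format CSV interchange for luminescence traces: columns `sample_id`,
#' `time_h`, `luminescence`; optional events CSV with columns `sample_id`,
#' `time_h`, `peptide`, `concentration_nM`.
#'
#' @param path CSV file of traces in long format.
#' @param events_path Optional CSV file of treatment events.
#' @return `read_traces()` returns a named list of [lumi_trace] objects.
#' @export
read_traces <- function(path, events_path = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("sample_id", "time_h", "luminescence")
  if (!all(req %in% names(df)))
    stop("trace CSV needs columns sample_id, time_h, luminescence")
  ev <- NULL
  if (!is.null(events_path)) {
    ev <- utils::read.csv(events_path, stringsAsFactors = FALSE)
    if (!all(c("sample_id", "time_h", "peptide", "concentration_nM") %in% names(ev)))
      stop("events CSV needs columns sample_id, time_h, peptide, concentration_nM")
  }
  ids <- unique(df$sample_id)
  out <- lapply(ids, function(id) {
    sub <- df[df$sample_id == id, , drop = FALSE]
    sub <- sub[order(sub$time_h), , drop = FALSE]
    e <- if (!is.null(ev)) ev[ev$sample_id == id, c("time_h", "peptide", "concentration_nM"), drop = FALSE]
    if (!is.null(e) && nrow(e) == 0L) e <- NULL
    lumi_trace(as.character(id), sub$time_h, sub$luminescence, events = e)
  })
  names(out) <- ids
  out
}

#' @rdname read_traces
#' @param traces List of [lumi_trace] objects.
#' @export
write_traces <- function(traces, path, events_path = NULL) {
  if (inherits(traces, "lumi_trace")) traces <- list(traces)
  df <- do.call(rbind, lapply(traces, as.data.frame))
  utils::write.csv(df, path, row.names = FALSE)
  if (!is.null(events_path)) {
    evs <- do.call(rbind, lapply(traces, function(tr) {
      if (is.null(tr$events) || !nrow(tr$events)) return(NULL)
      cbind(sample_id = tr$sample_id, tr$events)
    }))
    if (is.null(evs))
      evs <- data.frame(sample_id = character(), time_h = numeric(),
                        peptide = character(), concentration_nM = numeric())
    utils::write.csv(evs, events_path, row.names = FALSE)
  }
  invisible(path)
}

#' Ground-truth table of a synthetic cohort
#'
#' @param traces List of [lumi_trace] objects from [generate_cohort()].
#' @return Data frame with one row per treatment event: sample id, peptide,
#'   dose, event time, true treatment phase (degrees) and injected shift
#'   (hours, delays negative).
#' @export
ground_truth_table <- function(traces) {
  do.call(rbind, lapply(traces, function(tr) {
    if (is.null(tr$ground_truth)) return(NULL)
    ev <- tr$events
    data.frame(sample_id = tr$sample_id,
               peptide = ev$peptide, concentration_nM = ev$concentration_nM,
               time_h = tr$ground_truth$time_h,
               phase_deg = tr$ground_truth$phase_deg,
               shift_h = tr$ground_truth$shift_h,
               true_period_h = tr$true_period_h)
  }))
}
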