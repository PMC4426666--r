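#' Trough detection on a detrended trace
#'
#' Finds local minima of the (smoothed) detrended signal and enforces a
#' minimum separation: candidates are ranked by depth and accepted greedily,
#' ties broken by the deeper minimum, then the earlier time. Smoothing the
#' trace first (see [smooth_trace()]) is recommended on noisy data; the
#' default pipeline applies a 2-h moving median.
#'
#' @param detrended A [lumi_trace] (normally a `detrended_trace`).
#' @param min_separation_h Minimum distance between troughs in hours; default
#'   12, i.e. half the circadian period.
#' @param smooth_window_h Moving-median window applied before detection;
#'   `0` disables. Default 2.
#' @return Numeric vector of trough times (hours), strictly increasing.
#'   Errors with "insufficient cycles" when fewer than two troughs exist
#'   (e.g. a constant trace).
#' @export
find_troughs <- function(detrended, min_separation_h = 12,
                         smooth_window_h = 2) {
  stopifnot(inherits(detrended, "lumi_trace"), min_separation_h > 0)
  tr <- if (smooth_window_h > 0) smooth_trace(detrended, smooth_window_h) else detrended
  v <- tr$value
  t <- tr$time_h
  n <- length(v)
  if (n < 3L) stop("insufficient cycles: trace too short")
  # strict local minima (flat plateaus, e.g. constants, yield none)
  cand <- which(v[2:(n - 1L)] <= v[1:(n - 2L)] & v[2:(n - 1L)] <= v[3:n] &
                  (v[2:(n - 1L)] < v[1:(n - 2L)] | v[2:(n - 1L)] < v[3:n])) + 1L
  if (length(cand) == 0L) stop("insufficient cycles: no local minima found")
  # prominence: a trough must be the minimum of its +/- min_separation
  # neighborhood, which discards shallow noise dips near peaks
  half_sep <- max(1L, round(min_separation_h / (t[2L] - t[1L])))
  wmin <- running_stat(v, half_sep, min)
  cand <- cand[v[cand] <= wmin[cand]]
  if (length(cand) == 0L) stop("insufficient cycles: no local minima found")
  # within half a detrending window of either end the running-mean residue is
  # unreliable and fabricates extrema; drop that zone when possible
  if (inherits(detrended, "detrended_trace")) {
    margin <- detrended$window_h / 2
    inner <- cand[t[cand] >= t[1L] + margin & t[cand] <= t[n] - margin]
    if (length(inner) >= 2L) cand <- inner
  }
  ord <- order(v[cand], t[cand])   # deeper first, then earlier
  cand <- cand[ord]
  kept <- integer(0)
  for (i in cand) {
    if (all(abs(t[i] - t[kept]) >= min_separation_h)) kept <- c(kept, i)
  }
  kept <- sort(kept)
  # refine each trough below grid resolution: vertex of a least-squares
  # parabola through the unsmoothed values within +/- 1 h of the candidate
  # (the median smoothing flattens minima and would otherwise bias them)
  dt <- t[2L] - t[1L]
  hw <- max(2L, ceiling(1 / dt))
  troughs <- vapply(kept, function(i) {
    j <- max(1L, i - hw):min(n, i + hw)
    x <- t[j] - t[i]
    fit <- stats::.lm.fit(cbind(1, x, x^2), detrended$value[j])
    a <- fit$coefficients[3L]; b <- fit$coefficients[2L]
    vertex <- -b / (2 * a)
    if (is.finite(vertex) && a > 0 && abs(vertex) <= hw * dt)
      t[i] + vertex else t[i]
  }, numeric(1L))
  troughs <- sort(troughs)
  if (length(troughs) < 2L) stop("insufficient cycles: fewer than 2 troughs")
  gaps <- diff(troughs)
  med <- stats::median(gaps)
  if (any(gaps < 0.5 * med | gaps > 1.5 * med))
    warning("irregular trough spacing: gaps outside [0.5, 1.5] x median gap")
  troughs
}

#' Midpoint peak times from troughs
#'
#' Peaks are defined as the middle time point between two consecutive
#' troughs, the convention used for luminometry rhythms rather than the raw
#' argmax (robust to the asymmetry a decaying envelope induces).
#'
#' @param troughs Increasing numeric vector of trough times (>= 2).
#' @return Numeric vector of peak times, one fewer than the troughs.
#' @export
#' @examples
#' peaks_from_troughs(c(18, 42, 66))  # 30, 54
peaks_from_troughs <- function(troughs) {
  if (length(troughs) < 2L) stop("need at least 2 troughs")
  (troughs[-length(troughs)] + troughs[-1L]) / 2
}

#' Period from inter-peak intervals
#'
#' The period is the mean of the first `n_cycles` consecutive inter-peak
#' intervals, averaged over 3 cycles when available and otherwise 2.
#'
#' @param peaks Increasing numeric vector of peak times (hours).
#' @param n_cycles 2 or 3, or `NULL` (default) to use 3 when there are at
#'   least 4 peaks, else 2.
#' @return Period in hours.
#' @export
estimate_period <- function(peaks, n_cycles = NULL) {
  if (is.null(n_cycles)) n_cycles <- if (length(peaks) >= 4L) 3L else 2L
  if (!n_cycles %in% c(2L, 3L)) stop("n_cycles must be 2 or 3")
  if (length(peaks) < n_cycles + 1L)
    stop("insufficient peaks for ", n_cycles, " cycles")
  mean(diff(peaks)[seq_len(n_cycles)])
}

# Design matrix of the damped cosine with the linear part profiled out:
# y = env * (c1 cos wt + c2 sin wt), env = exp(-lambda (t - t0)).
# When the data were produced by running-mean detrending, the regressors are
# passed through the same truncated-window running-mean subtraction (operator
# D), so the model is compared to the data under the identical filter and the
# window edges do not bias the fit; two detrended polynomial nuisance columns
# absorb what the filter leaves of the slow baseline. D(constant) = 0, so no
# intercept is needed. The operator indices and nuisance columns depend only
# on the grid and are precomputed once per fit.
sine_design_ctx <- function(t, detrend_half = NULL) {
  ctx <- list(t = t, half = detrend_half)
  if (!is.null(detrend_half)) {
    n <- length(t)
    ctx$lo <- pmax(1L, seq_len(n) - detrend_half)
    ctx$hi <- pmin(n, seq_len(n) + detrend_half)
    ctx$len <- ctx$hi - ctx$lo + 1L
    tc <- (t - mean(t)) / max(diff(range(t)), 1)
    ctx$N <- cbind(detrend_col(tc, ctx), detrend_col(tc^2, ctx))
  }
  ctx
}

detrend_col <- function(x, ctx) {
  cs <- c(0, cumsum(x))
  x - (cs[ctx$hi + 1L] - cs[ctx$lo]) / ctx$len
}

damped_sine_design <- function(tau, lambda, t0, ctx) {
  w <- 2 * pi / tau
  env <- exp(-lambda * (ctx$t - t0))
  if (is.null(ctx$half))
    return(cbind(env * cos(w * ctx$t), env * sin(w * ctx$t)))
  cbind(detrend_col(env * cos(w * ctx$t), ctx),
        detrend_col(env * sin(w * ctx$t), ctx), ctx$N)
}

damped_sine_rss <- function(par, y, t0, ctx) {
  X <- damped_sine_design(par[1L], par[2L], t0, ctx)
  fit <- stats::.lm.fit(X, y)
  sum(fit$residuals^2)
}

damped_sine_linear <- function(tau, lambda, y, t0, ctx) {
  X <- damped_sine_design(tau, lambda, t0, ctx)
  fit <- stats::.lm.fit(X, y)
  c1 <- fit$coefficients[1L]; c2 <- fit$coefficients[2L]
  list(c1 = c1, c2 = c2, rss = sum(fit$residuals^2),
       fitted = y - fit$residuals)
}

#' Fit a damped sinusoid to a detrended trace window
#'
#' Least-squares fit of \eqn{A e^{-\lambda (t - t_0)}
#' \cos(2\pi (t - t_{peak})/\tau)} over a window of a detrended trace, with
#' \eqn{\lambda \ge 0} (a plain sine is the boundary case \eqn{\lambda = 0}).
#' For fixed \eqn{(\tau, \lambda)} the amplitude and phase enter linearly and
#' are profiled out, so the optimiser works in two dimensions only,
#' initialised from the extrema-based period and restarted from perturbed
#' periods if needed. The reference peak is the fitted peak nearest the
#' window centre.
#'
#' @param detrended A [lumi_trace] (normally detrended).
#' @param window Length-2 numeric `[t_start, t_end]` in hours; default the
#'   whole trace. Must contain at least two full cycles.
#' @param period_bounds Plausibility band for the period in hours; default
#'   `c(16, 32)`.
#' @param damped If `FALSE`, fixes \eqn{\lambda = 0}. Default `TRUE`.
#' @return An object of class `rhythm_fit` with elements `period_h`,
#'   `amplitude` (envelope value at the reference peak), `damping_rate`,
#'   `peak_time_h` (reference fitted peak), `window`, `residual_rms`,
#'   `converged`, `flags`, plus the data needed by its methods.
#' @export
fit_sine <- function(detrended, window = NULL, period_bounds = c(16, 32),
                     damped = TRUE) {
  stopifnot(inherits(detrended, "lumi_trace"))
  if (is.null(window))
    window <- range(detrended$time_h)
  idx <- detrended$time_h >= window[1L] & detrended$time_h <= window[2L]
  t <- detrended$time_h[idx]
  y <- detrended$value[idx]
  dhalf <- if (inherits(detrended, "detrended_trace")) detrended$detrend_half
  span <- diff(range(t))
  if (span < 2 * period_bounds[1L])
    stop("window contains fewer than 2 cycles at the minimum plausible period")
  flags <- character(0)
  # initialise period from extrema where possible
  tau0 <- tryCatch({
    sub <- detrended; sub$time_h <- t; sub$value <- y
    tr <- find_troughs(sub, min_separation_h = period_bounds[1L] / 2)
    if (length(tr) >= 3L) estimate_period(peaks_from_troughs(tr), 2L)
    else mean(diff(tr))
  }, error = function(e) mean(period_bounds))
  tau0 <- min(max(tau0, period_bounds[1L]), period_bounds[2L])
  t0 <- t[1L]
  lam_hi <- if (damped) 0.2 else 0
  starts <- unique(pmin(pmax(c(tau0, tau0 - 2, tau0 + 2), period_bounds[1L]),
                        period_bounds[2L]))
  best <- NULL
  ctx <- sine_design_ctx(t, dhalf)
  for (s in starts) {
    res <- tryCatch(
      stats::optim(c(s, if (damped) 0.01 else 0), damped_sine_rss,
                   y = y, t0 = t0, ctx = ctx, method = "L-BFGS-B",
                   lower = c(period_bounds[1L], 0),
                   upper = c(period_bounds[2L], max(lam_hi, 1e-10))),
      error = function(e) NULL)
    if (!is.null(res) && (is.null(best) || res$value < best$value)) best <- res
  }
  if (is.null(best)) {
    flags <- c(flags, "non-convergence")
    best <- list(par = c(tau0, 0), value = sum(y^2), convergence = 1L)
  }
  tau <- best$par[1L]; lambda <- best$par[2L]
  lin <- damped_sine_linear(tau, lambda, y, t0, ctx)
  R <- sqrt(lin$c1^2 + lin$c2^2)
  psi <- atan2(lin$c2, lin$c1)          # y = env * R * cos(w t - psi)
  w <- 2 * pi / tau
  centre <- mean(window)
  k <- round((centre - psi / w) / tau)
  peak_time <- psi / w + k * tau        # fitted peak nearest window centre
  if (span < 2 * tau) flags <- c(flags, "short-window")
  if (R <= 0) flags <- c(flags, "zero-amplitude")
  structure(list(period_h = tau, amplitude = R * exp(-lambda * (peak_time - t0)),
                 damping_rate = lambda, peak_time_h = peak_time,
                 window = window, residual_rms = sqrt(lin$rss / length(t)),
                 rss = lin$rss, n = length(t),
                 c1 = lin$c1, c2 = lin$c2, t0 = t0,
                 fitted_values = lin$fitted,
                 converged = is.null(best$convergence) || best$convergence == 0L,
                 flags = flags, time_h = t, value = y,
                 sample_id = detrended$sample_id),
            class = "rhythm_fit")
}

fit_values <- function(fit, t) {
  w <- 2 * pi / fit$period_h
  env <- exp(-fit$damping_rate * (t - fit$t0))
  env * (fit$c1 * cos(w * t) + fit$c2 * sin(w * t))
}

#' @export
print.rhythm_fit <- function(x, ...) {
  cat(sprintf(
    "<rhythm_fit> %s [%.1f, %.1f] h: period %.3f h, amplitude %.2f, damping %.4f /h\n",
    x$sample_id, x$window[1L], x$window[2L], x$period_h, x$amplitude,
    x$damping_rate))
  cat(sprintf("  reference peak %.3f h, residual RMS %.3f (n = %d)%s\n",
              x$peak_time_h, x$residual_rms, x$n,
              if (length(x$flags)) paste0(" [", paste(x$flags, collapse = ", "), "]") else ""))
  invisible(x)
}

#' @export
coef.rhythm_fit <- function(object, ...) {
  c(period_h = object$period_h, amplitude = object$amplitude,
    damping_rate = object$damping_rate, peak_time_h = object$peak_time_h)
}

#' @export
summary.rhythm_fit <- function(object, ...) {
  tss <- sum((object$value - mean(object$value))^2)
  out <- list(coef = coef(object), residual_rms = object$residual_rms,
              r_squared = if (tss > 0) 1 - object$rss / tss else NA_real_,
              n = object$n, flags = object$flags, window = object$window,
              sample_id = object$sample_id)
  class(out) <- "summary.rhythm_fit"
  out
}

#' @export
print.summary.rhythm_fit <- function(x, ...) {
  cat(sprintf("Damped-sine fit for %s over [%.1f, %.1f] h (n = %d)\n",
              x$sample_id, x$window[1L], x$window[2L], x$n))
  print(round(x$coef, 4))
  cat(sprintf("residual RMS %.4f, R^2 %.4f\n", x$residual_rms, x$r_squared))
  if (length(x$flags)) cat("flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' @export
predict.rhythm_fit <- function(object, newdata = NULL, ...) {
  t <- if (is.null(newdata)) object$time_h else
    if (is.list(newdata)) newdata$time_h else as.numeric(newdata)
  fit_values(object, t)
}

#' @export
fitted.rhythm_fit <- function(object, ...) object$fitted_values

#' @export
residuals.rhythm_fit <- function(object, ...)
  object$value - object$fitted_values

#' @export
plot.rhythm_fit <- function(x, ...) {
  graphics::plot(x$time_h, x$value, type = "l", col = "grey40",
                 xlab = "time (h)", ylab = "detrended luminescence",
                 main = x$sample_id, ...)
  graphics::lines(x$time_h, fitted(x), col = "red")
  graphics::abline(v = x$peak_time_h, lty = 2)
  invisible(x)
}

#' Simulate new traces from a fitted rhythm
#'
#' Draws noisy replicates of the fitted damped sinusoid on the fitted grid,
#' with noise at the fit's residual RMS.
#'
#' @param object A `rhythm_fit`.
#' @param nsim Number of replicates.
#' @param seed Optional integer seed.
#' @param ... Unused.
#' @return Data frame of `nsim` simulated value columns on the fit grid.
#' @export
simulate.rhythm_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  mu <- fitted(object)
  out <- as.data.frame(replicate(
    nsim, mu + stats::rnorm(length(mu), 0, object$residual_rms)))
  names(out) <- paste0("sim_", seq_len(nsim))
  cbind(time_h = object$time_h, out)
}

#' Extrapolated fitted peak times
#'
#' Peak times of a fitted rhythm extended beyond its window: the reference
#' peak plus integer multiples of the period.
#'
#' @param fit A `rhythm_fit`.
#' @param from,to Time range (hours) to cover.
#' @return Numeric vector of peak times within `[from, to]`.
#' @export
extrapolated_peaks <- function(fit, from, to) {
  tau <- fit$period_h
  k <- seq(floor((from - fit$peak_time_h) / tau),
           ceiling((to - fit$peak_time_h) / tau))
  pk <- fit$peak_time_h + k * tau
  pk[pk >= from & pk <= to]
}

#' Treatment phase in degrees
#'
#' Converts a treatment time to the degree scale of the luminescence cycle:
#' the ascending zero crossing is 0/360 degrees and the peak is 90 degrees, so
#' \deqn{\phi = \frac{T_p - P_{bt}}{\tau} \times 360 + 90}
#' wrapped into `[0, 360)`, where \eqn{T_p} is the treatment time, \eqn{P_{bt}}
#' the last fitted peak at or before the treatment, and \eqn{\tau} the period.
#'
#' @param T_p Treatment time in hours (since recording start).
#' @param P_bt Peak time before treatment in hours (`P_bt <= T_p`).
#' @param tau Period in hours (> 0).
#' @return An object of class `treatment_phase`: list with `degrees` (wrapped
#'   into `[0, 360)`), `degrees_raw` (the formula value before modular
#'   reduction), `T_p`, `P_bt`, `tau`.
#' @export
#' @examples
#' treatment_phase_degrees(44, 44, 24)$degrees          # at the peak: 90
#' treatment_phase_degrees(62, 44, 24)$degrees_raw      # 0.75 cycle: 360
treatment_phase_degrees <- function(T_p, P_bt, tau) {
  if (tau <= 0) stop("tau must be > 0")
  if (T_p < P_bt) stop("treatment before the reference peak")
  if (T_p > P_bt + tau * (1 + 1e-6))
    stop("P_bt must be the peak immediately before treatment")
  raw <- ((T_p - P_bt) / tau) * 360 + 90
  structure(list(degrees = wrap360(raw), degrees_raw = raw,
                 T_p = T_p, P_bt = P_bt, tau = tau),
            class = "treatment_phase")
}

#' @export
print.treatment_phase <- function(x, ...) {
  cat(sprintf("<treatment_phase> %.2f deg (raw %.2f): T_p %.2f h, P_bt %.2f h, tau %.3f h\n",
              x$degrees, x$degrees_raw, x$T_p, x$P_bt, x$tau))
  invisible(x)
}
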