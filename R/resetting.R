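# wrap a shift in hours into (-tau/2, tau/2]
wrap_shift <- function(shift, tau) {
  # ceiling(x - 0.5) keeps +tau/2 and sends -tau/2 to +tau/2
  shift - tau * ceiling(shift / tau - 0.5)
}

#' Phase shift of one treated trace
#'
#' Estimates the phase shift produced by a treatment by comparing
#' extrapolated peak times from damped-sine fits before and after the event:
#' the pre-treatment fit is extrapolated forward, and the shift is the
#' extrapolated pre-treatment peak nearest the first fitted post-treatment
#' peak minus that post-treatment peak, wrapped into `(-tau/2, tau/2]`. A
#' later observed peak therefore gives a negative value (delay); advances are
#' positive. The pre-treatment window ends at the event; the post-treatment
#' window starts at the first detected trough after the event, skipping the
#' acute transient.
#'
#' @param trace A [lumi_trace] with exactly one treatment event (or `event`
#'   given explicitly).
#' @param event Optional single-row data frame overriding `trace$events`.
#' @param window_h Detrending window in hours. Default 24.
#' @param period_bounds Plausibility band for fitted periods. Default
#'   `c(16, 32)`.
#' @param min_separation_h Trough separation for the post-window anchor.
#'   Default 12.
#' @param damped Fit a damping term (see [fit_sine()]). Default `TRUE`.
#' @return An object of class `phase_shift_estimate`: list with `sample_id`,
#'   `shift_h`, `phase_deg` (treatment phase from the pre-fit), `peptide`,
#'   `dose_nM`, `pre_fit`, `post_fit`, `flags`.
#' @export
phase_shift <- function(trace, event = NULL, window_h = 24,
                        period_bounds = c(16, 32), min_separation_h = 12,
                        damped = TRUE) {
  stopifnot(inherits(trace, "lumi_trace"))
  if (is.null(event)) {
    if (is.null(trace$events) || nrow(trace$events) != 1L)
      stop("trace must carry exactly one event (or pass `event`)")
    event <- trace$events
  }
  te <- event$time_h[1L]
  flags <- character(0)
  # pre- and post-treatment segments are detrended separately so that the
  # running mean never straddles the event (the shifted oscillation would
  # otherwise leak into the pre-treatment baseline and vice versa)
  pre_det <- tryCatch(baseline_subtract(crop_trace(trace, trace$time_h[1L], te),
                                        window_h),
                      error = function(e) NULL)
  pre <- if (!is.null(pre_det))
    tryCatch(fit_sine(pre_det, period_bounds = period_bounds, damped = damped),
             error = function(e) NULL)
  if (is.null(pre)) stop("insufficient cycles before the treatment")
  # post window anchored at the first trough after the event
  det <- baseline_subtract(trace, window_h)
  troughs <- tryCatch(find_troughs(det, min_separation_h = min_separation_h),
                      error = function(e) numeric(0))
  post_start <- troughs[troughs > te][1L]
  if (is.na(post_start)) post_start <- te + pre$period_h / 4
  post_det <- tryCatch(baseline_subtract(
    crop_trace(trace, post_start, max(trace$time_h)), window_h),
    error = function(e) NULL)
  post <- if (!is.null(post_det))
    tryCatch(fit_sine(post_det, period_bounds = period_bounds, damped = damped),
             error = function(e) NULL)
  if (is.null(post)) stop("insufficient cycles after the treatment")
  flags <- c(flags, pre$flags, post$flags)
  tau <- pre$period_h
  # first fitted post-treatment peak at or after the event
  k <- ceiling((te - post$peak_time_h) / post$period_h)
  post_peak <- post$peak_time_h + k * post$period_h
  # nearest extrapolated pre-treatment peak
  kp <- round((post_peak - pre$peak_time_h) / tau)
  pre_peak <- pre$peak_time_h + kp * tau
  shift <- wrap_shift(pre_peak - post_peak, tau)
  # treatment phase from the pre-fit extrapolation
  P_bt <- pre$peak_time_h + floor((te - pre$peak_time_h) / tau) * tau
  ph <- treatment_phase_degrees(te, P_bt, tau)
  structure(list(sample_id = trace$sample_id, shift_h = shift,
                 phase_deg = ph$degrees,
                 peptide = if ("peptide" %in% names(event)) event$peptide[1L] else NA_character_,
                 dose_nM = if ("concentration_nM" %in% names(event)) event$concentration_nM[1L] else NA_real_,
                 pre_fit = pre, post_fit = post, flags = flags),
            class = "phase_shift_estimate")
}

#' @export
print.phase_shift_estimate <- function(x, ...) {
  cat(sprintf("<phase_shift_estimate> %s: %+.3f h at %.1f deg (%s, %g nM)%s\n",
              x$sample_id, x$shift_h, x$phase_deg, x$peptide, x$dose_nM,
              if (length(x$flags)) paste0(" [", paste(unique(x$flags), collapse = ", "), "]") else ""))
  invisible(x)
}

#' Phase shifts for a whole cohort
#'
#' Applies [phase_shift()] to every trace and collects the estimates into a
#' data frame suitable for [fit_prc()] and [dose_response()].
#'
#' @param traces List of [lumi_trace] objects, each with one event.
#' @param ... Passed to [phase_shift()].
#' @return Data frame with columns `sample_id`, `peptide`, `dose_nM`,
#'   `phase_deg`, `shift_h`, `flagged`.
#' @export
estimate_shifts <- function(traces, ...) {
  rows <- lapply(traces, function(tr) {
    est <- phase_shift(tr, ...)
    data.frame(sample_id = est$sample_id, peptide = est$peptide,
               dose_nM = est$dose_nM, phase_deg = est$phase_deg,
               shift_h = est$shift_h, flagged = length(est$flags) > 0)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Harmonic phase-response-curve regression
#'
#' Ordinary least squares of individual phase shifts on a first- and
#' second-order harmonic basis of the treatment phase:
#' \deqn{shift = a_0 + a_1 \sin\phi + b_1 \cos\phi + a_2 \sin 2\phi +
#'       b_2 \cos 2\phi}
#' fitted unweighted on the individual slice estimates. Predictions on a
#' 1-degree grid are 360-degree periodic by construction.
#'
#' @param estimates Data frame with columns `phase_deg` and `shift_h` (as
#'   returned by [estimate_shifts()]), or a list of `phase_shift_estimate`
#'   objects.
#' @return An object of class `prc_fit` with `coefficients` (a0, a1, b1, a2,
#'   b2), `grid` (data frame phase 0..359 with predicted shift), `r_squared`
#'   (`NA` and flag "flat" when the shifts have no variance), `n`, `lm_fit`.
#' @export
fit_prc <- function(estimates) {
  if (is.list(estimates) && !is.data.frame(estimates) &&
      all(vapply(estimates, inherits, TRUE, "phase_shift_estimate")))
    estimates <- data.frame(
      phase_deg = vapply(estimates, `[[`, 0, "phase_deg"),
      shift_h = vapply(estimates, `[[`, 0, "shift_h"))
  phi <- estimates$phase_deg * pi / 180
  y <- estimates$shift_h
  if (length(y) < 8L) stop("need at least 8 phase-shift estimates")
  quad <- unique(floor(wrap360(estimates$phase_deg) / 90))
  if (length(quad) < 3L)
    stop("phases must span at least 3 quadrants of the cycle")
  df <- data.frame(y = y, s1 = sin(phi), c1 = cos(phi),
                   s2 = sin(2 * phi), c2 = cos(2 * phi))
  qrx <- qr(cbind(1, df$s1, df$c1, df$s2, df$c2))
  if (qrx$rank < 5L) stop("rank-deficient design: phases too concentrated")
  fit <- stats::lm(y ~ s1 + c1 + s2 + c2, data = df)
  cf <- stats::coef(fit)
  names(cf) <- c("a0", "a1", "b1", "a2", "b2")
  grid_deg <- 0:359
  gr <- grid_deg * pi / 180
  pred <- cf[1L] + cf[2L] * sin(gr) + cf[3L] * cos(gr) +
    cf[4L] * sin(2 * gr) + cf[5L] * cos(2 * gr)
  tss <- sum((y - mean(y))^2)
  flags <- character(0)
  r2 <- if (tss > 0) 1 - sum(stats::residuals(fit)^2) / tss else {
    flags <- "flat"; NA_real_
  }
  structure(list(coefficients = cf,
                 grid = data.frame(phase_deg = grid_deg, shift_h = as.numeric(pred)),
                 r_squared = r2, n = length(y), flags = flags,
                 data = estimates, lm_fit = fit),
            class = "prc_fit")
}

#' @export
coef.prc_fit <- function(object, ...) object$coefficients

#' @export
print.prc_fit <- function(x, ...) {
  cat(sprintf("<prc_fit> n = %d, R^2 = %s\n", x$n,
              ifelse(is.na(x$r_squared), "NA", sprintf("%.3f", x$r_squared))))
  print(round(x$coefficients, 4))
  if (length(x$flags)) cat("flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' @export
predict.prc_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$grid$shift_h)
  phi <- (if (is.list(newdata)) newdata$phase_deg else as.numeric(newdata)) * pi / 180
  cf <- object$coefficients
  as.numeric(cf[1L] + cf[2L] * sin(phi) + cf[3L] * cos(phi) +
               cf[4L] * sin(2 * phi) + cf[5L] * cos(2 * phi))
}

#' @export
residuals.prc_fit <- function(object, ...)
  object$data$shift_h - predict(object, object$data)

#' @export
summary.prc_fit <- function(object, ...) summary(object$lm_fit, ...)

#' @export
plot.prc_fit <- function(x, ...) {
  graphics::plot(x$data$phase_deg, x$data$shift_h, xlab = "treatment phase (deg)",
                 ylab = "phase shift (h)", xlim = c(0, 360), ...)
  graphics::lines(x$grid$phase_deg, x$grid$shift_h, lty = 2, col = "red")
  graphics::abline(h = 0, col = "grey")
  invisible(x)
}

#' Phase of maximal delay of a fitted PRC
#'
#' Locates the most negative predicted shift on the 1-degree grid (the phase
#' of the largest delay); ties are broken by the smallest phase. A fit with
#' essentially no structure (prediction range below `tol`) is flagged flat.
#'
#' @param model A `prc_fit`.
#' @param tol Flatness tolerance in hours: a fitted curve whose total span is
#'   below this (default 0.2 h, about 1% of a circadian cycle) has no
#'   meaningful extremum. Default 0.2.
#' @return List with `phase_deg`, `shift_h`, `flat`.
#' @export
prc_extremum <- function(model, tol = 0.2) {
  stopifnot(inherits(model, "prc_fit"))
  p <- model$grid$shift_h
  if (diff(range(p)) < tol)
    return(list(phase_deg = NA_real_, shift_h = p[1L], flat = TRUE))
  i <- which.min(p)[1L]
  list(phase_deg = model$grid$phase_deg[i], shift_h = p[i], flat = FALSE)
}

#' Dose-response table with one-way ANOVA against vehicle
#'
#' Summarises shift estimates per peptide and dose (mean, SEM, n), runs a
#' one-way ANOVA across the dose groups including vehicle, and performs
#' Bonferroni-adjusted pairwise comparisons of each dose against vehicle
#' using the pooled ANOVA error term. Significance stars: * p < 0.05,
#' ** p < 0.01, *** p < 0.001 (adjusted).
#'
#' @param estimates Data frame from [estimate_shifts()] (columns `peptide`,
#'   `dose_nM`, `shift_h`).
#' @param vehicle_label Peptide label of the vehicle group. Default `"PBS"`.
#' @return An object of class `dose_response_table`: list with `table` (one
#'   row per peptide x dose plus the vehicle row), `anova` (per-peptide F,
#'   df, p), `vehicle_label`.
#' @export
dose_response <- function(estimates, vehicle_label = "PBS") {
  veh <- estimates[estimates$peptide == vehicle_label, , drop = FALSE]
  if (nrow(veh) == 0L) stop("vehicle group '", vehicle_label, "' missing")
  peptides <- setdiff(unique(estimates$peptide), vehicle_label)
  rows <- list()
  anovas <- list()
  cell <- function(x, peptide, dose, p_adj = NA_real_) {
    data.frame(peptide = peptide, dose_nM = dose, mean_shift_h = mean(x),
               sem = stats::sd(x) / sqrt(length(x)), n = length(x),
               p_adj_vs_vehicle = p_adj,
               stars = stars_for(p_adj), stringsAsFactors = FALSE)
  }
  rows[["vehicle"]] <- cell(veh$shift_h, vehicle_label, 0)
  for (pep in peptides) {
    sub <- estimates[estimates$peptide == pep, , drop = FALSE]
    doses <- sort(unique(sub$dose_nM))
    groups <- c(list(veh$shift_h),
                lapply(doses, function(d) sub$shift_h[sub$dose_nM == d]))
    if (length(groups) < 2L) stop("need at least one dose group besides vehicle")
    y <- unlist(groups)
    g <- factor(rep(seq_along(groups), lengths(groups)))
    if (stats::var(y) == 0) {
      # degenerate case: every observation identical, nothing to test
      df_err <- length(y) - length(groups)
      anovas[[pep]] <- data.frame(peptide = pep, F = 0,
                                  df1 = length(groups) - 1L, df2 = df_err,
                                  p = 1)
      for (i in seq_along(doses))
        rows[[paste(pep, doses[i])]] <- cell(groups[[i + 1L]], pep, doses[i], 1)
      next
    }
    fit <- stats::aov(y ~ g)
    an <- summary(fit)[[1L]]
    ms_err <- an["Residuals", "Mean Sq"]
    df_err <- an["Residuals", "Df"]
    anovas[[pep]] <- data.frame(
      peptide = pep, F = an[1L, "F value"], df1 = an[1L, "Df"],
      df2 = df_err, p = an[1L, "Pr(>F)"])
    n_cmp <- length(doses)
    for (i in seq_along(doses)) {
      xd <- groups[[i + 1L]]
      se <- sqrt(ms_err * (1 / length(xd) + 1 / nrow(veh)))
      tval <- (mean(xd) - mean(veh$shift_h)) / se
      p <- min(1, 2 * stats::pt(-abs(tval), df_err) * n_cmp)
      rows[[paste(pep, doses[i])]] <- cell(xd, pep, doses[i], p)
    }
  }
  structure(list(table = do.call(rbind, c(rows, make.row.names = FALSE)),
                 anova = do.call(rbind, c(anovas, make.row.names = FALSE)),
                 vehicle_label = vehicle_label),
            class = "dose_response_table")
}

stars_for <- function(p) {
  ifelse(is.na(p), "", ifelse(p < 0.001, "***",
                              ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "ns"))))
}

#' @export
print.dose_response_table <- function(x, ...) {
  cat("Dose-response table (shifts in h; delays negative); vehicle:",
      x$vehicle_label, "\n")
  print(x$table, digits = 4, row.names = FALSE)
  cat("\nOne-way ANOVA across dose groups (incl. vehicle):\n")
  print(x$anova, digits = 4, row.names = FALSE)
  invisible(x)
}

#' Group comparisons as used for slice and expression statistics
#'
#' `method = "mann_whitney"` runs a two-sided Mann-Whitney (Wilcoxon
#' rank-sum) test between two groups. `method = "anova2_bonferroni"` runs a
#' two-way ANOVA (factors crossed, with interaction) followed by
#' Bonferroni-adjusted pairwise t comparisons of the levels of the first
#' factor within each level of the second, using the pooled error term.
#' p < 0.05 is flagged significant.
#'
#' @param values_a,values_b Numeric vectors (Mann-Whitney), each with at
#'   least 3 observations.
#' @param method `"mann_whitney"` or `"anova2_bonferroni"`.
#' @param design For the two-way ANOVA: data frame with columns `value`,
#'   `factor1`, `factor2` (then `values_a`/`values_b` are ignored).
#' @return A list report: `method`, `statistic`, `p_value`, `significant`,
#'   and for the ANOVA also `anova_table` and `post_tests` (data frame with
#'   Bonferroni-adjusted p per comparison).
#' @export
compare_groups <- function(values_a = NULL, values_b = NULL,
                           method = c("mann_whitney", "anova2_bonferroni"),
                           design = NULL) {
  method <- match.arg(method)
  if (method == "mann_whitney") {
    if (length(values_a) < 3L || length(values_b) < 3L)
      stop("need at least 3 observations per group")
    wt <- stats::wilcox.test(values_a, values_b, exact = NULL)
    return(list(method = method, statistic = unname(wt$statistic),
                p_value = wt$p.value, significant = wt$p.value < 0.05))
  }
  if (is.null(design) ||
      !all(c("value", "factor1", "factor2") %in% names(design)))
    stop("anova2_bonferroni needs a design data frame with value, factor1, factor2")
  design$factor1 <- factor(design$factor1)
  design$factor2 <- factor(design$factor2)
  tab <- table(design$factor1, design$factor2)
  if (any(tab == 0)) stop("unbalanced design: empty factor combinations")
  if (any(tab < 3)) stop("need at least 3 observations per group")
  fit <- stats::aov(value ~ factor1 * factor2, data = design)
  an <- summary(fit)[[1L]]
  ms_err <- an["Residuals", "Mean Sq"]
  df_err <- an["Residuals", "Df"]
  lev1 <- levels(design$factor1)
  cmb <- utils::combn(lev1, 2, simplify = FALSE)
  post <- list()
  for (l2 in levels(design$factor2)) {
    for (pr in cmb) {
      xa <- design$value[design$factor1 == pr[1L] & design$factor2 == l2]
      xb <- design$value[design$factor1 == pr[2L] & design$factor2 == l2]
      se <- sqrt(ms_err * (1 / length(xa) + 1 / length(xb)))
      tval <- (mean(xa) - mean(xb)) / se
      post[[paste(pr[1L], "vs", pr[2L], "@", l2)]] <-
        data.frame(comparison = paste(pr[1L], "vs", pr[2L]),
                   at = l2, t = tval, p_raw = 2 * stats::pt(-abs(tval), df_err))
    }
  }
  post <- do.call(rbind, c(post, make.row.names = FALSE))
  post$p_adj <- pmin(1, post$p_raw * nrow(post))
  post$significant <- post$p_adj < 0.05
  list(method = method,
       statistic = an[1:3, "F value"],
       p_value = an[1:3, "Pr(>F)"],
       significant = any(an[1:3, "Pr(>F)"] < 0.05),
       anova_table = an, post_tests = post)
}
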