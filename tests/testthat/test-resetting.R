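test_that("vehicle-treated noiseless traces yield a zero shift", {
  p <- clean_params()
  tr <- simulate_trace(p, peptide_response("PBS"),
                       data.frame(time_h = 50, peptide = "PBS",
                                  concentration_nM = 0), sample_id = "v")
  est <- suppressWarnings(phase_shift(tr))
  expect_lt(abs(est$shift_h), 0.05)
})

test_that("injected shifts are recovered at zero noise within 0.05 h", {
  for (s in c(-8, -4, 0, 2)) {
    est <- suppressWarnings(phase_shift(const_shift_trace(s)))
    expect_lt(abs(est$shift_h - s), 0.05)
  }
})

test_that("shifts identical modulo the period give identical estimates", {
  base <- suppressWarnings(phase_shift(const_shift_trace(-4)))
  plus <- suppressWarnings(phase_shift(const_shift_trace(-4 + 24)))
  minus <- suppressWarnings(phase_shift(const_shift_trace(-4 - 24)))
  # the cosine arguments differ by exactly 2*pi, so the traces agree to
  # floating rounding and the estimates to optimizer precision
  expect_equal(plus$shift_h, base$shift_h, tolerance = 1e-6)
  expect_equal(minus$shift_h, base$shift_h, tolerance = 1e-6)
  expect_gt(base$shift_h, -12); expect_lte(abs(base$shift_h), 12)
})

test_that("the shift estimator is unbiased over noisy replicates", {
  # 5% amplitude noise; injected shifts across the reported effect range
  injected <- c(-8, -4, 0, 2, 4)
  errs <- unlist(lapply(injected, function(s) {
    r <- const_shift_response(s)
    vapply(1:20, function(seed) {
      tr <- simulate_trace(oscillator_params(noise_sd = 5), r,
                           saturating_event(), seed = seed + 1000 * (s + 10),
                           sample_id = "n")
      suppressWarnings(phase_shift(tr)$shift_h) - s
    }, numeric(1))
  }))
  expect_length(errs, 100L)
  expect_lt(abs(mean(errs)), 0.1)
})

test_that("phase_shift demands a single event and enough cycles", {
  p <- clean_params()
  tr <- simulate_trace(p, sample_id = "none")
  expect_error(phase_shift(tr), "exactly one event")
  early <- simulate_trace(p, const_shift_response(-4), saturating_event(10),
                          sample_id = "early")
  expect_error(suppressWarnings(phase_shift(early)), "before the treatment")
})

test_that("harmonic PRC regression recovers exact coefficients and flags flat fits", {
  cf <- c(a0 = -2.5, a1 = 0.7, b1 = 4, a2 = -0.3, b2 = -1.5)
  phi <- seq(0, 345, by = 15)
  r <- phi * pi / 180
  shifts <- cf[1] + cf[2] * sin(r) + cf[3] * cos(r) +
    cf[4] * sin(2 * r) + cf[5] * cos(2 * r)
  m <- fit_prc(data.frame(phase_deg = phi, shift_h = shifts))
  expect_equal(unname(coef(m)), unname(cf), tolerance = 1e-9)
  expect_gt(m$r_squared, 1 - 1e-9)
  # periodicity of the prediction
  expect_equal(predict(m, 0), predict(m, 360), tolerance = 1e-9)
  # all-zero shifts: zero coefficients, R^2 flagged
  m0 <- fit_prc(data.frame(phase_deg = phi, shift_h = rep(0, length(phi))))
  expect_equal(max(abs(coef(m0))), 0, tolerance = 1e-12)
  expect_true(is.na(m0$r_squared))
  expect_true("flat" %in% m0$flags)
})

test_that("PRC regression rejects degenerate designs", {
  expect_error(fit_prc(data.frame(phase_deg = rep(100, 10), shift_h = rnorm(10))),
               "quadrant")
  expect_error(fit_prc(data.frame(phase_deg = c(0, 90, 180), shift_h = 1:3)),
               "at least 8")
})

test_that("prc_extremum finds the analytic minimum of a pure first harmonic", {
  phi <- seq(0, 352.5, by = 7.5)
  shifts <- -4 * sin(phi * pi / 180)
  m <- fit_prc(data.frame(phase_deg = phi, shift_h = shifts))
  ex <- prc_extremum(m)
  expect_false(ex$flat)
  expect_equal(ex$phase_deg, 90)
  expect_equal(ex$shift_h, -4, tolerance = 1e-9)
  flat <- prc_extremum(fit_prc(data.frame(phase_deg = phi,
                                          shift_h = rep(0, length(phi)))))
  expect_true(flat$flat)
})

test_that("PRC recovery: 48 phase-spread noisy traces localize the OXM delay maximum", {
  traces <- generate_cohort(prc_cohort_spec("OXM"), seed = 20)
  shifts <- suppressWarnings(estimate_shifts(traces))
  m <- fit_prc(shifts)
  ex <- prc_extremum(m)
  expect_lt(abs(ex$phase_deg - 180), 20)
  true_min <- expected_shift(peptide_response("OXM"), 180, 450)
  expect_lt(abs(ex$shift_h - true_min) / abs(true_min), 0.1)
})

test_that("dose_response summarises cells and matches a textbook ANOVA oracle", {
  est <- data.frame(
    peptide = rep(c("PBS", "OXM", "OXM"), each = 5),
    dose_nM = rep(c(0, 45, 450), each = 5),
    shift_h = c(0.1, -0.2, 0, 0.2, -0.1,
                -6.8, -7.2, -7.0, -7.4, -6.6,
                -8.1, -7.8, -8.0, -8.2, -7.9))
  dr <- dose_response(est)
  expect_equal(nrow(dr$table), 3L)
  expect_equal(dr$table$n, rep(5L, 3))
  # brute-force one-way ANOVA over the three groups
  groups <- split(est$shift_h, paste(est$peptide, est$dose_nM))
  k <- length(groups); N <- length(est$shift_h)
  grand <- mean(est$shift_h)
  ssb <- sum(vapply(groups, function(g) length(g) * (mean(g) - grand)^2, 0))
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), 0))
  f_oracle <- (ssb / (k - 1)) / (ssw / (N - k))
  expect_equal(dr$anova$F, f_oracle, tolerance = 1e-9)
  # Bonferroni-adjusted pairwise t against vehicle, pooled error term
  ms <- ssw / (N - k)
  t45 <- (mean(groups[["OXM 45"]]) - mean(groups[["PBS 0"]])) /
    sqrt(ms * (1 / 5 + 1 / 5))
  p_oracle <- min(1, 2 * pt(-abs(t45), N - k) * 2)
  row45 <- dr$table[dr$table$dose_nM == 45, ]
  expect_equal(row45$p_adj_vs_vehicle, p_oracle, tolerance = 1e-9)
  expect_equal(row45$stars, "***")
})

test_that("identical constant groups give F = 0 and no significance", {
  est <- data.frame(peptide = rep(c("PBS", "X"), each = 5),
                    dose_nM = rep(c(0, 450), each = 5),
                    shift_h = rep(1.5, 10))
  dr <- dose_response(est)
  expect_equal(dr$anova$F, 0)
  expect_true(all(dr$table$stars %in% c("", "ns")))
})

test_that("dose_response requires a vehicle group", {
  est <- data.frame(peptide = "OXM", dose_nM = 450, shift_h = rnorm(5))
  expect_error(dose_response(est), "vehicle")
})

test_that("Mann-Whitney comparisons behave at the extremes", {
  same <- suppressWarnings(  # exact p impossible with ties, expected here
    compare_groups(c(1, 2, 3, 4, 5), c(1, 2, 3, 4, 5), method = "mann_whitney"))
  expect_gt(same$p_value, 0.05)
  sep <- compare_groups(c(1, 2, 3), c(10, 11, 12), method = "mann_whitney")
  expect_equal(unname(sep$statistic), 0)
  expect_error(compare_groups(c(1, 2), c(3, 4, 5), method = "mann_whitney"),
               "at least 3")
})

test_that("Mann-Whitney type-I error matches its exact achievable size", {
  n <- 10
  # exact size of the two-sided exact test at nominal 0.05
  w <- 0:(n * n)
  pv <- vapply(w, function(x)
    min(1, 2 * min(pwilcox(x, n, n), 1 - pwilcox(x - 1, n, n))), numeric(1))
  exact_size <- sum(dwilcox(w, n, n)[pv < 0.05])
  set.seed(99)
  rej <- mean(vapply(1:500, function(i) {
    compare_groups(rnorm(n), rnorm(n), method = "mann_whitney")$significant
  }, logical(1)))
  mc_err <- 3 * sqrt(exact_size * (1 - exact_size) / 500)
  expect_lt(abs(rej - exact_size), mc_err)
  expect_lt(abs(exact_size - 0.05), 0.02)
})

test_that("two-way ANOVA with Bonferroni post-tests flags a clear interaction effect", {
  set.seed(7)
  design <- expand.grid(rep = 1:5, factor1 = c("PBS", "OXM"),
                        factor2 = c("0min", "60min"))
  design$value <- rnorm(20, sd = 0.3) +
    ifelse(design$factor1 == "OXM" & design$factor2 == "60min", 4, 0)
  rep2 <- compare_groups(method = "anova2_bonferroni", design = design)
  expect_true(rep2$significant)
  post <- rep2$post_tests
  hit <- post[post$at == "60min", ]
  expect_true(hit$significant)
  expect_lte(max(post$p_adj), 1)
  miss <- post[post$at == "0min", ]
  expect_false(miss$significant)
  # degenerate designs are rejected
  bad <- design[design$factor1 != "OXM" | design$factor2 != "60min", ]
  expect_error(compare_groups(method = "anova2_bonferroni", design = bad),
               "unbalanced")
})

test_that("estimated delay magnitude grows with dose for a Hill-response cohort", {
  traces <- generate_cohort(dose_response_cohort_spec("OXM"), seed = 31)
  shifts <- suppressWarnings(estimate_shifts(traces))
  oxm <- shifts[shifts$peptide == "OXM", ]
  agg_m <- tapply(oxm$shift_h, oxm$dose_nM, mean)
  agg_se <- tapply(oxm$shift_h, oxm$dose_nM, function(x) sd(x) / sqrt(length(x)))
  doses <- sort(unique(oxm$dose_nM))
  for (i in seq_len(length(doses) - 1)) {
    lo <- as.character(doses[i]); hi <- as.character(doses[i + 1])
    expect_gte(abs(agg_m[[hi]]) + agg_se[[hi]] + agg_se[[lo]], abs(agg_m[[lo]]))
  }
})
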