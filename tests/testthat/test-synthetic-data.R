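test_that("expected_shift follows PRC x Hill: zero at dose 0, zero for null peptides", {
  oxm <- peptide_response("OXM")
  expect_identical(expected_shift(oxm, 123.4, 0), 0)
  for (pep in c("GLP-1", "GLP-2", "GRPP", "PBS")) {
    null <- peptide_response(pep)
    for (phi in c(0, 90, 180, 271.5))
      expect_identical(expected_shift(null, phi, 450), 0)
  }
})

test_that("packaged OXM response delays 8 h at 180 degrees and saturating dose", {
  oxm <- peptide_response("OXM")
  expect_equal(expected_shift(oxm, 180, Inf), -8)
  expect_equal(expected_shift(oxm, 180, 1e6), -8, tolerance = 1e-4)
  # 180 degrees is the PRC minimum
  grid <- seq(0, 359.5, by = 0.5)
  prc <- vapply(grid, function(p) expected_shift(oxm, p, Inf), numeric(1))
  expect_equal(grid[which.min(prc)], 180)
  # Hill calibration: 450 nM near-saturating, 0.5 nM near-inactive
  expect_gte(expected_shift(oxm, 180, 450) / -8, 0.95)
  expect_lte(expected_shift(oxm, 180, 0.5) / -8, 0.15)
})

test_that("packaged GCG and DEX responses match their reported shapes", {
  gcg <- peptide_response("GCG")
  expect_equal(expected_shift(gcg, 180, Inf), -3)
  expect_gte(expected_shift(gcg, 180, 450) / -3, 0.95)
  dex <- peptide_response("DEX")
  sat <- 1e5  # 100 uM
  delays <- vapply(seq(10, 80, by = 10), function(p)
    expected_shift(dex, p, sat), numeric(1))
  advances <- vapply(seq(100, 170, by = 10), function(p)
    expected_shift(dex, p, sat), numeric(1))
  expect_true(all(delays < 0))
  expect_true(all(advances > 0))
  expect_lt(abs(expected_shift(dex, 270, sat)), 0.1)
})

test_that("expected_shift rejects invalid inputs", {
  oxm <- peptide_response("OXM")
  expect_error(expected_shift(oxm, 360, 450))
  expect_error(expected_shift(oxm, -1, 450))
  expect_error(expected_shift(oxm, NaN, 450))
  expect_error(expected_shift(oxm, 180, -2))
})

test_that("noise-free trace is the exact damped sinusoid plus baseline", {
  p <- clean_params()
  tr <- simulate_trace(p, sample_id = "exact")
  at_peak <- tr$value[tr$time_h == p$initial_peak_time_h]
  expect_equal(at_peak,
               p$baseline_level * exp(-p$baseline_decay_rate * p$initial_peak_time_h) +
                 p$amplitude)
  analytic <- p$baseline_level * exp(-p$baseline_decay_rate * tr$time_h) +
    p$amplitude * cos(2 * pi * (tr$time_h - p$initial_peak_time_h) / p$period_h)
  expect_equal(tr$value, analytic, tolerance = 1e-12)
})

test_that("vehicle events leave the trace untouched", {
  p <- clean_params()
  plain <- simulate_trace(p, sample_id = "a")
  veh <- simulate_trace(p, peptide_response("PBS"),
                        data.frame(time_h = 50, peptide = "PBS",
                                   concentration_nM = 0), sample_id = "a")
  expect_identical(plain$value, veh$value)
  expect_equal(veh$ground_truth$shift_h, 0)
})

test_that("an injected delay moves post-event peaks later by exactly the shift", {
  p <- clean_params()
  s <- -4
  tr <- const_shift_trace(s, p)
  te <- 50
  # post-event samples equal the analytically shifted cosine (the realized
  # shift includes the Hill factor, 1 - 1e-9 at this dose)
  s_real <- tr$ground_truth$shift_h
  expect_equal(s_real, s, tolerance = 1e-8)
  post <- tr$time_h >= te
  analytic_post <- p$baseline_level * exp(-p$baseline_decay_rate * tr$time_h[post]) +
    p$amplitude * cos(2 * pi * (tr$time_h[post] - p$initial_peak_time_h + s_real) / p$period_h)
  expect_equal(tr$value[post], analytic_post, tolerance = 1e-12)
  # the observed post-event peak sits at the pre-event extrapolation + 4 h
  idx <- tr$time_h > 60 & tr$time_h < 90
  obs_peak <- tr$time_h[idx][which.max(tr$value[idx])]
  extrapolated <- 68  # peaks at 20, 44, 68 before shifting
  expect_equal(obs_peak, extrapolated - s, tolerance = 0.25)
})

test_that("identical seeds reproduce traces and cohorts bit for bit", {
  p <- oscillator_params()  # noisy
  a <- simulate_trace(p, seed = 42, sample_id = "s")
  b <- simulate_trace(p, seed = 42, sample_id = "s")
  expect_identical(a$value, b$value)
  spec <- cohort_spec(peptide_response("OXM"), doses_nM = c(4.5, 450),
                      replicates = 2)
  expect_identical(generate_cohort(spec, seed = 5), generate_cohort(spec, seed = 5))
})

test_that("generate_cohort yields one trace per cell with phases in the window", {
  spec <- cohort_spec(peptide_response("OXM"), doses_nM = 450, replicates = 3,
                      phase_window_deg = c(180, 200),
                      params = clean_params())
  traces <- generate_cohort(spec, seed = 2)
  treated <- Filter(function(tr) tr$events$peptide[1] == "OXM", traces)
  expect_length(treated, 3L)
  phases <- vapply(treated, function(tr) tr$ground_truth$phase_deg, numeric(1))
  expect_true(all(phases >= 180 & phases <= 200))
})

test_that("cohort ground-truth shifts equal expected_shift at the realized phase and dose", {
  spec <- dose_response_cohort_spec("OXM")
  traces <- generate_cohort(spec, seed = 9)
  expect_length(traces, 6 * 5 + 5)
  gt <- ground_truth_table(traces)
  oxm <- peptide_response("OXM")
  recomputed <- mapply(function(phi, dose, pep) {
    if (pep == "PBS") 0 else expected_shift(oxm, phi, dose)
  }, gt$phase_deg, gt$concentration_nM, gt$peptide)
  expect_equal(gt$shift_h, unname(recomputed), tolerance = 1e-12)
})

test_that("qPCR generator: flat fold profile round-trips to 1 at zero noise", {
  cfg <- qpcr_induction_config(noise_sd = 0)
  cfg$genes$Per1$fold <- rep(1, 4)
  cfg$genes$Per2$fold <- rep(1, 4)
  cq <- generate_qpcr_timecourse(cfg, seed = 1)
  rel <- relative_expression(cq, "Per1", "Actb", calibrator = 0,
                             calibrator_by = "timepoint")
  expect_equal(rel$relative_expression, rep(1, nrow(rel)), tolerance = 1e-12)
})

test_that("qPCR generator: fold 4 at efficiency 2 lowers target Cq by 2 cycles", {
  cfg <- list(timepoints = c(0, 60),
              genes = list(T = list(fold = c(1, 4), efficiency = 2, base_cq = 26),
                           R = list(fold = c(1, 1), efficiency = 2, base_cq = 18)),
              reference_gene = "R", replicates = 1, noise_sd = 0)
  cq <- generate_qpcr_timecourse(cfg, seed = 1)
  t0 <- cq$Cq[cq$gene == "T" & cq$timepoint == 0]
  t60 <- cq$Cq[cq$gene == "T" & cq$timepoint == 60]
  expect_equal(t0 - t60, 2)
})

test_that("packaged induction panel shows transient Per1 and sustained Per2", {
  cq <- generate_qpcr_timecourse(qpcr_induction_config(noise_sd = 0), seed = 1)
  per1 <- relative_expression(cq, "Per1", "Actb", calibrator = 0,
                              calibrator_by = "timepoint")
  prof1 <- tapply(per1$relative_expression, per1$timepoint, mean)
  expect_equal(names(which.max(prof1)), "60")
  expect_lt(prof1[["120"]], 1.5)  # back toward baseline by 120 min
  per2 <- relative_expression(cq, "Per2", "Actb", calibrator = 0,
                              calibrator_by = "timepoint")
  prof2 <- tapply(per2$relative_expression, per2$timepoint, mean)
  expect_gt(prof2[["120"]], 2)    # Per2 stays elevated
})

test_that("generator rejects invalid configurations", {
  expect_error(oscillator_params(sampling_interval_h = 4), "sampling_interval_h")
  expect_error(oscillator_params(duration_h = 48))
  expect_error(simulate_trace(clean_params(), const_shift_response(0),
                              saturating_event(time_h = 500)),
               "outside duration")
  bad <- qpcr_induction_config()
  bad$genes$Per1$efficiency <- 1
  expect_error(generate_qpcr_timecourse(bad), "efficiency")
})
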