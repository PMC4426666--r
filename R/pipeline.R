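#' Read a pipeline configuration file
#'
#' Configurations are structured YAML with sections `generator` (cohort
#' simulation), `analysis` (detrending and fitting parameters) and optional
#' `qpcr`, plus top-level `seed` and `outdir`. Any omitted key falls back to
#' the package default.
#'
#' @param path YAML file path.
#' @return Named list (class `pipeline_config`).
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  structure(cfg, class = "pipeline_config")
}

default_pipeline_config <- function() {
  list(seed = 1,
       generator = list(peptide = "OXM",
                        doses_nM = c(0.5, 1.5, 4.5, 15, 45, 450),
                        replicates = 5,
                        phase_window_deg = c(180, 200),
                        noise_sd = 5),
       analysis = list(window_h = 24, min_separation_h = 12,
                       period_bounds = c(16, 32), damped = TRUE),
       qpcr = list(enabled = TRUE, noise_sd = 0.1, replicates = 3))
}

merge_config <- function(base, override) {
  for (k in names(override)) {
    if (is.list(base[[k]]) && is.list(override[[k]]))
      base[[k]] <- merge_config(base[[k]], override[[k]])
    else base[[k]] <- override[[k]]
  }
  base
}

#' Run the full analysis pipeline
#'
#' Orchestrates simulate, detrend, fit, shift, PRC, dose-response and
#' (optionally) the synthetic qPCR panel as one seeded, reproducible run.
#' Per-stage CSVs, a JSON summary and a log file are written under `outdir`;
#' runs with the same configuration and seed produce byte-identical
#' summaries. Input files are never modified; each run writes into its own
#' directory.
#'
#' @param config A config list / `pipeline_config` (see
#'   [read_pipeline_config()]) or a path to a YAML file; `NULL` uses the
#'   package defaults (an OXM dose-response cohort).
#' @param seed Integer seed overriding the config's. All stage substreams are
#'   derived deterministically from it.
#' @param outdir Output directory (created if missing); overrides the
#'   config's.
#' @return Invisibly, a list with `shifts`, `dose_table`, `prc`,
#'   `summary` (the JSON content), and `outdir`.
#' @export
run_pipeline <- function(config = NULL, seed = NULL, outdir = NULL) {
  if (is.character(config)) config <- read_pipeline_config(config)
  cfg <- merge_config(default_pipeline_config(),
                      if (is.null(config)) list() else config)
  if (!is.null(seed)) cfg$seed <- seed
  if (!is.null(outdir)) cfg$outdir <- outdir
  if (is.null(cfg$outdir)) cfg$outdir <- file.path(tempdir(), "lumiphase_run")
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  logf <- file.path(cfg$outdir, "run.log")
  logline <- function(...) cat(sprintf(...), "\n", sep = "", file = logf,
                               append = TRUE)
  cat(sprintf("lumiphase %s pipeline run, seed %d (%s)\n",
              as.character(utils::packageVersion("lumiphase")), cfg$seed,
              format(Sys.time())), file = logf)
  logline("times in hours; phases in degrees on [0, 360); delays negative")

  gen <- cfg$generator
  osc_args <- gen[intersect(names(gen), names(formals(oscillator_params)))]
  params <- do.call(oscillator_params, osc_args)
  responses <- stats::setNames(lapply(gen$peptide, peptide_response),
                               gen$peptide)
  spec <- cohort_spec(responses, doses_nM = unlist(gen$doses_nM),
                      replicates = gen$replicates,
                      phase_window_deg = unlist(gen$phase_window_deg),
                      params = params)
  set.seed(cfg$seed)
  stage_seeds <- sample.int(.Machine$integer.max, 3L)

  # stage 1: simulate
  traces <- generate_cohort(spec, seed = stage_seeds[1L])
  write_traces(traces, file.path(cfg$outdir, "traces.csv"),
               events_path = file.path(cfg$outdir, "events.csv"))
  gt <- ground_truth_table(traces)
  utils::write.csv(gt, file.path(cfg$outdir, "ground_truth.csv"),
                   row.names = FALSE)
  logline("simulate: %d traces (%d samples each)", length(traces),
          length(traces[[1L]]$time_h))

  # stage 2: detrend
  ana <- cfg$analysis
  detrended <- lapply(traces, baseline_subtract, window_h = ana$window_h)
  det_df <- do.call(rbind, lapply(detrended, function(d)
    cbind(as.data.frame(d), window_h = d$window_h)))
  utils::write.csv(det_df, file.path(cfg$outdir, "detrended.csv"),
                   row.names = FALSE)
  logline("detrend: running mean, window %.1f h", ana$window_h)

  # stage 3: per-sample rhythm descriptors (full-trace fit and extrema)
  fit_rows <- lapply(detrended, function(d) {
    tryCatch({
      tro <- find_troughs(d, min_separation_h = ana$min_separation_h)
      pks <- peaks_from_troughs(tro)
      per <- tryCatch(estimate_period(pks), error = function(e) NA_real_)
      ft <- fit_sine(d, period_bounds = unlist(ana$period_bounds),
                     damped = isTRUE(ana$damped))
      data.frame(sample_id = d$sample_id, n_troughs = length(tro),
                 first_trough_h = tro[1L], extrema_period_h = per,
                 fit_period_h = ft$period_h, fit_amplitude = ft$amplitude,
                 fit_damping = ft$damping_rate, fit_peak_h = ft$peak_time_h,
                 residual_rms = ft$residual_rms)
    }, error = function(e)
      data.frame(sample_id = d$sample_id, n_troughs = NA, first_trough_h = NA,
                 extrema_period_h = NA, fit_period_h = NA, fit_amplitude = NA,
                 fit_damping = NA, fit_peak_h = NA, residual_rms = NA))
  })
  fits_df <- do.call(rbind, c(fit_rows, make.row.names = FALSE))
  utils::write.csv(fits_df, file.path(cfg$outdir, "fits.csv"),
                   row.names = FALSE)
  failed <- fits_df$sample_id[is.na(fits_df$fit_period_h)]
  if (length(failed))
    logline("fit: FAILED samples: %s", paste(failed, collapse = ", "))

  # stage 4: phase shifts
  shifts <- estimate_shifts(traces, window_h = ana$window_h,
                            period_bounds = unlist(ana$period_bounds),
                            min_separation_h = ana$min_separation_h,
                            damped = isTRUE(ana$damped))
  utils::write.csv(shifts, file.path(cfg$outdir, "shifts.csv"),
                   row.names = FALSE)
  logline("shift: %d estimates, %d flagged", nrow(shifts), sum(shifts$flagged))

  # stage 5: PRC (needs phases spanning >= 3 quadrants); a vehicle-only
  # cohort gets its PRC fitted on the vehicle shifts (expected flat)
  prc_in <- shifts[shifts$peptide != "PBS", , drop = FALSE]
  if (nrow(prc_in) == 0L) prc_in <- shifts
  prc <- tryCatch(fit_prc(prc_in),
                  error = function(e) {
                    logline("prc: skipped (%s)", conditionMessage(e)); NULL
                  })
  ext <- NULL
  if (!is.null(prc)) {
    utils::write.csv(prc$grid, file.path(cfg$outdir, "prc_grid.csv"),
                     row.names = FALSE)
    ext <- prc_extremum(prc)
    logline("prc: R^2 %s, extremum %s",
            format(prc$r_squared),
            if (ext$flat) "flat" else sprintf("%g deg (%.3f h)",
                                              ext$phase_deg, ext$shift_h))
  }

  # stage 6: dose-response vs vehicle
  dr <- NULL
  if (length(setdiff(unique(shifts$peptide), "PBS")) > 0L) {
    dr <- dose_response(shifts, vehicle_label = "PBS")
    utils::write.csv(dr$table, file.path(cfg$outdir, "dose_response.csv"),
                     row.names = FALSE)
    logline("dose: %d cells", nrow(dr$table))
  } else logline("dose: skipped (vehicle-only cohort)")

  # stage 7: synthetic qPCR induction panel
  qp <- NULL
  if (isTRUE(cfg$qpcr$enabled)) {
    qcfg <- qpcr_induction_config(noise_sd = cfg$qpcr$noise_sd,
                                  replicates = cfg$qpcr$replicates)
    qp <- generate_qpcr_timecourse(qcfg, seed = stage_seeds[2L])
    utils::write.csv(qp, file.path(cfg$outdir, "qpcr_cq.csv"),
                     row.names = FALSE)
    rel <- do.call(rbind, lapply(c("Per1", "Per2", "Bmal1"), function(g) {
      r <- relative_expression(qp, g, "Actb", calibrator = 0,
                               calibrator_by = "timepoint")
      cbind(gene = g, r)
    }))
    utils::write.csv(rel, file.path(cfg$outdir, "qpcr_relative.csv"),
                     row.names = FALSE)
    logline("qpcr: %d Cq records", nrow(qp))
  }

  mean_by_dose <- stats::aggregate(shift_h ~ peptide + dose_nM, data = shifts,
                                   FUN = mean)
  summary_obj <- list(
    seed = cfg$seed,
    n_traces = length(traces),
    parameters = list(window_h = ana$window_h,
                      min_separation_h = ana$min_separation_h,
                      period_bounds = unlist(ana$period_bounds)),
    mean_fit_period_h = mean(fits_df$fit_period_h, na.rm = TRUE),
    mean_shift_by_dose = mean_by_dose,
    prc = if (!is.null(prc)) list(
      coefficients = as.list(prc$coefficients),
      r_squared = prc$r_squared,
      extremum = ext) else NULL,
    dose_anova = if (!is.null(dr)) dr$anova else NULL)
  jsonlite::write_json(summary_obj, file.path(cfg$outdir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  logline("done")
  invisible(list(shifts = shifts, dose_table = dr, prc = prc,
                 summary = summary_obj, outdir = cfg$outdir))
}
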