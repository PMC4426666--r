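#' Oscillator parameters for synthetic luminescence traces
#'
#' Parameters of the damped-sinusoid trace model
#' \deqn{L(t) = b_0 e^{-kt} + A e^{-\lambda t}
#'       \cos\left(\frac{2\pi (t - t_{peak})}{\tau}\right) + \epsilon}
#' where \eqn{\tau} is the free-running period, \eqn{A} the initial
#' amplitude, \eqn{\lambda} the amplitude damping rate of the explant,
#' \eqn{t_{peak}} the time of the first luminescence peak, \eqn{b_0 e^{-kt}}
#' the monotonically decaying baseline, and \eqn{\epsilon} i.i.d. Gaussian
#' noise.
#'
#' @param period_h Free-running period in hours (> 0). Default 24.
#' @param amplitude Initial oscillation amplitude in counts/s (>= 0).
#' @param damping_rate Exponential amplitude decay rate in 1/h (>= 0).
#' @param initial_peak_time_h Time of the first peak in hours.
#' @param baseline_level Baseline level at t = 0 in counts/s.
#' @param baseline_decay_rate Baseline exponential decay rate in 1/h.
#' @param noise_sd Gaussian noise standard deviation in counts/s (>= 0).
#' @param sampling_interval_h Sampling interval in hours; must be positive
#'   and finer than an eighth of the period.
#' @param duration_h Recording length in hours; at least three periods.
#' @return An object of class `oscillator_params` (a validated list).
#' @export
oscillator_params <- function(period_h = 24, amplitude = 100,
                              damping_rate = 0.01,
                              initial_peak_time_h = 20,
                              baseline_level = 500,
                              baseline_decay_rate = 0.01,
                              noise_sd = 5,
                              sampling_interval_h = 1 / 6,
                              duration_h = 120) {
  stopifnot(period_h > 0, amplitude >= 0, damping_rate >= 0, noise_sd >= 0,
            sampling_interval_h > 0, sampling_interval_h < period_h / 8,
            duration_h >= 3 * period_h)
  structure(list(period_h = period_h, amplitude = amplitude,
                 damping_rate = damping_rate,
                 initial_peak_time_h = initial_peak_time_h,
                 baseline_level = baseline_level,
                 baseline_decay_rate = baseline_decay_rate,
                 noise_sd = noise_sd,
                 sampling_interval_h = sampling_interval_h,
                 duration_h = duration_h),
            class = "oscillator_params")
}

#' Treatment response: phase-response curve times Hill dose-response
#'
#' Ground-truth resetting behaviour of one peptide. The phase shift injected
#' by a treatment at oscillator phase \eqn{\phi} (degrees) and dose \eqn{d}
#' (nM) is \deqn{\Delta(\phi, d) = PRC(\phi) \cdot
#'   \frac{d^{n}}{d^{n} + EC_{50}^{n}}}
#' with the PRC a two-harmonic Fourier series
#' \eqn{PRC(\phi) = a_0 + a_1 \sin\phi + b_1 \cos\phi + a_2 \sin 2\phi +
#' b_2 \cos 2\phi} in hours, delays negative and advances positive.
#'
#' @param peptide_name Label, e.g. `"OXM"`.
#' @param prc_coefficients Numeric vector `(a0, a1, b1, a2, b2)` in hours.
#' @param ec50 Half-maximal concentration in nM (> 0).
#' @param hill_n Hill coefficient (> 0).
#' @param amplitude_damping_factor Multiplier in `[0, 1]` applied to the
#'   oscillation amplitude after a non-vehicle treatment.
#' @return An object of class `treatment_response`.
#' @seealso [peptide_response()] for the packaged calibrations.
#' @export
treatment_response <- function(peptide_name, prc_coefficients = c(0, 0, 0, 0, 0),
                               ec50 = 5, hill_n = 1,
                               amplitude_damping_factor = 1) {
  prc_coefficients <- as.numeric(prc_coefficients)
  stopifnot(length(prc_coefficients) == 5L, all(is.finite(prc_coefficients)),
            ec50 > 0, hill_n > 0,
            amplitude_damping_factor >= 0, amplitude_damping_factor <= 1)
  names(prc_coefficients) <- c("a0", "a1", "b1", "a2", "b2")
  structure(list(peptide_name = peptide_name,
                 prc_coefficients = prc_coefficients,
                 ec50 = ec50, hill_n = hill_n,
                 amplitude_damping_factor = amplitude_damping_factor),
            class = "treatment_response")
}

#' Packaged peptide response calibrations
#'
#' Loads the response configuration shipped with the package for one of the
#' tested peptides: `"OXM"`, `"GCG"`, `"GLP-1"`, `"GLP-2"`, `"GRPP"`,
#' `"DEX"`, `"PBS"`. Calibrations follow the reported effect sizes: the OXM
#' phase-response curve has its maximal delay of -8 h at 180 degrees, GCG -3 h,
#' DEX delays in 0-90 degrees and advances in 100-180 degrees, and the three
#' inactive peptides (and vehicle) are null. Hill parameters are set so a
#' 450 nM dose is near-saturating and 0.5 nM near-inactive.
#'
#' @param name Peptide label (case-insensitive).
#' @return A [treatment_response()] object.
#' @export
peptide_response <- function(name) {
  key <- toupper(name)
  file <- system.file("extdata", "responses",
                      paste0(gsub("-", "", tolower(key)), ".yaml"),
                      package = "lumiphase")
  if (!nzchar(file)) stop("no packaged response for peptide '", name, "'")
  cfg <- yaml::read_yaml(file)
  treatment_response(cfg$peptide_name,
                     unlist(cfg$prc_coefficients),
                     ec50 = cfg$ec50, hill_n = cfg$hill_n,
                     amplitude_damping_factor = cfg$amplitude_damping_factor)
}

prc_value <- function(coefficients, phase_deg) {
  r <- phase_deg * pi / 180
  coefficients[1L] + coefficients[2L] * sin(r) + coefficients[3L] * cos(r) +
    coefficients[4L] * sin(2 * r) + coefficients[5L] * cos(2 * r)
}

hill_fraction <- function(dose_nM, ec50, hill_n) {
  if (dose_nM == 0) return(0)
  if (is.infinite(dose_nM)) return(1)
  dn <- dose_nM^hill_n
  dn / (dn + ec50^hill_n)
}

#' Expected (ground-truth) phase shift of a treatment
#'
#' The shift injected by the generator: the peptide's phase-response curve
#' evaluated at the treatment phase, scaled by the Hill occupancy at the
#' given dose. Delays are negative, advances positive.
#'
#' @param response A [treatment_response()].
#' @param phase_deg Oscillator phase at treatment in degrees, `[0, 360)`.
#' @param dose_nM Dose in nM (>= 0; `Inf` gives the saturating shift).
#' @return Signed shift in hours.
#' @export
#' @examples
#' expected_shift(peptide_response("OXM"), 180, Inf)  # -8 h
#' expected_shift(peptide_response("OXM"), 180, 0)    # vehicle: 0 h
expected_shift <- function(response, phase_deg, dose_nM) {
  stopifnot(inherits(response, "treatment_response"))
  if (!is.finite(phase_deg) || is.na(dose_nM) || (is.nan(dose_nM)))
    stop("non-finite phase or dose")
  if (phase_deg < 0 || phase_deg >= 360) stop("phase_deg must be in [0, 360)")
  if (dose_nM < 0) stop("dose_nM must be >= 0")
  as.numeric(prc_value(response$prc_coefficients, phase_deg) *
               hill_fraction(dose_nM, response$ec50, response$hill_n))
}

wrap360 <- function(deg) {
  out <- deg %% 360
  out[out < 0] <- out[out < 0] + 360
  out
}

# oscillator phase (degrees) at time t given the true peak schedule:
# peaks sit at initial_peak_time_h - offset (+ k*tau); the phase convention
# puts a peak at 90 degrees and the ascending zero crossing at 0/360.
true_phase_deg <- function(t, initial_peak_time_h, period_h, offset_h = 0) {
  wrap360(((t - (initial_peak_time_h - offset_h)) / period_h) * 360 + 90)
}

#' Simulate one luminescence trace
#'
#' Generates a damped-sinusoid trace with exponentially decaying baseline and
#' Gaussian noise. Each treatment event applies an instantaneous phase shift
#' equal to [expected_shift()] at the oscillator phase realized at the event
#' time (delays move subsequent peaks later), and multiplies the amplitude by
#' the response's `amplitude_damping_factor` thereafter (vehicle events, dose
#' 0, leave the trace untouched).
#'
#' @param params An [oscillator_params()].
#' @param response A [treatment_response()] governing all events' effects.
#' @param events Data frame with columns `time_h`, `peptide`,
#'   `concentration_nM` (may be `NULL` or empty).
#' @param seed Integer seed; identical seeds give identical traces.
#' @param sample_id Sample label.
#' @return A [lumi_trace] with `ground_truth` recording, per event, the
#'   realized treatment phase (degrees) and injected shift (hours), and
#'   `true_period_h` set to `params$period_h`.
#' @export
simulate_trace <- function(params, response = treatment_response("PBS"),
                           events = NULL, seed = NULL, sample_id = "sim") {
  stopifnot(inherits(params, "oscillator_params"))
  if (!is.null(seed)) set.seed(seed)
  t <- seq(0, params$duration_h, by = params$sampling_interval_h)
  tau <- params$period_h
  if (!is.null(events) && nrow(events) > 0L) {
    events <- as.data.frame(events)
    if (is.unsorted(events$time_h)) events <- events[order(events$time_h), ]
    if (any(events$time_h < 0 | events$time_h > params$duration_h))
      stop("event outside duration")
  }
  offset <- 0      # cumulative phase shift in hours (advance positive)
  amp_scale <- 1
  gt <- NULL
  value <- numeric(length(t))
  bounds <- c(if (!is.null(events)) events$time_h, Inf)
  seg_start <- -Inf
  n_ev <- if (is.null(events)) 0L else nrow(events)
  for (k in seq_len(n_ev + 1L)) {
    seg_end <- bounds[k]
    idx <- t >= seg_start & t < seg_end
    value[idx] <- amp_scale * params$amplitude *
      exp(-params$damping_rate * t[idx]) *
      cos(2 * pi * (t[idx] - params$initial_peak_time_h + offset) / tau)
    if (k <= n_ev) {
      te <- events$time_h[k]
      phi <- true_phase_deg(te, params$initial_peak_time_h, tau, offset)
      dose <- events$concentration_nM[k]
      s <- expected_shift(response, phi, dose)
      gt <- rbind(gt, data.frame(time_h = te, phase_deg = phi, shift_h = s))
      offset <- offset + s
      if (dose > 0) amp_scale <- amp_scale * response$amplitude_damping_factor
      seg_start <- te
    }
  }
  baseline <- params$baseline_level * exp(-params$baseline_decay_rate * t)
  noise <- if (params$noise_sd > 0) stats::rnorm(length(t), 0, params$noise_sd) else 0
  lumi_trace(sample_id, t, baseline + value + noise, events = events,
             ground_truth = gt, true_period_h = tau)
}

#' Cohort specification for synthetic treatment experiments
#'
#' Describes a simulated slice-culture experiment: a set of peptides (each
#' with its [treatment_response()]), dose levels, replicates per dose, and
#' the treatment-phase window (degrees) in which each slice is treated.
#' Vehicle (PBS, dose 0) replicates are always included.
#'
#' @param responses Named list of [treatment_response()] objects.
#' @param doses_nM Numeric vector of dose levels in nM (non-empty).
#' @param replicates Replicates per peptide-dose cell (>= 1). Default 5.
#' @param phase_window_deg Length-2 numeric, treatment-phase window in
#'   degrees within `[0, 360]` (end may equal 360 for a full-cycle spread).
#' @param params Base [oscillator_params()] shared by all traces.
#' @param vehicle_replicates Number of PBS control traces. Default
#'   `replicates`.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(responses, doses_nM, replicates = 5,
                        phase_window_deg = c(180, 200),
                        params = oscillator_params(),
                        vehicle_replicates = replicates) {
  if (inherits(responses, "treatment_response")) responses <- list(responses)
  stopifnot(length(doses_nM) > 0, replicates >= 1,
            length(phase_window_deg) == 2L,
            phase_window_deg[1L] >= 0, phase_window_deg[2L] <= 360,
            phase_window_deg[1L] < phase_window_deg[2L])
  if (is.null(names(responses)))
    names(responses) <- vapply(responses, `[[`, "", "peptide_name")
  structure(list(responses = responses, doses_nM = doses_nM,
                 replicates = replicates,
                 phase_window_deg = phase_window_deg, params = params,
                 vehicle_replicates = vehicle_replicates),
            class = "cohort_spec")
}

# treatment time realizing phase phi: phi degrees after (phi-90)/360 of a
# cycle past the reference true peak
time_at_phase <- function(phi_deg, ref_peak_h, period_h) {
  ref_peak_h + period_h * (wrap360(phi_deg - 90)) / 360
}

#' Generate a synthetic treated cohort
#'
#' One trace per peptide x dose x replicate plus vehicle controls. Treatment
#' phases are stratified across the requested window (replicate i is drawn
#' uniformly from the i-th equal subdivision of the window) so small cohorts
#' still cover it; treatment times are placed relative to the second true
#' peak, leaving at least two full cycles on each side of the event.
#'
#' @param spec A [cohort_spec()].
#' @param seed Integer seed for reproducibility.
#' @return List of [lumi_trace] objects with ground truth attached.
#' @export
generate_cohort <- function(spec, seed = 1) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(seed)
  p <- spec$params
  ref_peak <- p$initial_peak_time_h + p$period_h  # second true peak
  win <- spec$phase_window_deg
  draw_phase <- function(i, n) {
    lo <- win[1L] + (i - 1L) / n * diff(win)
    hi <- win[1L] + i / n * diff(win)
    phi <- stats::runif(1L, lo, hi)
    if (phi >= 360) phi <- phi - 360
    phi
  }
  traces <- list()
  for (pep in names(spec$responses)) {
    resp <- spec$responses[[pep]]
    for (dose in spec$doses_nM) {
      for (r in seq_len(spec$replicates)) {
        phi <- draw_phase(r, spec$replicates)
        te <- time_at_phase(phi, ref_peak, p$period_h)
        ev <- data.frame(time_h = te, peptide = pep, concentration_nM = dose)
        id <- sprintf("%s_%gnM_r%d", pep, dose, r)
        traces[[id]] <- simulate_trace(
          p, resp, ev, seed = sample.int(.Machine$integer.max, 1L),
          sample_id = id)
      }
    }
  }
  veh <- treatment_response("PBS")
  for (r in seq_len(spec$vehicle_replicates)) {
    phi <- draw_phase(r, spec$vehicle_replicates)
    te <- time_at_phase(phi, ref_peak, p$period_h)
    ev <- data.frame(time_h = te, peptide = "PBS", concentration_nM = 0)
    id <- sprintf("PBS_r%d", r)
    traces[[id]] <- simulate_trace(
      p, veh, ev, seed = sample.int(.Machine$integer.max, 1L), sample_id = id)
  }
  traces
}

#' Packaged dose-response cohort specification
#'
#' The simulated analogue of the slice dose-response experiment: six dose
#' levels from 0.5 to 450 nM, five replicates per dose, treatments in the
#' 180-200 degree window, plus five PBS controls — 35 traces in 7 groups of 5.
#'
#' @param peptide Peptide name understood by [peptide_response()].
#' @param noise_sd Trace noise in counts/s; default 5 (5% of the default
#'   amplitude of 100).
#' @return A [cohort_spec()].
#' @export
dose_response_cohort_spec <- function(peptide, noise_sd = 5) {
  cohort_spec(stats::setNames(list(peptide_response(peptide)), peptide),
              doses_nM = c(0.5, 1.5, 4.5, 15, 45, 450),
              replicates = 5, phase_window_deg = c(180, 200),
              params = oscillator_params(noise_sd = noise_sd))
}

#' Packaged phase-response-curve cohort specification
#'
#' Traces at a single saturating dose with treatment phases stratified over
#' the full cycle, for estimating a phase-response curve.
#'
#' @inheritParams dose_response_cohort_spec
#' @param n Number of traces (phases stratified over `[0, 360)`). Default 48.
#' @param dose_nM Dose in nM; default 450 (near-saturating for the packaged
#'   calibrations of the active peptides).
#' @return A [cohort_spec()] with no extra vehicle traces. The recording is
#'   144 h so that even the latest treatment times (phases just short of a
#'   peak fall almost a full cycle after the reference peak) leave two full
#'   cycles after the event.
#' @export
prc_cohort_spec <- function(peptide, n = 48, dose_nM = 450, noise_sd = 5) {
  cohort_spec(stats::setNames(list(peptide_response(peptide)), peptide),
              doses_nM = dose_nM, replicates = n,
              phase_window_deg = c(0, 360),
              params = oscillator_params(noise_sd = noise_sd,
                                         duration_h = 144),
              vehicle_replicates = 0)
}
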