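# shared fixtures for the test suite; everything is generated in code

# noiseless, undamped oscillator with constant-free dynamics for exact checks
clean_params <- function(...) {
  oscillator_params(noise_sd = 0, damping_rate = 0, ...)
}

# a single-peptide response injecting a constant shift at saturating dose
const_shift_response <- function(shift_h) {
  treatment_response("CONST", c(shift_h, 0, 0, 0, 0), ec50 = 1, hill_n = 1)
}

saturating_event <- function(time_h = 50, peptide = "CONST") {
  data.frame(time_h = time_h, peptide = peptide, concentration_nM = 1e9)
}

# treated zero-noise trace carrying one constant-shift event
const_shift_trace <- function(shift_h, params = clean_params(), time_h = 50) {
  simulate_trace(params, const_shift_response(shift_h),
                 saturating_event(time_h), sample_id = "fixture")
}

expect_quiet_warnings <- function(expr) {
  suppressWarnings(expr)
}
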