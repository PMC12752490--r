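# shared fixtures built in code

# noiseless instrument: lag and delay still applied
quiet_instrument <- function(sample_rate = 200, transport_delay = 0.43) {
  instrument_model(sample_rate = sample_rate,
                   transport_delay = transport_delay,
                   flow_noise_sd = 0, gas_noise_sd = 0)
}

# small flat-top flow pulse train for detection tests
pulse_train <- function(n_pulses = 3, peak = 2, width = 1, gap = 2,
                        fs = 200) {
  dt <- 1 / fs
  lobe <- peak * sin(pi * seq(0, width, by = dt) / width)
  pause <- rep(0, round(gap * fs))
  fl <- pause
  for (k in seq_len(n_pulses)) fl <- c(fl, lobe, pause)
  flow_trace((seq_along(fl) - 1L) * dt, fl, fs)
}

fit_quietly <- function(trials, spec = timecourse_spec()) {
  suppressWarnings(fit_timecourse(trials, spec))
}

curve_quietly <- function(fit, ...) {
  suppressWarnings(population_curve(fit, ...))
}
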