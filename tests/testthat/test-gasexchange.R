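test_that("flow calibration recovers the inverse of a gain error", {
  tr <- simulate_calibration(7.0, speeds = c(2, 4, 6))
  cal1 <- calibrate_flow(tr)
  expect_equal(cal1$gain, 1.0, tolerance = 1e-4)
  expect_lt(cal1$relative_error, 1e-3)
  expect_equal(cal1$recovered_volumes, rep(7.0, 6), tolerance = 1e-3)

  halved <- flow_trace(tr$time, tr$flow * 0.5, tr$sample_rate)
  cal2 <- calibrate_flow(halved)
  expect_equal(cal2$gain, 2.0, tolerance = 1e-4)

  flat <- flow_trace(tr$time, rep(0, length(tr$time)), tr$sample_rate)
  expect_error(calibrate_flow(flat), "threshold")
})

test_that("breath detection segments expiratory lobes with hysteresis", {
  cfg <- sim_config(instrument = quiet_instrument(transport_delay = 0))
  sim <- simulate_breath_train(0.73, 0.81, duration = 5, cfg, seed = 2)
  w <- detect_breaths(sim$flow)
  expect_equal(nrow(w), 14L)            # matches generator ground truth
  expect_true(all(w$i_end[-nrow(w)] < w$i_start[-1]))  # non-overlapping

  fs <- 200
  zero <- flow_trace(seq(0, 5, by = 1 / fs),
                     rep(0, 5 * fs + 1), fs)
  expect_equal(nrow(detect_breaths(zero)), 0L)

  # a sub-threshold dip shorter than min_gap does not split the breath
  dt <- 1 / fs
  lobe <- 3 * sin(pi * seq(0, 1, by = dt))
  fl <- c(rep(0, 200), lobe, rep(0.01, round(0.1 * fs)), lobe, rep(0, 200))
  one <- detect_breaths(flow_trace((seq_along(fl) - 1) * dt, fl, fs))
  expect_equal(nrow(one), 1L)
  # ... while a dip longer than min_gap does
  fl2 <- c(rep(0, 200), lobe, rep(0, round(0.5 * fs)), lobe, rep(0, 200))
  two <- detect_breaths(flow_trace((seq_along(fl2) - 1) * dt, fl2, fs))
  expect_equal(nrow(two), 2L)
})

test_that("gas alignment removes the configured or estimated transport delay", {
  cfg <- sim_config(instrument = quiet_instrument(transport_delay = 0.5))
  rec <- simulate_trial_recording(0.73, 0.81, 3, cfg, noise = FALSE,
                                  seed = 2)
  al <- align_gas(rec$flow, rec$gas, method = "xcorr")
  expect_equal(attr(al, "estimated_delay"), 0.5,
               tolerance = 0.1)   # within the analyzer-lag-induced skew

  # fixed mode is an exact configured shift
  al2 <- align_gas(rec$flow, rec$gas, method = "fixed", delay = 0.43)
  expect_equal(attr(al2, "applied_delay"), 0.43)

  # zero delay is the identity
  cfg0 <- sim_config(instrument = quiet_instrument(transport_delay = 0))
  rec0 <- simulate_trial_recording(0.73, 0.81, 2, cfg0, noise = FALSE,
                                   seed = 2)
  al0 <- align_gas(rec0$flow, rec0$gas, method = "fixed")
  expect_equal(al0$fo2, rec0$gas$fo2)

  expect_error(align_gas(rec$flow, rec$gas, method = "xcorr",
                         max_lag = 0.2), "max_lag")
})

test_that("response-time correction inverts the analyzer lag", {
  fs <- 200
  t <- seq(0, 8, by = 1 / fs)
  n <- length(t)
  f <- flow_trace(t, rep(0, n), fs)
  m <- instrument_model(sample_rate = fs, transport_delay = 0,
                        flow_noise_sd = 0, gas_noise_sd = 0)
  tau <- 0.067 / log(10)

  # blurred step: plateau recovered to < 1% of the step
  step <- 0.15 + 0.05 * (t >= 2)
  deg <- apply_instrument(f, gas_trace(t, step, rep(0.01, n), fs), m,
                          seed = 1)
  pure <- correct_response_time(deg$gas, lowpass_cutoff = NULL)
  pl <- t > 2 + 3 * tau & t < 4
  expect_lt(max(abs(pure$fo2[pl] - 0.20)) / 0.05, 0.01)
  filt <- correct_response_time(deg$gas)       # with the default low-pass
  pl2 <- t > 2.3 & t < 4
  expect_lt(max(abs(filt$fo2[pl2] - 0.20)) / 0.05, 0.01)

  # constant signal is unchanged
  const <- gas_trace(t, rep(0.17, n), rep(0.01, n), fs)
  cc <- correct_response_time(const, lowpass_cutoff = NULL)
  expect_equal(cc$fo2, rep(0.17, n), tolerance = 1e-12)

  # 5 Hz sinusoid amplitude recovered within 2% at 200 Hz sampling
  sine <- 0.17 + 0.01 * sin(2 * pi * 5 * t)
  degS <- apply_instrument(f, gas_trace(t, sine, rep(0.01, n), fs), m,
                           seed = 1)
  corS <- correct_response_time(degS$gas)
  mid <- t > 1 & t < 7
  amp <- sqrt(2) * sd(corS$fo2[mid])
  expect_equal(amp, 0.01, tolerance = 0.02)

  # under-resolved time constant rejected
  slow <- gas_trace(t, sine, rep(0.01, n), fs, t90_o2 = 0.01)
  expect_error(correct_response_time(slow), "under-resolved")
})

test_that("STPD factor matches the closed form and is monotone", {
  dry0 <- ambient_conditions(air_temp = 0, rh = 0)
  expect_equal(stpd_factor(dry0), 1.0, tolerance = 1e-12)

  # exhaled air saturated at 37 C, 760 mmHg
  expect_equal(stpd_factor(ambient_conditions(), gas_temp = 37,
                           saturated = TRUE), 0.826, tolerance = 1e-3)

  # mean ambient conditions of the emulated study, closed form
  amb <- ambient_conditions(air_temp = 21.6, rh = 55)
  p_h2o <- 0.55 * 6.1121 *
    exp((18.678 - 21.6 / 234.5) * (21.6 / (257.14 + 21.6))) * 0.750061683
  expect_equal(stpd_factor(amb),
               (760 - p_h2o) / 760 * 273.15 / (273.15 + 21.6),
               tolerance = 1e-10)

  # < 1 when warm or humid; decreasing in temperature and humidity
  expect_lt(stpd_factor(ambient_conditions(air_temp = 10, rh = 0)), 1)
  expect_lt(stpd_factor(ambient_conditions(air_temp = 0, rh = 50)), 1)
  f_t <- vapply(c(0, 10, 20, 30), function(tc)
    stpd_factor(ambient_conditions(air_temp = tc, rh = 40)), numeric(1))
  expect_true(all(diff(f_t) < 0))
  f_rh <- vapply(c(0, 30, 60, 90), function(r)
    stpd_factor(ambient_conditions(air_temp = 25, rh = r)), numeric(1))
  expect_true(all(diff(f_rh) < 0))

  expect_error(stpd_factor(ambient_conditions(barometric_pressure = 30),
                           gas_temp = 37, saturated = TRUE), "pressure")
})

test_that("per-breath integration recovers known exchange and tidal volume", {
  fs <- 200
  dt <- 1 / fs
  # half-sine of peak 2 l/s over 2 s integrates to 2AT/pi = 2.546 l
  lobe <- 2 * sin(pi * seq(0, 2, by = dt) / 2)
  fl <- c(rep(0, 100), lobe, rep(0, 100))
  tt <- (seq_along(fl) - 1) * dt
  ftr <- flow_trace(tt, fl, fs)
  amb_gas <- gas_trace(tt, rep(0.2095, length(fl)),
                       rep(0.0004, length(fl)), fs)
  w <- detect_breaths(ftr)
  b <- breath_exchange(w[1, ], ftr, amb_gas)
  expect_equal(b$vt_exp, 2 * 2 * 2 / pi, tolerance = 1e-3)
  # gas at ambient throughout: zero exchange
  expect_equal(b$vo2_breath, 0, tolerance = 1e-9)
  expect_equal(b$vco2_breath, 0, tolerance = 1e-9)

  # synthetic breath with known O2 deficit matches generator truth
  cfg <- sim_config(instrument = quiet_instrument(transport_delay = 0))
  sim <- simulate_breath_train(0.73, 0.81, 5, cfg, seed = 4)
  wins <- detect_breaths(sim$flow)
  b1 <- breath_exchange(wins[1, ], sim$flow, sim$gas)
  expect_equal(b1$vo2_breath, sim$truth$vo2_breath[1], tolerance = 0.005)
})

test_that("trial summary divides summed breath volumes by duration", {
  cfg <- sim_config(instrument = quiet_instrument(transport_delay = 0))
  sim <- simulate_breath_train(0.73, 0.81, 5, cfg, seed = 4)
  wins <- detect_breaths(sim$flow)
  breaths <- lapply(seq_len(nrow(wins)), function(k)
    breath_exchange(wins[k, ], sim$flow, sim$gas))
  tm <- summarize_trial(breaths, duration = 5)
  expect_equal(tm$vo2_rate, 0.73, tolerance = 0.005)
  expect_equal(tm$breath_rate, 14 / 5)      # 2.8 / min
  expect_equal(tm$rer, 0.81, tolerance = 0.005)

  # conservation: sum of breaths equals integral over the expiratory union
  inst <- sum(vapply(seq_len(nrow(wins)), function(k) {
    idx <- wins$i_start[k]:wins$i_end[k]
    pracma::trapz(sim$flow$time[idx],
                  pmax(sim$flow$flow[idx], 0) * (0.2095 - sim$gas$fo2[idx]))
  }, numeric(1)))
  expect_equal(sum(vapply(breaths, `[[`, numeric(1), "vo2_breath")), inst,
               tolerance = 1e-6)

  expect_error(summarize_trial(breaths, duration = 0), "duration")
  # zero CO2 everywhere: RER 0 with a physiological-range warning
  zero_gas <- gas_trace(sim$gas$time, sim$gas$fo2,
                        rep(0.0004, length(sim$gas$time)),
                        sim$gas$sample_rate)
  b0 <- lapply(seq_len(nrow(wins)), function(k)
    breath_exchange(wins[k, ], sim$flow, zero_gas))
  expect_warning(tm0 <- summarize_trial(b0, duration = 5), "RER")
  expect_equal(tm0$rer, 0, tolerance = 1e-9)
  # all-invalid breaths rejected
  dead <- list(list(vo2_breath = 0, vco2_breath = 0, vt_exp = 0,
                    valid = FALSE))
  expect_error(summarize_trial(dead, duration = 5), "valid")
})

test_that("processing applies the expired-gas STPD factor", {
  cfg <- sim_config(instrument = quiet_instrument())
  rec <- simulate_trial_recording(0.73, 0.81, 3, cfg, noise = FALSE,
                                  seed = 5)
  amb <- ambient_conditions()
  tm_std <- process_trial(rec$flow, rec$gas, duration = 3)
  tm_amb <- process_trial(rec$flow, rec$gas, duration = 3, conditions = amb)
  expect_equal(tm_amb$vo2_rate / tm_std$vo2_rate,
               stpd_factor(amb, gas_temp = 37, saturated = TRUE),
               tolerance = 1e-9)
})
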