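#' Flow calibration result
#'
#' @param gain multiplicative gain mapping raw to calibrated flow (> 0).
#' @param recovered_volumes per-stroke volumes (l) after applying the gain.
#' @param known_volume the syringe volume the strokes were checked against.
#' @return An object of class `calibration_result` with the gain, per-stroke
#'   recovered volumes and the mean relative error.
#' @export
calibration_result <- function(gain, recovered_volumes, known_volume) {
  if (gain <= 0) stop("gain must be > 0")
  structure(
    list(gain = gain, recovered_volumes = recovered_volumes,
         known_volume = known_volume,
         relative_error = mean(abs(recovered_volumes - known_volume)) /
           known_volume),
    class = "calibration_result"
  )
}

#' @export
print.calibration_result <- function(x, ...) {
  cat(sprintf(
    "<calibration_result> gain %.4f from %d strokes, mean |error| %.2f%%\n",
    x$gain, length(x$recovered_volumes), 100 * x$relative_error))
  invisible(x)
}

# find contiguous index runs where `above` is TRUE, merging gaps shorter than
# min_gap_samples, and expand each run outwards to the nearest sign change
find_lobes <- function(x, above, min_gap_samples) {
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- cbind(starts[r$values], ends[r$values])
  if (nrow(runs) == 0L) return(runs)
  # merge runs separated by short sub-threshold dips (hysteresis)
  merged <- runs[1, , drop = FALSE]
  if (nrow(runs) > 1L) {
    for (k in 2:nrow(runs)) {
      if (runs[k, 1] - merged[nrow(merged), 2] - 1L < min_gap_samples)
        merged[nrow(merged), 2] <- runs[k, 2]
      else merged <- rbind(merged, runs[k, ])
    }
  }
  # expand to enclosing zero crossings of x
  n <- length(x)
  for (k in seq_len(nrow(merged))) {
    i <- merged[k, 1]
    while (i > 1L && x[i - 1L] > 0) i <- i - 1L
    j <- merged[k, 2]
    while (j < n && x[j + 1L] > 0) j <- j + 1L
    merged[k, ] <- c(i, j)
  }
  merged[!duplicated(merged[, 1]), , drop = FALSE]
}

#' Calibrate a flow trace against a known syringe volume
#'
#' Detects pump strokes in a calibration recording, integrates each stroke,
#' and chooses the multiplicative gain that makes the mean absolute recovered
#' stroke volume equal the known syringe volume.
#'
#' @param raw a [flow_trace()] containing at least one complete stroke.
#' @param known_volume syringe volume in litres (default 7.0).
#' @param threshold_frac stroke-detection threshold as a fraction of the
#'   maximum absolute flow (default 0.02).
#' @param min_gap minimum sub-threshold gap (s) separating distinct strokes.
#' @param smooth_cutoff low-pass cutoff (Hz) for the detection copy (stroke
#'   windows are found on a smoothed signal so sensor noise cannot bridge or
#'   split strokes; integration still uses the raw samples); `NULL` disables.
#' @return A [calibration_result()].
#' @export
calibrate_flow <- function(raw, known_volume = 7.0, threshold_frac = 0.02,
                           min_gap = 0.3, smooth_cutoff = 10) {
  if (known_volume <= 0) stop("known_volume must be > 0")
  x <- raw$flow
  fs <- raw$sample_rate
  if (!is.null(smooth_cutoff) && smooth_cutoff < fs / 2) {
    bf <- signal::butter(2, smooth_cutoff / (fs / 2))
    x <- signal::filtfilt(bf, x)
  }
  h <- threshold_frac * max(abs(x))
  if (h == 0)
    stop(sprintf(
      "no strokes detected: trace is flat below the %g x max-flow threshold",
      threshold_frac))
  gap <- round(min_gap * fs)
  pos <- find_lobes(x, x > h, gap)
  neg <- find_lobes(-x, -x > h, gap)
  lobes <- rbind(pos, neg)
  if (nrow(lobes) == 0L)
    stop(sprintf(
      "no strokes detected above the %g x max-flow threshold", threshold_frac))
  vols <- apply(lobes, 1, function(w) {
    idx <- w[1]:w[2]
    abs(pracma::trapz(raw$time[idx], raw$flow[idx]))
  })
  gain <- known_volume / mean(vols)
  calibration_result(gain, gain * vols, known_volume)
}

#' Apply a calibration gain to a flow trace
#'
#' @param flow a [flow_trace()].
#' @param calibration a [calibration_result()].
#' @return The calibrated [flow_trace()].
#' @export
apply_calibration <- function(flow, calibration) {
  flow_trace(flow$time, flow$flow * calibration$gain, flow$sample_rate,
             calibration)
}

#' Detect breaths in a flow trace
#'
#' Segments the expiration-positive flow signal into expiratory lobes using a
#' threshold with hysteresis: an expiration starts when (smoothed) flow rises
#' above the threshold and ends once it stays below it for at least `min_gap`
#' seconds; sub-threshold dips shorter than `min_gap` do not split a breath.
#' Detection runs on a low-pass-smoothed copy of the signal so that sensor
#' noise cannot seed spurious lobes; window boundaries are then expanded to
#' the enclosing zero crossings of the smoothed signal. Windows are half-open
#' `[t_start, t_end)` on the sample grid and never overlap.
#'
#' @param flow a (calibrated) [flow_trace()].
#' @param threshold_frac detection threshold as a fraction of the maximum
#'   smoothed flow (default 0.02).
#' @param min_gap hysteresis gap, seconds (default 0.3).
#' @param min_duration minimum expiratory duration (s) for a window to count
#'   as a breath (default 0.2).
#' @param smooth_cutoff low-pass cutoff (Hz) for the detection copy; `NULL`
#'   disables smoothing.
#' @return A data frame with one row per breath: `i_start`, `i_end` (sample
#'   indices), `t_start`, `t_end` (s). Zero rows for an all-zero trace.
#' @export
detect_breaths <- function(flow, threshold_frac = 0.02, min_gap = 0.3,
                           min_duration = 0.2, smooth_cutoff = 10) {
  x <- flow$flow
  fs <- flow$sample_rate
  if (!is.null(smooth_cutoff) && smooth_cutoff < fs / 2) {
    bf <- signal::butter(2, smooth_cutoff / (fs / 2))
    x <- signal::filtfilt(bf, x)
  }
  h <- threshold_frac * max(x, 0)
  empty <- data.frame(i_start = integer(0), i_end = integer(0),
                      t_start = numeric(0), t_end = numeric(0))
  if (h <= 0) return(empty)
  lobes <- find_lobes(x, x > h, round(min_gap * fs))
  if (nrow(lobes) == 0L) return(empty)
  keep <- (lobes[, 2] - lobes[, 1]) / fs >= min_duration
  lobes <- lobes[keep, , drop = FALSE]
  data.frame(i_start = lobes[, 1], i_end = lobes[, 2],
             t_start = flow$time[lobes[, 1]], t_end = flow$time[lobes[, 2]])
}

#' Phase-align the gas trace to the flow trace
#'
#' Removes the gas transport delay so that expired-gas deflections line up
#' with the expiratory flow that produced them. The default uses the
#' configured (metadata) transport delay, which matches a fixed tubing
#' geometry; alternatively the delay can be estimated by cross-correlating the
#' CO2 excursion with positive flow.
#'
#' @param flow a [flow_trace()].
#' @param gas a [gas_trace()] on the same time base.
#' @param method `"fixed"` (use `gas$transport_delay` or `delay`) or
#'   `"xcorr"` (estimate by cross-correlation).
#' @param delay delay (s) to remove in fixed mode; defaults to the trace
#'   metadata.
#' @param max_lag largest admissible delay (s) in xcorr mode; an estimate at
#'   or beyond this bound raises an error (it usually means the channels are
#'   mispaired).
#' @return The aligned [gas_trace()] (delay metadata set to 0), with
#'   attributes `applied_delay` and, in xcorr mode, `estimated_delay`.
#' @export
align_gas <- function(flow, gas, method = c("fixed", "xcorr"), delay = NULL,
                      max_lag = 2) {
  check_shared_grid(flow, gas)
  method <- match.arg(method)
  fs <- gas$sample_rate
  if (method == "fixed") {
    d <- if (is.null(delay)) gas$transport_delay else delay
  } else {
    lag_max <- round(max_lag * fs)
    a <- pmax(flow$flow, 0)
    b <- gas$fco2 - stats::median(gas$fco2)
    cc <- stats::ccf(b, a, lag.max = lag_max, plot = FALSE)
    pos <- cc$lag >= 0
    d <- cc$lag[pos][which.max(cc$acf[pos])] / fs
    if (d >= max_lag)
      stop("estimated transport delay hits the max_lag bound; ",
           "check channel pairing")
  }
  k <- d * fs
  shift_frac <- function(x, k) {
    # advance x by k samples (k >= 0), linear interpolation, edge-padded
    n <- length(x)
    idx <- seq_len(n) + k
    out <- stats::approx(seq_len(n), x, xout = pmin(idx, n), rule = 2)$y
    out
  }
  out <- gas_trace(gas$time, shift_frac(gas$fo2, k), shift_frac(gas$fco2, k),
                   fs, t90_o2 = gas$t90_o2, t90_co2 = gas$t90_co2,
                   transport_delay = 0)
  attr(out, "applied_delay") <- d
  if (method == "xcorr") attr(out, "estimated_delay") <- d
  out
}

#' Correct gas channels for analyzer response time
#'
#' Inverts the first-order analyzer lag by the continuous-time inverse filter
#' `x(t) = y(t) + tau * dy/dt` with `tau = t90 / ln(10)` per channel
#' (central-difference derivative), then applies a 4th-order Butterworth
#' low-pass (zero-phase, default 10 Hz) to bound the noise amplification that
#' pure inversion would otherwise make unbounded.
#'
#' @param gas a [gas_trace()] with t90 metadata.
#' @param lowpass_cutoff post-inversion low-pass cutoff in Hz; `NULL` or a
#'   value at/above Nyquist disables it.
#' @return The corrected [gas_trace()] (t90 metadata set to a near-zero
#'   sentinel, 1e-9, marking the channels as corrected).
#' @export
correct_response_time <- function(gas, lowpass_cutoff = 10) {
  fs <- gas$sample_rate
  dt <- 1 / fs
  invert <- function(y, t90) {
    tau <- t90 / log(10)
    if (tau <= 0) stop("t90 must be > 0")
    if (tau < 2 * dt)
      stop(sprintf(
        "time constant %.4g s under-resolved at %g Hz (needs >= 2 samples)",
        tau, fs))
    n <- length(y)
    dydt <- c(y[2] - y[1],
              (y[3:n] - y[1:(n - 2)]) / 2,
              y[n] - y[n - 1]) / dt
    x <- y + tau * dydt
    if (!is.null(lowpass_cutoff) && lowpass_cutoff < fs / 2) {
      bf <- signal::butter(4, lowpass_cutoff / (fs / 2))
      x <- signal::filtfilt(bf, x)
    }
    x
  }
  fo2 <- pmin(pmax(invert(gas$fo2, gas$t90_o2), 0), 1)
  fco2 <- pmin(pmax(invert(gas$fco2, gas$t90_co2), 0), 1)
  gas_trace(gas$time, fo2, fco2, fs, t90_o2 = 1e-9, t90_co2 = 1e-9,
            transport_delay = gas$transport_delay)
}

#' Ambient conditions for respirometry corrections
#'
#' @param air_temp air temperature, degrees C.
#' @param rh relative humidity, percent (0-100).
#' @param barometric_pressure barometric pressure, mmHg.
#' @param water_temp pool water temperature, degrees C.
#' @return An object of class `ambient_conditions`.
#' @export
ambient_conditions <- function(air_temp = 21.6, rh = 55,
                               barometric_pressure = 760,
                               water_temp = 22.7) {
  if (rh < 0 || rh > 100) stop("rh must lie in [0, 100]")
  if (barometric_pressure <= 0) stop("barometric_pressure must be > 0")
  structure(list(air_temp = air_temp, rh = rh,
                 barometric_pressure = barometric_pressure,
                 water_temp = water_temp),
            class = "ambient_conditions")
}

# saturation water-vapour pressure (mmHg) over water, Arden Buck formula
saturation_pressure_mmHg <- function(temp_c) {
  hpa <- 6.1121 * exp((18.678 - temp_c / 234.5) *
                        (temp_c / (257.14 + temp_c)))
  hpa * 0.750061683
}

#' STPD conversion factor
#'
#' Factor converting a gas volume measured at ambient (or body) temperature,
#' pressure and humidity to standard temperature and pressure, dry:
#' `((P_b - P_H2O) / 760) * (273.15 / (273.15 + T))`, with the water-vapour
#' pressure `P_H2O` equal to the relative-humidity-scaled saturation pressure
#' at the gas temperature (Arden Buck saturation formula). Exhaled air is
#' treated as saturated at 37 degrees C.
#'
#' @param conditions an [ambient_conditions()] supplying pressure and, when
#'   `saturated = FALSE`, the ambient humidity.
#' @param gas_temp gas temperature in degrees C; defaults to the ambient air
#'   temperature, or 37 for saturated exhaled gas.
#' @param saturated logical; `TRUE` treats the gas as fully saturated (RH
#'   100%), as for exhaled air.
#' @return The dimensionless STPD factor.
#' @export
#' @examples
#' cond <- ambient_conditions(air_temp = 0, rh = 0)
#' stpd_factor(cond)                          # 1: already at STPD
#' stpd_factor(ambient_conditions(), gas_temp = 37, saturated = TRUE)
stpd_factor <- function(conditions = ambient_conditions(), gas_temp = NULL,
                        saturated = FALSE) {
  if (is.null(gas_temp))
    gas_temp <- if (saturated) 37 else conditions$air_temp
  rh <- if (saturated) 100 else conditions$rh
  p_h2o <- rh / 100 * saturation_pressure_mmHg(gas_temp)
  pb <- conditions$barometric_pressure
  if (pb <= p_h2o)
    stop("barometric pressure must exceed the water-vapour pressure")
  if (gas_temp <= -273.15) stop("gas temperature below absolute zero")
  ((pb - p_h2o) / 760) * (273.15 / (273.15 + gas_temp))
}

#' Per-breath gas exchange
#'
#' Integrates the instantaneous oxygen uptake
#' `v'O2(t) = flow(t) * (F_I,O2 - F_E,O2(t))` and carbon-dioxide output
#' `v'CO2(t) = flow(t) * (F_E,CO2(t) - F_I,CO2)` over one expiratory window
#' (trapezoidal rule), along with the expired tidal volume. Expired volumes
#' are converted to STPD assuming the exhaled gas is saturated at 37 degrees
#' C; with `conditions = NULL` no STPD correction is applied (factor 1),
#' appropriate for signals that are already standardized, e.g. synthetic
#' traces.
#'
#' @param window one row of [detect_breaths()] output (list or 1-row data
#'   frame with `i_start`, `i_end`).
#' @param flow a calibrated [flow_trace()].
#' @param gas the aligned, response-corrected [gas_trace()].
#' @param conditions an [ambient_conditions()] or `NULL`.
#' @param fi_o2,fi_co2 inspired dry fractions (ambient air defaults).
#' @return A list of class `breath`: `t_start`, `t_end`, `vt_exp_atps`,
#'   `vt_exp` (STPD), `vo2_breath`, `vco2_breath` (l STPD), `valid`.
#' @export
breath_exchange <- function(window, flow, gas, conditions = NULL,
                            fi_o2 = 0.2095, fi_co2 = 0.0004) {
  check_shared_grid(flow, gas)
  idx <- window$i_start:window$i_end
  tt <- flow$time[idx]
  fl <- flow$flow[idx]
  pos <- pmax(fl, 0)
  vt_atps <- pracma::trapz(tt, pos)
  factor <- if (is.null(conditions)) 1 else
    stpd_factor(conditions, gas_temp = 37, saturated = TRUE)
  valid <- vt_atps > 0
  vo2 <- factor * pracma::trapz(tt, pos * (fi_o2 - gas$fo2[idx]))
  vco2 <- factor * pracma::trapz(tt, pos * (gas$fco2[idx] - fi_co2))
  structure(
    list(t_start = tt[1], t_end = tt[length(tt)],
         vt_exp_atps = vt_atps, vt_exp = factor * vt_atps,
         vo2_breath = vo2, vco2_breath = vco2, valid = valid),
    class = "breath"
  )
}

#' Summarize a trial from its breaths
#'
#' Sums per-breath O2/CO2 volumes over the valid breaths of a measurement and
#' divides by the trial duration, yielding the trial-level gas-exchange rates;
#' also reports breathing frequency, mean expired tidal volume and the
#' respiratory exchange ratio. Invalid breaths are excluded from every
#' summary, including the breathing-frequency numerator.
#'
#' @param breaths list of [breath_exchange()] results.
#' @param duration trial duration, minutes (> 0).
#' @param animal_id,day,time_since_feeding trial metadata; `time_since_feeding`
#'   of 0 denotes the fasted measurement.
#' @param conditions optional [ambient_conditions()], carried through.
#' @return An object of class `trial_measurement` with `vo2_rate`,
#'   `vco2_rate` (l min^-1 STPD), `rer`, `breath_rate` (min^-1), `vt_mean`
#'   (l), `n_breaths`, `n_invalid` and the metadata.
#' @export
summarize_trial <- function(breaths, duration, animal_id = NA, day = NA,
                            time_since_feeding = NA, conditions = NULL) {
  if (duration <= 0) stop("duration must be > 0")
  valid <- vapply(breaths, function(b) isTRUE(b$valid), logical(1))
  if (!any(valid)) stop("no valid breaths in trial")
  vo2 <- sum(vapply(breaths[valid], `[[`, numeric(1), "vo2_breath"))
  vco2 <- sum(vapply(breaths[valid], `[[`, numeric(1), "vco2_breath"))
  vo2_rate <- vo2 / duration
  vco2_rate <- vco2 / duration
  rer <- vco2_rate / vo2_rate
  if (is.finite(rer) && (rer < 0.7 || rer > 1.0))
    warning(sprintf("RER %.2f outside the physiological range [0.7, 1.0]",
                    rer))
  structure(
    list(animal_id = animal_id, day = day,
         time_since_feeding = time_since_feeding, duration = duration,
         vo2_rate = vo2_rate, vco2_rate = vco2_rate, rer = rer,
         breath_rate = sum(valid) / duration,
         vt_mean = mean(vapply(breaths[valid], `[[`, numeric(1), "vt_exp")),
         n_breaths = sum(valid), n_invalid = sum(!valid),
         conditions = conditions),
    class = "trial_measurement"
  )
}

#' @export
print.trial_measurement <- function(x, ...) {
  label <- if (is.null(x$animal_id) || is.na(x$animal_id)) "" else
    sprintf("%s t=%s min: ", x$animal_id, format(x$time_since_feeding))
  cat(sprintf(
    paste0("<trial_measurement> %sV'O2 %.3f, V'CO2 %.3f l/min, ",
           "RER %.2f, %d breaths (%.1f/min), VT %.2f l\n"),
    label, x$vo2_rate, x$vco2_rate,
    x$rer, x$n_breaths, x$breath_rate, x$vt_mean))
  invisible(x)
}

#' Process a raw measurement end to end
#'
#' Runs the full per-trial chain: optional flow calibration gain, gas/flow
#' phase alignment, analyzer response-time deconvolution, breath detection,
#' per-breath integration and trial summary.
#'
#' @param flow a [flow_trace()].
#' @param gas the matching [gas_trace()].
#' @param duration trial duration in minutes; defaults to the trace length.
#' @param conditions optional [ambient_conditions()] for STPD correction.
#' @param calibration optional [calibration_result()] applied to the flow.
#' @param align_method passed to [align_gas()].
#' @param deconvolve logical; run [correct_response_time()].
#' @param fi_o2,fi_co2 inspired fractions.
#' @param ... detection tuning passed to [detect_breaths()].
#' @inheritParams summarize_trial
#' @return A [summarize_trial()] result with attribute `breaths`.
#' @export
process_trial <- function(flow, gas, duration = NULL, conditions = NULL,
                          calibration = NULL, align_method = "fixed",
                          deconvolve = TRUE, fi_o2 = 0.2095,
                          fi_co2 = 0.0004, animal_id = NA, day = NA,
                          time_since_feeding = NA, ...) {
  if (is.null(duration))
    duration <- diff(range(flow$time)) / 60
  if (!is.null(calibration)) flow <- apply_calibration(flow, calibration)
  gas <- align_gas(flow, gas, method = align_method)
  if (deconvolve && gas$t90_o2 > 1e-8) gas <- correct_response_time(gas)
  wins <- detect_breaths(flow, ...)
  if (nrow(wins) == 0L) stop("no breaths detected in trial")
  breaths <- lapply(seq_len(nrow(wins)), function(k)
    breath_exchange(wins[k, ], flow, gas, conditions,
                    fi_o2 = fi_o2, fi_co2 = fi_co2))
  out <- summarize_trial(breaths, duration, animal_id = animal_id, day = day,
                         time_since_feeding = time_since_feeding,
                         conditions = conditions)
  attr(out, "breaths") <- breaths
  out
}
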