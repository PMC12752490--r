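#' Instrument model for synthetic traces
#'
#' Describes the degradation applied to ideal signals: first-order analyzer
#' lag (one time constant per gas channel, parameterized by the 90%-response
#' time t90), a transport delay through the gas sampling line, and additive
#' Gaussian noise on the flow and gas channels.
#'
#' @param sample_rate sampling rate in Hz. The default 200 Hz keeps simulated
#'   traces small; the acquisition hardware being emulated samples at 2000 Hz
#'   and that rate is fully supported.
#' @param t90_o2,t90_co2 90% response times (s); defaults 0.067 and 0.094.
#' @param transport_delay gas transport delay (s); default 0.43.
#' @param flow_noise_sd additive flow noise SD (l s^-1).
#' @param gas_noise_sd additive gas-fraction noise SD (dimensionless).
#'
#' @return An object of class `instrument_model`.
#' @export
instrument_model <- function(sample_rate = 200,
                             t90_o2 = 0.067, t90_co2 = 0.094,
                             transport_delay = 0.43,
                             flow_noise_sd = 0.05,
                             gas_noise_sd = 5e-4) {
  if (sample_rate <= 0) stop("sample_rate must be > 0")
  if (t90_o2 <= 0 || t90_co2 <= 0) stop("t90 values must be > 0")
  if (transport_delay < 0) stop("transport_delay must be >= 0")
  if (flow_noise_sd < 0 || gas_noise_sd < 0) stop("noise SDs must be >= 0")
  structure(
    list(sample_rate = sample_rate, t90_o2 = t90_o2, t90_co2 = t90_co2,
         transport_delay = transport_delay, flow_noise_sd = flow_noise_sd,
         gas_noise_sd = gas_noise_sd),
    class = "instrument_model"
  )
}

#' Simulation configuration
#'
#' Defines the study conditions for the synthetic-data generator. The defaults
#' emulate the measured bottlenose-dolphin study design: fasted oxygen
#' consumption around 0.73 l O2 min^-1, a postprandial rise peaking ~36% above
#' baseline at 60 min and returning to baseline by 170 min, tidal volumes
#' around 3.7 l at 2.8 breaths min^-1, between-animal and between-day random
#' intercept SDs of 0.13 and 0.087 l O2 min^-1, and a residual SD of
#' 0.20 l O2 min^-1.
#'
#' @param n_animals number of animals (default 8).
#' @param trials_per_animal feeding trials (days) per animal (default 6, so the
#'   total number of fasted measurements is close to the 49 of the emulated
#'   study).
#' @param timepoints minutes since feeding at which metabolic rate is measured;
#'   must be sorted ascending and start at 0 (the fasted measurement).
#' @param baseline_vo2 fasted oxygen consumption rate, l O2 min^-1.
#' @param peak_fraction fractional rise above baseline at the peak.
#' @param peak_time,return_time minutes since feeding of the peak and of the
#'   return to baseline; `peak_time < return_time`.
#' @param animal_sd,day_sd,residual_sd random-intercept and residual SDs,
#'   l O2 min^-1.
#' @param tidal_volume_mean,tidal_volume_sd per-breath expired volume (l).
#' @param breath_rate_mean,breath_rate_sd breathing frequency (min^-1); the SD
#'   acts as log-normal jitter on inter-breath intervals when
#'   `breath_jitter = TRUE`.
#' @param rer_mean respiratory exchange ratio, in \[0.7, 1.0\].
#' @param exp_duration,insp_duration expiration / inspiration durations (s) of
#'   the half-sine breath waveform.
#' @param instrument an [instrument_model()].
#' @param breath_jitter logical; jitter inter-breath intervals.
#' @param shared_curve logical; if `TRUE` all timepoints of a trial share one
#'   realization of the feeding response (one day effect); if `FALSE` each
#'   measurement gets an independent perturbation. Both modes exist because
#'   the emulated protocol does not pin this down; `TRUE` is the default.
#' @param seed master seed; per-animal streams are derived from it so adding
#'   animals does not perturb existing ones.
#'
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_animals = 8,
                       trials_per_animal = 6,
                       timepoints = c(0, 30, 60, 90, 120),
                       baseline_vo2 = 0.73,
                       peak_fraction = 0.36,
                       peak_time = 60,
                       return_time = 170,
                       animal_sd = 0.13,
                       day_sd = 0.087,
                       residual_sd = 0.20,
                       tidal_volume_mean = 3.7,
                       tidal_volume_sd = 1.3,
                       breath_rate_mean = 2.8,
                       breath_rate_sd = 1.3,
                       rer_mean = 0.81,
                       exp_duration = 1.2,
                       insp_duration = 1.6,
                       instrument = instrument_model(),
                       breath_jitter = FALSE,
                       shared_curve = TRUE,
                       seed = 1L) {
  if (n_animals < 0 || trials_per_animal < 0)
    stop("counts must be >= 0")
  if (any(diff(timepoints) <= 0) || timepoints[1] != 0)
    stop("timepoints must be sorted ascending and start at 0")
  if (any(c(animal_sd, day_sd, residual_sd, tidal_volume_sd,
            breath_rate_sd) < 0))
    stop("all SDs must be >= 0")
  if (rer_mean < 0.7 || rer_mean > 1.0)
    stop("rer_mean must lie in [0.7, 1.0]")
  if (peak_time >= return_time) stop("peak_time must be < return_time")
  if (baseline_vo2 <= 0 || tidal_volume_mean <= 0 || breath_rate_mean <= 0)
    stop("baseline_vo2, tidal volume and breath rate must be > 0")
  if (!inherits(instrument, "instrument_model"))
    stop("instrument must be an instrument_model")
  structure(
    list(n_animals = as.integer(n_animals),
         trials_per_animal = as.integer(trials_per_animal),
         timepoints = timepoints, baseline_vo2 = baseline_vo2,
         peak_fraction = peak_fraction, peak_time = peak_time,
         return_time = return_time, animal_sd = animal_sd, day_sd = day_sd,
         residual_sd = residual_sd, tidal_volume_mean = tidal_volume_mean,
         tidal_volume_sd = tidal_volume_sd,
         breath_rate_mean = breath_rate_mean,
         breath_rate_sd = breath_rate_sd, rer_mean = rer_mean,
         exp_duration = exp_duration, insp_duration = insp_duration,
         instrument = instrument, breath_jitter = breath_jitter,
         shared_curve = shared_curve, seed = as.integer(seed)),
    class = "sim_config"
  )
}

#' Postprandial metabolic-rate curve
#'
#' The deterministic time course of oxygen consumption after a meal used as
#' ground truth by the generator: baseline at the moment of feeding, a
#' unimodal rise peaking `peak_fraction` above baseline at `peak_time`, and a
#' return to baseline at `return_time`, after which the curve stays at
#' baseline. The rise and fall are raised-cosine (squared-sine) arcs, so the
#' curve is continuously differentiable with zero slope at t = 0, the peak
#' and the return.
#'
#' @param t minutes since feeding (vectorized); must be >= 0.
#' @param config a [sim_config()] supplying baseline and shape parameters.
#'
#' @return Oxygen consumption rate(s), l O2 min^-1.
#' @export
#' @examples
#' cfg <- sim_config()
#' hif_curve(c(0, 60, 200), cfg)   # baseline, peak, back to baseline
hif_curve <- function(t, config = sim_config()) {
  if (any(t < 0)) stop("time since feeding must be >= 0")
  p <- config$peak_time
  r <- config$return_time
  g <- numeric(length(t))
  up <- t > 0 & t < p
  down <- t >= p & t < r
  g[up] <- sin(pi / 2 * t[up] / p)^2
  g[down] <- cos(pi / 2 * (t[down] - p) / (r - p))^2
  config$baseline_vo2 * (1 + config$peak_fraction * g)
}

# raised-cosine kernel integral over [0, upper] minutes (closed form),
# used for ground-truth AUC of the feeding response
hif_kernel_integral <- function(config, upper) {
  p <- config$peak_time
  r <- config$return_time
  u1 <- min(upper, p)
  # int sin^2(pi/2 t/p) dt = t/2 - (p/(2 pi)) sin(pi t / p)
  i1 <- u1 / 2 - p / (2 * pi) * sin(pi * u1 / p)
  i2 <- 0
  if (upper > p) {
    u2 <- min(upper, r) - p
    w <- r - p
    # int cos^2(pi/2 u/w) du = u/2 + (w/(2 pi)) sin(pi u / w)
    i2 <- u2 / 2 + w / (2 * pi) * sin(pi * u2 / w)
  }
  i1 + i2
}

#' True oxygen volume under the generator curve
#'
#' Closed-form integral of [hif_curve()] from 0 to `upper` minutes, in l O2.
#' Used as the ground-truth area under the curve when checking fitted
#' population curves.
#'
#' @param config a [sim_config()].
#' @param upper upper limit of integration, minutes.
#' @return Volume of O2, litres.
#' @export
hif_true_auc <- function(config, upper = 133) {
  config$baseline_vo2 * upper +
    config$baseline_vo2 * config$peak_fraction *
      hif_kernel_integral(config, upper)
}

#' Simulate a breath train with known gas exchange
#'
#' Generates ideal (pre-instrument) flow and expired gas-fraction traces for
#' one metabolic measurement. Breaths are half-sine inspiratory and expiratory
#' lobes (expiration positive). During each expiration the expired O2 fraction
#' is depressed below, and the CO2 fraction raised above, ambient by constant
#' amounts chosen so that exact trapezoidal integration of the sampled signals
#' reproduces `target_vo2` and `target_rer` to round-off.
#'
#' @param target_vo2 trial-mean oxygen consumption rate, l O2 min^-1 (> 0).
#' @param target_rer respiratory exchange ratio V'CO2/V'O2.
#' @param duration trial duration in minutes (> 0).
#' @param config a [sim_config()].
#' @param fi_o2,fi_co2 inspired (ambient, dry) gas fractions.
#' @param seed seed for tidal-volume and interval jitter; `NULL` uses the
#'   config seed.
#'
#' @return A list with `flow` ([flow_trace()]), `gas` ([gas_trace()]) and
#'   `truth`, a list holding the per-breath expired volumes and O2/CO2 volumes
#'   on the sample grid, the expiratory windows, the constant O2
#'   deficit/CO2 excess, and `trial_vo2`/`trial_vco2` (the exact trial rates
#'   before any instrument degradation).
#' @export
simulate_breath_train <- function(target_vo2, target_rer, duration,
                                  config = sim_config(),
                                  fi_o2 = 0.2095, fi_co2 = 0.0004,
                                  seed = NULL) {
  if (duration <= 0) stop("duration must be > 0")
  if (target_vo2 <= 0) stop("target_vo2 must be > 0")
  if (target_rer < 0) stop("target_rer must be >= 0")
  set.seed(if (is.null(seed)) config$seed else seed)

  fs <- config$instrument$sample_rate
  dt <- 1 / fs
  dur_s <- duration * 60
  n <- floor(dur_s * fs) + 1L
  time <- (seq_len(n) - 1L) * dt

  # breath start times: regular at the mean rate, optional log-normal jitter
  interval <- 60 / config$breath_rate_mean            # s
  # tolerance guards the float boundary (e.g. 300 / (60/2.8) = 14 - eps)
  n_br <- floor(dur_s / interval + 1e-9)
  if (n_br < 1L) stop("duration too short for a single breath")
  starts <- (seq_len(n_br) - 1L) * interval + 0.25 * interval
  if (config$breath_jitter && config$breath_rate_sd > 0) {
    cv <- config$breath_rate_sd / config$breath_rate_mean
    jit <- stats::rlnorm(n_br, -cv^2 / 2, cv) * interval
    starts <- cumsum(jit) - jit[1] + 0.25 * interval
    starts <- starts[starts + config$insp_duration + config$exp_duration <
                       dur_s]
    n_br <- length(starts)
  }

  # per-breath expired volumes (truncated normal, strictly positive)
  vt <- stats::rnorm(n_br, config$tidal_volume_mean, config$tidal_volume_sd)
  vt <- pmax(vt, 0.2 * config$tidal_volume_mean)

  t_in <- config$insp_duration
  t_ex <- config$exp_duration
  flow <- numeric(n)
  exp_win <- matrix(0L, n_br, 2, dimnames = list(NULL, c("i_start", "i_end")))
  vt_grid <- numeric(n_br)
  for (k in seq_len(n_br)) {
    # inspiration (negative lobe), matched volume
    i0 <- floor(starts[k] * fs) + 1L
    i1 <- min(i0 + round(t_in * fs), n)
    idx <- i0:i1
    flow[idx] <- flow[idx] -
      pi * vt[k] / (2 * t_in) * sin(pi * (time[idx] - time[i0]) / t_in)
    # expiration (positive half-sine)
    e0 <- i1 + 1L
    e1 <- min(e0 + round(t_ex * fs), n)
    idx <- e0:e1
    flow[idx] <- flow[idx] +
      pi * vt[k] / (2 * t_ex) * sin(pi * (time[idx] - time[e0]) / t_ex)
    exp_win[k, ] <- c(e0, e1)
    vt_grid[k] <- pracma::trapz(time[idx], flow[idx])
  }

  # constant expired O2 deficit / CO2 excess reproducing the targets exactly
  # under trapezoidal integration of the sampled signals
  d_o2 <- target_vo2 * duration / sum(vt_grid)
  e_co2 <- target_rer * d_o2
  if (d_o2 > fi_o2)
    stop("infeasible gas fractions: required expired O2 below zero")
  if (fi_co2 + e_co2 + (fi_o2 - d_o2) > 1)
    stop("infeasible gas fractions: fo2 + fco2 would exceed 1")

  fo2 <- rep(fi_o2, n)
  fco2 <- rep(fi_co2, n)
  for (k in seq_len(n_br)) {
    idx <- exp_win[k, 1]:exp_win[k, 2]
    fo2[idx] <- fi_o2 - d_o2
    fco2[idx] <- fi_co2 + e_co2
  }

  truth <- list(
    breath_volumes = vt_grid,
    vo2_breath = d_o2 * vt_grid,
    vco2_breath = e_co2 * vt_grid,
    exp_windows = exp_win,
    o2_deficit = d_o2, co2_excess = e_co2,
    trial_vo2 = sum(d_o2 * vt_grid) / duration,
    trial_vco2 = sum(e_co2 * vt_grid) / duration,
    fi_o2 = fi_o2, fi_co2 = fi_co2
  )
  inst <- config$instrument
  list(
    flow = flow_trace(time, flow, fs),
    gas = gas_trace(time, fo2, fco2, fs, t90_o2 = inst$t90_o2,
                    t90_co2 = inst$t90_co2, transport_delay = 0),
    truth = truth
  )
}

# discrete first-order lag, time constant tau (s); y1 initialized at x1
first_order_lag <- function(x, dt, tau) {
  if (tau <= 0) return(x)
  a <- exp(-dt / tau)
  as.numeric(stats::filter(x * (1 - a), a, method = "recursive",
                           init = x[1]))
}

# delay a signal by an integer number of samples, padding with the first value
shift_by_samples <- function(x, k) {
  if (k == 0L) return(x)
  c(rep(x[1], k), x[seq_len(length(x) - k)])
}

#' Apply instrument degradation to ideal traces
#'
#' Passes each gas channel through a first-order lag with time constant
#' `tau = t90 / ln(10)` (so a step reaches 90% of its change at t90), delays
#' the gas channels by the transport delay, and adds Gaussian noise to all
#' channels. Deterministic for a fixed seed.
#'
#' @param flow a [flow_trace()].
#' @param gas a [gas_trace()] on the same time base.
#' @param model an [instrument_model()].
#' @param seed integer seed for the noise.
#' @return A list with degraded `flow` and `gas` traces; the gas trace carries
#'   the lag/delay metadata needed to undo the degradation.
#' @export
apply_instrument <- function(flow, gas, model = instrument_model(),
                             seed = 1L) {
  check_shared_grid(flow, gas)
  dt <- 1 / flow$sample_rate
  tau_o2 <- model$t90_o2 / log(10)
  tau_co2 <- model$t90_co2 / log(10)
  k <- as.integer(round(model$transport_delay * flow$sample_rate))

  fo2 <- shift_by_samples(first_order_lag(gas$fo2, dt, tau_o2), k)
  fco2 <- shift_by_samples(first_order_lag(gas$fco2, dt, tau_co2), k)
  fl <- flow$flow
  set.seed(seed)
  if (model$flow_noise_sd > 0)
    fl <- fl + stats::rnorm(length(fl), 0, model$flow_noise_sd)
  if (model$gas_noise_sd > 0) {
    fo2 <- fo2 + stats::rnorm(length(fo2), 0, model$gas_noise_sd)
    fco2 <- fco2 + stats::rnorm(length(fco2), 0, model$gas_noise_sd)
  }
  fo2 <- pmin(pmax(fo2, 0), 1)
  fco2 <- pmin(pmax(fco2, 0), 1)
  list(
    flow = flow_trace(flow$time, fl, flow$sample_rate, flow$calibration),
    gas = gas_trace(gas$time, fo2, fco2, gas$sample_rate,
                    t90_o2 = model$t90_o2, t90_co2 = model$t90_co2,
                    transport_delay = k / flow$sample_rate)
  )
}

#' Simulate a calibration-syringe recording
#'
#' Emulates the calibration procedure: a known-volume syringe is pumped
#' through the spirometer at a series of flow speeds. Each push/pull stroke is
#' a half-sine whose ground-truth integral is exactly +/- `volume`.
#'
#' @param volume syringe volume in litres (default 7.0).
#' @param speeds vector of peak stroke flows, l s^-1; one push/pull pair is
#'   generated per speed.
#' @param config a [sim_config()]; supplies the sample rate and flow noise.
#' @param noise logical; add the instrument flow noise.
#' @param seed seed for the noise.
#' @return A [flow_trace()] with attribute `stroke_windows` (index matrix) and
#'   `true_volume`.
#' @export
simulate_calibration <- function(volume = 7.0, speeds = c(2, 4, 6),
                                 config = sim_config(), noise = FALSE,
                                 seed = 1L) {
  if (volume <= 0) stop("volume must be > 0")
  if (length(speeds) == 0) stop("at least one stroke speed is required")
  if (any(speeds <= 0)) stop("stroke speeds must be > 0")
  fs <- config$instrument$sample_rate
  dt <- 1 / fs
  pause <- 1.0                        # s of zero flow between strokes
  segs <- list()
  windows <- NULL
  t_cursor <- 0
  n_pause <- round(pause * fs)
  idx_cursor <- 0L
  for (s in speeds) {
    T_str <- pi * volume / (2 * s)    # half-sine of peak s integrating to vol
    n_str <- round(T_str * fs)
    tt <- (seq_len(n_str) - 1L) * dt
    push <- s * sin(pi * tt / T_str)
    for (sgn in c(1, -1)) {
      segs[[length(segs) + 1L]] <- rep(0, n_pause)
      idx_cursor <- idx_cursor + n_pause
      segs[[length(segs) + 1L]] <- sgn * push
      windows <- rbind(windows, c(idx_cursor + 1L, idx_cursor + n_str))
      idx_cursor <- idx_cursor + n_str
    }
  }
  segs[[length(segs) + 1L]] <- rep(0, n_pause)
  fl <- unlist(segs)
  if (noise && config$instrument$flow_noise_sd > 0) {
    set.seed(seed)
    fl <- fl + stats::rnorm(length(fl), 0, config$instrument$flow_noise_sd)
  }
  time <- (seq_along(fl) - 1L) * dt
  out <- flow_trace(time, fl, fs)
  attr(out, "stroke_windows") <- windows
  attr(out, "true_volume") <- volume
  out
}

#' Generate a study-design trial table with known ground truth
#'
#' Produces one row per (animal, trial day, timepoint) with simulated oxygen
#' consumption `vo2 = hif_curve(t) + animal effect + day effect + residual`,
#' plus covariates (body mass, age, sex, meal energy, pool temperature) drawn
#' from ranges mimicking the emulated study population. Per-animal random
#' streams are derived from the master seed, so increasing `n_animals` leaves
#' earlier animals' rows unchanged.
#'
#' @param config a [sim_config()].
#' @return A list with `trials` (data frame: `animal_id`, `day`, `time_min`,
#'   `vo2_l_min`, `intake_kcal`, `meal_fraction`, `age_yr`, `mass_kg`,
#'   `pool_temp_c`, `sex`), `animals` (one row per animal) and `truth`
#'   (per-animal and per-day effects, the noise-free rates, and the config).
#' @export
make_study_dataset <- function(config = sim_config()) {
  if (config$n_animals < 1) stop("config must include at least one animal")
  if (config$trials_per_animal < 1) stop("at least one trial per animal")
  tps <- config$timepoints

  # covariate pools mimicking the emulated study population
  intake_pool <- c(2658, 2658, 1798, 1798, 2658, 1798, 1659, 2221)
  frac_pool <- c(0.35, 0.16, 0.18, 0.24, 0.25, 0.20, 0.18, 0.19)

  rows <- list()
  animals <- list()
  effects_a <- numeric(config$n_animals)
  day_eff <- list()
  for (i in seq_len(config$n_animals)) {
    set.seed(config$seed + 7919L * i)   # per-animal stream
    a_i <- stats::rnorm(1, 0, config$animal_sd)
    effects_a[i] <- a_i
    mass <- stats::rnorm(1, 183.9, 28.4)
    mass <- min(max(mass, 120), 260)
    age <- round(stats::runif(1, 5, 40))
    sex <- if (stats::runif(1) < 0.75) "M" else "F"
    j <- ((i - 1L) %% length(intake_pool)) + 1L
    intake <- intake_pool[j]
    frac <- frac_pool[j]
    d_ij <- stats::rnorm(config$trials_per_animal, 0, config$day_sd)
    day_eff[[i]] <- d_ij
    for (tr in seq_len(config$trials_per_animal)) {
      pool_temp <- stats::rnorm(1, 22.7, 1.3)
      mu <- hif_curve(tps, config)
      eps <- stats::rnorm(length(tps), 0, config$residual_sd)
      extra_day <- if (config$shared_curve) d_ij[tr] else
        d_ij[tr] + 0      # per-measurement mode perturbs below
      vo2 <- mu + a_i + extra_day + eps
      if (!config$shared_curve)
        vo2 <- vo2 + stats::rnorm(length(tps), 0, config$day_sd / 2)
      rows[[length(rows) + 1L]] <- data.frame(
        animal_id = sprintf("A%02d", i),
        day = sprintf("A%02d_d%02d", i, tr),
        time_min = tps,
        vo2_l_min = vo2,
        true_vo2_l_min = mu + a_i + extra_day,
        intake_kcal = intake,
        meal_fraction = frac,
        age_yr = age,
        mass_kg = mass,
        pool_temp_c = pool_temp,
        sex = sex,
        stringsAsFactors = FALSE
      )
    }
    animals[[i]] <- data.frame(
      animal_id = sprintf("A%02d", i), sex = sex, age_yr = age,
      mass_kg = mass, intake_kcal = intake, meal_fraction = frac,
      maturity = if (age < 8) "juvenile" else "adult",
      stringsAsFactors = FALSE
    )
  }
  trials <- do.call(rbind, rows)
  rownames(trials) <- NULL
  list(
    trials = trials,
    animals = do.call(rbind, animals),
    truth = list(animal_effects = effects_a, day_effects = day_eff,
                 config = config)
  )
}

#' Simulate, degrade and return one raw measurement
#'
#' Convenience wrapper: builds an ideal breath train for a target V'O2/RER,
#' then applies the configured instrument model. Useful for end-to-end tests
#' of the processing chain.
#'
#' @inheritParams simulate_breath_train
#' @param noise logical; apply the instrument noise (lag and delay are always
#'   applied).
#' @param seed seed controlling breath-level and noise randomness.
#' @return A list with `flow`, `gas` (degraded traces) and `truth`.
#' @export
simulate_trial_recording <- function(target_vo2, target_rer, duration,
                                     config = sim_config(), noise = TRUE,
                                     seed = 1L) {
  ideal <- simulate_breath_train(target_vo2, target_rer, duration, config,
                                 seed = seed)
  model <- config$instrument
  if (!noise) {
    model$flow_noise_sd <- 0
    model$gas_noise_sd <- 0
  }
  deg <- apply_instrument(ideal$flow, ideal$gas, model, seed = seed + 1L)
  list(flow = deg$flow, gas = deg$gas, truth = ideal$truth)
}
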