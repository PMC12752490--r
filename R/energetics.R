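#' Classify a measurement as BMR or RMR
#'
#' A fasted (time since feeding 0) measurement on an adult meets the basal
#' criteria (postabsorptive, quiescent, thermoneutral) and is labelled BMR; a
#' fasted measurement on a juvenile, or any postprandial measurement, is
#' resting metabolic rate (RMR).
#'
#' @param time_since_feeding minutes since feeding; 0 means fasted.
#' @param maturity `"adult"` or `"juvenile"`.
#' @return `"BMR"` or `"RMR"` (vectorized).
#' @export
classify_measurement <- function(time_since_feeding, maturity) {
  if (any(is.na(maturity)))
    stop("maturity is required to classify a measurement")
  maturity <- match.arg(maturity, c("adult", "juvenile"), several.ok = TRUE)
  ifelse(time_since_feeding == 0 & maturity == "adult", "BMR", "RMR")
}

#' Allometric basal metabolic rate prediction
#'
#' Kleiber's interspecific scaling for terrestrial mammals,
#' `BMR = 0.0093 * Mb^0.75` with mass in kg and BMR in l O2 min^-1.
#'
#' @param body_mass body mass in kg (> 0).
#' @param coef,exponent scaling constants; defaults 0.0093 and 0.75.
#' @return Predicted BMR, l O2 min^-1.
#' @export
kleiber_bmr <- function(body_mass, coef = 0.0093, exponent = 0.75) {
  if (any(body_mass <= 0)) stop("body mass must be > 0")
  coef * body_mass^exponent
}

#' Kleiber ratio
#'
#' Measured fasted oxygen consumption divided by the allometric prediction
#' [kleiber_bmr()].
#'
#' @param measured_vo2 fasted V'O2, l O2 min^-1 (> 0).
#' @inheritParams kleiber_bmr
#' @return Dimensionless ratio.
#' @export
kleiber_ratio <- function(measured_vo2, body_mass, coef = 0.0093,
                          exponent = 0.75) {
  if (any(measured_vo2 <= 0)) stop("measured V'O2 must be > 0")
  measured_vo2 / kleiber_bmr(body_mass, coef, exponent)
}

#' Postprandial rise in metabolic rate
#'
#' Difference between a recorded (resting) metabolic rate and the basal rate.
#' Negative values are preserved: postprandial rates can fall below the fasted
#' measurement.
#'
#' @param rmr,bmr metabolic rates, l O2 min^-1.
#' @return `rmr - bmr`, l O2 min^-1.
#' @export
delta_mr <- function(rmr, bmr) rmr - bmr

#' SDA scope
#'
#' Relative increase in metabolism due to digestion: peak postprandial
#' metabolic rate divided by the basal rate.
#'
#' @param peak_mr peak metabolic rate, l O2 min^-1.
#' @param bmr basal metabolic rate, l O2 min^-1 (> 0).
#' @return Dimensionless scope.
#' @export
sda_scope <- function(peak_mr, bmr) {
  if (any(bmr <= 0)) stop("bmr must be > 0")
  peak_mr / bmr
}

#' Convert an oxygen volume to energy
#'
#' @param volume litres of O2 (>= 0).
#' @param coef energetic coefficient, kcal per litre O2 (default 4.8, the
#'   value conventional in marine-mammal energetics).
#' @return Energy in kcal.
#' @export
o2_to_kcal <- function(volume, coef = 4.8) {
  if (any(volume < 0)) stop("volume must be >= 0")
  coef * volume
}

#' Heat increment of feeding as a percentage of gross energy intake
#'
#' The excess O2 consumed above baseline over the trial window, converted to
#' energy, expressed as a percentage of the meal's gross energy.
#'
#' @param excess_o2 excess oxygen volume above baseline, litres.
#' @param gei gross energy intake of the meal, kcal (> 0).
#' @param coef kcal per litre O2, passed to [o2_to_kcal()].
#' @return HIF in percent of GEI.
#' @export
hif_percent_gei <- function(excess_o2, gei, coef = 4.8) {
  if (any(gei <= 0)) stop("gross energy intake must be > 0")
  100 * o2_to_kcal(excess_o2, coef) / gei
}

#' Excess oxygen volume above baseline
#'
#' Splits the total O2 consumed over a window into the baseline (BMR
#' maintained for the whole window) and the excess attributable to digestion.
#'
#' @param auc total O2 volume over the window (area under the fitted curve),
#'   litres.
#' @param bmr basal metabolic rate, l O2 min^-1.
#' @param window window length, minutes (> 0).
#' @return A list with `auc_volume`, `baseline_volume`, `excess_volume`
#'   (litres).
#' @export
excess_volume <- function(auc, bmr, window) {
  if (window <= 0) stop("window must be > 0")
  baseline <- bmr * window
  list(auc_volume = auc, baseline_volume = baseline,
       excess_volume = auc - baseline)
}

#' Scale a single-meal digestive cost to the whole day
#'
#' Assuming the feeding response is linear in caloric intake, a meal that is
#' `meal_fraction` of the daily ration implies a daily digestive O2 cost of
#' `excess / meal_fraction`, reported also as a percentage of the O2 the
#' animal would use maintaining BMR for 24 h.
#'
#' @param excess_o2 excess O2 above baseline for the measured meal, litres.
#' @param meal_fraction the meal as a fraction of daily energy intake, in
#'   (0, 1].
#' @param bmr basal metabolic rate, l O2 min^-1.
#' @return A list with `daily_digestive_volume` (l), `daily_bmr_volume` (l)
#'   and `daily_pct_bmr` (percent).
#' @export
daily_cost <- function(excess_o2, meal_fraction, bmr) {
  if (any(meal_fraction <= 0 | meal_fraction > 1))
    stop("meal_fraction must lie in (0, 1]")
  daily <- excess_o2 / meal_fraction
  daily_bmr <- bmr * 1440
  list(daily_digestive_volume = daily, daily_bmr_volume = daily_bmr,
       daily_pct_bmr = 100 * daily / daily_bmr)
}

#' Extend the digestive cost beyond the measured window
#'
#' If the postprandial elevation has not finished by the end of the measured
#' window, the tail can be approximated by a constant resting rate between
#' `t_start` and `t_end`. The extra volume is scaled to the day by the same
#' meal-fraction argument as [daily_cost()]. Note the printed procedure scales
#' the whole tail volume (not the tail's excess above BMR); the excess-based
#' alternative is `(rmr_tail - bmr) * (t_end - t_start)` and is returned as
#' `extra_excess_volume` for comparison.
#'
#' @param rmr_tail assumed resting rate over the tail, l O2 min^-1.
#' @param t_start,t_end tail window, minutes (`t_end > t_start`).
#' @param meal_fraction the meal as a fraction of daily intake.
#' @param bmr basal metabolic rate, l O2 min^-1.
#' @return A list with `extra_volume` (l), `extra_excess_volume` (l),
#'   `extended_daily_volume` (l) and `extended_daily_pct_bmr` (percent).
#' @export
extended_daily_cost <- function(rmr_tail, t_start, t_end, meal_fraction,
                                bmr) {
  if (t_end <= t_start) stop("t_end must be > t_start")
  extra <- rmr_tail * (t_end - t_start)
  sc <- daily_cost(max(extra, 0), meal_fraction, bmr)
  list(extra_volume = extra,
       extra_excess_volume = (rmr_tail - bmr) * (t_end - t_start),
       extended_daily_volume = sc$daily_digestive_volume,
       extended_daily_pct_bmr = sc$daily_pct_bmr)
}

#' Mass-specific metabolic rate
#'
#' @param rate metabolic rate, l O2 min^-1.
#' @param mass body mass, kg (> 0).
#' @return Rate in ml O2 min^-1 kg^-1.
#' @export
mass_specific <- function(rate, mass) {
  if (any(mass <= 0)) stop("mass must be > 0")
  rate * 1000 / mass
}

#' Per-animal and study-level energetics report
#'
#' Computes, per animal: BMR (mean fasted V'O2), Kleiber ratio (mean of
#' per-trial ratios), fasted RER, maximal postprandial rise (mean over trials
#' of the day's peak postprandial V'O2 minus that day's fasted V'O2) and SDA
#' scope (mean over trials of peak/fasted); then study-level grand statistics
#' as unweighted means across animals (trial-count-weighted means are offered
#' because per-animal trial counts are unequal).
#'
#' @param trials data frame with columns `animal_id`, `day`, `time_min`,
#'   `vo2_l_min` and optionally `rer`.
#' @param animals data frame with `animal_id`, `mass_kg`, `maturity`.
#' @param day_matched logical; compare each day's peak to that day's fasted
#'   measurement (default) rather than to the animal's overall BMR.
#' @param weighted logical; weight the study means by per-animal fasted trial
#'   counts instead of the default unweighted mean.
#' @return A list of class `energetics_report`: `per_animal` data frame
#'   (`animal_id`, `n_fasted`, `bmr`, `kleiber_ratio`, `max_delta_mr`,
#'   `sda_scope`, `fasted_rer`, `label`) and `study` (means and SDs across
#'   animals plus the total fasted trial count).
#' @export
summarize_individuals <- function(trials, animals, day_matched = TRUE,
                                  weighted = FALSE) {
  ids <- unique(trials$animal_id)
  rows <- list()
  for (id in ids) {
    tr <- trials[trials$animal_id == id, , drop = FALSE]
    an <- animals[animals$animal_id == id, , drop = FALSE]
    fasted <- tr[tr$time_min == 0, , drop = FALSE]
    if (nrow(fasted) == 0L) {
      warning(sprintf("animal %s has no fasted trial; excluded", id))
      next
    }
    bmr <- mean(fasted$vo2_l_min)
    kr <- mean(kleiber_ratio(fasted$vo2_l_min, an$mass_kg[1]))
    rer <- if ("rer" %in% names(tr)) mean(fasted$rer) else NA_real_
    # per-day peak postprandial rise and scope
    dmr <- scope <- c()
    for (d in unique(tr$day)) {
      td <- tr[tr$day == d, , drop = FALSE]
      post <- td[td$time_min > 0, , drop = FALSE]
      if (nrow(post) == 0L) next
      base <- if (day_matched && any(td$time_min == 0))
        mean(td$vo2_l_min[td$time_min == 0]) else bmr
      peak <- max(post$vo2_l_min)
      dmr <- c(dmr, delta_mr(peak, base))
      scope <- c(scope, sda_scope(peak, base))
    }
    rows[[length(rows) + 1L]] <- data.frame(
      animal_id = id, n_fasted = nrow(fasted), bmr = bmr,
      kleiber_ratio = kr,
      max_delta_mr = if (length(dmr)) mean(dmr) else NA_real_,
      sda_scope = if (length(scope)) mean(scope) else NA_real_,
      fasted_rer = rer,
      label = classify_measurement(0, an$maturity[1]),
      stringsAsFactors = FALSE
    )
  }
  per_animal <- do.call(rbind, rows)
  w <- if (weighted) per_animal$n_fasted else rep(1, nrow(per_animal))
  wmean <- function(x) sum(w * x, na.rm = TRUE) / sum(w[!is.na(x)])
  study <- list(
    bmr_mean = wmean(per_animal$bmr),
    bmr_sd = stats::sd(per_animal$bmr),
    kleiber_mean = wmean(per_animal$kleiber_ratio),
    kleiber_sd = stats::sd(per_animal$kleiber_ratio),
    max_delta_mr_mean = wmean(per_animal$max_delta_mr),
    max_delta_mr_sd = stats::sd(per_animal$max_delta_mr),
    sda_scope_mean = wmean(per_animal$sda_scope),
    sda_scope_sd = stats::sd(per_animal$sda_scope),
    fasted_rer_mean = wmean(per_animal$fasted_rer),
    n_fasted_total = sum(per_animal$n_fasted)
  )
  structure(list(per_animal = per_animal, study = study),
            class = "energetics_report")
}

#' @export
print.energetics_report <- function(x, ...) {
  cat(sprintf(
    paste0("<energetics_report> %d animals, %d fasted trials\n",
           "  BMR %.2f +/- %.2f l O2/min | Kleiber %.2f | max dMR %.2f | ",
           "SDA scope %.2f\n"),
    nrow(x$per_animal), x$study$n_fasted_total, x$study$bmr_mean,
    x$study$bmr_sd, x$study$kleiber_mean, x$study$max_delta_mr_mean,
    x$study$sda_scope_mean))
  invisible(x)
}

#' Full heat-increment-of-feeding summary
#'
#' Composes [excess_volume()], [hif_percent_gei()], [daily_cost()] and
#' (optionally) [extended_daily_cost()] into one record.
#'
#' @param auc fitted total O2 volume over the window, litres.
#' @param bmr basal metabolic rate, l O2 min^-1.
#' @param window window length, minutes.
#' @param gei gross energy intake of the meal, kcal.
#' @param meal_fraction meal as a fraction of daily intake.
#' @param rmr_tail,tail_end optional constant tail rate (l O2 min^-1) and its
#'   end time (min) for the extended estimate; the tail starts at `window`.
#' @param coef kcal per litre O2.
#' @return A list of class `hif_summary`.
#' @export
hif_summary <- function(auc, bmr, window, gei, meal_fraction,
                        rmr_tail = NULL, tail_end = NULL, coef = 4.8) {
  ev <- excess_volume(auc, bmr, window)
  dc <- daily_cost(max(ev$excess_volume, 0), meal_fraction, bmr)
  out <- c(ev, list(
    hif_pct_gei = hif_percent_gei(max(ev$excess_volume, 0), gei, coef),
    daily_digestive_volume = dc$daily_digestive_volume,
    daily_bmr_volume = dc$daily_bmr_volume,
    daily_pct_bmr = dc$daily_pct_bmr,
    window = window, gei = gei, meal_fraction = meal_fraction
  ))
  if (!is.null(rmr_tail) && !is.null(tail_end))
    out <- c(out, extended_daily_cost(rmr_tail, window, tail_end,
                                      meal_fraction, bmr))
  structure(out, class = "hif_summary")
}

#' @export
print.hif_summary <- function(x, ...) {
  cat(sprintf(
    paste0("<hif_summary> window %g min: AUC %.1f l, baseline %.1f l, ",
           "excess %.1f l\n  HIF %.1f%% GEI | daily digestive cost %.1f l ",
           "(%.1f%% of daily BMR)\n"),
    x$window, x$auc_volume, x$baseline_volume, x$excess_volume,
    x$hif_pct_gei, x$daily_digestive_volume, x$daily_pct_bmr))
  if (!is.null(x$extra_volume))
    cat(sprintf("  extended tail: +%.1f l -> %.1f%% of daily BMR\n",
                x$extra_volume, x$extended_daily_pct_bmr))
  invisible(x)
}
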