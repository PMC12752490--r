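#' Model specification for the postprandial time course
#'
#' The oxygen-consumption time course is modelled with a normal generalized
#' additive mixed model: shrinkage thin-plate regression splines (basis
#' dimension `k`) of time since feeding, meal energy, age, body mass and pool
#' temperature; a tensor-product interaction of time and meal energy; sex as
#' a binary fixed effect; and random intercepts for animal and trial day.
#' Smoothing parameters are selected by maximum likelihood with an extra
#' selection penalty that can shrink any smooth (null space included) to zero.
#'
#' @param k basis dimension for every smooth term (default 4; must be >= 3).
#' @param method smoothing-parameter criterion, `"ML"` (default) or `"REML"`.
#' @param select logical; add the null-space selection penalty (default TRUE).
#' @return An object of class `timecourse_spec`.
#' @export
timecourse_spec <- function(k = 4, method = c("ML", "REML"), select = TRUE) {
  if (k < 3) stop("basis dimension must be >= 3")
  structure(list(k = k, method = match.arg(method), select = select),
            class = "timecourse_spec")
}

# coerce a trial table into the typed analysis frame the model expects
prepare_model_frame <- function(trials) {
  need <- c("animal_id", "day", "time_min", "vo2_l_min", "intake_kcal",
            "age_yr", "mass_kg", "pool_temp_c", "sex")
  miss <- setdiff(need, names(trials))
  if (length(miss))
    stop("trial table is missing column(s): ", paste(miss, collapse = ", "))
  df <- data.frame(
    vo2 = trials$vo2_l_min,
    time = trials$time_min,
    intake = trials$intake_kcal,
    age = trials$age_yr,
    mass = trials$mass_kg,
    pool_temp = trials$pool_temp_c,
    male01 = as.numeric(trials$sex == "M"),
    animal_id = factor(trials$animal_id),
    day = factor(trials$day)
  )
  if (anyNA(df)) stop("trial table contains missing values")
  df
}

timecourse_formula <- function(spec, drop = character(0)) {
  k <- spec$k
  sm <- function(v) sprintf("s(%s, bs = 'ts', k = %d)", v, k)
  terms <- c("male01", sm("time"))
  for (v in c("intake", "age", "mass", "pool_temp"))
    if (!v %in% drop) terms <- c(terms, sm(v))
  if (!"intake" %in% drop)
    terms <- c(terms, sprintf("te(time, intake, k = c(%d, %d))", k, k))
  for (v in c("animal_id", "day"))
    if (!v %in% drop) terms <- c(terms, sprintf("s(%s, bs = 're')", v))
  stats::as.formula(paste("vo2 ~", paste(terms, collapse = " + ")))
}

# covariates whose smooths cannot be identified from the data at hand
# (constant continuous covariates, single-level grouping factors); their
# terms are dropped (with a warning at the call site) rather than passed to
# the smooth constructor, which would error
degenerate_covariates <- function(df) {
  cand <- c("intake", "age", "mass", "pool_temp", "animal_id", "day")
  cand[vapply(cand, function(v) length(unique(df[[v]])) == 1L, logical(1))]
}

#' Build the penalized design for the time-course model
#'
#' Exposes the model matrix and penalty blocks without fitting: one penalized
#' block per shrinkage smooth, a tensor-product block for the time-by-intake
#' interaction, the sex indicator column, and one indicator block per random
#' intercept (animal, day). Column bookkeeping (`first_col`/`last_col` per
#' term) is returned for downstream prediction.
#'
#' @param trials trial table (see [fit_timecourse()]).
#' @param spec a [timecourse_spec()].
#' @return A list with `X` (design matrix), `terms` (data frame of term
#'   labels and column ranges), `penalties` (list of per-smooth penalty
#'   matrices) and `n_coef`.
#' @export
build_design <- function(trials, spec = timecourse_spec()) {
  df <- prepare_model_frame(trials)
  if (length(unique(df$time)) < 2)
    stop("need at least two distinct time values")
  drop <- degenerate_covariates(df)
  for (v in drop)
    warning(sprintf(
      "covariate '%s' is constant; dropping its smooth term", v))
  G <- mgcv::gam(timecourse_formula(spec, drop), data = df,
                 method = spec$method, select = spec$select, fit = FALSE)
  terms <- data.frame(
    label = vapply(G$smooth, `[[`, character(1), "label"),
    first_col = vapply(G$smooth, `[[`, numeric(1), "first.para"),
    last_col = vapply(G$smooth, `[[`, numeric(1), "last.para"),
    stringsAsFactors = FALSE
  )
  terms <- rbind(
    data.frame(label = c("(Intercept)", "male01"), first_col = 1:2,
               last_col = 1:2, stringsAsFactors = FALSE),
    terms)
  list(X = G$X, terms = terms,
       penalties = lapply(G$smooth, function(s) s$S),
       n_coef = ncol(G$X))
}

#' Fit the postprandial time-course model
#'
#' Fits the penalized-spline mixed model of [timecourse_spec()] to a trial
#' table by penalized maximum likelihood (mgcv), and extracts the random-
#' effect and residual standard deviations.
#'
#' @param trials data frame with one row per measurement and columns
#'   `animal_id`, `day`, `time_min`, `vo2_l_min`, `intake_kcal`, `age_yr`,
#'   `mass_kg`, `pool_temp_c`, `sex` ("M"/"F"). Fasted rows (`time_min == 0`)
#'   are included in the fit.
#' @param spec a [timecourse_spec()].
#' @return An object of class `timecourse_fit`: the mgcv fit (`gam`), the
#'   analysis frame (`data`), the model specification (`spec`), the marginal
#'   covariate means
#'   (`profile`), random-effect SDs `sd_animal`, `sd_day` and `sd_residual`.
#' @export
fit_timecourse <- function(trials, spec = timecourse_spec()) {
  df <- prepare_model_frame(trials)
  if (length(unique(df$time)) < 2)
    stop("need at least two distinct time values")
  drop <- degenerate_covariates(df)
  for (v in drop)
    warning(sprintf(
      "covariate '%s' is constant; dropping its smooth term", v))
  g <- mgcv::gam(timecourse_formula(spec, drop), data = df,
                 method = spec$method, select = spec$select)
  if (!g$converged) stop("time-course model failed to converge")
  vc <- tryCatch({
    tmp <- utils::capture.output(v <- mgcv::gam.vcomp(g, rescale = TRUE))
    v
  }, error = function(e) NULL)
  get_sd <- function(nm) {
    if (is.null(vc)) return(NA_real_)
    if (is.matrix(vc)) {
      i <- grep(nm, rownames(vc), fixed = TRUE)
      if (length(i)) unname(vc[i[1], 1]) else NA_real_
    } else {
      i <- grep(nm, names(vc), fixed = TRUE)
      if (length(i)) unname(vc[i[1]]) else NA_real_
    }
  }
  profile <- list(
    time = mean(df$time), intake = mean(df$intake), age = mean(df$age),
    mass = mean(df$mass), pool_temp = mean(df$pool_temp),
    male01 = mean(df$male01)
  )
  structure(
    list(gam = g, data = df, spec = spec, profile = profile,
         sd_animal = get_sd("s(animal_id)"), sd_day = get_sd("s(day)"),
         sd_residual = sqrt(g$sig2)),
    class = "timecourse_fit"
  )
}

#' @export
print.timecourse_fit <- function(x, ...) {
  cat(sprintf(
    paste0("<timecourse_fit> n = %d, %d coefficients (%s, select = %s)\n",
           "  random-effect SDs: animal %.3f, day %.3f; residual %.3f\n"),
    nrow(x$data), length(stats::coef(x$gam)), x$spec$method,
    x$spec$select, x$sd_animal, x$sd_day, x$sd_residual))
  invisible(x)
}

#' Approximate per-term hypothesis tests
#'
#' Wald-type tests of the null hypothesis of no association between oxygen
#' consumption and each model term (mgcv's `anova.gam` machinery for smooth
#' terms, the coefficient z-test for the parametric sex effect).
#'
#' @param fit a [timecourse_fit()].
#' @return Data frame with columns `term`, `statistic`, `p_value`.
#' @export
term_tests <- function(fit) {
  a <- mgcv::anova.gam(fit$gam)
  sm <- data.frame(term = rownames(a$s.table),
                   statistic = a$s.table[, "F"],
                   p_value = a$s.table[, "p-value"],
                   stringsAsFactors = FALSE)
  pt <- NULL
  if (!is.null(a$pTerms.table) && nrow(a$pTerms.table) > 0)
    pt <- data.frame(term = rownames(a$pTerms.table),
                     statistic = a$pTerms.table[, "F"],
                     p_value = a$pTerms.table[, "p-value"],
                     stringsAsFactors = FALSE)
  out <- rbind(pt, sm)
  rownames(out) <- NULL
  out
}

# linear-predictor matrix at a time grid, marginal over the sample's
# animal-level covariates, random-effect columns zeroed. Each animal
# contributes one covariate row (its intake/age/mass/sex and mean pool
# temperature); predictions are averaged across those rows at every grid
# time. Averaging over the observed covariates -- rather than plugging in
# covariate means -- matters because animal-level smooths such as
# te(time, intake) are only identified near observed covariate values;
# evaluated at an unobserved mean intake they can return arbitrary
# interpolant values. `overrides` pins named covariates to fixed values
# instead of marginalizing them.
population_lpmatrix <- function(fit, grid, overrides = list()) {
  df <- fit$data
  ref <- do.call(rbind, lapply(split(df, df$animal_id, drop = TRUE),
                               function(d)
    data.frame(intake = mean(d$intake), age = mean(d$age),
               mass = mean(d$mass), pool_temp = mean(d$pool_temp),
               male01 = mean(d$male01))))
  bad <- setdiff(names(overrides),
                 c("intake", "age", "mass", "pool_temp", "male01"))
  if (length(bad))
    stop("unknown profile covariate(s): ", paste(bad, collapse = ", "))
  for (v in names(overrides)) ref[[v]] <- overrides[[v]]
  n_ref <- nrow(ref)
  nd <- ref[rep(seq_len(n_ref), times = length(grid)), , drop = FALSE]
  nd$time <- rep(grid, each = n_ref)
  nd$animal_id <- df$animal_id[1]
  nd$day <- df$day[1]
  re_labels <- intersect(vapply(fit$gam$smooth, `[[`, character(1), "label"),
                         c("s(animal_id)", "s(day)"))
  Xp <- stats::predict(fit$gam, newdata = nd, type = "lpmatrix",
                       exclude = re_labels)
  # `exclude` zeroes the contributions; zero the columns explicitly too so
  # posterior draws of random-effect coefficients cannot leak into the band
  for (s in fit$gam$smooth)
    if (s$label %in% re_labels)
      Xp[, s$first.para:s$last.para] <- 0
  rowsum(Xp, group = rep(seq_along(grid), each = n_ref)) / n_ref
}

#' Draw coefficient samples from the posterior
#'
#' Samples the model coefficients for uncertainty propagation. The default is
#' the Gaussian approximation to the posterior (multivariate normal with the
#' coefficient covariance of the penalized fit), which is adequate for this
#' normal-likelihood model; `method = "mh"` runs mgcv's random-walk
#' Metropolis-Hastings sampler instead. Both are reproducible by seed.
#'
#' @param fit a [timecourse_fit()].
#' @param n number of draws (> 0); 10,000 by default.
#' @param seed integer seed.
#' @param method `"gaussian"` or `"mh"`.
#' @return An `n` x n_coef matrix of coefficient draws.
#' @export
posterior_samples <- function(fit, n = 10000, seed = 1L,
                              method = c("gaussian", "mh")) {
  if (n <= 0) stop("n must be > 0")
  method <- match.arg(method)
  set.seed(seed)
  if (method == "gaussian") {
    mgcv::rmvn(n, stats::coef(fit$gam), stats::vcov(fit$gam))
  } else {
    tmp <- utils::capture.output(
      mh <- mgcv::gam.mh(fit$gam, ns = n, burn = min(1000, n), thin = 1))
    mh$bs[seq_len(min(n, nrow(mh$bs))), , drop = FALSE]
  }
}

#' Population-level expected time course
#'
#' Expected oxygen consumption over a time grid at the population level:
#' random-effect terms are excluded and the animal-level covariates
#' (intake, age, mass, sex, pool temperature) are marginalized over the
#' analysis sample, i.e. the curve is the average of the per-animal predicted
#' curves. A posterior-resampled 95% band is attached. Sex can instead be
#' pinned via `profile` as a fractional indicator (e.g. 0.76 for a population
#' 76% male), which under the additive sex effect equals the corresponding
#' mixture of the sex-specific curves.
#'
#' @param fit a [timecourse_fit()].
#' @param grid time grid, minutes (default 0-133 by 1).
#' @param profile named list pinning any of `intake`, `age`, `mass`,
#'   `pool_temp`, `male01` to fixed values; unnamed covariates are
#'   marginalized over the sample.
#' @param n_samples posterior draws for the band.
#' @param seed seed for the draws.
#' @param method posterior sampling method, see [posterior_samples()].
#' @return A data frame of class `population_curve` with `time`, `vo2`,
#'   `lower`, `upper`; the profile and coefficient draws are attached as
#'   attributes (`profile`, `samples`, `lpmatrix`).
#' @export
population_curve <- function(fit, grid = seq(0, 133, by = 1), profile = NULL,
                             n_samples = 1000, seed = 1L,
                             method = "gaussian") {
  if (is.unsorted(grid)) stop("grid must be sorted ascending")
  overrides <- as.list(profile %||% list())
  rng <- range(fit$data$time)
  if (min(grid) < rng[1] || max(grid) > rng[2])
    warning(sprintf(
      "grid extends beyond the observed time range [%g, %g]: extrapolating",
      rng[1], rng[2]))
  Xp <- population_lpmatrix(fit, grid, overrides)
  mu <- drop(Xp %*% stats::coef(fit$gam))
  bs <- posterior_samples(fit, n = n_samples, seed = seed, method = method)
  sim <- Xp %*% t(bs)
  qs <- apply(sim, 1, stats::quantile, probs = c(0.025, 0.975))
  out <- data.frame(time = grid, vo2 = mu, lower = qs[1, ], upper = qs[2, ])
  class(out) <- c("population_curve", "data.frame")
  attr(out, "profile") <- utils::modifyList(fit$profile, overrides)
  attr(out, "samples") <- bs
  attr(out, "lpmatrix") <- Xp
  out
}

#' Area under the population curve
#'
#' Integrates the fitted population-level oxygen-consumption curve over a
#' window by the trapezoidal rule, with standard error and percentile interval
#' from per-draw AUCs of the posterior coefficient samples.
#'
#' @param curve a [population_curve()] (carrying its samples), or a
#'   [timecourse_fit()], in which case the curve is built first.
#' @param window integration window `c(0, T)` in minutes (default
#'   `c(0, 133)`).
#' @param by grid spacing in minutes when a curve must be built (default 1).
#' @param level interval level (default 0.95).
#' @param ... passed to [population_curve()] when `curve` is a fit.
#' @return A list of class `auc_estimate`: `point`, `se`, `lower`, `upper`
#'   (l O2), `n_samples`, `window`.
#' @export
auc_timecourse <- function(curve, window = c(0, 133), by = 1, level = 0.95,
                           ...) {
  if (inherits(curve, "timecourse_fit"))
    curve <- population_curve(curve, grid = seq(window[1], window[2],
                                                by = by), ...)
  grid <- curve$time
  if (window[1] < min(grid) || window[2] > max(grid))
    stop("curve grid does not cover the integration window")
  keep <- grid >= window[1] & grid <= window[2]
  if (max(diff(grid[keep])) > 5)
    stop("curve grid has gaps wider than 5 min inside the window")
  point <- pracma::trapz(grid[keep], curve$vo2[keep])
  bs <- attr(curve, "samples")
  Xp <- attr(curve, "lpmatrix")
  aucs <- NULL
  se <- lower <- upper <- NA_real_
  if (!is.null(bs) && !is.null(Xp)) {
    sim <- Xp[keep, , drop = FALSE] %*% t(bs)
    aucs <- apply(sim, 2, function(y) pracma::trapz(grid[keep], y))
    se <- stats::sd(aucs)
    qs <- stats::quantile(aucs, c((1 - level) / 2, 1 - (1 - level) / 2))
    lower <- unname(qs[1])
    upper <- unname(qs[2])
  }
  structure(list(point = point, se = se, lower = lower, upper = upper,
                 n_samples = if (is.null(bs)) 0L else nrow(bs),
                 window = window, samples = aucs),
            class = "auc_estimate")
}

#' @export
print.auc_estimate <- function(x, ...) {
  cat(sprintf(
    "<auc_estimate> %.1f +/- %.1f l O2 over [%g, %g] min (95%% CI %.1f-%.1f, %d draws)\n",
    x$point, x$se, x$window[1], x$window[2], x$lower, x$upper, x$n_samples))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
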