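test_that("design construction exposes stable penalized blocks", {
  cfg <- sim_config(seed = 3)
  ds <- make_study_dataset(cfg)
  d1 <- build_design(ds$trials)
  d2 <- build_design(ds$trials)
  expect_identical(d1$n_coef, d2$n_coef)
  expect_identical(d1$terms, d2$terms)
  expect_equal(nrow(d1$X), nrow(ds$trials))
  labs <- d1$terms$label
  expect_true(all(c("s(time)", "s(intake)", "s(age)", "s(mass)",
                    "s(pool_temp)", "te(time,intake)", "s(animal_id)",
                    "s(day)", "male01") %in% labs))
  # shrinkage smooths of basis dimension 4 contribute k-1 = 3 columns each
  sm <- d1$terms[d1$terms$label == "s(time)", ]
  expect_equal(sm$last_col - sm$first_col + 1, 3)
  # random-intercept block has one column per level
  re <- d1$terms[d1$terms$label == "s(animal_id)", ]
  expect_equal(re$last_col - re$first_col + 1,
               length(unique(ds$trials$animal_id)))

  # one animal: unidentifiable terms (constant covariates, the single-level
  # animal intercept) are dropped with a warning
  one <- ds$trials[ds$trials$animal_id == "A01", ]
  w <- capture_warnings(dd <- build_design(one))
  expect_true(any(grepl("constant", w)))
  expect_false("s(animal_id)" %in% dd$terms$label)
  expect_true("s(time)" %in% dd$terms$label)

  expect_error(build_design(ds$trials[ds$trials$time_min == 0, ]),
               "distinct time")
})

test_that("flat truth with zero random SDs shrinks the smooths to a constant", {
  cfg <- sim_config(peak_fraction = 0, animal_sd = 0, day_sd = 0,
                    residual_sd = 0.02, seed = 5)
  ds <- make_study_dataset(cfg)
  fit <- fit_quietly(ds$trials)
  cur <- curve_quietly(fit, n_samples = 200, seed = 1)
  expect_lt((max(cur$vo2) - min(cur$vo2)) / 0.73, 0.01)
  expect_equal(mean(cur$vo2), 0.73, tolerance = 0.01)
  # nuisance smooth shrunk to ~zero: varying its profile value is inert
  c_lo <- curve_quietly(fit, profile = list(pool_temp = 21),
                        n_samples = 50, seed = 1)
  c_hi <- curve_quietly(fit, profile = list(pool_temp = 24),
                        n_samples = 50, seed = 1)
  expect_lt(max(abs(c_lo$vo2 - c_hi$vo2)), 0.01)
})

test_that("fitted population curve recovers the feeding response", {
  cfg <- sim_config(seed = 11)
  ds <- make_study_dataset(cfg)
  fit <- fit_quietly(ds$trials)
  expect_equal(fit$sd_residual, 0.20, tolerance = 0.15)
  cur <- curve_quietly(fit, n_samples = 400, seed = 2)
  # band contains the point estimate, grid sorted
  expect_true(all(cur$lower <= cur$vo2 & cur$vo2 <= cur$upper))
  expect_false(is.unsorted(cur$time))
  # peak location and height in the right region
  pk <- cur$time[which.max(cur$vo2)]
  expect_gt(pk, 30)
  expect_lt(pk, 100)
  expect_gt(max(cur$vo2), min(cur$vo2) + 0.05)
})

test_that("sex enters as a fractional indicator, linearly", {
  cfg <- sim_config(seed = 11)
  ds <- make_study_dataset(cfg)
  fit <- fit_quietly(ds$trials)
  g <- seq(0, 120, by = 10)
  cm <- curve_quietly(fit, grid = g, profile = list(male01 = 1),
                      n_samples = 50, seed = 1)
  cf <- curve_quietly(fit, grid = g, profile = list(male01 = 0),
                      n_samples = 50, seed = 1)
  cx <- curve_quietly(fit, grid = g, profile = list(male01 = 0.76),
                      n_samples = 50, seed = 1)
  expect_equal(cx$vo2, 0.76 * cm$vo2 + 0.24 * cf$vo2, tolerance = 1e-9)
})

test_that("posterior draws are seeded and consistent with the fit", {
  cfg <- sim_config(seed = 11)
  ds <- make_study_dataset(cfg)
  fit <- fit_quietly(ds$trials)
  b1 <- posterior_samples(fit, n = 200, seed = 9)
  b2 <- posterior_samples(fit, n = 200, seed = 9)
  expect_identical(b1, b2)
  expect_error(posterior_samples(fit, n = 0), "n must be")

  # sample covariance converges to the coefficient covariance
  b <- posterior_samples(fit, n = 10000, seed = 1)
  V <- vcov(fit$gam)
  expect_equal(diag(stats::cov(b)), diag(V), tolerance = 0.05)
  # sample-mean curve agrees with the point curve within MC error
  cur <- curve_quietly(fit, n_samples = 10000, seed = 1)
  Xp <- attr(cur, "lpmatrix")
  mu_mc <- rowMeans(Xp %*% t(attr(cur, "samples")))
  mc_se <- apply(Xp %*% t(attr(cur, "samples")), 1, sd) / 100
  expect_true(all(abs(mu_mc - cur$vo2) < 3 * mc_se + 1e-8))

  # Metropolis-Hastings mode is seeded too
  m1 <- posterior_samples(fit, n = 200, seed = 4, method = "mh")
  m2 <- posterior_samples(fit, n = 200, seed = 4, method = "mh")
  expect_identical(m1, m2)
  expect_equal(ncol(m1), length(coef(fit$gam)))
})

test_that("trapezoidal AUC is exact on linear curves and refinement-stable", {
  # rectangle: constant baseline over 133 min
  const <- data.frame(time = 0:133, vo2 = rep(0.73, 134))
  a0 <- auc_timecourse(const, window = c(0, 133))
  expect_equal(a0$point, 97.09, tolerance = 1e-9)
  # trapezoid exact on degree-1 curves
  lin <- data.frame(time = 0:100, vo2 = 0.5 + 0.002 * (0:100))
  expect_equal(auc_timecourse(lin, window = c(0, 100))$point,
               0.5 * 100 + 0.002 * 100^2 / 2, tolerance = 1e-12)
  # 1-min sampling of the generator curve within 0.5% of the closed form
  cfg <- sim_config()
  samp <- data.frame(time = 0:133, vo2 = hif_curve(0:133, cfg))
  expect_equal(auc_timecourse(samp, window = c(0, 133))$point,
               hif_true_auc(cfg, 133), tolerance = 0.005)

  # halving the grid spacing moves a fitted-curve AUC by < 0.1%
  ds <- make_study_dataset(sim_config(seed = 11))
  fit <- fit_quietly(ds$trials)
  c1 <- curve_quietly(fit, grid = seq(0, 133, 1), n_samples = 50, seed = 1)
  c2 <- curve_quietly(fit, grid = seq(0, 133, 0.5), n_samples = 50, seed = 1)
  a1 <- auc_timecourse(c1, window = c(0, 133))$point
  a2 <- auc_timecourse(c2, window = c(0, 133))$point
  expect_lt(abs(a1 - a2) / a1, 0.001)

  # gaps and short grids are rejected
  gap <- data.frame(time = c(0, 50, 133), vo2 = rep(0.7, 3))
  expect_error(auc_timecourse(gap, window = c(0, 133)), "gaps")
  expect_error(auc_timecourse(const, window = c(0, 200)), "cover")
})

test_that("excess volume on zero-effect data is centred on zero", {
  excesses <- vapply(1:5, function(r) {
    cfg <- sim_config(peak_fraction = 0, seed = 300 + r)
    ds <- make_study_dataset(cfg)
    fit <- fit_quietly(ds$trials)
    a <- auc_timecourse(fit, window = c(0, 120), n_samples = 50, seed = r)
    a$point - 0.73 * 120
  }, numeric(1))
  # each replicate's excess is small relative to the true feeding response
  # (~21 l), and the replicate mean is centred near zero
  expect_lt(abs(mean(excesses)), 8)
  expect_true(all(abs(excesses) < 20))
})

test_that("term tests flag the time effect and stay quiet on null terms", {
  cfg <- sim_config(residual_sd = 0.10, seed = 21)
  ds <- make_study_dataset(cfg)
  fit <- fit_quietly(ds$trials)
  tt <- term_tests(fit)
  expect_true(all(c("s(time)", "s(pool_temp)", "male01") %in% tt$term))
  expect_lt(tt$p_value[tt$term == "s(time)"], 0.001)
  expect_gt(tt$p_value[tt$term == "s(pool_temp)"], 0.01)
})
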