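toy_series <- function(n = 5, sigma = 0.05, seed = 3, p = fig1_logistic()) {
  set.seed(seed)
  tt <- seq(0.1, 2, length.out = n)
  series_data(tt, solve_growth_analytic(p, tt) + rnorm(n, 0, sigma))
}

test_that("negloglik equals a brute-force Gaussian density sum", {
  s <- toy_series()
  spec <- model_spec(fig1_logistic())
  f <- solve_growth_analytic(fig1_logistic(), s$times)
  for (sg in c(0.03, 0.1)) {
    oracle <- -2 * sum(dnorm(s$values, f, sg, log = TRUE))
    expect_equal(negloglik(s, spec, sigma = sg), oracle)
    oracle_p <- -2 * sum(dnorm(s$values, f, sg * f, log = TRUE))
    expect_equal(negloglik(s, spec, residual_model = "proportional", sigma = sg),
                 oracle_p)
  }
})

test_that("negloglik scales as expected in sigma", {
  s <- toy_series()
  spec <- model_spec(fig1_logistic())
  f <- solve_growth_analytic(fig1_logistic(), s$times)
  sse <- sum((s$values - f)^2)
  n <- length(s$values)
  # zero residuals leave only the normalising term
  s0 <- series_data(s$times, f)
  expect_equal(negloglik(s0, spec, sigma = 0.2), n * log(2 * pi * 0.2^2))
  # halving sigma quadruples the SSE term
  t1 <- negloglik(s, spec, sigma = 0.2) - n * log(2 * pi * 0.2^2)
  t2 <- negloglik(s, spec, sigma = 0.1) - n * log(2 * pi * 0.1^2)
  expect_equal(t2 / t1, 4)
  expect_equal(t1, sse / 0.04)
})

test_that("noise-free logistic data is recovered to 1e-4 relative", {
  p <- fig1_logistic()
  tt <- seq(0.1, 2, length.out = 20)
  d <- series_data(tt, solve_growth_analytic(p, tt))
  f <- fit_single(d, model_spec(growth_params("logistic", B0 = 0.01, kb = 2, Bmax = 3)),
                  multistart = 3, seed = 1)
  expect_lt(max(abs(f$estimates[c("B0", "kb", "Bmax")] - c(0.001, 6, 1)) /
                c(0.001, 6, 1)), 1e-4)
  expect_true(f$convergence$converged)
  expect_equal(f$aic, f$objective + 2 * f$n_params)
  # SEs available and finite on a well-posed noisy problem
  fn <- fit_single(toy_series(n = 25), model_spec(p), multistart = 2, seed = 1)
  expect_true(all(is.finite(fn$se[c("B0", "kb", "Bmax")])))
})

test_that("fits need more observations than parameters", {
  d <- series_data(c(1, 2, 3), c(0.1, 0.4, 0.8))
  expect_error(fit_single(d, model_spec(fig1_logistic())), "n_params \\+ 1")
})

test_that("model-selection criteria implement their penalties exactly", {
  fake_fit <- function(obj, p, n) structure(
    list(objective = obj, n_params = p, n_obs = n,
         spec = list(growth = list(family = "logistic"))), class = "fit_result")
  fits <- list(a = fake_fit(100, 3, 100), b = fake_fit(100, 4, 100))
  for (crit in c("aic", "hq", "hq_as_printed")) {
    tab <- model_selection(fits, crit)
    expect_equal(tab$model[1], "a")       # equal objectives: fewer params wins
  }
  tab <- model_selection(fits, "aic")
  expect_equal(tab[[4]], 100 + 2 * c(3, 4))
  tab <- model_selection(fits, "hq")
  expect_equal(tab[[4]] - 100, 2 * c(3, 4) * log(log(100)))
  expect_equal(tab[[4]][2] - 100, 12.2174, tolerance = 1e-4)
  tab <- model_selection(fits, "hq_as_printed")
  expect_equal(tab[[4]][2] - 100, 36.8414, tolerance = 1e-4)
  expect_equal(nrow(model_selection(list(fake_fit(5, 3, 10)))), 1L)
  expect_error(model_selection(list(fake_fit(1, 3, 10), fake_fit(1, 3, 12))),
               "identical data")
})

test_that("two-stage analysis summarises the estimate distribution", {
  p <- fig1_logistic()
  tt <- seq(0.1, 2, length.out = 15)
  # identical channels, zero noise: stage-2 SD ~ 0
  dat0 <- lapply(1:3, function(i)
    series_data(tt, solve_growth_analytic(p, tt), channel_id = paste0("C", i)))
  ts0 <- fit_two_stage(dat0, model_spec(p), multistart = 1, compute_se = FALSE)
  expect_lt(max(ts0$summary$sd[ts0$summary$parameter != "sigma"], na.rm = TRUE), 1e-4)

  # 20% lognormal CV on Bmax recovered by the stage-2 summary
  des <- population_design(model_spec(p), tt, n_experiments = 30,
                           channels_per_experiment = 1,
                           cv_percent = c(Bmax = 20), sigma = 0.005)
  dat <- generate_dataset(des, seed = 5)
  ts <- fit_two_stage(dat, model_spec(p), multistart = 1, compute_se = FALSE)
  cvB <- ts$summary$cv_percent[ts$summary$parameter == "Bmax"]
  expect_gt(cvB, 12); expect_lt(cvB, 28)

  # a channel with too few points is excluded, not fatal
  bad <- series_data(c(1, 2), c(0.5, 0.9), channel_id = "BAD")
  ts2 <- fit_two_stage(c(dat0, list(bad)), model_spec(p), multistart = 1,
                       compute_se = FALSE)
  expect_match(ts2$failed, "BAD")
  expect_length(ts2$channel_fits, 3)
  expect_error(fit_two_stage(dat0[1], model_spec(p)), ">= 2 channels")
})

test_that("weighted residuals behave like standard normal draws under the truth", {
  p <- fig1_logistic()
  set.seed(9)
  tt <- seq(0.02, 2, length.out = 200)
  y <- solve_growth_analytic(p, tt) + rnorm(200, 0, 0.05)
  f <- fit_single(series_data(tt, y), model_spec(p), multistart = 2, seed = 2,
                  compute_se = FALSE)
  wr <- weighted_residuals(f)
  expect_named(wr, c("experiment_id", "channel_id", "time_h", "observed",
                     "predicted", "wres"))
  expect_lt(abs(mean(wr$wres)), 3 / sqrt(200))
  expect_gt(sd(wr$wres), 0.8); expect_lt(sd(wr$wres), 1.2)

  # perfect predictions give all-zero raw residuals
  d0 <- series_data(tt[1:20], solve_growth_analytic(p, tt[1:20]))
  f0 <- fit_single(d0, model_spec(p), multistart = 1, seed = 1, compute_se = FALSE)
  expect_lt(max(abs(f0$residuals)), 1e-6)

  # invariance under joint unit rescaling of data and sigma
  scale <- 1000
  ys <- y * scale
  fs <- fit_single(series_data(tt, ys),
                   model_spec(growth_params("logistic", B0 = 1, kb = 6, Bmax = 1000)),
                   multistart = 2, seed = 2, compute_se = FALSE)
  expect_equal(weighted_residuals(fs)$wres, wr$wres, tolerance = 1e-3)
})

test_that("each growth family is recovered from its own simulated data", {
  set.seed(21)
  tt <- seq(0.04, 2, length.out = 50)
  fams <- list(
    logistic = fig1_logistic(),
    gompertz = fig1_gompertz(),
    bertalanffy = growth_params("bertalanffy", B0 = 0.05, kb = 4, kd = 2,
                                lam = 0.25, delta = 1))
  for (nm in names(fams)) {
    p <- fams[[nm]]
    # the bertalanffy exponents are held at their structural values: with all
    # five parameters free the (kb, lam) / (kd, delta) pairs trade off and
    # single-series estimates are not separately identifiable
    est <- if (nm == "bertalanffy") c("B0", "kb", "kd") else c("B0", "kb", "Bmax")
    truth <- biofilmkin:::.current_values(model_spec(p), est)
    bias <- rowMeans(sapply(1:10, function(s) {
      set.seed(s)
      ref <- biofilmkin:::.predict_series(model_spec(p), tt, "live")
      y <- ref + rnorm(50, 0, 0.02 * max(ref))
      fit <- fit_single(series_data(tt, pmax(y, 1e-8)), model_spec(p),
                        estimate = est, init = truth * exp(0.2),
                        multistart = 2, seed = s, compute_se = FALSE)
      (fit$estimates[names(truth)] - truth) / truth
    }))
    expect_lt(max(abs(bias[c("kb", if (nm == "bertalanffy") "kd" else "Bmax")])),
              0.05, label = paste(nm, "parameter bias"))
  }
})

test_that("laplace marginal likelihood matches adaptive Gauss-Hermite quadrature", {
  # one lognormal random effect on kb, 4 channels x 3 observations
  p <- growth_params("exponential", B0 = 1, kb = 0.5)
  spec <- model_spec(p)
  tt <- c(0.5, 1, 2)
  set.seed(4)
  omega <- 0.3; sigma <- 0.15; delta <- c(B0 = 1, kb = 0.5)
  dat <- lapply(1:4, function(j) {
    kbj <- 0.5 * exp(rnorm(1, 0, omega))
    series_data(tt, 1 * exp(kbj * tt) + rnorm(3, 0, sigma),
                channel_id = paste0("C", j))
  })
  inner <- lapply(dat, function(s)
    biofilmkin:::.make_inner(s, spec, c("B0", "kb"), "kb", NULL))
  lap <- biofilmkin:::.laplace_neg2ll(inner, rep(3, 4), delta, omega, sigma)$value

  # oracle: adaptive GH quadrature (15 nodes) centred at each channel's mode
  gh <- pracma::gaussHermite(15)
  m2ll <- 0
  for (j in 1:4) {
    s <- dat[[j]]
    logdens <- function(eta) vapply(eta, function(e) {
      f <- 1 * exp(0.5 * exp(e) * tt)
      sum(dnorm(s$values, f, sigma, log = TRUE)) + dnorm(e, 0, omega, log = TRUE)
    }, numeric(1))
    dens <- function(eta) exp(logdens(eta))
    mode <- optimize(function(e) -logdens(e), c(-3, 3))$minimum
    h <- sqrt(1 / max(pracma::hessian(function(e) -logdens(e), mode), 1e-6))
    lik <- sum(gh$w * dens(mode + sqrt(2) * h * gh$x) * exp(gh$x^2)) * sqrt(2) * h
    m2ll <- m2ll - 2 * log(lik)
  }
  expect_lt(abs(lap - m2ll) / abs(m2ll), 0.005)
})

test_that("with zero inter-channel variability the mixed fit collapses to pooling", {
  p <- fig1_logistic()
  tt <- seq(0.1, 2, length.out = 12)
  des <- population_design(model_spec(p), tt, n_experiments = 4,
                           channels_per_experiment = 1, sigma = 0.02)
  dat <- generate_dataset(des, seed = 8)
  pooled <- fit_single(dat, model_spec(p), multistart = 2, seed = 1,
                       compute_se = FALSE)
  suppressMessages(
    mf <- fit_mixed_effects(dat, model_spec(p), random = "Bmax",
                            control = list(maxit = 250), seed = 1))
  expect_equal(unname(mf$fixed_effects["Bmax"]),
               unname(pooled$estimates["Bmax"]), tolerance = 0.02)
  expect_lt(mf$cv_percent[["Bmax"]], 5)
})

test_that("the mixed-effects fitter recovers the generating hierarchy", {
  p <- fig1_logistic()
  tt <- seq(0.1, 2, length.out = 12)
  des <- population_design(model_spec(p), tt, n_experiments = 8,
                           channels_per_experiment = 1,
                           cv_percent = c(Bmax = 20), sigma = 0.02)
  dat <- generate_dataset(des, seed = 14)
  mf <- fit_mixed_effects(dat, model_spec(p), random = "Bmax",
                          control = list(maxit = 300), seed = 1)
  expect_equal(unname(mf$fixed_effects[["Bmax"]]), 1, tolerance = 0.15)
  expect_equal(unname(mf$fixed_effects[["kb"]]), 6, tolerance = 0.15)
  expect_gt(mf$cv_percent[["Bmax"]], 5); expect_lt(mf$cv_percent[["Bmax"]], 45)
  expect_equal(mf$sigma, 0.02, tolerance = 0.5)
  expect_error(fit_mixed_effects(dat[1:2], model_spec(p), random = "Bmax"),
               ">= 3 channels")
  expect_error(fit_mixed_effects(dat, model_spec(p), random = "nope"),
               "subset")
})

test_that("empirical-Bayes estimates shrink toward the population mode", {
  p <- fig1_logistic()
  tt <- seq(0.1, 2, length.out = 12)
  des <- population_design(model_spec(p), tt, n_experiments = 6,
                           channels_per_experiment = 1,
                           cv_percent = c(Bmax = 25), sigma = 0.02)
  dat <- generate_dataset(des, seed = 31)
  mf <- fit_mixed_effects(dat, model_spec(p), random = "Bmax",
                          control = list(maxit = 250), seed = 1)
  # empty series: prior mode, population-typical parameters
  eb0 <- empirical_bayes(mf, NULL, times = tt)
  expect_true(eb0$typical)
  expect_equal(unname(eb0$eta), 0)
  expect_equal(eb0$params, mf$fixed_effects)

  # the penalised mode never deviates further than the unpenalised one
  # (obtained by making the prior essentially flat), and keeps its sign
  mf_wide <- mf; mf_wide$omega["Bmax"] <- 25
  for (j in seq_along(dat)) {
    eta_free <- empirical_bayes(mf_wide, dat[[j]])$eta[["Bmax"]]
    eta_pen <- empirical_bayes(mf, dat[[j]])$eta[["Bmax"]]
    expect_lte(abs(eta_pen), abs(eta_free) + 1e-6)
    if (abs(eta_free) > 1e-4) expect_gte(eta_pen * eta_free, 0)
  }

  # with a huge prior variance the EB Bmax approaches the individual-fit
  # estimate obtained with the other parameters held at the population values
  pop_spec <- biofilmkin:::.update_spec(model_spec(p),
                                        as.list(mf$fixed_effects[c("B0", "kb")]))
  ind <- fit_single(dat[[1]], pop_spec, estimate = "Bmax",
                    init = mf$fixed_effects["Bmax"],
                    multistart = 1, seed = 1, compute_se = FALSE)
  eb_wide <- empirical_bayes(mf_wide, dat[[1]])
  expect_equal(unname(eb_wide$params[["Bmax"]]),
               unname(ind$estimates[["Bmax"]]), tolerance = 0.05)
})

test_that("population-fit weighted residuals use individual predictions", {
  p <- fig1_logistic()
  tt <- seq(0.1, 2, length.out = 12)
  des <- population_design(model_spec(p), tt, n_experiments = 4,
                           channels_per_experiment = 1,
                           cv_percent = c(Bmax = 15), sigma = 0.02)
  dat <- generate_dataset(des, seed = 2)
  mf <- fit_mixed_effects(dat, model_spec(p), random = "Bmax",
                          control = list(maxit = 200), seed = 1)
  wr <- weighted_residuals(mf)
  expect_equal(nrow(wr), 4 * 12)
  expect_lt(abs(mean(wr$wres)), 1)
  expect_lt(sd(wr$wres), 2)
})
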