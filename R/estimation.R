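#' A single measured biofilm time series
#'
#' One channel's measurements of one variable/compartment, the unit the
#' estimation layer fits.
#'
#' @param times Sampling times (h), strictly increasing.
#' @param values Measurements, finite.
#' @param experiment_id,channel_id Labels identifying the flow-cell
#'   experiment and channel.
#' @param variable One of `"biomass"`, `"avg_thickness"`,
#'   `"colony_volume"`, `"area"`.
#' @param compartment `"live"` or `"dead"`.
#' @param unit Measurement unit label.
#' @return An object of class `series_data`.
#' @export
series_data <- function(times, values, experiment_id = "E1", channel_id = "C1",
                        variable = c("biomass", "avg_thickness", "colony_volume", "area"),
                        compartment = c("live", "dead"), unit = "") {
  variable <- match.arg(variable); compartment <- match.arg(compartment)
  if (length(times) != length(values)) stop("times and values must have equal length")
  if (is.unsorted(times, strictly = TRUE)) stop("times must be strictly increasing")
  if (any(!is.finite(values))) stop("values must be finite")
  structure(list(experiment_id = experiment_id, channel_id = channel_id,
                 variable = variable, compartment = compartment,
                 times = as.numeric(times), values = as.numeric(values), unit = unit),
            class = "series_data")
}

# ---- parameter plumbing ------------------------------------------------

.growth_names <- c("B0", "kb", "Bmax", "kd", "lam", "delta", "t_lag")

# write named natural-scale parameter values back into a spec (no
# revalidation: optimisers work on scales that keep them in-domain)
.update_spec <- function(spec, p) {
  for (nm in names(p)) {
    if (nm %in% .growth_names) spec$growth[[nm]] <- unname(p[[nm]])
    else spec$agent_effect[[nm]] <- unname(p[[nm]])
  }
  spec
}

# default estimated-parameter set for a spec
.default_estimate <- function(spec) {
  g <- switch(spec$growth$family,
    exponential = c("B0", "kb"),
    logistic    = c("B0", "kb", "Bmax"),
    gompertz    = c("B0", "kb", "Bmax"),
    bertalanffy = c("B0", "kb", "kd", "lam", "delta"))
  ae <- spec$agent_effect
  a <- if (is.null(ae)) character(0)
  else if (inherits(ae, "agent_params"))
    switch(ae$model, linear = "theta1", threshold = "theta1",
           saturating = c("theta1", "theta2"))
  else switch(ae$model,
    additive_linear = c("theta1", "theta2"),
    linear_interaction = c("theta1", "theta2", "theta3"),
    competitive_interaction = c("scale", "alpha"),
    competitive_antagonism = "scale")
  c(g, a)
}

.current_values <- function(spec, nms) {
  vapply(nms, function(nm)
    if (nm %in% .growth_names) spec$growth[[nm]] else spec$agent_effect[[nm]],
    numeric(1))
}

# log-scale packing; bertalanffy's 0 < lam < delta is enforced by storing
# log(delta - lam) when both are estimated
.pack <- function(p) {
  if (all(c("lam", "delta") %in% names(p))) {
    p[".lgap"] <- p[["delta"]] - p[["lam"]]
    p <- p[names(p) != "delta"]
  }
  log(pmax(unlist(p), 1e-12))
}
.unpack <- function(x) {
  p <- exp(x)
  if (".lgap" %in% names(p)) {
    p[["delta"]] <- p[["lam"]] + p[[".lgap"]]
    p <- p[names(p) != ".lgap"]
  }
  p
}

# live (or dead) model predictions at data times; cache accelerates the
# logistic + linear-kill family
.predict_series <- function(spec, times, compartment = "live",
                            cache = NULL, rtol = 1e-7, atol = 1e-9) {
  if (compartment == "live" && is.null(spec$post_plateau) && spec$dead_model == "none") {
    if (!is.null(cache) && .fast_path_ok(spec)) {
      g <- spec$growth
      return(.sim_live_fast(g$B0, g$kb, g$Bmax, .fast_kill_coefs(spec), g$t_lag, cache))
    }
    if (is.null(spec$agent_effect))
      return(if (spec$growth$family == "bertalanffy") .sim_bert_rk4(spec$growth, times)
             else solve_growth_analytic(spec$growth, times))
  }
  tg <- sort(unique(c(0, times)))
  need_dead <- compartment == "dead"
  sim_spec <- spec
  if (!need_dead && spec$dead_model != "none") sim_spec$dead_model <- "none"
  traj <- simulate_trajectory(sim_spec, tg, rtol = rtol, atol = atol)
  idx <- match(times, traj$times)
  if (need_dead) traj$D[idx] else traj$B[idx]
}

#' Gaussian -2 log-likelihood of a model for one or more series
#'
#' Computes \eqn{-2\log L} for a [model_spec()] (optionally with
#' parameter values overridden) against one `series_data` or a list of
#' them; a list is fitted jointly (e.g. live + dead channels of the same
#' flow cell) by summing contributions under a shared residual scale.
#'
#' Residual models: `additive` gives
#' \eqn{n \ln(2\pi\sigma^2) + SSE/\sigma^2}; `proportional` scales each
#' residual by its prediction, \eqn{\sigma f_i} being the SD of
#' observation i.
#'
#' If the model cannot be simulated at the proposed parameters a large
#' but finite penalised value is returned so optimisers can recover.
#'
#' @param data A `series_data` or list of them.
#' @param spec A [model_spec()].
#' @param params Optional named vector of natural-scale parameter values
#'   overriding those in `spec`.
#' @param residual_model `"additive"` or `"proportional"`.
#' @param sigma Residual scale (measurement units for additive; a CV for
#'   proportional); > 0.
#' @return The scalar \eqn{-2\log L}.
#' @export
negloglik <- function(data, spec, params = NULL,
                      residual_model = c("additive", "proportional"), sigma) {
  residual_model <- match.arg(residual_model)
  if (inherits(data, "series_data")) data <- list(data)
  if (sigma <= 0) stop("sigma must be positive")
  if (!is.null(params)) spec <- .update_spec(spec, as.list(params))
  tot <- 0
  for (s in data) {
    f <- tryCatch(.predict_series(spec, s$times, s$compartment),
                  error = function(e) NULL)
    if (is.null(f) || any(!is.finite(f))) return(1e10 + sum(unlist(lapply(data, `[[`, "values"))^2))
    r <- s$values - f
    tot <- tot + if (residual_model == "additive") {
      length(r) * log(2 * pi * sigma^2) + sum(r^2) / sigma^2
    } else {
      if (any(f <= 0)) return(1e10)
      sum(log(2 * pi * (sigma * f)^2)) + sum((r / (sigma * f))^2)
    }
  }
  tot
}

# crude but robust data-driven starting values
.heuristic_init <- function(data, spec, estimate) {
  y <- unlist(lapply(data, `[[`, "values")); tt <- unlist(lapply(data, `[[`, "times"))
  ymax <- max(y, 1e-6); ypos <- y[y > 0]
  init <- as.list(.current_values(spec, estimate))
  thalf <- tt[which.min(abs(y - ymax / 2))]
  for (nm in names(init)) {
    v <- init[[nm]]
    ok <- is.numeric(v) && length(v) == 1 && is.finite(v) && v > 0
    if (ok) next
    init[[nm]] <- switch(nm,
      B0 = max(min(ypos, ymax / 2), ymax / 1e3),
      Bmax = ymax,
      kb = log(4) / max(thalf, diff(range(tt)) / 10),
      kd = 1, lam = 0.5, delta = 1.5,
      theta1 = 1e-3, theta2 = 1e-3, theta3 = 1e-6,
      scale = 1, alpha = 1, 1)
  }
  unlist(init)
}

.restore_rng <- function() {
  has <- exists(".Random.seed", envir = globalenv())
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  function() {
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  }
}

#' Maximum-likelihood fit of a model to one series (or joint live/dead)
#'
#' Bounded local optimisation from `multistart` starting points (the
#' supplied or heuristic start plus log-scale jittered copies), keeping
#' the best objective.  Positive parameters are log-transformed; for the
#' bertalanffy family the constraint `0 < lam < delta` is enforced by
#' optimising `log(lam)` and `log(delta - lam)`.  With additive
#' residuals the residual SD is profiled out analytically and the
#' nonlinear step is a Levenberg-Marquardt least-squares
#' ([minpack.lm::nls.lm()]); with proportional residuals the full
#' \eqn{-2\log L} is minimised by quasi-Newton.
#'
#' @param data A `series_data` or list of them (joint fit).
#' @param spec A [model_spec()] holding the structural model; parameter
#'   values in it serve as defaults/fixed values.
#' @param estimate Character vector of parameter names to estimate;
#'   defaults to the spec's growth parameters plus any agent-effect
#'   coefficients.
#' @param init Optional named vector of starting values (natural scale).
#' @param lower,upper Optional named bounds (natural scale).
#' @param residual_model `"additive"` (default) or `"proportional"`.
#' @param multistart Number of starts (default 8).
#' @param seed RNG seed controlling the jitter; fits are deterministic
#'   given the seed.
#' @param compute_se Compute standard errors from the inverse observed
#'   information (central finite differences); `NA` when the information
#'   matrix is singular.
#' @return An object of class `fit_result`: estimates (including
#'   `sigma`), standard errors, `objective` (\eqn{-2\log L}), `n_obs`,
#'   `n_params` (estimated parameters + residual scale), `aic`, `hq`,
#'   residuals, weighted residuals, fitted values, convergence report
#'   and the seed.
#' @export
fit_single <- function(data, spec, estimate = NULL, init = NULL,
                       lower = NULL, upper = NULL,
                       residual_model = c("additive", "proportional"),
                       multistart = 8, seed = 1, compute_se = TRUE) {
  residual_model <- match.arg(residual_model)
  if (inherits(data, "series_data")) data <- list(data)
  if (is.null(estimate)) estimate <- .default_estimate(spec)
  n_obs <- sum(vapply(data, function(s) length(s$values), integer(1)))
  if (n_obs < length(estimate) + 1L)
    stop("need at least n_params + 1 observations")

  start <- .heuristic_init(data, spec, estimate)
  if (!is.null(init)) start[names(init)] <- init
  x0 <- .pack(as.list(start[estimate]))
  lo <- rep(-Inf, length(x0)); hi <- rep(Inf, length(x0))
  names(lo) <- names(hi) <- names(x0)
  if (!is.null(lower)) for (nm in intersect(names(lower), names(lo))) lo[nm] <- log(lower[[nm]])
  if (!is.null(upper)) for (nm in intersect(names(upper), names(hi))) hi[nm] <- log(upper[[nm]])

  # caches for the fast logistic path (one per series)
  caches <- if (.fast_path_ok(spec))
    lapply(data, function(s) if (s$compartment == "live") .fast_cache(spec, s$times)) else
    vector("list", length(data))

  predict_all <- function(p) {
    sp <- .update_spec(spec, as.list(p))
    lapply(seq_along(data), function(i)
      .predict_series(sp, data[[i]]$times, data[[i]]$compartment, cache = caches[[i]]))
  }
  resid_fun <- function(x) {  # stacked raw residuals, huge on failure
    p <- .unpack(x)
    f <- tryCatch(predict_all(p), error = function(e) NULL)
    if (is.null(f) || any(!is.finite(unlist(f))))
      return(rep(1e4, n_obs))
    unlist(lapply(seq_along(data), function(i) data[[i]]$values - f[[i]]))
  }
  obj_prop <- function(x) {   # -2logL with sigma profiled, proportional
    p <- .unpack(x)
    f <- tryCatch(predict_all(p), error = function(e) NULL)
    if (is.null(f) || any(!is.finite(unlist(f))) || any(unlist(f) <= 0)) return(1e10)
    fr <- unlist(f); yy <- unlist(lapply(data, `[[`, "values"))
    s2 <- mean(((yy - fr) / fr)^2)
    n_obs * log(2 * pi * s2) + sum(log(fr^2)) + n_obs
  }

  restore <- .restore_rng(); on.exit(restore())
  set.seed(seed)
  starts <- c(list(x0), lapply(seq_len(max(multistart - 1L, 0L)), function(i)
    pmin(pmax(x0 + stats::rnorm(length(x0), 0, 0.35), lo), hi)))

  best <- NULL; log_lines <- character(0)
  for (si in seq_along(starts)) {
    res <- tryCatch({
      if (residual_model == "additive") {
        fit <- minpack.lm::nls.lm(par = starts[[si]], lower = lo, upper = hi,
                                  fn = resid_fun,
                                  control = minpack.lm::nls.lm.control(maxiter = 200))
        rr <- resid_fun(fit$par)
        s2 <- sum(rr^2) / n_obs
        list(par = fit$par, objective = n_obs * log(2 * pi * s2) + n_obs,
             sigma = sqrt(s2), conv = fit$info %in% 1:4,
             msg = fit$message)
      } else {
        fit <- stats::nlminb(starts[[si]], obj_prop, lower = lo, upper = hi)
        list(par = fit$par, objective = fit$objective,
             sigma = {
           p <- .unpack(fit$par); f <- unlist(predict_all(p))
           sqrt(mean(((unlist(lapply(data, `[[`, "values")) - f) / f)^2))
         }, conv = fit$convergence == 0, msg = fit$message)
      }
    }, error = function(e) NULL)
    if (is.null(res)) { log_lines <- c(log_lines, sprintf("start %d: error", si)); next }
    log_lines <- c(log_lines, sprintf("start %d: obj %.4f (%s)", si, res$objective, res$msg))
    if (is.null(best) || res$objective < best$objective) best <- res
  }
  if (is.null(best)) stop(paste(c("all starts failed:", log_lines), collapse = "\n"))

  est <- .unpack(best$par)[estimate]
  sigma <- best$sigma
  fitted <- unlist(predict_all(est))
  yy <- unlist(lapply(data, `[[`, "values"))
  resid <- yy - fitted
  wres <- if (residual_model == "additive") resid / sigma else resid / (sigma * fitted)
  p_tot <- length(estimate) + 1L

  se <- rep(NA_real_, length(estimate) + 1L)
  names(se) <- c(estimate, "sigma")
  if (compute_se) {
    nl <- function(v) negloglik(data, spec, params = stats::setNames(v[seq_along(estimate)], estimate),
                                residual_model = residual_model, sigma = v[length(v)])
    H <- tryCatch(pracma::hessian(nl, c(est, sigma)), error = function(e) NULL)
    if (!is.null(H)) {
      cov <- tryCatch(2 * solve(H), error = function(e) NULL)
      if (!is.null(cov) && all(diag(cov) > 0))
        se <- stats::setNames(sqrt(diag(cov)), c(estimate, "sigma"))
      else message("information matrix singular or indefinite: standard errors not available")
    }
  }

  structure(list(estimates = c(est, sigma = sigma), se = se,
                 objective = best$objective, n_obs = n_obs, n_params = p_tot,
                 aic = best$objective + 2 * p_tot,
                 hq = best$objective + 2 * p_tot * log(log(n_obs)),
                 residuals = resid, weighted_residuals = wres, fitted = fitted,
                 residual_model = residual_model,
                 convergence = list(converged = best$conv, starts = log_lines),
                 spec = .update_spec(spec, as.list(est)), estimate = estimate,
                 data = data, seed = seed),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("Model fit (%s growth): -2logL = %.3f, AIC = %.3f, n = %d\n",
              x$spec$growth$family, x$objective, x$aic, x$n_obs))
  tab <- data.frame(estimate = x$estimates,
                    se = x$se[names(x$estimates)])
  print(tab, digits = 4)
  invisible(x)
}

#' Rank competing fits by an information criterion
#'
#' AIC is \eqn{-2\log L + 2p}; Hannan-Quinn (`hq`) is
#' \eqn{-2\log L + 2p\ln(\ln n)}.  `hq_as_printed` is a stricter
#' variant, \eqn{-2\log L + 2p\ln n}, matching the verbal description
#' sometimes given for HQ ("twice the log of the number of observations
#' times the number of parameters"); the standard form is the default.
#' Ties are broken toward fewer parameters.
#'
#' @param fits A (optionally named) list of `fit_result` objects fitted
#'   to identical data.
#' @param criterion `"aic"`, `"hq"` or `"hq_as_printed"`.
#' @return Data frame with model, objective, `n_params`, criterion value
#'   and rank, ordered best first.
#' @export
model_selection <- function(fits, criterion = c("aic", "hq", "hq_as_printed")) {
  criterion <- match.arg(criterion)
  if (inherits(fits, "fit_result")) fits <- list(fits)
  n <- vapply(fits, `[[`, numeric(1), "n_obs")
  if (length(unique(n)) != 1L) stop("fits must be on identical data (n_obs differ)")
  obj <- vapply(fits, `[[`, numeric(1), "objective")
  p <- vapply(fits, `[[`, numeric(1), "n_params")
  val <- switch(criterion,
    aic = obj + 2 * p,
    hq = obj + 2 * p * log(log(n)),
    hq_as_printed = obj + 2 * p * log(n))
  nms <- names(fits)
  if (is.null(nms)) nms <- vapply(fits, function(f) f$spec$growth$family, character(1))
  ord <- order(val, p)
  out <- data.frame(model = nms, objective = obj, n_params = p, value = val)[ord, ]
  names(out)[names(out) == "value"] <- criterion
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Two-stage population analysis
#'
#' Stage 1 fits every channel independently with [fit_single()]; stage 2
#' summarises the distribution of the per-channel estimates (mean, SD,
#' CV% = 100 SD/mean).  Channels whose stage-1 fit fails are excluded
#' and listed.
#'
#' @param dataset List of `series_data`, one per channel.
#' @param spec A [model_spec()] shared by all channels, or a list of
#'   specs (one per channel, e.g. different dosing arms).
#' @param ... Passed to [fit_single()].
#' @return List with `channel_fits`, `summary` (data frame of parameter
#'   mean/sd/cv_percent) and `failed` (channel ids).
#' @export
fit_two_stage <- function(dataset, spec, ...) {
  if (inherits(dataset, "series_data")) dataset <- list(dataset)
  if (length(dataset) < 2L) stop("two-stage analysis needs >= 2 channels")
  specs <- if (inherits(spec, "model_spec")) rep(list(spec), length(dataset)) else spec
  ids <- vapply(dataset, function(s) paste(s$experiment_id, s$channel_id, sep = ":"), character(1))
  fits <- vector("list", length(dataset)); names(fits) <- ids
  for (i in seq_along(dataset))
    fits[i] <- list(tryCatch(fit_single(dataset[[i]], specs[[i]], ...),
                             error = function(e) NULL))
  ok <- !vapply(fits, is.null, logical(1))
  if (sum(ok) < 2L) stop("fewer than 2 channels could be fitted")
  est <- do.call(rbind, lapply(fits[ok], `[[`, "estimates"))
  summ <- data.frame(parameter = colnames(est),
                     mean = colMeans(est),
                     sd = apply(est, 2, stats::sd))
  summ$cv_percent <- 100 * summ$sd / summ$mean
  rownames(summ) <- NULL
  list(channel_fits = fits[ok], summary = summ, failed = ids[!ok])
}

# ---- nonlinear mixed effects (Laplace) --------------------------------

# inner penalised objective for one channel:
#   g(eta) = SSE(eta)/(2 sigma^2) + sum(eta^2/(2 omega^2))
.make_inner <- function(series, spec, estimate, random, cache) {
  force(series); force(spec); force(estimate); force(random); force(cache)
  function(eta, delta, omega, sigma) {
    p <- delta
    p[random] <- p[random] * exp(eta)
    f <- tryCatch(.predict_series(.update_spec(spec, as.list(p)),
                                  series$times, series$compartment, cache = cache),
                  error = function(e) NULL)
    if (is.null(f) || any(!is.finite(f))) return(1e8 + sum(eta^2))
    sum((series$values - f)^2) / (2 * sigma^2) + sum(eta^2 / (2 * omega^2))
  }
}

# Laplace-approximate marginal -2logL at fixed population parameters.
# inner: list of per-channel penalised objectives from .make_inner;
# returns the value and the per-channel modes (for warm starting).
.laplace_neg2ll <- function(inner, n_j, delta, omega, sigma, eta_start = NULL) {
  J <- length(inner); q <- length(omega)
  if (is.null(eta_start)) eta_start <- matrix(0, J, q)
  tot <- sum(n_j) * log(2 * pi * sigma^2) + J * sum(log(omega^2))
  etas <- matrix(0, J, q); fail <- integer(0)
  for (j in seq_len(J)) {
    gj <- function(e) inner[[j]](e, delta, omega, sigma)
    op <- tryCatch(
      stats::optim(eta_start[j, ], gj, method = "BFGS",
                   control = list(maxit = 100, reltol = 1e-10)),
      error = function(e) NULL)
    if (is.null(op)) {
      fail <- c(fail, j)
      op <- list(par = eta_start[j, ], value = gj(eta_start[j, ]))
    }
    etas[j, ] <- op$par
    H <- .fd_hessian(gj, op$par)
    ld <- tryCatch(determinant(H, logarithm = TRUE), error = function(e) NULL)
    ldet <- if (is.null(ld) || ld$sign <= 0) sum(log(pmax(diag(H), 1e-8)))
            else as.numeric(ld$modulus)
    tot <- tot + 2 * op$value + ldet
  }
  list(value = tot, eta = etas, failed = fail)
}

# central finite-difference Hessian (small q; keeps the inner loop light)
.fd_hessian <- function(fn, x, h = 1e-3) {
  q <- length(x); H <- matrix(0, q, q)
  f0 <- fn(x)
  for (i in seq_len(q)) {
    ei <- replace(numeric(q), i, h)
    H[i, i] <- (fn(x + ei) - 2 * f0 + fn(x - ei)) / h^2
    if (i < q) for (j in seq((i + 1L), q)) {
      ej <- replace(numeric(q), j, h)
      H[i, j] <- H[j, i] <-
        (fn(x + ei + ej) - fn(x + ei - ej) - fn(x - ei + ej) + fn(x - ei - ej)) / (4 * h^2)
    }
  }
  H
}

#' Laplace-approximate nonlinear mixed-effects fit
#'
#' Fits the hierarchical model in which channel j's parameters are
#' \eqn{\delta \exp(\eta_j)} with \eqn{\eta_j \sim N(0, \Omega)}
#' (lognormal random effects on the parameters named in `random`,
#' diagonal \eqn{\Omega}) and observations carry additive Gaussian
#' residual error with SD \eqn{\sigma}.  The marginal likelihood is
#' approximated by the Laplace method: for each channel the
#' random-effect mode \eqn{\hat\eta_j} is found by an inner quasi-Newton
#' optimisation (warm-started across outer iterations), the inner
#' Hessian is taken by central finite differences, and the outer
#' optimisation over \eqn{(\log\delta, \log\omega, \log\sigma)} uses
#' Nelder-Mead.
#'
#' Random effects are lognormal because all kinetic parameters are
#' positive; inter-channel variability is reported as
#' CV% = \eqn{100\sqrt{e^{\omega^2} - 1}}.  One level of random effects
#' (channel) is used; experiment-level effects can be emulated by
#' treating each experiment:channel pair as a channel.
#'
#' @param dataset List of `series_data`, one per channel (>= 3).
#' @param spec A [model_spec()] shared by all channels, or a list of
#'   specs matching `dataset` (e.g. per-arm PK).
#' @param random Character vector of parameter names receiving a random
#'   effect (non-empty; must be a subset of `estimate`).
#' @param estimate Fixed-effect parameter names; defaults to the spec's
#'   full parameter set as in [fit_single()].
#' @param init Optional named list with elements `delta` (named vector),
#'   `omega`, `sigma`; anything missing is initialised from a naive
#'   pooled fit.
#' @param control List: `maxit` outer Nelder-Mead iterations (default
#'   600), `reltol` (default 1e-7).
#' @param seed RNG seed (used by the pooled initial fit's multistart).
#' @return An object of class `population_fit` with fixed effects,
#'   `omega`/`cv_percent`, `sigma`, per-channel empirical-Bayes modes
#'   `eta`, the marginal `objective` (\eqn{-2\log L}), AIC/HQ, EB
#'   individual predictions, convergence report and seed.  If all
#'   `omega` collapse toward 0 the fit reduces gracefully to the pooled
#'   model (a message is emitted).
#' @export
fit_mixed_effects <- function(dataset, spec, random, estimate = NULL,
                              init = NULL, control = list(), seed = 1) {
  if (length(dataset) < 3L) stop("mixed-effects fitting needs >= 3 channels")
  specs <- if (inherits(spec, "model_spec")) rep(list(spec), length(dataset)) else spec
  if (length(specs) != length(dataset)) stop("spec list must match dataset length")
  if (is.null(estimate)) estimate <- .default_estimate(specs[[1]])
  if (!length(random) || !all(random %in% estimate))
    stop("random must name a non-empty subset of the estimated parameters")
  maxit <- control$maxit %||% 600
  reltol <- control$reltol %||% 1e-7
  J <- length(dataset); q <- length(random); p <- length(estimate)
  n_j <- vapply(dataset, function(s) length(s$values), numeric(1))
  n_obs <- sum(n_j)

  caches <- lapply(seq_len(J), function(j)
    if (.fast_path_ok(specs[[j]]) && dataset[[j]]$compartment == "live")
      .fast_cache(specs[[j]], dataset[[j]]$times) else NULL)
  inner <- lapply(seq_len(J), function(j)
    .make_inner(dataset[[j]], specs[[j]], estimate, random, caches[[j]]))

  # ---- initial values: naive pooled fit (eta = 0) ----
  if (is.null(init$delta) || is.null(init$sigma)) {
    pooled_resid <- function(x) {
      pp <- .unpack(x)
      unlist(lapply(seq_len(J), function(j) {
        f <- tryCatch(.predict_series(.update_spec(specs[[j]], as.list(pp)),
                                      dataset[[j]]$times, dataset[[j]]$compartment,
                                      cache = caches[[j]]),
                      error = function(e) NULL)
        if (is.null(f) || any(!is.finite(f))) rep(1e4, n_j[j]) else dataset[[j]]$values - f
      }))
    }
    start <- .heuristic_init(dataset, specs[[1]], estimate)
    pf <- minpack.lm::nls.lm(par = .pack(as.list(start[estimate])), fn = pooled_resid,
                             control = minpack.lm::nls.lm.control(maxiter = 200))
    delta0 <- .unpack(pf$par)[estimate]
    sigma0 <- sqrt(sum(pooled_resid(pf$par)^2) / n_obs)
  }
  delta0 <- init$delta %||% delta0
  sigma0 <- init$sigma %||% sigma0
  omega0 <- init$omega %||% rep(0.2, q)

  psi0 <- c(log(delta0), log(omega0), log(sigma0))
  eta_warm <- matrix(0, J, q)

  marginal <- function(psi, keep = FALSE) {
    delta <- stats::setNames(exp(psi[seq_len(p)]), estimate)
    omega <- pmin(pmax(exp(psi[p + seq_len(q)]), 1e-4), 20)
    sigma <- exp(psi[p + q + 1L])
    lp <- .laplace_neg2ll(inner, n_j, delta, omega, sigma, eta_start = eta_warm)
    eta_warm <<- lp$eta
    if (keep) list(value = lp$value, eta = lp$eta, delta = delta, omega = omega,
                   sigma = sigma, failed = lp$failed)
    else lp$value
  }

  opt <- stats::optim(psi0, marginal, method = "Nelder-Mead",
                      control = list(maxit = maxit, reltol = reltol))
  fin <- marginal(opt$par, keep = TRUE)
  if (length(fin$failed))
    warning("inner optimisation flagged channels: ", paste(fin$failed, collapse = ", "))
  if (all(fin$omega <= 2e-4))
    message("random-effect variances collapsed to ~0: estimates reduce to the pooled fit")

  # empirical-Bayes individual predictions
  eb_pred <- lapply(seq_len(J), function(j) {
    pj <- fin$delta; pj[random] <- pj[random] * exp(fin$eta[j, ])
    .predict_series(.update_spec(specs[[j]], as.list(pj)),
                    dataset[[j]]$times, dataset[[j]]$compartment, cache = caches[[j]])
  })

  n_par <- p + q + 1L
  structure(list(fixed_effects = fin$delta,
                 sigma = unname(fin$sigma),
                 omega = stats::setNames(fin$omega, random),
                 cv_percent = stats::setNames(100 * sqrt(exp(fin$omega^2) - 1), random),
                 eta = fin$eta, random = random, estimate = estimate,
                 objective = fin$value, n_obs = n_obs, n_params = n_par,
                 aic = fin$value + 2 * n_par,
                 hq = fin$value + 2 * n_par * log(log(n_obs)),
                 eb_predictions = eb_pred, dataset = dataset, specs = specs,
                 approximation = "laplace",
                 convergence = list(code = opt$convergence, outer_evals = opt$counts[1],
                                    flagged_channels = fin$failed),
                 seed = seed),
            class = "population_fit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.population_fit <- function(x, ...) {
  cat(sprintf("Nonlinear mixed-effects fit (Laplace): -2logL = %.3f, %d channels, %d obs\n",
              x$objective, length(x$dataset), x$n_obs))
  tab <- data.frame(estimate = x$fixed_effects,
                    cv_percent = ifelse(names(x$fixed_effects) %in% x$random,
                                        x$cv_percent[names(x$fixed_effects)], NA))
  print(tab, digits = 4)
  cat(sprintf("Residual SD sigma = %.4g\n", x$sigma))
  invisible(x)
}

#' Empirical-Bayes estimates for one channel
#'
#' Returns the random-effect posterior mode \eqn{\hat\eta} maximising
#' the channel likelihood times the lognormal prior under a converged
#' population fit, the implied individual parameters, and the individual
#' predicted trajectory.  An empty/`NULL` series returns the
#' population-typical parameters (prior mode, \eqn{\hat\eta = 0}) with
#' `typical = TRUE`.
#'
#' @param popfit A `population_fit`.
#' @param series A `series_data` (or `NULL` for the population-typical
#'   answer).
#' @param spec Optional [model_spec()] for the series (defaults to the
#'   population fit's first spec).
#' @param times Times at which to return predictions (defaults to the
#'   series times).
#' @return List with `eta`, `params`, `predictions`, `times`,
#'   `typical`.
#' @export
empirical_bayes <- function(popfit, series = NULL, spec = NULL, times = NULL) {
  stopifnot(inherits(popfit, "population_fit"))
  spec <- spec %||% popfit$specs[[1]]
  if (is.null(series) || length(series$values) == 0L) {
    times <- times %||% seq(0, 1, length.out = 2)
    pars <- popfit$fixed_effects
    pred <- .predict_series(.update_spec(spec, as.list(pars)), times, "live")
    return(list(eta = stats::setNames(rep(0, length(popfit$random)), popfit$random),
                params = pars, predictions = pred, times = times, typical = TRUE))
  }
  cache <- if (.fast_path_ok(spec) && series$compartment == "live")
    .fast_cache(spec, series$times) else NULL
  gj <- .make_inner(series, spec, popfit$estimate, popfit$random, cache)
  op <- stats::optim(rep(0, length(popfit$random)),
                     function(e) gj(e, popfit$fixed_effects, popfit$omega, popfit$sigma),
                     method = "BFGS", control = list(maxit = 200, reltol = 1e-12))
  pars <- popfit$fixed_effects
  pars[popfit$random] <- pars[popfit$random] * exp(op$par)
  times <- times %||% series$times
  pred <- .predict_series(.update_spec(spec, as.list(pars)), times, series$compartment,
                          cache = if (identical(times, series$times)) cache else NULL)
  list(eta = stats::setNames(op$par, popfit$random), params = pars,
       predictions = pred, times = times, typical = FALSE)
}

#' Weighted residuals of a fit
#'
#' Observed minus predicted, scaled by the residual SD: `sigma` for
#' additive models, `sigma * prediction` for proportional ones (with
#' zero-prediction observations flagged and excluded).  For population
#' fits the predictions are the empirical-Bayes individual predictions,
#' i.e. conditional on the estimated fixed effects, variances and
#' per-channel modes.
#'
#' @param fit A `fit_result` or `population_fit`.
#' @param data Optional data to residualise (defaults to the data the
#'   fit was computed on).
#' @return Data frame with `experiment_id`, `channel_id`, `time_h`,
#'   `observed`, `predicted`, `wres`.
#' @export
weighted_residuals <- function(fit, data = NULL) {
  if (inherits(fit, "fit_result")) {
    data <- data %||% fit$data
    if (inherits(data, "series_data")) data <- list(data)
    preds <- unlist(lapply(data, function(s) {
      cache <- if (.fast_path_ok(fit$spec) && s$compartment == "live")
        .fast_cache(fit$spec, s$times) else NULL
      .predict_series(fit$spec, s$times, s$compartment, cache = cache)
    }))
    sigma <- fit$estimates[["sigma"]]
    obs <- unlist(lapply(data, `[[`, "values"))
    tt <- unlist(lapply(data, `[[`, "times"))
    ids <- do.call(rbind, lapply(data, function(s)
      data.frame(experiment_id = rep(s$experiment_id, length(s$times)),
                 channel_id = rep(s$channel_id, length(s$times)))))
    scale <- if (fit$residual_model == "additive") rep(sigma, length(preds)) else sigma * preds
  } else if (inherits(fit, "population_fit")) {
    data <- fit$dataset
    preds <- unlist(fit$eb_predictions)
    obs <- unlist(lapply(data, `[[`, "values"))
    tt <- unlist(lapply(data, `[[`, "times"))
    ids <- do.call(rbind, lapply(data, function(s)
      data.frame(experiment_id = rep(s$experiment_id, length(s$times)),
                 channel_id = rep(s$channel_id, length(s$times)))))
    scale <- rep(fit$sigma, length(preds))
  } else stop("fit must be a fit_result or population_fit")
  out <- data.frame(ids, time_h = tt, observed = obs, predicted = preds,
                    wres = (obs - preds) / scale)
  bad <- !is.finite(out$wres)
  if (any(bad)) {
    warning(sum(bad), " observation(s) with zero/invalid scale excluded")
    out <- out[!bad, ]
  }
  rownames(out) <- NULL
  out
}
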