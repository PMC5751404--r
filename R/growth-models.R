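#' Kinetic parameters of a biofilm growth law
#'
#' Constructs and validates the parameter set of one of the four growth
#' laws used throughout the package.  All validation happens here, at
#' construction, so rate evaluations inside ODE loops stay branch-light.
#'
#' The rate forms are
#' \describe{
#'   \item{exponential}{\eqn{g(B) = k_b B}}
#'   \item{logistic}{\eqn{g(B) = k_b B (1 - B/B_{max})}}
#'   \item{gompertz}{\eqn{g(B) = k_b B \ln(B_{max}/B)}}
#'   \item{bertalanffy}{\eqn{g(B) = k_b B^\lambda - k_d B^\delta}, with
#'     \eqn{0 < \lambda < \delta}.  The logistic law is the special case
#'     \eqn{\lambda = 1,\ \delta = 2,\ k_d = k_b/B_{max}}.}
#' }
#'
#' @param family One of `"exponential"`, `"logistic"`, `"gompertz"`,
#'   `"bertalanffy"`.
#' @param B0 Initial biofilm level (measurement units, e.g. um or
#'   um^3/um^2); must be positive.
#' @param kb Growth rate (1/h); must be positive.
#' @param Bmax Carrying capacity (measurement units); required for
#'   logistic/gompertz, rejected otherwise.
#' @param kd Loss rate (bertalanffy only; units depend on `delta`).
#' @param lam,delta Growth and loss exponents (dimensionless,
#'   bertalanffy only); must satisfy `0 < lam < delta`.
#' @param t_lag Dormancy lag time (h, default 0): net growth is zero for
#'   `t < t_lag`.
#' @return An object of class `growth_params`.
#' @examples
#' growth_params("logistic", B0 = 0.001, kb = 6, Bmax = 1)
#' @export
growth_params <- function(family = c("exponential", "logistic", "gompertz", "bertalanffy"),
                          B0, kb, Bmax = NULL, kd = NULL, lam = NULL, delta = NULL,
                          t_lag = 0) {
  family <- match.arg(family)
  stopifnot(is.numeric(B0), length(B0) == 1L, is.finite(B0),
            is.numeric(kb), length(kb) == 1L, is.finite(kb),
            is.numeric(t_lag), length(t_lag) == 1L, is.finite(t_lag))
  if (B0 <= 0) stop("B0 must be positive")
  if (kb <= 0) stop("kb must be positive")
  if (t_lag < 0) stop("t_lag must be nonnegative")
  needs_bmax <- family %in% c("logistic", "gompertz")
  if (needs_bmax) {
    if (is.null(Bmax)) stop(sprintf("family '%s' requires Bmax", family))
    if (!is.finite(Bmax) || Bmax <= 0) stop("Bmax must be positive")
  } else if (!is.null(Bmax)) {
    stop(sprintf("family '%s' does not take Bmax", family))
  }
  if (family == "bertalanffy") {
    if (is.null(kd) || is.null(lam) || is.null(delta))
      stop("bertalanffy requires kd, lam and delta")
    if (kd <= 0) stop("kd must be positive")
    if (!(lam > 0 && lam < delta))
      stop("bertalanffy requires 0 < lam < delta")
  } else if (!is.null(kd) || !is.null(lam) || !is.null(delta)) {
    stop(sprintf("kd/lam/delta only apply to the bertalanffy family, not '%s'", family))
  }
  structure(list(family = family, B0 = B0, kb = kb, Bmax = Bmax,
                 kd = kd, lam = lam, delta = delta, t_lag = t_lag),
            class = "growth_params")
}

#' @export
print.growth_params <- function(x, ...) {
  flds <- x[!vapply(x, is.null, logical(1))]
  cat("Biofilm growth law:", x$family, "\n")
  nums <- flds[names(flds) != "family"]
  cat(paste(sprintf("  %s = %g", names(nums), unlist(nums)), collapse = "\n"), "\n")
  invisible(x)
}

#' Instantaneous growth rate g(B)
#'
#' Evaluates the agent-free growth rate of the chosen law at biofilm
#' level `B`.  At `B = 0` every family returns 0 (the Gompertz limit
#' \eqn{B \ln(B_{max}/B) \to 0} is taken by continuity).  For the
#' Gompertz law `B > Bmax` is legal and yields a negative rate.
#'
#' @param params A [growth_params()] object.
#' @param B Biofilm level(s), nonnegative; vectorised.
#' @return Growth rate(s), units/h.
#' @examples
#' p <- growth_params("gompertz", B0 = 0.001, kb = 6, Bmax = 1)
#' growth_rate(p, c(0, 0.5, 1))
#' @export
growth_rate <- function(params, B) {
  stopifnot(inherits(params, "growth_params"))
  if (any(!is.finite(B)) || any(B < 0)) stop("B must be finite and nonnegative")
  switch(params$family,
    exponential = params$kb * B,
    logistic    = params$kb * B * (1 - B / params$Bmax),
    gompertz    = ifelse(B == 0, 0, params$kb * B * log(params$Bmax / B)),
    bertalanffy = params$kb * B^params$lam - params$kd * B^params$delta)
}

# lag-shifted time used by every closed-form solution
.lag_time <- function(t, t_lag) pmax(t - t_lag, 0)

#' Closed-form solution of a growth law
#'
#' Evaluates the analytic solution B(t) for the exponential, logistic or
#' Gompertz law.  A dormancy lag is applied by evaluating the solution at
#' `max(t - t_lag, 0)`.  The bertalanffy family has no closed form; use
#' [simulate_trajectory()].
#'
#' @param params A [growth_params()] object.
#' @param times Nonnegative times (h), vectorised.
#' @return Biofilm levels on `times`.
#' @examples
#' p <- growth_params("logistic", B0 = 0.001, kb = 6, Bmax = 1)
#' solve_growth_analytic(p, c(0, 0.5, 1))
#' @export
solve_growth_analytic <- function(params, times) {
  stopifnot(inherits(params, "growth_params"))
  if (any(!is.finite(times)) || any(times < 0)) stop("times must be finite and nonnegative")
  t <- .lag_time(times, params$t_lag)
  B0 <- params$B0; kb <- params$kb; Bmax <- params$Bmax
  switch(params$family,
    exponential = B0 * exp(kb * t),
    logistic    = Bmax * B0 / (B0 + (Bmax - B0) * exp(-kb * t)),
    gompertz    = Bmax * exp(log(B0 / Bmax) * exp(-kb * t)),
    bertalanffy = stop("bertalanffy has no closed-form solution; use simulate_trajectory()"))
}

#' Biofilm doubling time
#'
#' Returns the interval \eqn{\Delta} such that \eqn{B(t+\Delta) = 2B(t)}.
#' Constant (\eqn{\ln 2/k_b}) only for exponential growth; for the
#' limited-growth laws it increases with `t` and becomes infinite once
#' \eqn{B(t) \ge B_{max}/2} (`Inf` is returned).
#'
#' For the Gompertz law the default closed form is derived from the
#' defining relation,
#' \eqn{\Delta = -\ln(1 - \ln 2\, e^{k_b t} / \ln(B_{max}/B_0))/k_b}.
#' `as_printed = TRUE` instead evaluates the simpler textbook expression
#' \eqn{\ln(\ln 2\, e^{k_b t} + 1)/k_b}, which omits the
#' \eqn{\ln(B_{max}/B_0)} factor and does not satisfy the defining
#' relation except in special cases; it is provided for comparison only.
#'
#' @param params A [growth_params()] object (exponential, logistic or
#'   gompertz).
#' @param t Time(s) at which the doubling time is evaluated (h, >= 0).
#' @param as_printed Gompertz only: use the simplified literature form
#'   (see Details).
#' @return Doubling time(s) in hours; `Inf` where undefined.
#' @export
doubling_time <- function(params, t, as_printed = FALSE) {
  stopifnot(inherits(params, "growth_params"))
  if (any(!is.finite(t)) || any(t < 0)) stop("t must be finite and nonnegative")
  kb <- params$kb; B0 <- params$B0; Bmax <- params$Bmax
  switch(params$family,
    exponential = rep(log(2) / kb, length(t)),
    logistic = {
      # B(t+D) = 2 B(t) on the closed form; during a lag the clock has not
      # started, so the remaining lag is added to the interval
      arg <- 0.5 - B0 / (2 * (Bmax - B0)) * exp(kb * .lag_time(t, params$t_lag))
      out <- rep(Inf, length(t))
      out[arg > 0] <- -log(arg[arg > 0]) / kb + pmax(params$t_lag - t[arg > 0], 0)
      out
    },
    gompertz = {
      tt <- .lag_time(t, params$t_lag)
      if (as_printed) {
        log(log(2) * exp(kb * tt) + 1) / kb
      } else {
        arg <- 1 - log(2) * exp(kb * tt) / log(Bmax / B0)
        out <- rep(Inf, length(t))
        out[arg > 0] <- -log(arg[arg > 0]) / kb + pmax(params$t_lag - t[arg > 0], 0)
        out
      }
    },
    bertalanffy = stop("doubling_time is not defined for the bertalanffy family"))
}

#' Biofilm inhibitory concentration (BIC) as a function of biofilm level
#'
#' The constant agent concentration that makes the net growth rate zero
#' at the current biofilm level `B`, under a linear kill model with
#' coefficient `theta1`.  Constant (\eqn{k_b/\theta_1}) for exponential
#' growth; a decreasing function of `B` for the limited-growth laws:
#' \eqn{(k_b/\theta_1)(1 - B/B_{max})} (logistic) and
#' \eqn{(k_b/\theta_1)\ln(B_{max}/B)} (gompertz).  For the bertalanffy
#' family, not covered by the original framework, the generic fixed point
#' \eqn{g(B)/(\theta_1 B)} is returned (an extension).
#'
#' @param params A [growth_params()] object.
#' @param B Biofilm level(s), positive.
#' @param theta1 Linear kill coefficient (1/h per concentration unit),
#'   positive.
#' @return Concentration(s) at which net growth is zero.  For the
#'   logistic law with `B > Bmax` growth is already non-positive and the
#'   value is floored at 0 with a warning.
#' @export
bic_concentration <- function(params, B, theta1) {
  stopifnot(inherits(params, "growth_params"))
  if (any(!is.finite(B)) || any(B <= 0)) stop("B must be finite and positive")
  if (!is.numeric(theta1) || length(theta1) != 1L || theta1 <= 0)
    stop("theta1 must be a positive scalar")
  kb <- params$kb; Bmax <- params$Bmax
  out <- switch(params$family,
    exponential = rep(kb / theta1, length(B)),
    logistic    = kb / theta1 * (1 - B / Bmax),
    gompertz    = kb / theta1 * log(Bmax / B),
    bertalanffy = growth_rate(params, B) / (theta1 * B))
  if (params$family == "logistic" && any(out < 0)) {
    warning("B exceeds Bmax: net growth already non-positive, BIC floored at 0")
    out <- pmax(out, 0)
  }
  out
}
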