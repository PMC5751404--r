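# shared fixtures: the reference simulation parameters used across tests
fig1_logistic <- function() growth_params("logistic", B0 = 0.001, kb = 6, Bmax = 1)
fig1_gompertz <- function() growth_params("gompertz", B0 = 0.001, kb = 6, Bmax = 1)

# constant-concentration profile (piecewise-linear with two equal knots)
const_profile <- function(C, horizon = 10, agent = "A")
  pk_profile(agent, "interpolated",
             points = data.frame(time = c(0, horizon), conc = c(C, C)))

# independent ODE oracle: adaptive integration of the rate form
integrate_rate_form <- function(params, times, rtol = 1e-10, atol = 1e-12) {
  out <- deSolve::lsoda(c(B = params$B0), sort(unique(c(0, times))),
                        function(t, y, p) list(growth_rate(params, max(y, 0))),
                        parms = NULL, rtol = rtol, atol = atol)
  out[match(times, out[, 1]), 2]
}
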