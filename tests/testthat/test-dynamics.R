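test_that("model specifications reject inconsistent assemblies", {
  lg <- fig1_logistic(); gm <- fig1_gompertz()
  two <- two_agent_params("additive_linear", theta1 = 0.1, theta2 = 0.1)
  expect_error(model_spec(lg, agent_effect = two, pk = list(pk_preset("MEM", 1))),
               "exactly two")
  expect_error(model_spec(lg, dead_model = "gompertz_difference"), "gompertz growth")
  expect_error(model_spec(gm, dead_model = "rate_coupled"), "gompertz_difference")
  expect_error(model_spec(lg, post_plateau = list(variant = "turnover", kl = 1)),
               "kp > 0")
  expect_error(model_spec(lg, pk = list(pk_preset("MEM", 1))), "without an agent_effect")
})

test_that("the rhs implements the coupled live/dead/endogenous equations", {
  lg <- growth_params("logistic", B0 = 0.5, kb = 2, Bmax = 4)
  sp <- model_spec(lg, dead_model = "rate_coupled")
  d <- biofilm_rhs(sp, 1, c(B = 1, D = 0, X = 1))
  expect_equal(d[["B"]], 2 * 1 * (1 - 1 / 4))
  expect_equal(d[["D"]], 2 * 1^2 / 4)             # logistic intrinsic loss
  # extinction is absorbing
  d0 <- biofilm_rhs(sp, 1, c(B = 0, D = 0.3, X = 1))
  expect_equal(unname(d0[c("B", "D")]), c(0, 0))
  # depletion with kl = 0 leaves X frozen
  spx <- model_spec(lg, post_plateau = list(variant = "depletion", kl = 0))
  expect_equal(biofilm_rhs(spx, 1, c(B = 1, D = 0, X = 1))[["X"]], 0)
  # bertalanffy dead equation uses kd * B^delta
  bt <- growth_params("bertalanffy", B0 = 0.5, kb = 4, kd = 2, lam = 0.25, delta = 1)
  spb <- model_spec(bt, dead_model = "rate_coupled")
  expect_equal(biofilm_rhs(spb, 0, c(B = 2, D = 0, X = 1))[["D"]], 2 * 2)
})

test_that("agent-free simulation matches the closed forms to 1e-6", {
  tt <- seq(0, 2, by = 0.05)
  for (p in list(fig1_logistic(), fig1_gompertz())) {
    tr <- simulate_trajectory(model_spec(p), tt)
    ref <- solve_growth_analytic(p, tt)
    expect_lt(max(abs(tr$B - ref) / ref), 1e-6)
  }
})

test_that("holding the agent at the BIC freezes the biofilm", {
  lg <- growth_params("logistic", B0 = 0.4, kb = 2, Bmax = 1)
  th1 <- 1.5
  bic <- bic_concentration(lg, lg$B0, th1)
  sp <- model_spec(lg, agent_effect = agent_params("linear", theta1 = th1),
                   pk = list(const_profile(bic)))
  tr <- simulate_trajectory(sp, seq(0, 5, by = 0.1))
  expect_lt(max(abs(tr$B - lg$B0)), 1e-6)
})

test_that("depletion post-plateau drives the biofilm toward zero", {
  lg <- growth_params("logistic", B0 = 0.01, kb = 3, Bmax = 1)
  sp <- model_spec(lg, post_plateau = list(variant = "depletion", kl = 0.5))
  tr <- simulate_trajectory(sp, seq(0, 40, by = 0.1))
  expect_gt(max(tr$B), 5 * tr$B[1])                  # rises first
  expect_lt(tr$B[length(tr$B)], 0.01 * max(tr$B))    # then declines to ~0
  expect_equal(tr$X[1], 1)
  # X(t) = 1 - kl * int B ds (quadrature on the simulated path)
  cumB <- c(0, cumsum((tr$B[-1] + tr$B[-length(tr$B)]) / 2 * diff(tr$times)))
  expect_lt(max(abs(tr$X - (1 - 0.5 * cumB))), 1e-3)  # trapezoid-limited check
})

test_that("turnover post-plateau settles at B* = kp/kl", {
  lg <- growth_params("logistic", B0 = 0.01, kb = 3, Bmax = 1)
  kp <- 0.2; kq <- 0.5; kl <- 0.8
  sp <- model_spec(lg, post_plateau = list(variant = "turnover",
                                           kl = kl, kp = kp, kq = kq))
  tr <- simulate_trajectory(sp, seq(0, 400, by = 0.5))
  expect_equal(tr$X[1], kp / kq)
  expect_equal(tr$B[length(tr$B)], kp / kl, tolerance = 1e-3)
})

test_that("the depletion variant with kl=0 reproduces plain growth", {
  lg <- fig1_logistic()
  sp <- model_spec(lg, post_plateau = list(variant = "depletion", kl = 0))
  tt <- seq(0, 2, by = 0.1)
  tr <- simulate_trajectory(sp, tt)
  expect_equal(tr$B, solve_growth_analytic(lg, tt), tolerance = 1e-7)
  expect_equal(tr$X, rep(1, length(tt)))
})

test_that("dormancy holds the state then replays the unlagged trajectory", {
  lag <- growth_params("logistic", B0 = 0.01, kb = 3, Bmax = 1, t_lag = 0.6)
  tr <- simulate_trajectory(model_spec(lag), seq(0, 3, by = 0.2))
  expect_equal(tr$B[tr$times <= 0.601], rep(0.01, 4), tolerance = 1e-9)
  free <- simulate_trajectory(model_spec(growth_params("logistic", B0 = 0.01,
                                                       kb = 3, Bmax = 1)),
                              seq(0, 2.4, by = 0.2))
  expect_equal(tr$B[tr$times >= 0.6], free$B, tolerance = 1e-6)
})

test_that("mass balance d(B+D)/dt = kb*B holds on the simulated paths", {
  lg <- growth_params("logistic", B0 = 0.05, kb = 2, Bmax = 1)
  sp0 <- model_spec(lg, dead_model = "rate_coupled")
  tr0 <- simulate_trajectory(sp0, seq(0, 4, by = 0.004))
  expect_lt(conservation_check(tr0, sp0), 1e-5 * max(lg$kb * tr0$B))

  spA <- model_spec(growth_params("logistic", B0 = 5, kb = 0.3, Bmax = 40),
                    agent_effect = agent_params("linear", theta1 = 0.003),
                    pk = list(pk_preset("MEM", 24)), dead_model = "rate_coupled")
  trA <- simulate_trajectory(spA, seq(0, 48, by = 0.02))
  expect_lt(conservation_check(trA, spA),
            1e-5 * max(0.3 * trA$B))
  expect_error(conservation_check(tr0, model_spec(fig1_gompertz())), "logistic")
})

test_that("killed biomass accumulates monotonically in the dead compartment", {
  sp <- model_spec(growth_params("logistic", B0 = 5, kb = 0.3, Bmax = 40),
                   agent_effect = agent_params("linear", theta1 = 0.01),
                   pk = list(pk_preset("MEM", c(12, 24))), dead_model = "rate_coupled")
  tr <- simulate_trajectory(sp, seq(0, 48, by = 0.25))
  expect_true(all(diff(tr$D) > -1e-9))
  expect_true(all(tr$D >= 0))
})

test_that("gompertz dead biofilm is the exponential-growth difference", {
  gm <- growth_params("gompertz", B0 = 0.01, kb = 1, Bmax = 1)
  sp <- model_spec(gm, dead_model = "gompertz_difference")
  tt <- seq(0, 3, by = 0.25)
  tr <- simulate_trajectory(sp, tt)
  expect_equal(tr$D, 0.01 * exp(tt) - tr$B, tolerance = 1e-8)
})

test_that("stimulatory agents add growth and produce no dead biomass", {
  base <- growth_params("exponential", B0 = 1, kb = 0.1)
  sp <- model_spec(base, agent_effect = agent_params("linear", theta1 = 0.05),
                   effect_sign = "stimulate", pk = list(const_profile(2, 50)),
                   dead_model = "rate_coupled")
  tr <- simulate_trajectory(sp, seq(0, 10, by = 0.5))
  expect_equal(tr$B, 1 * exp((0.1 + 0.05 * 2) * tr$times), tolerance = 1e-6)
  expect_equal(tr$D, rep(0, length(tr$times)))
})

test_that("threshold kills switch off exactly at the concentration crossing", {
  lg <- growth_params("logistic", B0 = 5, kb = 0.3, Bmax = 40)
  mem <- pk_preset("MEM", 24)
  hi <- model_spec(lg, agent_effect = agent_params("threshold", theta1 = 0.003,
                                                   theta2 = 200),
                   pk = list(mem))
  ctrl <- simulate_trajectory(model_spec(lg), seq(0, 48, by = 1))
  never <- simulate_trajectory(hi, seq(0, 48, by = 1))
  expect_equal(never$B, ctrl$B, tolerance = 1e-8)   # threshold above peak: no effect
  lo <- model_spec(lg, agent_effect = agent_params("threshold", theta1 = 0.003,
                                                   theta2 = 1e-6),
                   pk = list(mem))
  lin <- model_spec(lg, agent_effect = agent_params("linear", theta1 = 0.003),
                    pk = list(mem))
  expect_equal(simulate_trajectory(lo, seq(0, 48, by = 1))$B,
               simulate_trajectory(lin, seq(0, 48, by = 1))$B, tolerance = 1e-4)
})

test_that("the fast logistic path agrees with the adaptive solver", {
  sp <- model_spec(growth_params("logistic", B0 = 1, kb = 0.0425, Bmax = 39.5),
                   agent_effect = two_agent_params("linear_interaction",
                                                   theta1 = 0.00301, theta2 = 0.00352,
                                                   theta3 = 0.000473),
                   pk = list(pk_preset("MEM", c(74, 82, 90), mode = "infusion"),
                             pk_preset("TOB", c(74, 82, 90))))
  tt <- seq(0, 168, by = 12)
  ref <- simulate_trajectory(sp, sort(unique(c(0, tt))))$B[match(tt, sort(unique(c(0, tt))))]
  fast <- biofilmkin:::.sim_live_fast(1, 0.0425, 39.5, biofilmkin:::.fast_kill_coefs(sp),
                                      0, biofilmkin:::.fast_cache(sp, tt))
  expect_lt(max(abs(fast - ref) / ref), 1e-4)
})

test_that("trajectories export tidily with deterministic column order", {
  sp <- model_spec(growth_params("logistic", B0 = 5, kb = 0.3, Bmax = 40),
                   agent_effect = agent_params("linear", theta1 = 0.003),
                   pk = list(pk_preset("MEM", 24)), dead_model = "rate_coupled")
  df <- as.data.frame(simulate_trajectory(sp, seq(0, 48, by = 12)))
  expect_named(df, c("time_h", "variable", "value"))
  expect_setequal(unique(df$variable), c("live", "dead", "conc:MEM"))
})
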