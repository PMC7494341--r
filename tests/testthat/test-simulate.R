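test_that("deterministic trajectories match closed-form solutions", {
  cfg <- make_preset("WT", t_end = 2)
  traj <- integrate_ode(cfg)
  expect_equal(traj$time[1], 0)
  expect_equal(as.numeric(traj[1, c("A", "R", "T", "P")]),
               c(cfg$A0, cfg$R0, cfg$T0, cfg$P0))
  # GliA half-life: A(ln 2 / lambda) = 0.5
  t_half <- log(2) / 0.86
  A_half <- stats::approx(traj$time, traj$A, xout = t_half)$y
  expect_equal(A_half, 0.5, tolerance = 1e-6)
  expect_equal(traj$A, exp(-0.86 * traj$time), tolerance = 1e-7)
  expect_equal(traj$R, exp(-0.86 * traj$time), tolerance = 1e-7)

  # fully decoupled Tgfb: linear ODE with closed form 1 - exp(-v_T t)
  bare <- model_config(epsilon = 0, t_end = 0.5)
  tb <- integrate_ode(bare)
  expect_equal(tb$T, 1 - exp(-50 * tb$time), tolerance = 1e-6)
})

test_that("halving the step changes the deterministic path negligibly", {
  cfg <- make_preset("hysteresis", t_end = 3)
  t1 <- integrate_ode(cfg, dt = 1e-3, record_dt = 0.01)
  t2 <- integrate_ode(cfg, dt = 5e-4, record_dt = 0.01)
  common <- intersect(round(t1$time, 6), round(t2$time, 6))
  i1 <- match(common, round(t1$time, 6)); i2 <- match(common, round(t2$time, 6))
  for (v in c("A", "R", "T", "P")) {
    expect_lt(max(abs(t1[[v]][i1] - t2[[v]][i2])), 1e-6)
  }
})

test_that("the noise-free SDE path agrees with the ODE solution", {
  cfg <- make_preset("WT", epsilon = 0, t_end = 3)
  sde <- integrate_sde(cfg, seed = 1, record_dt = 0.01)
  ode <- integrate_ode(cfg, record_dt = 0.01)
  i <- match(round(sde$time, 6), round(ode$time, 6))
  for (v in c("A", "R", "T", "P")) {
    # Euler vs RK4: O(dt) discretization difference only
    expect_lt(max(abs(sde[[v]] - ode[[v]][i])), 0.02)
  }
})

test_that("correlated noise with equal rates keeps GliA and GliR identical", {
  cfg <- make_preset("hysteresis", epsilon = 0.3, correlated_AR = TRUE,
                     t_end = 2)
  traj <- integrate_sde(cfg, seed = 5)
  expect_equal(traj$A, traj$R)
  unc <- integrate_sde(update_config(cfg, correlated_AR = FALSE), seed = 5)
  expect_false(isTRUE(all.equal(unc$A, unc$R)))
})

test_that("the ensemble mean of GliA follows its analytic expectation", {
  # multiplicative noise leaves E[A(t)] = exp(-lambda t) (martingale factor)
  cfg <- make_preset("direct", epsilon = 0.2, t_end = 2)
  ens <- run_ensemble(cfg, 2000, seed = 9, keep = c("A", "P"),
                      record_dt = 0.25)
  mean_A <- rowMeans(ens$paths$A)
  expect_equal(mean_A, exp(-0.86 * ens$times), tolerance = 0.02)
})

test_that("ensemble summaries behave at the degenerate corners", {
  cfg <- make_preset("WT", t_end = 1)
  one <- run_ensemble(cfg, 1, seed = 3, keep = c("A", "R", "T", "P"))
  sm <- tidy(one)
  med_P <- sm$median[sm$variable == "P"]
  expect_equal(med_P, one$paths$P[, 1])

  det <- run_ensemble(update_config(cfg, epsilon = 0), 5, seed = 3)
  sm <- tidy(det)
  expect_equal(sm$upper - sm$lower, rep(0, nrow(sm)))
  expect_true(all(sm$lower <= sm$median & sm$median <= sm$upper))
})

test_that("the 90% envelope covers the deterministic path", {
  cfg <- make_preset("WT", epsilon = 0.05, t_end = 3)
  ens <- run_ensemble(cfg, 300, seed = 17, record_dt = 0.05)
  det <- integrate_ode(update_config(cfg, epsilon = 0), record_dt = 0.05)
  sm <- tidy(ens)
  smP <- sm[sm$variable == "P", ]
  i <- match(round(smP$time, 6), round(det$time, 6))
  covered <- smP$lower <= det$P[i] + 1e-9 & det$P[i] <= smP$upper + 1e-9
  expect_gte(mean(covered), 0.9)
})

test_that("stochastic runs are reproducible and bounded", {
  cfg <- make_preset("hysteresis", epsilon = 0.3, t_end = 2)
  a <- integrate_sde(cfg, seed = 11)
  b <- integrate_sde(cfg, seed = 11)
  expect_identical(a, b)
  c_ <- integrate_sde(cfg, seed = 12)
  expect_false(identical(a$P, c_$P))
  # non-negativity after clipping; excursions above 1 are limited to the
  # stationary Ornstein-Uhlenbeck scale eps/sqrt(2v) of the restoring drift
  for (v in c("A", "R", "T", "P")) expect_true(all(a[[v]] >= 0))
  expect_true(all(a$T <= 1 + 6 * 0.3 / sqrt(2 * cfg$v_T)))
  expect_true(all(a$P <= 1 + 6 * 0.3 / sqrt(2 * cfg$v_P)))
})

test_that("ensemble statistics are stable under base-seed permutation", {
  cfg <- make_preset("direct", epsilon = 0.1, t_end = 3)
  s1 <- switch_statistics(likelihood_path(run_ensemble(cfg, 400, seed = 1)))
  s2 <- switch_statistics(likelihood_path(run_ensemble(cfg, 400, seed = 2)))
  expect_equal(s1$delta_t, s2$delta_t, tolerance = 0.1)
  expect_equal(s1$t_switch, s2$t_switch, tolerance = 0.05)
})
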