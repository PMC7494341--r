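test_that("the gamma threshold keeps mean 0.4 at every noise level", {
  for (eta in c(0.25, 0.5, 1, 2, 4)) {
    rd <- readout_model(eta)
    expect_equal(rd$k * rd$theta, 0.4)
    expect_equal(rd$k * rd$theta^2, 0.016 * eta)
  }
  expect_error(readout_model(0), "positive")
  expect_error(readout_model(-1), "positive")
})

test_that("the differentiation likelihood is the gamma CDF of Phox2b", {
  rd <- readout_model(1)
  expect_equal(mn_likelihood(0, rd), 0)
  expect_lt(abs(mn_likelihood(50, rd) - 1), 1e-12)
  # CDF at the mean exceeds 0.5 (gamma median < mean), against a numeric
  # quadrature oracle of the gamma density
  dens <- function(x) x^(rd$k - 1) * exp(-x / rd$theta) /
    (gamma(rd$k) * rd$theta^rd$k)
  oracle <- stats::integrate(dens, 0, 0.4, rel.tol = 1e-10)$value
  expect_equal(mn_likelihood(0.4, rd), oracle, tolerance = 1e-7)
  expect_gt(mn_likelihood(0.4, rd), 0.5)
  expect_lt(mn_likelihood(0.4, rd), 0.6)
  # monotone non-decreasing in P
  p <- seq(0, 1, by = 0.01)
  expect_true(all(diff(mn_likelihood(p, rd)) >= 0))
})

test_that("population likelihood averages per-replicate likelihoods", {
  cfg <- make_preset("direct", epsilon = 0.2, t_end = 2)
  ens <- run_ensemble(cfg, 2, seed = 4)
  rd <- readout_model(1)
  lik <- likelihood_path(ens, rd)
  manual <- (mn_likelihood(ens$paths$P[, 1], rd) +
               mn_likelihood(ens$paths$P[, 2], rd)) / 2
  expect_equal(lik$likelihood, manual)
  # and differs in general from the likelihood of the mean path
  mp <- likelihood_path(ens, rd, method = "mean_path")
  expect_false(isTRUE(all.equal(lik$likelihood, mp$likelihood)))
})

test_that("switch statistics interpolate crossings linearly", {
  lin <- tibble::tibble(time = c(0, 1), likelihood = c(1, 0))
  st <- switch_statistics(lin)
  expect_equal(st$t_95, 0.05)
  expect_equal(st$t_05, 0.95)
  expect_equal(st$delta_t, 0.9)
  expect_equal(st$t_switch, 0.5)
  expect_false(st$no_switch)

  flat <- tibble::tibble(time = 0:5, likelihood = rep(1, 6))
  st <- switch_statistics(flat)
  expect_true(st$no_switch)
  expect_true(is.na(st$t_05))

  low <- tibble::tibble(time = 0:5, likelihood = rep(0.5, 6))
  expect_true(switch_statistics(low)$no_mn_phase)
})

test_that("direct-network transition interval matches a root-finding oracle", {
  # chain: P(t) = H+(e^{-lambda t}, h_AP) at quasi-steady Phox2b, so the
  # likelihood crossing solves GammaCDF(H+(e^{-lambda t}, 0.25)) = level.
  cfg <- make_preset("direct", epsilon = 0)
  lik <- likelihood_path(integrate_ode(cfg, record_dt = 0.002),
                         readout_model(1))
  st <- switch_statistics(lik)
  oracle_cross <- function(level) {
    f <- function(t) {
      stats::pgamma(hill_pos(exp(-0.86 * t), 0.25), shape = 10,
                    scale = 0.04) - level
    }
    stats::uniroot(f, c(0.01, 6), tol = 1e-10)$root
  }
  # quasi-steady approximation is good to ~1/v_P
  expect_equal(st$t_95, oracle_cross(0.95), tolerance = 0.02)
  expect_equal(st$t_05, oracle_cross(0.05), tolerance = 0.02)
  expect_equal(st$delta_t, oracle_cross(0.05) - oracle_cross(0.95),
               tolerance = 0.02)
})

test_that("transition interval widens with threshold noise", {
  cfg <- make_preset("direct", epsilon = 0)
  traj <- integrate_ode(cfg, record_dt = 0.005)
  dts <- vapply(c(0.25, 0.5, 1, 2, 4), function(eta) {
    switch_statistics(likelihood_path(traj, readout_model(eta)))$delta_t
  }, numeric(1))
  expect_true(all(diff(dts) > 0))
})

test_that("switch time scales inversely with the Gli decay rate", {
  t_sw <- vapply(c(0.43, 0.86, 1.72), function(lam) {
    cfg <- make_preset("direct", epsilon = 0, lambda_A = lam,
                       lambda_R = lam, t_end = 12)
    switch_statistics(likelihood_path(integrate_ode(cfg,
                                                    record_dt = 0.005),
                                      readout_model(1)))$t_switch
  }, numeric(1))
  prod <- t_sw * c(0.43, 0.86, 1.72)
  expect_equal(prod[2] / prod[1], 1, tolerance = 0.02)
  expect_equal(prod[3] / prod[2], 1, tolerance = 0.02)
})
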