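# Independent brute-force oracle: count sign changes of the production
# balance on a very dense Tgfb grid, written out from the model equations
# without using the package's root finder.
oracle_roots <- function(cfg, R, A = 0, n = 200001) {
  Tg <- seq(0, 1, length.out = n)
  hp <- function(x, h) x^2 / (h^2 + x^2)
  hw_pos <- function(x, h, w) (1 - w) + w * hp(x, h)
  hw_neg <- function(x, h, w) (1 - w) + w * (1 - hp(x, h))
  base <- (1 - cfg$omega_TT) *
    hw_pos(A, ifelse(cfg$omega_AT > 0, cfg$h_AT, 1), cfg$omega_AT) *
    hw_neg(R, ifelse(cfg$omega_RT > 0, cfg$h_RT, 1), cfg$omega_RT)
  self <- if (cfg$omega_TT > 0) cfg$omega_TT * hp(Tg, cfg$h_TT) else 0
  g <- base + self - Tg
  s <- sign(g)
  s[s == 0] <- -1  # a root on a grid point is still a crossing
  idx <- which(s[-n] * s[-1] < 0)
  (Tg[idx] + Tg[idx + 1]) / 2
}

# local copy of the balance for the forward-integration cross-check
tgfb_balance_pub <- function(T, R, cfg) {
  (1 - cfg$omega_TT) * hill_neg(R, cfg$h_RT) +
    cfg$omega_TT * hill_pos(T, cfg$h_TT) - T
}

test_that("steady states match the dense-grid oracle", {
  hys <- make_preset("hysteresis")
  # bistable window at intermediate/high GliR, single state at low GliR
  for (R in c(0, 0.1, 0.3, 0.5, 1)) {
    st <- t_steady_states(hys, R = R)
    orc <- oracle_roots(hys, R)
    expect_equal(nrow(st), length(orc))
    expect_equal(st$T_star, orc, tolerance = 1e-4)
  }
  expect_equal(nrow(t_steady_states(hys, R = 0.5)), 3)
  expect_equal(nrow(t_steady_states(hys, R = 0.1)), 1)

  # without self-activation the balance is linear in T: unique root equal
  # to the production term
  relay <- make_preset("relay")
  for (R in c(0, 0.2, 1, 5)) {
    st <- t_steady_states(relay, R = R)
    expect_equal(nrow(st), 1)
    expect_equal(st$T_star, hill_neg(R, 0.15), tolerance = 1e-8)
    expect_true(st$stable)
  }
  # full repression at large GliR
  expect_lt(t_steady_states(relay, R = 100)$T_star, 1e-3)
})

test_that("stability labels agree with forward integration at frozen Gli", {
  hys <- make_preset("hysteresis", epsilon = 0)
  st <- t_steady_states(hys, R = 0.5)
  expect_equal(st$stable, c(TRUE, FALSE, TRUE))
  relax_to <- function(T0) {
    T <- T0
    for (i in 1:4000) {
      T <- T + 1e-3 * 50 * tgfb_balance_pub(T, 0.5, hys)
    }
    T
  }
  # perturbing off each stable root returns to it; the unstable root
  # separates the basins
  expect_equal(relax_to(st$T_star[1] + 0.01), st$T_star[1],
               tolerance = 1e-3)
  expect_equal(relax_to(st$T_star[3] - 0.01), st$T_star[3],
               tolerance = 1e-3)
  expect_equal(relax_to(st$T_star[2] - 0.01), st$T_star[1],
               tolerance = 1e-3)
  expect_equal(relax_to(st$T_star[2] + 0.01), st$T_star[3],
               tolerance = 1e-3)
})

test_that("the hysteretic row has a one-way bistable window", {
  bd <- sweep_bifurcation(make_preset("hysteresis"),
                          R_grid = seq(0, 1, length.out = 201))
  g <- glance(bd)
  expect_true(g$one_way)
  up <- bd$fold_points$R_fold[bd$fold_points$type == "up"]
  expect_length(up, 1)
  # oracle bracket for the fold: root count changes between these R
  expect_equal(length(oracle_roots(make_preset("hysteresis"), 0.235)), 1)
  expect_equal(length(oracle_roots(make_preset("hysteresis"), 0.245)), 3)
  expect_gt(up, 0.235); expect_lt(up, 0.245)
  # return fold beyond any attainable GliR
  expect_true(is.infinite(g$R_down) && g$R_up < g$R_down)
  # between two stable branches there is an unstable one
  tri <- dplyr::filter(bd$branches, R > up) |>
    dplyr::group_by(R) |> dplyr::summarise(pat = paste(stable, collapse = ""))
  expect_true(all(tri$pat == "TRUEFALSETRUE"))
})

test_that("weak self-activation and no self-activation yield no folds", {
  bd <- sweep_bifurcation(make_preset("self_activation"),
                          R_grid = seq(0, 1, length.out = 101))
  expect_equal(nrow(bd$fold_points), 0)
  expect_false(bd$one_way)

  bd0 <- sweep_bifurcation(make_preset("relay"),
                           R_grid = seq(0, 1, length.out = 101))
  expect_equal(nrow(bd0$fold_points), 0)
  # single branch, monotone in R
  expect_true(all(diff(bd0$branches$T_star) < 0))
})

test_that("fold locations are invariant under scan-grid refinement", {
  up_at <- function(n_grid) {
    bd <- sweep_bifurcation(make_preset("hysteresis"),
                            R_grid = seq(0.1, 0.4, length.out = 31),
                            n_grid = n_grid)
    bd$fold_points$R_fold[bd$fold_points$type == "up"]
  }
  expect_equal(up_at(2001), up_at(4001), tolerance = 1e-4)
})

test_that("a slow GliR decline jumps to high Tgfb at the static up-fold", {
  # quasi-static passage: a slow decay makes the dynamic jump collapse
  # onto the fold found by the static scan
  lam <- 0.1
  hys <- make_preset("hysteresis", epsilon = 0, t_end = 25,
                     lambda_A = lam, lambda_R = lam)
  bd <- sweep_bifurcation(hys, R_grid = seq(0, 1, length.out = 201))
  R_up <- bd$fold_points$R_fold[bd$fold_points$type == "up"]
  traj <- integrate_ode(hys, record_dt = 0.002)
  # time at which T crosses the unstable gap upward
  t_jump <- traj$time[which(traj$T > 0.5)[1]]
  R_at_jump <- exp(-lam * t_jump)
  # the jump happens as GliR passes the fold, with a small dynamic lag
  expect_lte(R_at_jump, R_up)
  expect_lt(R_up - R_at_jump, 0.02)
})
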