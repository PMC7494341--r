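#' Deterministic integration of the timer network
#'
#' Integrates the four-variable system with a fixed-step classical
#' Runge-Kutta scheme (via \pkg{deSolve}) on the grid `seq(0, t_end, dt)`,
#' ignoring the kinetic noise amplitude. GliA and GliR follow their
#' closed-form exponentials to integration tolerance.
#'
#' @param config A [model_config()].
#' @param dt Step size override (days); defaults to `config$dt`.
#' @param record_dt Output thinning interval (days); defaults to `dt`
#'   (every step).
#' @return A tibble of class `gli_trajectory` with columns `time`, `A`,
#'   `R`, `T`, `P` and attributes `config` and `mode`.
#' @examples
#' traj <- integrate_ode(make_preset("direct", t_end = 2))
#' head(traj)
#' @export
integrate_ode <- function(config, dt = config$dt, record_dt = dt) {
  stopifnot(inherits(config, "gli_config"))
  times <- seq(0, config$t_end, by = dt)
  y0 <- c(A = config$A0, R = config$R0, T = config$T0, P = config$P0)
  deriv <- function(t, y, parms) {
    d <- model_rhs(y[["A"]], y[["R"]], y[["T"]], y[["P"]], config = parms)
    list(c(d$dA, d$dR, d$dT, d$dP))
  }
  out <- deSolve::ode(y = y0, times = times, func = deriv, parms = config,
                      method = "rk4")
  out <- as.data.frame(out)
  bad <- !stats::complete.cases(out) |
    !apply(is.finite(as.matrix(out)), 1, all)
  if (any(bad)) {
    row <- which(bad)[1]
    var <- names(out)[which(!is.finite(as.numeric(out[row, ])))[1]]
    stop(sprintf(
      "Integration became non-finite in variable `%s` at t = %g; reduce dt.",
      var, out$time[row]), call. = FALSE)
  }
  keep <- thin_index(length(times), max(1L, round(record_dt / dt)))
  new_trajectory(out[keep, , drop = FALSE], config, mode = "ode", seed = NA)
}

#' Stochastic integration with multiplicative noise
#'
#' Integrates the system as the Ito stochastic differential equation
#' `dx = f(x) dt + epsilon * x * dW` (one independent Wiener process per
#' variable) with a fixed-step Euler-Maruyama scheme at `config$dt`. When
#' `correlated_AR` is set, GliA and GliR receive identical Wiener
#' increments; otherwise all four increments are independent. States are
#' clipped at 0 after each step (zero is absorbing for the exact
#' multiplicative-noise process). With `epsilon = 0` the path reproduces
#' the deterministic trajectory up to the Euler-vs-RK4 discretization
#' difference (order `dt`).
#'
#' @param config A [model_config()].
#' @param seed Integer RNG seed (required; the global RNG state is
#'   restored afterwards).
#' @param record_dt Output thinning interval (days).
#' @return A `gli_trajectory` tibble (see [integrate_ode()]) with a `seed`
#'   attribute.
#' @examples
#' traj <- integrate_sde(make_preset("direct", t_end = 2), seed = 1)
#' @export
integrate_sde <- function(config, seed, record_dt = 0.005) {
  sim <- sim_engine(config, m = 1L, seed = seed, record_dt = record_dt,
                    keep = c("A", "R", "T", "P"), summarize = FALSE)
  df <- data.frame(time = sim$times,
                   A = sim$paths$A[, 1], R = sim$paths$R[, 1],
                   T = sim$paths$T[, 1], P = sim$paths$P[, 1])
  new_trajectory(df, config, mode = "sde", seed = seed)
}

#' Ensemble of stochastic replicates with quantile envelopes
#'
#' Runs `n_replicates` independent stochastic paths from a single base
#' seed and summarizes each variable by its median and a quantile envelope
#' (default 5th-95th percentile, the 90% band) at every recorded time.
#' Per-replicate Phox2b paths are retained (by default) so the population
#' differentiation likelihood can be computed per replicate and then
#' averaged; see [likelihood_path()].
#'
#' @param config A [model_config()].
#' @param n_replicates Number of replicates (>= 1).
#' @param seed Integer base seed; all replicate noise derives from it.
#' @param quantiles Lower/upper envelope probabilities.
#' @param record_dt Output thinning interval (days).
#' @param keep Character subset of `c("A","R","T","P")`: per-replicate
#'   paths to retain as matrices (time x replicate).
#' @return An object of class `gli_ensemble`: a list with `times`,
#'   `summary` (long tibble: `time`, `variable`, `median`, `lower`,
#'   `upper`), `paths`, `n_replicates`, `config`, `seed`, `quantiles`.
#' @examples
#' ens <- run_ensemble(make_preset("direct", t_end = 2), 50, seed = 1)
#' dplyr::filter(tidy(ens), variable == "A")
#' @export
run_ensemble <- function(config, n_replicates, seed,
                         quantiles = c(0.05, 0.95), record_dt = 0.005,
                         keep = "P") {
  stopifnot(n_replicates >= 1)
  sim <- sim_engine(config, m = as.integer(n_replicates), seed = seed,
                    record_dt = record_dt, keep = keep, summarize = TRUE,
                    quantiles = quantiles)
  structure(
    list(times = sim$times, summary = sim$summary, paths = sim$paths,
         n_replicates = as.integer(n_replicates), config = config,
         seed = seed, quantiles = quantiles),
    class = "gli_ensemble")
}

#' @export
print.gli_ensemble <- function(x, ...) {
  cat(sprintf(
    "<gli_ensemble> %d replicates, %d time points, epsilon = %g, eta = %g\n",
    x$n_replicates, length(x$times), x$config$epsilon, x$config$eta))
  invisible(x)
}

# ---- shared fixed-step Euler-Maruyama engine ------------------------------
#
# Steps m cells/replicates in lockstep as column vectors. `nb` is an
# m x k matrix of neighbour indices; when supplied, the Tgfb input of the
# self-activation and Phox2b-repression terms is replaced by the
# diffusion-averaged field 0.5*T + 0.5*<T>_nn (the -T decay keeps the own
# T). All four noise streams are always drawn so that correlated and
# uncorrelated runs from the same seed share identical randomness for T
# and P (paired comparisons).
sim_engine <- function(config, m, seed = NULL, record_dt = 0.005,
                       nb = NULL, keep = "P", summarize = TRUE,
                       quantiles = c(0.05, 0.95)) {
  stopifnot(inherits(config, "gli_config"))
  dt <- config$dt
  n_steps <- as.integer(round(config$t_end / dt))
  every <- max(1L, as.integer(round(record_dt / dt)))
  rec_steps <- unique(c(seq(0L, n_steps, by = every), n_steps))
  times <- rec_steps * dt
  n_rec <- length(rec_steps)

  if (!is.null(seed)) withr::local_seed(as.integer(seed))

  A <- rep(config$A0, m); R <- rep(config$R0, m)
  T <- rep(config$T0, m); P <- rep(config$P0, m)

  keep <- intersect(c("A", "R", "T", "P"), keep)
  paths <- stats::setNames(
    lapply(keep, function(v) matrix(NA_real_, n_rec, m)), keep)
  qmat <- if (summarize) {
    array(NA_real_, dim = c(n_rec, 4L, 3L),
          dimnames = list(NULL, c("A", "R", "T", "P"),
                          c("median", "lower", "upper")))
  }

  eps <- config$epsilon
  sq <- sqrt(dt)
  la <- config$lambda_A; lr <- config$lambda_R
  vT <- config$v_T; vP <- config$v_P
  record <- function(slot) {
    state <- list(A = A, R = R, T = T, P = P)
    for (v in keep) paths[[v]][slot, ] <<- state[[v]]
    if (summarize) {
      for (v in c("A", "R", "T", "P")) {
        qs <- stats::quantile(state[[v]], c(0.5, quantiles), names = FALSE,
                              type = 7)
        qmat[slot, v, ] <<- qs
      }
    }
  }

  slot <- 1L
  record(slot)
  for (i in seq_len(n_steps)) {
    T_eff <- if (is.null(nb)) T else {
      0.5 * T + 0.5 * rowMeans(matrix(T[nb], nrow = m))
    }
    d <- model_rhs(A, R, T, P, config = config, T_eff = T_eff)
    if (eps > 0) {
      zA <- stats::rnorm(m); zR <- stats::rnorm(m)
      zT <- stats::rnorm(m); zP <- stats::rnorm(m)
      if (config$correlated_AR) zR <- zA
      A <- A + d$dA * dt + eps * A * sq * zA
      R <- R + d$dR * dt + eps * R * sq * zR
      T <- T + d$dT * dt + eps * T * sq * zT
      P <- P + d$dP * dt + eps * P * sq * zP
      A <- pmax(A, 0); R <- pmax(R, 0); T <- pmax(T, 0); P <- pmax(P, 0)
    } else {
      A <- A + d$dA * dt
      R <- R + d$dR * dt
      T <- T + d$dT * dt
      P <- P + d$dP * dt
    }
    if (i == rec_steps[slot + 1L]) {
      slot <- slot + 1L
      if (any(!is.finite(A)) || any(!is.finite(T)) ||
          any(!is.finite(R)) || any(!is.finite(P))) {
        bad <- c(A = any(!is.finite(A)), R = any(!is.finite(R)),
                 T = any(!is.finite(T)), P = any(!is.finite(P)))
        stop(sprintf(
          "Simulation became non-finite in `%s` at t = %g; reduce dt.",
          names(bad)[bad][1], i * dt), call. = FALSE)
      }
      record(slot)
    }
  }

  summary <- NULL
  if (summarize) {
    summary <- tidyr::expand_grid(
      variable = factor(c("A", "R", "T", "P"),
                        levels = c("A", "R", "T", "P")),
      time = times) |>
      dplyr::arrange(.data$variable, .data$time)
    summary$median <- as.vector(qmat[, , "median"])
    summary$lower <- as.vector(qmat[, , "lower"])
    summary$upper <- as.vector(qmat[, , "upper"])
    summary <- dplyr::select(summary, "time", "variable", "median",
                             "lower", "upper")
  }
  list(times = times, paths = paths, summary = summary)
}

thin_index <- function(n, every) {
  unique(c(seq(1L, n, by = every), n))
}

new_trajectory <- function(df, config, mode, seed) {
  out <- tibble::as_tibble(df[, c("time", "A", "R", "T", "P")])
  class(out) <- c("gli_trajectory", class(out))
  attr(out, "config") <- config
  attr(out, "mode") <- mode
  attr(out, "seed") <- seed
  out
}
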