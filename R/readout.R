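#' Gamma-threshold differentiation readout
#'
#' The likelihood that a cell with Phox2b level `P` differentiates as a
#' motor neuron is modelled as the cumulative distribution function of a
#' gamma-distributed threshold with shape `k = 10 / eta` and scale
#' `theta = 0.04 * eta`. The threshold mean is `k * theta = 0.4` for every
#' noise level, while the variance `k * theta^2 = 0.016 * eta` grows
#' linearly with `eta`, so `eta` tunes readout noisiness without moving
#' the average threshold.
#'
#' @param eta Threshold-noise level, `> 0`.
#' @return An object of class `gli_readout` with fields `eta`, `k`,
#'   `theta`.
#' @examples
#' rd <- readout_model(eta = 1)
#' rd$k * rd$theta          # 0.4, independent of eta
#' mn_likelihood(0.4, rd)
#' @export
readout_model <- function(eta = 1) {
  if (!is.numeric(eta) || length(eta) != 1 || !is.finite(eta) || eta <= 0) {
    stop("`eta` must be a single positive number.", call. = FALSE)
  }
  structure(list(eta = eta, k = 10 / eta, theta = 0.04 * eta),
            class = "gli_readout")
}

#' @export
print.gli_readout <- function(x, ...) {
  cat(sprintf(
    "<gli_readout> eta = %g (gamma shape k = %g, scale theta = %g;\n",
    x$eta, x$k, x$theta))
  cat(sprintf("  threshold mean = %.3g, variance = %.3g)\n",
              x$k * x$theta, x$k * x$theta^2))
  invisible(x)
}

#' @describeIn readout_model Likelihood of motor-neuron differentiation at
#'   Phox2b level `P` (vectorized): the regularized lower incomplete gamma
#'   function evaluated at `P`.
#' @param P Phox2b concentration(s), non-negative.
#' @param readout A `gli_readout`.
#' @export
mn_likelihood <- function(P, readout = readout_model()) {
  stopifnot(inherits(readout, "gli_readout"))
  if (any(!is.finite(P)) || any(P < 0)) {
    stop("`P` must be finite and non-negative.", call. = FALSE)
  }
  out <- stats::pgamma(P, shape = readout$k, scale = readout$theta)
  dim(out) <- dim(P)
  out
}

#' Differentiation-likelihood time course
#'
#' Maps a Phox2b trajectory onto the motor-neuron differentiation
#' likelihood. For a single trajectory this is the pointwise gamma CDF of
#' its `P` column. For an ensemble or lattice the likelihood is computed
#' per replicate/cell first and then averaged across them at each time
#' point — the population likelihood, which preserves cell-to-cell
#' variability (it is *not* the likelihood of the mean Phox2b path; set
#' `method = "mean_path"` for that alternative convention).
#'
#' @param x A `gli_trajectory`, `gli_ensemble` or `gli_lattice`.
#' @param readout A [readout_model()]; defaults to the `eta` stored in the
#'   generating config.
#' @param method For ensembles/lattices: `"population"` (average of
#'   per-replicate likelihoods, default) or `"mean_path"` (likelihood of
#'   the across-replicate mean Phox2b).
#' @param ... Passed between methods.
#' @return A tibble of class `gli_likelihood` with columns `time`,
#'   `likelihood`.
#' @examples
#' traj <- integrate_ode(make_preset("direct", t_end = 4))
#' lik <- likelihood_path(traj)
#' switch_statistics(lik)
#' @export
likelihood_path <- function(x, readout = NULL, ...) {
  UseMethod("likelihood_path")
}

default_readout <- function(x, readout) {
  if (!is.null(readout)) {
    stopifnot(inherits(readout, "gli_readout"))
    return(readout)
  }
  cfg <- if (inherits(x, "gli_trajectory")) attr(x, "config") else x$config
  readout_model(cfg$eta)
}

#' @export
likelihood_path.gli_trajectory <- function(x, readout = NULL, ...) {
  rd <- default_readout(x, readout)
  new_likelihood(x$time, mn_likelihood(x$P, rd), rd)
}

#' @export
likelihood_path.gli_ensemble <- function(x, readout = NULL,
                                         method = c("population",
                                                    "mean_path"), ...) {
  rd <- default_readout(x, readout)
  method <- match.arg(method)
  if (is.null(x$paths$P)) {
    stop("Ensemble was run with `keep` excluding \"P\"; ",
         "re-run with keep = \"P\".", call. = FALSE)
  }
  lik <- if (method == "population") {
    rowMeans(mn_likelihood(x$paths$P, rd))
  } else {
    mn_likelihood(rowMeans(x$paths$P), rd)
  }
  new_likelihood(x$times, lik, rd)
}

new_likelihood <- function(time, likelihood, readout) {
  out <- tibble::tibble(time = time, likelihood = likelihood)
  class(out) <- c("gli_likelihood", class(out))
  attr(out, "readout") <- readout
  out
}

#' Switch-time statistics of a likelihood curve
#'
#' Locates the downward crossings of a differentiation-likelihood curve:
#' `t_95` (last downward crossing of the upper level, default 0.95),
#' `t_05` (first downward crossing of the lower level, default 0.05) and
#' `t_switch` (first downward crossing of 0.5). The transition period is
#' `delta_t = t_05 - t_95`. Using the *last* upper and *first* lower
#' crossing yields the widest (conservative) interval when noise makes the
#' curve non-monotone. Crossing times are linearly interpolated between
#' grid points.
#'
#' If the curve never rises above the upper level, `t_95` is `NA` and
#' `no_mn_phase` is set; if it never falls below the lower level, `t_05`
#' is `NA` and `no_switch` is set (the expected outcome for the
#' Gli1ON:Tgfbr1-KO mutant).
#'
#' @param lik A `gli_likelihood` tibble, or any data frame with columns
#'   `time` and `likelihood`.
#' @param upper,lower,mid Crossing levels.
#' @return A one-row tibble: `t_95`, `t_05`, `t_switch`, `delta_t`,
#'   `no_mn_phase`, `no_switch`.
#' @examples
#' lik <- tibble::tibble(time = c(0, 1), likelihood = c(1, 0))
#' switch_statistics(lik)  # t_95 = 0.05, t_05 = 0.95, delta_t = 0.9
#' @export
switch_statistics <- function(lik, upper = 0.95, lower = 0.05, mid = 0.5) {
  stopifnot(all(c("time", "likelihood") %in% names(lik)))
  tm <- lik$time
  y <- lik$likelihood
  t_95 <- down_crossing(tm, y, upper, which = "last")
  t_05 <- down_crossing(tm, y, lower, which = "first")
  t_switch <- down_crossing(tm, y, mid, which = "first")
  no_mn_phase <- !any(y >= upper)
  no_switch <- !any(y <= lower)
  tibble::tibble(
    t_95 = t_95, t_05 = t_05, t_switch = t_switch,
    delta_t = t_05 - t_95,
    no_mn_phase = no_mn_phase, no_switch = no_switch)
}

# Linearly interpolated time where y crosses `level` going down.
down_crossing <- function(tm, y, level, which = c("first", "last")) {
  which <- match.arg(which)
  i <- which(y[-length(y)] >= level & y[-1] < level)
  if (length(i) == 0) return(NA_real_)
  i <- if (which == "first") i[1] else i[length(i)]
  frac <- (y[i] - level) / (y[i] - y[i + 1])
  tm[i] + frac * (tm[i + 1] - tm[i])
}
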