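#' Build a model configuration
#'
#' A configuration fully parameterizes one variant of the Gli timer network:
#' the five link weights `omega_*`, their Hill thresholds `h_*`, kinetic
#' rates, noise settings, initial conditions and the integration grid.
#' Weights of 0 switch links off, in which case the paired threshold is
#' unused and may be left `NA`.
#'
#' Variables are dimensionless: GliA (`A`) and GliR (`R`) are normalized to
#' their starting levels (`A0 = R0 = 1`), while Tgfb (`T`) and Phox2b (`P`)
#' are scaled so that their maximal steady concentration is 1. Time is in
#' days; the default decay rate 0.86/day gives the Gli proteins a half-life
#' of about 0.8 days, matching the multi-day motor-neuron window.
#'
#' `P0 = NULL` (the default) sets Phox2b to its quasi-steady value at the
#' initial GliA and Tgfb levels, `Hw+(A0, h_AP) * Hw-(T0, h_TP)`; with the
#' fast Phox2b turnover (`v_P = 90`/day) any other start decays to this
#' value within ~0.02 days.
#'
#' @param omega_AT,omega_RT,omega_TT,omega_AP,omega_TP Link weights in
#'   `[0, 1]`: GliA->Tgfb, GliR-|Tgfb, Tgfb self-activation, GliA->Phox2b,
#'   Tgfb-|Phox2b.
#' @param h_AT,h_RT,h_TT,h_AP,h_TP Hill thresholds paired with the weights;
#'   must be positive when the weight is nonzero, `NA` otherwise.
#' @param lambda_A,lambda_R Exponential decay rates of GliA and GliR (per
#'   day).
#' @param v_T,v_P Production/decay rate constants of Tgfb and Phox2b (per
#'   day).
#' @param epsilon Kinetic (multiplicative) noise amplitude, `>= 0`.
#' @param eta Threshold-noise level of the differentiation readout, `> 0`.
#' @param correlated_AR If `TRUE`, GliA and GliR receive identical Wiener
#'   increments; if `FALSE` (default) independent ones.
#' @param A0,R0,T0,P0 Initial conditions. `P0 = NULL` means quasi-steady.
#' @param t_end,dt Simulation horizon and step (days).
#' @param hill_coefficient Hill exponent, fixed at 2 in the model.
#'
#' @return An object of class `gli_config` (a validated named list).
#' @seealso [make_preset()] for the canonical network rows and mutants,
#'   [read_model_config()] / [write_model_config()] for file round-trips.
#' @examples
#' cfg <- make_preset("WT")
#' cfg$h_AP
#' @export
model_config <- function(omega_AT = 0, omega_RT = 0, omega_TT = 0,
                         omega_AP = 0, omega_TP = 0,
                         h_AT = NA_real_, h_RT = NA_real_, h_TT = NA_real_,
                         h_AP = NA_real_, h_TP = NA_real_,
                         lambda_A = 0.86, lambda_R = 0.86,
                         v_T = 50, v_P = 90,
                         epsilon = 0.1, eta = 1, correlated_AR = FALSE,
                         A0 = 1, R0 = 1, T0 = 0, P0 = NULL,
                         t_end = 6, dt = 1e-3,
                         hill_coefficient = 2) {
  cfg <- list(
    omega_AT = omega_AT, omega_RT = omega_RT, omega_TT = omega_TT,
    omega_AP = omega_AP, omega_TP = omega_TP,
    h_AT = h_AT, h_RT = h_RT, h_TT = h_TT, h_AP = h_AP, h_TP = h_TP,
    lambda_A = lambda_A, lambda_R = lambda_R, v_T = v_T, v_P = v_P,
    epsilon = epsilon, eta = eta, correlated_AR = isTRUE(correlated_AR),
    A0 = A0, R0 = R0, T0 = T0, P0 = P0,
    t_end = t_end, dt = dt, hill_coefficient = hill_coefficient
  )
  validate_config(cfg)
}

config_keys <- function() {
  c("omega_AT", "omega_RT", "omega_TT", "omega_AP", "omega_TP",
    "h_AT", "h_RT", "h_TT", "h_AP", "h_TP",
    "lambda_A", "lambda_R", "v_T", "v_P",
    "epsilon", "eta", "correlated_AR",
    "A0", "R0", "T0", "P0", "t_end", "dt", "hill_coefficient")
}

validate_config <- function(cfg) {
  num1 <- function(key, value) {
    if (!is.numeric(value) || length(value) != 1 || !is.finite(value)) {
      stop(sprintf("`%s` must be a single finite number.", key),
           call. = FALSE)
    }
    as.numeric(value)
  }
  links <- c("AT", "RT", "TT", "AP", "TP")
  for (lk in links) {
    wk <- paste0("omega_", lk)
    w <- num1(wk, cfg[[wk]])
    if (w < 0 || w > 1) {
      stop(sprintf("`%s` = %g is outside [0, 1].", wk, w), call. = FALSE)
    }
    cfg[[wk]] <- w
    hk <- paste0("h_", lk)
    h <- cfg[[hk]]
    if (w > 0) {
      cfg[[hk]] <- num1(hk, h)
      if (cfg[[hk]] <= 0) {
        stop(sprintf("`%s` must be > 0 when `%s` > 0.", hk, wk),
             call. = FALSE)
      }
    } else {
      # unused threshold: representable as absent, never read
      cfg[[hk]] <- if (is.null(h) || is.na(h)) NA_real_ else num1(hk, h)
    }
  }
  for (key in c("lambda_A", "lambda_R", "v_T", "v_P")) {
    cfg[[key]] <- num1(key, cfg[[key]])
    if (cfg[[key]] < 0) {
      stop(sprintf("`%s` must be non-negative.", key), call. = FALSE)
    }
  }
  if (cfg$v_T <= 0 || cfg$v_P <= 0) {
    stop("`v_T` and `v_P` must be strictly positive.", call. = FALSE)
  }
  cfg$epsilon <- num1("epsilon", cfg$epsilon)
  if (cfg$epsilon < 0) stop("`epsilon` must be >= 0.", call. = FALSE)
  cfg$eta <- num1("eta", cfg$eta)
  if (cfg$eta <= 0) stop("`eta` must be > 0.", call. = FALSE)
  if (!is.logical(cfg$correlated_AR) || length(cfg$correlated_AR) != 1) {
    stop("`correlated_AR` must be TRUE or FALSE.", call. = FALSE)
  }
  for (key in c("A0", "R0", "T0")) {
    cfg[[key]] <- num1(key, cfg[[key]])
    if (cfg[[key]] < 0) {
      stop(sprintf("`%s` must be non-negative.", key), call. = FALSE)
    }
  }
  if (cfg$T0 > 1) stop("`T0` must lie in [0, 1].", call. = FALSE)
  cfg$hill_coefficient <- num1("hill_coefficient", cfg$hill_coefficient)
  if (cfg$hill_coefficient <= 0) {
    stop("`hill_coefficient` must be positive.", call. = FALSE)
  }
  if (is.null(cfg$P0) || (length(cfg$P0) == 1 && is.na(cfg$P0))) {
    n <- cfg$hill_coefficient
    cfg$P0 <- weighted_hill_pos(cfg$A0, cfg$h_AP, cfg$omega_AP, n) *
      weighted_hill_neg(cfg$T0, cfg$h_TP, cfg$omega_TP, n)
  } else {
    cfg$P0 <- num1("P0", cfg$P0)
    if (cfg$P0 < 0 || cfg$P0 > 1) {
      stop("`P0` must lie in [0, 1].", call. = FALSE)
    }
  }
  cfg$t_end <- num1("t_end", cfg$t_end)
  cfg$dt <- num1("dt", cfg$dt)
  if (cfg$t_end <= 0 || cfg$dt <= 0) {
    stop("`t_end` and `dt` must be positive.", call. = FALSE)
  }
  if (cfg$dt * max(cfg$v_T, cfg$v_P) > 0.5) {
    stop(sprintf(
      "`dt` = %g is too coarse for v_T/v_P = %g (dt * rate must be <= 0.5).",
      cfg$dt, max(cfg$v_T, cfg$v_P)), call. = FALSE)
  }
  structure(cfg[config_keys()], class = "gli_config")
}

#' @export
print.gli_config <- function(x, ...) {
  cat("<gli_config>\n")
  links <- c("AT", "RT", "TT", "AP", "TP")
  w <- vapply(paste0("omega_", links), function(k) x[[k]], numeric(1))
  h <- vapply(paste0("h_", links), function(k) x[[k]], numeric(1))
  cat("  weights  :", paste(sprintf("%s=%g", links, w), collapse = " "), "\n")
  cat("  thresholds:",
      paste(sprintf("%s=%s", links, ifelse(is.na(h), "-", format(h))),
            collapse = " "), "\n")
  cat(sprintf("  rates    : lambda_A=%g lambda_R=%g v_T=%g v_P=%g\n",
              x$lambda_A, x$lambda_R, x$v_T, x$v_P))
  cat(sprintf("  noise    : epsilon=%g eta=%g correlated_AR=%s\n",
              x$epsilon, x$eta, x$correlated_AR))
  cat(sprintf("  init     : A0=%g R0=%g T0=%g P0=%.4g\n",
              x$A0, x$R0, x$T0, x$P0))
  cat(sprintf("  grid     : t_end=%g dt=%g hill=%g\n",
              x$t_end, x$dt, x$hill_coefficient))
  invisible(x)
}

#' Update fields of a model configuration
#'
#' Returns a new validated configuration with the named fields replaced.
#'
#' @param config A `gli_config`.
#' @param ... Named fields to replace (see [model_config()]).
#' @return A `gli_config`.
#' @examples
#' quiet <- update_config(make_preset("WT"), epsilon = 0)
#' @export
update_config <- function(config, ...) {
  stopifnot(inherits(config, "gli_config"))
  changes <- list(...)
  unknown <- setdiff(names(changes), config_keys())
  if (length(unknown) > 0) {
    stop("Unknown configuration field(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  cfg <- unclass(config)
  for (key in names(changes)) cfg[[key]] <- changes[[key]]
  validate_config(cfg)
}

#' Read and write model configurations as flat YAML
#'
#' Configurations serialize to a flat key-value YAML file using the keys
#' `omega_AT` ... `h_TP`, `lambda_A`, `lambda_R`, `v_T`, `v_P`, `epsilon`,
#' `eta`, `correlated_AR`, `A0`, `R0`, `T0`, `P0`, `t_end`, `dt`,
#' `hill_coefficient`. Unknown keys are rejected with an error naming them;
#' absent thresholds may be omitted or written as `.na`. Canonical files
#' for the five network rows ship under
#' `system.file("extdata", "configs", package = "glitimer")`.
#'
#' @param path File path.
#' @param config A `gli_config`.
#' @return `read_model_config()` returns a `gli_config`;
#'   `write_model_config()` returns `path` invisibly.
#' @examples
#' f <- system.file("extdata", "configs", "full_network_wt.yaml",
#'                  package = "glitimer")
#' read_model_config(f)$omega_TT
#' @export
read_model_config <- function(path) {
  if (!file.exists(path)) {
    stop("Config file not found: ", path, call. = FALSE)
  }
  raw <- yaml::read_yaml(path)
  unknown <- setdiff(names(raw), config_keys())
  if (length(unknown) > 0) {
    stop("Unknown configuration key(s) in ", path, ": ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  args <- formals(model_config)
  cfg <- lapply(args, function(d) if (is.call(d)) eval(d) else d)
  cfg$P0 <- NULL
  for (key in names(raw)) cfg[[key]] <- raw[[key]]
  validate_config(cfg)
}

#' @rdname read_model_config
#' @export
write_model_config <- function(config, path) {
  stopifnot(inherits(config, "gli_config"))
  out <- unclass(config)
  out <- out[config_keys()]
  out <- out[!vapply(out, function(v) length(v) == 1 && is.na(v), logical(1))]
  yaml::write_yaml(out, path)
  invisible(path)
}
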