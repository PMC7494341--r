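#' Right-hand side of the timer network
#'
#' Evaluates the time derivatives of the four-variable system
#' \deqn{dA/dt = -\lambda_A A, \quad dR/dt = -\lambda_R R,}
#' \deqn{dT/dt = v_T [(1-\omega_{TT}) H^{w+}(A, h_{AT}) H^{w-}(R, h_{RT})
#'   + \omega_{TT} H^{+}(T_{eff}, h_{TT}) - T],}
#' \deqn{dP/dt = v_P [H^{w+}(A, h_{AP}) H^{w-}(T_{eff}, h_{TP}) - P].}
#' GliA and GliR decay exponentially; Tgfb production combines the weighted
#' GliA/GliR input with Tgfb self-activation (weight `omega_TT`), and
#' Phox2b production is driven by GliA and repressed by Tgfb.
#'
#' `T_eff` is the Tgfb concentration *seen by* the self-activation and the
#' Phox2b-repression terms. In single-cell simulations it equals the cell's
#' own `T`; the lattice module substitutes the diffusion-averaged field
#' `0.5 T + 0.5 <T>_nn` here. The linear `-T` decay term always uses the
#' cell's own `T`.
#'
#' All arguments vectorize over cells/replicates.
#'
#' @param A,R,T,P State values (non-negative).
#' @param config A [model_config()].
#' @param T_eff Effective Tgfb input; defaults to `T`.
#' @return A list with components `dA`, `dR`, `dT`, `dP`.
#' @examples
#' cfg <- make_preset("WT")
#' model_rhs(A = 1, R = 1, T = 0, P = cfg$P0, config = cfg)
#' @export
model_rhs <- function(A, R, T, P, config, T_eff = T) {
  if (any(!is.finite(A)) || any(!is.finite(R)) ||
      any(!is.finite(T)) || any(!is.finite(P))) {
    stop("Non-finite state passed to model_rhs().", call. = FALSE)
  }
  n <- config$hill_coefficient
  production_T <-
    (1 - config$omega_TT) *
      weighted_hill_pos(A, config$h_AT, config$omega_AT, n) *
      weighted_hill_neg(R, config$h_RT, config$omega_RT, n) +
    tgfb_self_term(T_eff, config)
  production_P <-
    weighted_hill_pos(A, config$h_AP, config$omega_AP, n) *
    weighted_hill_neg(T_eff, config$h_TP, config$omega_TP, n)
  list(
    dA = -config$lambda_A * A,
    dR = -config$lambda_R * R,
    dT = config$v_T * (production_T - T),
    dP = config$v_P * (production_P - P)
  )
}

# omega_TT * H+(T, h_TT): the self-activation contribution to Tgfb
# production. The weight appears once, as the prefactor, so that the term
# vanishes entirely at omega_TT = 0 and total production stays <= 1.
tgfb_self_term <- function(T_eff, config) {
  if (config$omega_TT == 0) return(0)
  config$omega_TT *
    hill_pos(T_eff, config$h_TT, config$hill_coefficient)
}

# Tgfb production at frozen (A, R) as a function of T: the function whose
# roots in [0, 1] are the Tgfb steady states. g(T) = production(T) - T.
tgfb_balance <- function(T, A, R, config) {
  n <- config$hill_coefficient
  base <- (1 - config$omega_TT) *
    weighted_hill_pos(A, config$h_AT, config$omega_AT, n) *
    weighted_hill_neg(R, config$h_RT, config$omega_RT, n)
  base + tgfb_self_term(T, config) - T
}
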