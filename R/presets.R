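#' Canonical network presets and mutant scenarios
#'
#' `make_preset()` returns a ready-made [model_config()] for the five
#' canonical network variants and the mutant genotypes modelled on top of
#' the full network:
#'
#' * `"direct"` — GliA -> Phox2b (`omega_AP = 1`, `h_AP = 0.25`).
#' * `"relay"` — GliR -| Tgfb -| Phox2b (`omega_RT = 1`, `h_RT = 0.15`,
#'   `omega_TP = 1`, `h_TP = 0.3`).
#' * `"self_activation"` — relay plus weak Tgfb self-activation
#'   (`omega_TT = 0.4`, `h_RT = 0.1`, `h_TT = 0.3`).
#' * `"hysteresis"` — relay plus strong self-activation making the Tgfb
#'   response bistable (`omega_TT = 0.94`, `h_RT = 0.2`, `h_TT = 0.3`).
#' * `"WT"` (alias `"full"`) — full network with the GliA links
#'   (`omega_AT = omega_AP = 1`, `h_AT = h_AP = 0.08`) on top of the
#'   hysteretic core.
#' * `"Tgfbr1_KO"` — WT without Tgfb signal reception: `omega_TP = 0`.
#' * `"Gli1_KO"` — WT with a 30% lower GliA starting level: `A0 = 0.7`.
#' * `"Gli1ON_Tgfbr1_KO"` — constitutive GliA (clamped at its initial
#'   value via `lambda_A = 0`) combined with `omega_TP = 0`; Phox2b then
#'   never drops below the motor-neuron threshold.
#'
#' Shared kinetic rates are `lambda_A = lambda_R = 0.86`/day, `v_T = 50`,
#' `v_P = 90`.
#'
#' @param name Preset name (see above); case-sensitive.
#' @param ... Field overrides forwarded to [update_config()], e.g.
#'   `epsilon = 0`.
#' @return A `gli_config`.
#' @examples
#' make_preset("Gli1_KO")$A0   # 0.7
#' preset_names()
#' @export
make_preset <- function(name, ...) {
  presets <- preset_list()
  if (!is.character(name) || length(name) != 1 || !name %in% names(presets)) {
    stop("Unknown preset ", deparse(substitute(name)),
         ". Available presets: ",
         paste(names(presets), collapse = ", "), call. = FALSE)
  }
  cfg <- do.call(model_config, presets[[name]])
  if (length(list(...)) > 0) cfg <- update_config(cfg, ...)
  cfg
}

#' @rdname make_preset
#' @export
preset_names <- function() names(preset_list())

preset_list <- function() {
  full <- list(omega_AT = 1, omega_RT = 1, omega_TT = 0.94,
               omega_AP = 1, omega_TP = 1,
               h_AT = 0.08, h_RT = 0.2, h_TT = 0.3,
               h_AP = 0.08, h_TP = 0.3)
  list(
    direct = list(omega_AP = 1, h_AP = 0.25),
    relay = list(omega_RT = 1, h_RT = 0.15, omega_TP = 1, h_TP = 0.3),
    self_activation = list(omega_RT = 1, h_RT = 0.1,
                           omega_TT = 0.4, h_TT = 0.3,
                           omega_TP = 1, h_TP = 0.3),
    hysteresis = list(omega_RT = 1, h_RT = 0.2,
                      omega_TT = 0.94, h_TT = 0.3,
                      omega_TP = 1, h_TP = 0.3),
    WT = full,
    full = full,
    Tgfbr1_KO = c(full[setdiff(names(full), "omega_TP")],
                  list(omega_TP = 0)),
    Gli1_KO = c(full, list(A0 = 0.7)),
    Gli1ON_Tgfbr1_KO = c(full[setdiff(names(full), "omega_TP")],
                         list(omega_TP = 0, lambda_A = 0, A0 = 1))
  )
}
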