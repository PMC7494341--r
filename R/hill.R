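#' Hill regulatory functions
#'
#' Positive and negative Hill functions with exponent `n` (default 2), and
#' their weighted forms used to switch individual regulatory links on and
#' off. The weighted positive form is `(1 - omega) + omega * H+(x, h)` and
#' the weighted negative form is `(1 - omega) + omega * H-(x, h)`, so a
#' weight of 0 removes the link entirely (the factor is identically 1) and
#' a weight of 1 recovers the plain Hill function.
#'
#' @param x Concentration(s), non-negative.
#' @param h Half-activation threshold, strictly positive (required whenever
#'   `omega > 0`).
#' @param omega Link weight in `[0, 1]`.
#' @param n Hill exponent; the model fixes this to 2.
#'
#' @return Numeric vector of regulatory factors in `[0, 1]`
#'   (`[1 - omega, 1]` for the weighted forms).
#'
#' @examples
#' hill_pos(0.3, 0.3)            # 0.5 at the half-activation point
#' hill_pos(0.3, 0.3) + hill_neg(0.3, 0.3)  # complements sum to 1
#' weighted_hill_pos(5, 0.1, omega = 0)     # absent link: exactly 1
#' @export
hill_pos <- function(x, h, n = 2) {
  check_hill_args(x, h)
  xn <- x^n
  xn / (h^n + xn)
}

#' @rdname hill_pos
#' @export
hill_neg <- function(x, h, n = 2) {
  check_hill_args(x, h)
  hn <- h^n
  hn / (hn + x^n)
}

#' @rdname hill_pos
#' @export
weighted_hill_pos <- function(x, h, omega, n = 2) {
  check_weight(omega)
  if (all(omega == 0)) return(rep(1, length(x)))
  (1 - omega) + omega * hill_pos(x, h, n)
}

#' @rdname hill_pos
#' @export
weighted_hill_neg <- function(x, h, omega, n = 2) {
  check_weight(omega)
  if (all(omega == 0)) return(rep(1, length(x)))
  (1 - omega) + omega * hill_neg(x, h, n)
}

check_hill_args <- function(x, h) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x < 0)) {
    stop("`x` must be finite and non-negative.", call. = FALSE)
  }
  if (!is.numeric(h) || any(!is.finite(h)) || any(h <= 0)) {
    stop("`h` must be finite and strictly positive.", call. = FALSE)
  }
  invisible(NULL)
}

check_weight <- function(omega) {
  if (!is.numeric(omega) || any(!is.finite(omega)) ||
      any(omega < 0) || any(omega > 1)) {
    stop("`omega` must lie in [0, 1].", call. = FALSE)
  }
  invisible(NULL)
}
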