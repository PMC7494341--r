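#' Tgfb steady states at frozen Gli levels
#'
#' Freezes GliA and GliR and finds all roots in `[0, 1]` of the Tgfb
#' balance `g(T) = production(T) - T`, where production combines the
#' weighted GliA/GliR input with the self-activation term. Roots are
#' located by sign-change scanning on a fine grid followed by bisection
#' refinement; stability follows from the sign of `g'(T)` (negative means
#' stable, since `dT/dt = v_T g(T)`). At least one root always exists
#' because `g(0) >= 0` and `g(1) <= 0`.
#'
#' @param config A [model_config()].
#' @param R Frozen GliR level (`>= 0`).
#' @param A Frozen GliA level (`>= 0`); irrelevant when `omega_AT = 0`.
#' @param n_grid Scan resolution on `[0, 1]`.
#' @param tol Bisection tolerance for root refinement.
#' @return A tibble with columns `T_star` (ascending) and `stable`.
#' @examples
#' t_steady_states(make_preset("hysteresis"), R = 0.5)  # bistable
#' t_steady_states(make_preset("hysteresis"), R = 0.1)  # high state only
#' @export
t_steady_states <- function(config, R, A = 0, n_grid = 10001,
                            tol = 1e-10) {
  stopifnot(inherits(config, "gli_config"), R >= 0, A >= 0)
  Tg <- seq(0, 1, length.out = n_grid)
  g <- tgfb_balance(Tg, A = A, R = R, config = config)
  roots <- numeric(0)
  exact <- which(g == 0)
  roots <- c(roots, Tg[exact])
  sgn <- sign(g)
  flips <- which(sgn[-n_grid] * sgn[-1] < 0)
  for (i in flips) {
    r <- stats::uniroot(function(T) tgfb_balance(T, A, R, config),
                        lower = Tg[i], upper = Tg[i + 1], tol = tol)$root
    roots <- c(roots, r)
  }
  roots <- sort(unique(roots))
  dg <- vapply(roots, function(r) {
    h <- 1e-6
    (tgfb_balance(min(r + h, 1), A, R, config) -
       tgfb_balance(max(r - h, 0), A, R, config)) /
      (min(r + h, 1) - max(r - h, 0))
  }, numeric(1))
  tibble::tibble(T_star = roots, stable = dg < 0)
}

#' Bifurcation diagram of Tgfb versus GliR
#'
#' Sweeps GliR over `R_grid`, collects every Tgfb steady state with its
#' stability label, and locates fold points — GliR values where branches
#' are created or annihilated — by bisection on the root count. For the
#' hysteretic network the low-Tgfb branch is annihilated as GliR declines
#' (the up-jump fold `R_up`); the high branch persists for every GliR in
#' the scan and beyond, so the return fold `R_down` is reported as `Inf`
#' and the diagram is flagged `one_way`: once jumped, the system cannot
#' return by restoring GliR.
#'
#' @param config A [model_config()].
#' @param R_grid GliR values to scan (default 401 points on `[0, 1]`, the
#'   normalized GliR scale).
#' @param A_policy How frozen GliA tracks GliR: `"off"` (A = 0; the
#'   GliA->Tgfb link is anyway absent in the reduced networks) or
#'   `"parallel"` (A = R, mirroring the parallel GliA/GliR gradients of
#'   the full network).
#' @param n_grid,tol Passed to [t_steady_states()].
#' @return An object of class `gli_bifurcation`: list with `branches`
#'   (tibble: `R`, `T_star`, `stable`, `branch_id`), `fold_points`
#'   (tibble: `R_fold`, `type` in `up`/`down`), `one_way`, `A_policy`,
#'   `config`.
#' @examples
#' bd <- sweep_bifurcation(make_preset("hysteresis"),
#'                         R_grid = seq(0, 1, length.out = 101))
#' bd$fold_points
#' @export
sweep_bifurcation <- function(config, R_grid = seq(0, 1, length.out = 401),
                              A_policy = c("off", "parallel"),
                              n_grid = 4001, tol = 1e-10) {
  A_policy <- match.arg(A_policy)
  R_grid <- sort(unique(R_grid))
  A_of <- function(R) if (A_policy == "parallel") R else 0
  states <- purrr::map(R_grid, function(R) {
    st <- t_steady_states(config, R = R, A = A_of(R), n_grid = n_grid,
                          tol = tol)
    st$R <- R
    st
  })
  counts <- vapply(states, nrow, integer(1))
  branches <- dplyr::bind_rows(states) |>
    dplyr::group_by(.data$R) |>
    dplyr::mutate(branch_id = dplyr::row_number()) |>
    dplyr::ungroup() |>
    dplyr::select("R", "T_star", "stable", "branch_id")

  folds <- list()
  count_at <- function(R) {
    nrow(t_steady_states(config, R = R, A = A_of(R), n_grid = n_grid,
                         tol = tol))
  }
  for (i in which(diff(counts) != 0)) {
    lo <- R_grid[i]; hi <- R_grid[i + 1]
    c_lo <- counts[i]; c_hi <- counts[i + 1]
    for (iter in 1:40) {
      midR <- (lo + hi) / 2
      if (count_at(midR) == c_lo) lo <- midR else hi <- midR
    }
    R_fold <- (lo + hi) / 2
    # roots appearing as R increases = the fold where, scanning downward in
    # R, the low branch dies (up-jump); roots disappearing = down-jump.
    type <- if (c_hi > c_lo) "up" else "down"
    folds[[length(folds) + 1]] <- tibble::tibble(R_fold = R_fold,
                                                 type = type)
  }
  fold_points <- if (length(folds) > 0) {
    dplyr::bind_rows(folds)
  } else {
    tibble::tibble(R_fold = numeric(0), type = character(0))
  }
  # bistable at the top of the scan but no annihilation of the high branch
  # anywhere: the return fold lies beyond any attainable GliR.
  one_way <- counts[length(counts)] > 1 && !any(fold_points$type == "down")
  if (one_way) {
    fold_points <- dplyr::bind_rows(
      fold_points, tibble::tibble(R_fold = Inf, type = "down"))
  }
  structure(
    list(branches = branches, fold_points = fold_points, one_way = one_way,
         A_policy = A_policy, config = config),
    class = "gli_bifurcation")
}

#' @export
print.gli_bifurcation <- function(x, ...) {
  nf <- sum(is.finite(x$fold_points$R_fold))
  cat(sprintf(
    "<gli_bifurcation> %d GliR values, %d finite fold point(s)%s\n",
    length(unique(x$branches$R)), nf,
    if (x$one_way) ", one-way switch (return fold at Inf)" else ""))
  if (nrow(x$fold_points) > 0) print(x$fold_points)
  invisible(x)
}
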