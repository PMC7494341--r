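#' Tgfb spatial averaging on a periodic lattice
#'
#' Computes the effective Tgfb field `0.5 * T + 0.5 * <T>_nn` on a 2-D
#' grid with periodic boundaries, where `<T>_nn` is the mean over the
#' nearest neighbours of each cell. This models short-range Tgfb
#' diffusion: each cell reads half its own Tgfb and half the local
#' neighbourhood average. Symmetric averaging conserves the global mean.
#'
#' @param T_field Numeric matrix of per-cell Tgfb values (rows x cols).
#' @param neighbourhood `"von_neumann"` (4 orthogonal neighbours, the
#'   default reading of "nearest neighbours" on a square grid) or
#'   `"moore"` (8 neighbours).
#' @param radius Neighbourhood radius; `2` adds the second shell
#'   (diffusion range has little effect on the results).
#' @param self_weight Weight on the cell's own Tgfb (default 0.5).
#' @return A matrix of effective Tgfb values, same shape as `T_field`.
#' @examples
#' Tm <- matrix(0, 5, 5); Tm[3, 3] <- 1
#' effective_T(Tm)[3, 3]        # 0.5
#' effective_T(Tm)[3, 4]        # 0.125
#' @export
effective_T <- function(T_field, neighbourhood = c("von_neumann", "moore"),
                        radius = 1, self_weight = 0.5) {
  stopifnot(is.matrix(T_field))
  neighbourhood <- match.arg(neighbourhood)
  nb <- neighbour_index(nrow(T_field), ncol(T_field), neighbourhood, radius)
  Tv <- as.vector(T_field)
  avg <- rowMeans(matrix(Tv[nb], nrow = length(Tv)))
  matrix(self_weight * Tv + (1 - self_weight) * avg,
         nrow(T_field), ncol(T_field))
}

# m x k matrix of periodic neighbour indices (column-major cell order).
neighbour_index <- function(rows, cols, neighbourhood = "von_neumann",
                            radius = 1) {
  offs <- expand.grid(di = -radius:radius, dj = -radius:radius)
  offs <- offs[!(offs$di == 0 & offs$dj == 0), ]
  if (neighbourhood == "von_neumann") {
    offs <- offs[abs(offs$di) + abs(offs$dj) <= radius, ]
  }
  i <- rep(seq_len(rows), times = cols)
  j <- rep(seq_len(cols), each = rows)
  idx <- function(di, dj) {
    ii <- ((i - 1 + di) %% rows) + 1
    jj <- ((j - 1 + dj) %% cols) + 1
    (jj - 1) * rows + ii
  }
  mapply(idx, offs$di, offs$dj)
}

#' Simulate the timer on a cell lattice with Tgfb averaging
#'
#' Runs the stochastic model for every cell of a `rows x cols` periodic
#' lattice. Kinetic noise is independent across cells; when `coupling` is
#' on, the Tgfb input of the self-activation and Phox2b-repression terms
#' is replaced each step by the spatially averaged field
#' `0.5 T + 0.5 <T>_nn` (see [effective_T()]), which synchronizes the
#' population-level fate switch despite cell-to-cell noise. With
#' `coupling = FALSE` the cells evolve as independent replicates, making
#' paired-seed comparisons of coupled versus uncoupled dynamics exact.
#'
#' @param config A [model_config()].
#' @param rows,cols Grid dimensions. The default 20 x 20 captures the
#'   averaging mechanism; it is insensitive to grid size and a larger
#'   grid (e.g. 100 x 100) can be requested directly.
#' @param seed Integer RNG seed.
#' @param coupling Enable Tgfb spatial averaging.
#' @param neighbourhood,radius See [effective_T()].
#' @param record_dt Output thinning interval (days).
#' @param keep Per-cell paths to retain (`"P"` and `"T"` by default).
#' @return An object of class `gli_lattice`: list with `times`, `paths`
#'   (time x cell matrices), `summary` (per-time quantile envelopes across
#'   cells), `rows`, `cols`, `coupling`, `config`, `seed`.
#' @examples
#' lat <- simulate_lattice(make_preset("hysteresis", t_end = 3, epsilon = 0),
#'                         rows = 4, cols = 4, seed = 1)
#' @export
simulate_lattice <- function(config, rows = 20, cols = 20, seed,
                             coupling = TRUE,
                             neighbourhood = c("von_neumann", "moore"),
                             radius = 1, record_dt = 0.01,
                             keep = c("P", "T")) {
  neighbourhood <- match.arg(neighbourhood)
  m <- rows * cols
  if (m > 250000) {
    stop("Lattice of ", rows, " x ", cols, " cells is too large; ",
         "reduce the grid (the averaging mechanism is size-insensitive).",
         call. = FALSE)
  }
  nb <- if (coupling) neighbour_index(rows, cols, neighbourhood, radius)
  sim <- sim_engine(config, m = m, seed = seed, record_dt = record_dt,
                    nb = nb, keep = keep, summarize = TRUE)
  structure(
    list(times = sim$times, paths = sim$paths, summary = sim$summary,
         rows = rows, cols = cols, coupling = coupling,
         neighbourhood = neighbourhood, radius = radius,
         config = config, seed = seed),
    class = "gli_lattice")
}

#' @export
print.gli_lattice <- function(x, ...) {
  cat(sprintf(
    "<gli_lattice> %d x %d cells (periodic), coupling %s, epsilon = %g\n",
    x$rows, x$cols, if (x$coupling) "on" else "off", x$config$epsilon))
  invisible(x)
}

#' @export
likelihood_path.gli_lattice <- function(x, readout = NULL,
                                        method = c("population",
                                                   "mean_path"), ...) {
  rd <- default_readout(x, readout)
  method <- match.arg(method)
  if (is.null(x$paths$P)) {
    stop("Lattice was run with `keep` excluding \"P\".", call. = FALSE)
  }
  lik <- if (method == "population") {
    rowMeans(mn_likelihood(x$paths$P, rd))
  } else {
    mn_likelihood(rowMeans(x$paths$P), rd)
  }
  new_likelihood(x$times, lik, rd)
}

#' Per-cell and per-replicate switch statistics
#'
#' Applies the gamma-threshold readout to every cell's (or replicate's)
#' own Phox2b path and records its individual likelihood crossings: the
#' 0.95 and 0.05 transitions, the 0.5 switch time and the per-cell
#' transition interval `delta_t`. The spread of `t_switch` across the
#' lattice measures how synchronously the population switches, while the
#' per-cell `delta_t` measures how fast each individual cell transits the
#' threshold distribution (contrast with [switch_statistics()] on the
#' population likelihood, which also reflects between-cell dispersion).
#'
#' @param lattice A [simulate_lattice()] result.
#' @param ensemble A [run_ensemble()] result.
#' @param readout A [readout_model()]; defaults to the config's `eta`.
#' @return A tibble with one row per cell (`row`, `col`) or replicate
#'   (`replicate`) and columns `t_95`, `t_05`, `t_switch`, `delta_t`
#'   (`NA` where a crossing does not occur within the horizon).
#' @export
cell_switch_times <- function(lattice, readout = NULL) {
  stopifnot(inherits(lattice, "gli_lattice"))
  rd <- default_readout(lattice, readout)
  if (is.null(lattice$paths$P)) {
    stop("Lattice was run without keeping \"P\".", call. = FALSE)
  }
  out <- per_path_switch_stats(lattice$times, lattice$paths$P, rd)
  tibble::tibble(
    row = rep(seq_len(lattice$rows), times = lattice$cols),
    col = rep(seq_len(lattice$cols), each = lattice$rows)) |>
    dplyr::bind_cols(out)
}

#' @rdname cell_switch_times
#' @export
replicate_switch_times <- function(ensemble, readout = NULL) {
  stopifnot(inherits(ensemble, "gli_ensemble"))
  rd <- default_readout(ensemble, readout)
  if (is.null(ensemble$paths$P)) {
    stop("Ensemble was run without keeping \"P\".", call. = FALSE)
  }
  out <- per_path_switch_stats(ensemble$times, ensemble$paths$P, rd)
  dplyr::bind_cols(
    tibble::tibble(replicate = seq_len(ncol(ensemble$paths$P))), out)
}

per_path_switch_stats <- function(times, P, readout) {
  lik <- mn_likelihood(P, readout)
  cross <- function(level, which) {
    vapply(seq_len(ncol(lik)), function(j) {
      down_crossing(times, lik[, j], level, which = which)
    }, numeric(1))
  }
  t95 <- cross(0.95, "last")
  t05 <- cross(0.05, "first")
  tibble::tibble(t_95 = t95, t_05 = t05,
                 t_switch = cross(0.5, "first"),
                 delta_t = t05 - t95)
}
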