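#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy and glance methods
#'
#' Broom-style accessors for the package's result objects. `tidy()`
#' returns the per-observation table (envelope rows, branch points, sweep
#' rows); `glance()` returns a one-row summary.
#'
#' @param x A `gli_ensemble`, `gli_bifurcation`, `gli_lattice` or
#'   `gli_sweep`.
#' @param ... Unused.
#' @return A tibble.
#' @name gli-tidiers
NULL

#' @rdname gli-tidiers
#' @export
tidy.gli_ensemble <- function(x, ...) x$summary

#' @rdname gli-tidiers
#' @export
glance.gli_ensemble <- function(x, ...) {
  tibble::tibble(
    n_replicates = x$n_replicates,
    n_times = length(x$times),
    t_end = x$config$t_end,
    epsilon = x$config$epsilon,
    eta = x$config$eta,
    correlated_AR = x$config$correlated_AR,
    seed = x$seed)
}

#' @rdname gli-tidiers
#' @export
tidy.gli_bifurcation <- function(x, ...) x$branches

#' @rdname gli-tidiers
#' @export
glance.gli_bifurcation <- function(x, ...) {
  up <- x$fold_points$R_fold[x$fold_points$type == "up"]
  down <- x$fold_points$R_fold[x$fold_points$type == "down"]
  tibble::tibble(
    n_R = length(unique(x$branches$R)),
    n_folds = nrow(x$fold_points),
    R_up = if (length(up) > 0) up[1] else NA_real_,
    R_down = if (length(down) > 0) down[1] else NA_real_,
    one_way = x$one_way,
    A_policy = x$A_policy)
}

#' @rdname gli-tidiers
#' @export
tidy.gli_lattice <- function(x, ...) x$summary

#' @rdname gli-tidiers
#' @export
glance.gli_lattice <- function(x, ...) {
  tibble::tibble(
    rows = x$rows, cols = x$cols,
    coupling = x$coupling,
    neighbourhood = x$neighbourhood, radius = x$radius,
    epsilon = x$config$epsilon, eta = x$config$eta, seed = x$seed)
}

#' @rdname gli-tidiers
#' @export
glance.gli_sweep <- function(x, ...) {
  tibble::tibble(
    param = unique(x$param),
    n_values = length(unique(x$value)),
    n_variants = length(unique(x$variant)),
    n_censored = sum(x$no_switch),
    spatial_averaging = isTRUE(attr(x, "spatial_averaging")),
    seed = attr(x, "seed"))
}
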