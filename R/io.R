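#' Export results to tidy CSV
#'
#' Writes trajectories, ensemble summaries, likelihood curves, bifurcation
#' diagrams, lattice snapshots and sweep tables to plain CSV in long
#' ("tidy") layout, the package's canonical interchange format.
#'
#' @param x A package result object (`gli_trajectory`, `gli_ensemble`,
#'   `gli_likelihood`, `gli_bifurcation`, `gli_lattice`, `gli_sweep`, or
#'   any data frame).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_result_csv <- function(x, path) {
  df <- tidy_result(x)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

tidy_result <- function(x) {
  if (inherits(x, "gli_trajectory")) {
    tidyr::pivot_longer(tibble::as_tibble(x), -"time",
                        names_to = "variable", values_to = "value")
  } else if (inherits(x, "gli_ensemble") || inherits(x, "gli_bifurcation")) {
    generics::tidy(x)
  } else if (inherits(x, "gli_lattice")) {
    lattice_long(x)
  } else if (is.data.frame(x)) {
    tibble::as_tibble(x)
  } else {
    stop("Don't know how to export an object of class ",
         paste(class(x), collapse = "/"), call. = FALSE)
  }
}

lattice_long <- function(x) {
  purrr::imap(x$paths, function(mat, var) {
    tibble::tibble(
      time = rep(x$times, times = ncol(mat)),
      row = rep(rep(seq_len(x$rows), times = x$cols), each = length(x$times)),
      col = rep(rep(seq_len(x$cols), each = x$rows), each = length(x$times)),
      variable = var,
      value = as.vector(mat))
  }) |> dplyr::bind_rows()
}

#' Run manifests for reproducible outputs
#'
#' A run manifest records what produced a set of output files: the
#' command label, the fully resolved configuration, every seed, the
#' package version, a timestamp and an inventory of output files with
#' their MD5 checksums. Deterministic runs re-executed from a manifest's
#' config and seeds reproduce byte-identical CSVs.
#'
#' @param command Free-text label of the operation.
#' @param config The `gli_config` used (serialized flat).
#' @param seeds Named or unnamed integer vector of seeds used (may be
#'   empty for deterministic runs).
#' @param outputs Character vector of output file paths to inventory.
#' @param path Where to write the manifest JSON.
#' @return The manifest list, invisibly.
#' @export
write_run_manifest <- function(path, command, config = NULL,
                               seeds = integer(), outputs = character()) {
  inventory <- lapply(outputs, function(f) {
    list(file = f,
         md5 = unname(tools::md5sum(f)),
         bytes = file.size(f))
  })
  manifest <- list(
    command = command,
    package = "glitimer",
    version = as.character(utils::packageVersion("glitimer")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seeds = as.list(seeds),
    config = if (!is.null(config)) {
      cfg <- unclass(config)[config_keys()]
      cfg[!vapply(cfg, function(v) length(v) == 1 && is.na(v), logical(1))]
    },
    outputs = inventory)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(manifest)
}
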