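#' Synthetic per-gene expression tables with planted ground truth
#'
#' Generates an expression summary table emulating the differentiation
#' time-course screens: per-gene FPKM at 0, 1, 2, 3.5, 4.5, 5.5 and
#' 6.5 DDC, the pairwise log2 fold-changes and p-values consumed by
#' [filter_downregulated()] and [classify_biphasic()], and a biotype
#' column. Each gene is drawn from one of seven classes built around
#' noiseless log2-FPKM template curves:
#'
#' * `biphasic_peak2`, `biphasic_peak3p5` — rise to a peak at 2 or
#'   3.5 DDC (>= 0.5 log2 up and down with margin) and are
#'   cyclopamine-repressed; the planted biphasic positives.
#' * `monotone_down` — decline throughout; the planted positives of the
#'   down-regulated screen.
#' * `monotone_up`, `flat` — planted negatives.
#' * `non_coding_decoy` — peak2-shaped and CyC-repressed but non-coding:
#'   violates exactly the biotype rule of either filter.
#' * `cyc_insensitive_decoy` — peak2-shaped and protein-coding but with a
#'   SAG-vs-CyC log2 fold-change of 0.2 (< 0.5): violates exactly the
#'   `cyc_fc` rule of the biphasic gate.
#'
#' Observed FPKMs are log-normal around the templates
#' (`2^(template + N(0, noise_sd))`), fold-changes are template
#' differences plus `N(0, noise_sd)` noise, and p-values are small
#' (`<= 0.01`) for contrasts whose template difference is a real change
#' (|diff| > 0.1) and uniform on `[0, 1]` otherwise. At `noise_sd = 0`
#' both filters recover the planted labels exactly.
#'
#' @param n_genes Number of genes.
#' @param class_mix Named fractions over the seven classes; must sum to 1.
#' @param noise_sd Standard deviation of the log2-scale noise (default
#'   0.1, a moderate between-replicate spread).
#' @param seed Integer RNG seed.
#' @return A tibble with `gene_id`, `biotype`, the `fpkm_*`/`lfc_*`/`p_*`
#'   columns, and ground-truth columns `true_class`,
#'   `true_downregulated` (at the default 0.22 cutoff) and
#'   `true_biphasic_label`.
#' @examples
#' tbl <- generate_synthetic_expression(200, noise_sd = 0, seed = 1)
#' table(tbl$true_class)
#' @export
generate_synthetic_expression <- function(
    n_genes = 700,
    class_mix = c(biphasic_peak2 = 0.10, biphasic_peak3p5 = 0.10,
                  monotone_down = 0.15, monotone_up = 0.15, flat = 0.30,
                  non_coding_decoy = 0.10, cyc_insensitive_decoy = 0.10),
    noise_sd = 0.1, seed = 1) {
  classes <- names(expression_templates())
  if (is.null(names(class_mix)) || !setequal(names(class_mix), classes)) {
    stop("`class_mix` must be named with exactly the classes: ",
         paste(classes, collapse = ", "), call. = FALSE)
  }
  class_mix <- class_mix[classes]
  if (abs(sum(class_mix) - 1) > 1e-8) {
    stop("`class_mix` fractions must sum to 1.", call. = FALSE)
  }
  if (noise_sd < 0) stop("`noise_sd` must be >= 0.", call. = FALSE)
  withr::local_seed(as.integer(seed))

  counts <- diff(c(0L, round(cumsum(class_mix) * n_genes)))
  gene_class <- rep(classes, counts)
  n <- length(gene_class)
  tpl <- expression_templates()
  times <- c("0", "1", "2", "3p5", "4p5", "5p5", "6p5")

  log2_tpl <- t(vapply(gene_class, function(cl) tpl[[cl]]$log2, numeric(7)))
  dimnames(log2_tpl) <- list(NULL, times)
  fpkm <- 2^(log2_tpl + matrix(stats::rnorm(n * 7, sd = noise_sd), n, 7))

  out <- tibble::tibble(
    gene_id = sprintf("gene_%05d", seq_len(n)),
    true_class = gene_class,
    biotype = unname(vapply(gene_class, function(cl) tpl[[cl]]$biotype,
                            character(1))))
  for (t in times) out[[paste0("fpkm_", t)]] <- fpkm[, t]

  lfc_pairs <- list(c("3p5", "5p5"), c("2", "0"), c("2", "1"),
                    c("2", "6p5"), c("2", "5p5"), c("2", "4p5"),
                    c("3p5", "0"), c("3p5", "1"), c("3p5", "6p5"))
  diffs <- list()
  for (pr in lfc_pairs) {
    key <- paste0(pr[1], "_", pr[2])
    d <- log2_tpl[, pr[1]] - log2_tpl[, pr[2]]
    diffs[[key]] <- d
    out[[paste0("lfc_", key)]] <- d + stats::rnorm(n, sd = noise_sd)
  }
  cyc <- unname(vapply(gene_class, function(cl) tpl[[cl]]$cyc_lfc,
                       numeric(1)))
  diffs[["sag_cyc_3p5"]] <- cyc
  out$lfc_sag_cyc_3p5 <- cyc + stats::rnorm(n, sd = noise_sd)

  for (key in c("3p5_5p5", "sag_cyc_3p5", "2_0", "2_6p5", "3p5_0",
                "3p5_6p5")) {
    true_change <- abs(diffs[[key]]) > 0.1
    out[[paste0("p_", key)]] <- ifelse(
      true_change,
      0.001 * stats::runif(n),
      stats::runif(n))
  }

  out$true_downregulated <- unname(vapply(
    gene_class, function(cl) tpl[[cl]]$downregulated, logical(1)))
  out$true_biphasic_label <- unname(vapply(
    gene_class, function(cl) tpl[[cl]]$biphasic, character(1)))
  out
}

# Class templates: log2-FPKM curves at (0, 1, 2, 3.5, 4.5, 5.5, 6.5) DDC,
# the SAG-vs-CyC log2 fold-change at 3.5 DDC, biotype, and the planted
# truth for both filters at their default cutoffs. Margins are >= 0.08
# log2 units away from every threshold the class is meant to satisfy or
# violate.
expression_templates <- function() {
  peak2 <- c(2, 3.2, 4, 3.4, 3.35, 3.1, 2.2)
  list(
    biphasic_peak2 = list(
      log2 = peak2, cyc_lfc = 1.5, biotype = "protein_coding",
      downregulated = TRUE, biphasic = "peak2"),
    biphasic_peak3p5 = list(
      log2 = c(2, 2.9, 3.4, 4, 3.6, 3.2, 2.5), cyc_lfc = 1.5,
      biotype = "protein_coding",
      downregulated = TRUE, biphasic = "peak3p5"),
    monotone_down = list(
      log2 = c(4.5, 4.2, 3.9, 3.5, 3.0, 2.6, 2.2), cyc_lfc = 0,
      biotype = "protein_coding",
      downregulated = TRUE, biphasic = "none"),
    monotone_up = list(
      log2 = c(1, 1.5, 2, 2.5, 3, 3.5, 4), cyc_lfc = 0,
      biotype = "protein_coding",
      downregulated = FALSE, biphasic = "none"),
    flat = list(
      log2 = rep(3, 7), cyc_lfc = 0, biotype = "protein_coding",
      downregulated = FALSE, biphasic = "none"),
    non_coding_decoy = list(
      log2 = peak2, cyc_lfc = 1.5, biotype = "lincRNA",
      downregulated = FALSE, biphasic = "none"),
    cyc_insensitive_decoy = list(
      log2 = peak2, cyc_lfc = 0.2, biotype = "protein_coding",
      downregulated = TRUE, biphasic = "none")
  )
}
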