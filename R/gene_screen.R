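#' Temporal expression-screen filters
#'
#' Two bespoke filters over per-gene time-course summary tables from an
#' embryonic-stem-cell differentiation series sampled at 0, 1, 2, 3.5,
#' 4.5, 5.5 and 6.5 days in differentiation conditions (DDC). The tables
#' carry FPKM values per time point plus pairwise log2 fold-changes and
#' p-values computed upstream by standard differential-expression
#' machinery (e.g. limma/voom); the filters consume those columns, they do
#' not fit models. Column naming: `fpkm_<t>`, `lfc_<t1>_<t2>`,
#' `p_<t1>_<t2>` with decimal points written as `p` (`3p5` = 3.5 DDC);
#' `lfc_sag_cyc_3p5` / `p_sag_cyc_3p5` contrast SAG- versus
#' cyclopamine-treated cultures at 3.5 DDC. The sign convention is
#' positive = higher at the first-named condition, so "down-regulated
#' between 3.5 and 5.5 DDC" corresponds to `lfc_3p5_5p5 >= cutoff`.
#'
#' `filter_downregulated()` flags genes down-regulated between 3.5 and
#' 5.5 DDC: `fpkm_3p5 >= 2`, `p_3p5_5p5 <= 0.05`,
#' `lfc_3p5_5p5 >= fc_cutoff` (default 0.22; 2.5 reproduces the stringent
#' tier) and protein-coding biotype. Raw p-values are gated, as printed;
#' multiple-testing correction belongs to the upstream DE step.
#'
#' Individual rules can be disabled via `relax` (rule ids in the `rule`
#' column of `screen_rules()`), which exists so that decoy classes
#' violating exactly one rule can be shown to be admitted by relaxing that
#' rule alone.
#'
#' @param table Data frame of per-gene summaries (see above; missing
#'   required columns raise an error naming them).
#' @param fc_cutoff Minimal log2 fold-change for the down-regulation
#'   contrast, `>= 0`.
#' @param relax Character vector of rule ids to disable.
#' @return The input tibble plus one logical column per rule
#'   (`pass_<rule>`) and `downregulated_pass`.
#' @examples
#' tbl <- generate_synthetic_expression(100, seed = 1)
#' sum(filter_downregulated(tbl)$downregulated_pass)
#' @export
filter_downregulated <- function(table, fc_cutoff = 0.22,
                                 relax = character()) {
  stopifnot(fc_cutoff >= 0)
  require_columns(table, c("fpkm_3p5", "p_3p5_5p5", "lfc_3p5_5p5",
                           "biotype"))
  rules <- list(
    fpkm = table$fpkm_3p5 >= 2,
    pvalue = table$p_3p5_5p5 <= 0.05,
    fold_change = table$lfc_3p5_5p5 >= fc_cutoff,
    biotype = table$biotype == "protein_coding")
  check_relax(relax, names(rules))
  out <- tibble::as_tibble(table)
  pass <- rep(TRUE, nrow(out))
  for (r in names(rules)) {
    out[[paste0("pass_", r)]] <- rules[[r]]
    if (!r %in% relax) pass <- pass & rules[[r]]
  }
  out$downregulated_pass <- pass
  out
}

#' Biphasic-gene classifier with cyclopamine-sensitivity gate
#'
#' Identifies genes whose expression peaks at 2 or 3.5 DDC and declines
#' thereafter, and whose induction is Shh-dependent (repressed by the Smo
#' antagonist cyclopamine). The initial gate requires expression
#' (`fpkm_2 >= 2` or `fpkm_3p5 >= 2`), CyC sensitivity
#' (`p_sag_cyc_3p5 <= 0.05` and `lfc_sag_cyc_3p5 >= 0.5`) and
#' protein-coding biotype. The peak rules are boolean conjunctions of the
#' printed inequalities:
#'
#' * peak at 2 DDC: differential expression against 0 and 6.5 DDC
#'   (`p_2_0 <= 0.05`, `p_2_6p5 <= 0.05`); up-regulation into the peak
#'   (`lfc_2_0 >= 0.5`, `lfc_2_1 >= 0`); down-regulation after it
#'   (`lfc_2_6p5 >= 0.5`, `lfc_2_5p5 >= 0.5`, `lfc_2_4p5 >= 0`).
#' * peak at 3.5 DDC: `p_3p5_0 <= 0.05`, `p_3p5_6p5 <= 0.05`;
#'   `lfc_3p5_0 >= 0.5`, `lfc_3p5_1 >= 0`, `lfc_2_1 >= 0`;
#'   `lfc_3p5_6p5 >= 0.5`, `lfc_3p5_5p5 >= 0.5`. (The `lfc_2_1 >= 0`
#'   condition inside the 3.5-peak rule is implemented verbatim from the
#'   published rule set, although it constrains the 2 DDC point.)
#'
#' A gene satisfying both peak rules is assigned the single peak time with
#' the higher FPKM (ties go to 2 DDC), so the final labels are mutually
#' exclusive: `"peak2"`, `"peak3p5"` or `"none"`.
#'
#' @inheritParams filter_downregulated
#' @return The input tibble plus logical columns `cyc_repressed`,
#'   `biphasic_peak2`, `biphasic_peak3p5` and the final `biphasic_label`.
#' @examples
#' tbl <- generate_synthetic_expression(100, seed = 1)
#' table(classify_biphasic(tbl)$biphasic_label)
#' @export
classify_biphasic <- function(table, relax = character()) {
  require_columns(table, c(
    "fpkm_2", "fpkm_3p5", "p_sag_cyc_3p5", "lfc_sag_cyc_3p5", "biotype",
    "p_2_0", "p_2_6p5", "lfc_2_0", "lfc_2_1", "lfc_2_6p5", "lfc_2_5p5",
    "lfc_2_4p5", "p_3p5_0", "p_3p5_6p5", "lfc_3p5_0", "lfc_3p5_1",
    "lfc_3p5_6p5", "lfc_3p5_5p5"))
  gate_rules <- list(
    fpkm = table$fpkm_2 >= 2 | table$fpkm_3p5 >= 2,
    cyc_p = table$p_sag_cyc_3p5 <= 0.05,
    cyc_fc = table$lfc_sag_cyc_3p5 >= 0.5,
    biotype = table$biotype == "protein_coding")
  peak2_rules <- list(
    peak2_de = table$p_2_0 <= 0.05 & table$p_2_6p5 <= 0.05,
    peak2_up_2_0 = table$lfc_2_0 >= 0.5,
    peak2_up_2_1 = table$lfc_2_1 >= 0,
    peak2_down_2_6p5 = table$lfc_2_6p5 >= 0.5,
    peak2_down_2_5p5 = table$lfc_2_5p5 >= 0.5,
    peak2_down_2_4p5 = table$lfc_2_4p5 >= 0)
  peak3_rules <- list(
    peak3p5_de = table$p_3p5_0 <= 0.05 & table$p_3p5_6p5 <= 0.05,
    peak3p5_up_3p5_0 = table$lfc_3p5_0 >= 0.5,
    peak3p5_up_3p5_1 = table$lfc_3p5_1 >= 0,
    peak3p5_up_2_1 = table$lfc_2_1 >= 0,
    peak3p5_down_3p5_6p5 = table$lfc_3p5_6p5 >= 0.5,
    peak3p5_down_3p5_5p5 = table$lfc_3p5_5p5 >= 0.5)
  all_ids <- c(names(gate_rules), names(peak2_rules), names(peak3_rules))
  check_relax(relax, all_ids)
  conj <- function(rules) {
    keep <- setdiff(names(rules), relax)
    Reduce(`&`, rules[keep], rep(TRUE, nrow(table)))
  }
  gate <- conj(gate_rules)
  peak2 <- gate & conj(peak2_rules)
  peak3 <- gate & conj(peak3_rules)
  out <- tibble::as_tibble(table)
  out$cyc_repressed <- gate
  out$biphasic_peak2 <- peak2
  out$biphasic_peak3p5 <- peak3
  out$biphasic_label <- dplyr::case_when(
    peak2 & peak3 & out$fpkm_3p5 > out$fpkm_2 ~ "peak3p5",
    peak2 ~ "peak2",
    peak3 ~ "peak3p5",
    .default = "none")
  out
}

#' @rdname filter_downregulated
#' @export
screen_rules <- function() {
  tibble::tibble(
    filter = c(rep("downregulated", 4), rep("biphasic", 16)),
    rule = c("fpkm", "pvalue", "fold_change", "biotype",
             "fpkm", "cyc_p", "cyc_fc", "biotype",
             "peak2_de", "peak2_up_2_0", "peak2_up_2_1",
             "peak2_down_2_6p5", "peak2_down_2_5p5", "peak2_down_2_4p5",
             "peak3p5_de", "peak3p5_up_3p5_0", "peak3p5_up_3p5_1",
             "peak3p5_up_2_1", "peak3p5_down_3p5_6p5",
             "peak3p5_down_3p5_5p5"))
}

require_columns <- function(table, cols) {
  missing <- setdiff(cols, names(table))
  if (length(missing) > 0) {
    stop("Expression table is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  invisible(NULL)
}

check_relax <- function(relax, known) {
  bad <- setdiff(relax, known)
  if (length(bad) > 0) {
    stop("Unknown rule id(s) in `relax`: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  invisible(NULL)
}
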