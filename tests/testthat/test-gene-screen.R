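test_that("a noiseless table is recovered exactly by both filters", {
  tbl <- generate_synthetic_expression(420, noise_sd = 0, seed = 1)
  dn <- filter_downregulated(tbl)
  expect_identical(dn$downregulated_pass, tbl$true_downregulated)
  bp <- classify_biphasic(tbl)
  expect_identical(bp$biphasic_label, tbl$true_biphasic_label)
  # final labels are mutually exclusive by construction
  expect_false(any(bp$biphasic_label == "peak2" &
                     bp$biphasic_label == "peak3p5"))
})

test_that("hand-built genes hit the printed thresholds", {
  base <- generate_synthetic_expression(10, noise_sd = 0, seed = 1)
  g <- base[base$true_class == "flat", ][1, ]
  g$fpkm_3p5 <- 10; g$p_3p5_5p5 <- 0.01; g$lfc_3p5_5p5 <- 0.5
  g$biotype <- "protein_coding"
  expect_true(filter_downregulated(g)$downregulated_pass)
  # FPKM below 2 at 3.5 DDC fails regardless of the other rules
  g$fpkm_3p5 <- 1.5
  expect_false(filter_downregulated(g)$downregulated_pass)
  g$fpkm_3p5 <- 10
  # stringent tier
  expect_false(filter_downregulated(g, fc_cutoff = 2.5)$downregulated_pass)
  g$lfc_3p5_5p5 <- 2.6
  expect_true(filter_downregulated(g, fc_cutoff = 2.5)$downregulated_pass)

  # a gene failing only the CyC fold-change gate is not biphasic
  tbl <- generate_synthetic_expression(420, noise_sd = 0, seed = 1)
  cyc <- tbl[tbl$true_class == "biphasic_peak2", ][1, ]
  cyc$lfc_sag_cyc_3p5 <- 0.3
  expect_equal(classify_biphasic(cyc)$biphasic_label, "none")
})

test_that("flat genes pass nothing", {
  tbl <- generate_synthetic_expression(
    100, class_mix = c(biphasic_peak2 = 0, biphasic_peak3p5 = 0,
                       monotone_down = 0, monotone_up = 0, flat = 1,
                       non_coding_decoy = 0, cyc_insensitive_decoy = 0),
    noise_sd = 0, seed = 3)
  expect_false(any(filter_downregulated(tbl)$downregulated_pass))
  expect_true(all(classify_biphasic(tbl)$biphasic_label == "none"))
})

test_that("each decoy class is rejected by exactly its planted rule", {
  tbl <- generate_synthetic_expression(700, noise_sd = 0, seed = 2)
  nc <- tbl[tbl$true_class == "non_coding_decoy", ]
  ci <- tbl[tbl$true_class == "cyc_insensitive_decoy", ]

  expect_true(all(classify_biphasic(nc)$biphasic_label == "none"))
  expect_true(all(
    classify_biphasic(nc, relax = "biotype")$biphasic_label == "peak2"))
  expect_false(any(filter_downregulated(nc)$downregulated_pass))
  expect_true(all(
    filter_downregulated(nc, relax = "biotype")$downregulated_pass))

  expect_true(all(classify_biphasic(ci)$biphasic_label == "none"))
  expect_true(all(
    classify_biphasic(ci, relax = "cyc_fc")$biphasic_label == "peak2"))
  # relaxing an unrelated rule does not admit them
  expect_true(all(
    classify_biphasic(ci, relax = "biotype")$biphasic_label == "none"))
  expect_error(classify_biphasic(ci, relax = "no_such_rule"),
               "no_such_rule")
})

test_that("the down-regulated filter is monotone in its cutoff and idempotent", {
  tbl <- generate_synthetic_expression(500, noise_sd = 0.3, seed = 9)
  counts <- vapply(c(0.22, 0.5, 1, 2.5), function(fc) {
    sum(filter_downregulated(tbl, fc_cutoff = fc)$downregulated_pass)
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))

  first <- filter_downregulated(tbl)
  kept <- first[first$downregulated_pass, names(tbl)]
  again <- filter_downregulated(kept)
  expect_true(all(again$downregulated_pass))
  expect_identical(again$gene_id, kept$gene_id)
  # order independence: the two filters commute on shared columns
  ab <- classify_biphasic(filter_downregulated(tbl))
  ba <- filter_downregulated(classify_biphasic(tbl))
  expect_identical(ab$biphasic_label, ba$biphasic_label)
  expect_identical(ab$downregulated_pass, ba$downregulated_pass)
})

test_that("missing contrast columns raise errors naming them", {
  tbl <- generate_synthetic_expression(20, noise_sd = 0, seed = 1)
  broken <- tbl[, setdiff(names(tbl), c("lfc_3p5_5p5", "p_2_0"))]
  expect_error(filter_downregulated(broken), "lfc_3p5_5p5")
  expect_error(classify_biphasic(broken), "p_2_0")
  expect_error(generate_synthetic_expression(
    10, class_mix = c(biphasic_peak2 = 0.5, biphasic_peak3p5 = 0.1,
                      monotone_down = 0.1, monotone_up = 0.1, flat = 0.1,
                      non_coding_decoy = 0.1,
                      cyc_insensitive_decoy = 0.2)),
    "sum to 1")
})

test_that("moderate noise yields high but imperfect recovery", {
  tbl <- generate_synthetic_expression(700, noise_sd = 0.1, seed = 5)
  bp <- classify_biphasic(tbl)
  truth <- tbl$true_biphasic_label
  acc <- mean(bp$biphasic_label == truth)
  expect_gt(acc, 0.9)
  dn <- filter_downregulated(tbl)
  expect_gt(mean(dn$downregulated_pass == tbl$true_downregulated), 0.9)
})
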