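ratio_tab <- gastric_reference("arm_ratio")

test_that("published arm counts reproduce their printed ratios", {
  rec <- arm_ratios(ratio_tab)
  fmt <- format_arm_ratios(rec)
  expect_equal(fmt$ratio_a, ratio_tab$ratio_n53p)
  expect_equal(fmt$ratio_b, ratio_tab$ratio_t53p)
  expect_equal(fmt$fold_change, ratio_tab$fold_change)
  expect_true(all(rec$significant))   # every listed hairpin exceeds 3-fold
})

test_that("fold change is symmetric, >= 1, and scale invariant", {
  rec <- arm_ratios(ratio_tab)
  swapped <- ratio_tab
  names(swapped)[match(c("N5p", "N3p", "T5p", "T3p"), names(swapped))] <-
    c("T5p", "T3p", "N5p", "N3p")
  rec_sw <- arm_ratios(swapped)
  expect_equal(rec$fold_change, rec_sw$fold_change)
  scaled <- ratio_tab
  scaled$N5p <- scaled$N5p * 7; scaled$N3p <- scaled$N3p * 7
  scaled$T5p <- scaled$T5p * 3; scaled$T3p <- scaled$T3p * 3
  expect_equal(arm_ratios(scaled)$fold_change, rec$fold_change)
  expect_true(all(rec$fold_change >= 1))
})

test_that("count filter and fold threshold flag exactly the planted rows", {
  fcs <- c(1, 2, 3, 3.01, 50)
  tab <- data.frame(premirna_id = sprintf("p%g", fcs),
                    N5p = 1000 * fcs, N3p = 1000, T5p = 1000, T3p = 1000)
  rec <- arm_ratios(tab)
  expect_equal(rec$premirna_id[rec$significant], c("p3.01", "p50"))
  # symmetric case: no signal
  rec <- arm_ratios(data.frame(premirna_id = "x", N5p = 10, N3p = 10,
                               T5p = 10, T3p = 10))
  expect_equal(rec$ratio_a, 1)
  expect_equal(rec$fold_change, 1)
  expect_true(rec$passes_count_filter)
  expect_false(rec$significant)
  # below-threshold counts never significant, zero denominators infinite
  rec <- arm_ratios(data.frame(premirna_id = "y", N5p = 900, N3p = 9,
                               T5p = 10, T3p = 0))
  expect_false(rec$passes_count_filter)
  expect_false(rec$significant)
  expect_true(is.infinite(rec$ratio_b))
})

test_that("exchange labels match the published annotation contradictions", {
  ex <- gastric_reference("exchange")
  calls <- mirbase_consistency(ex)
  expect_equal(calls$exch_label, ex$exch_label)
  # spot checks against the printed narrative
  expect_equal(calls$exch_label[ex$premirna_id == "hsa-mir-1307"], "N")
  expect_equal(calls$exch_label[ex$premirna_id == "hsa-mir-1303"], "T")
  expect_equal(calls$exch_label[ex$premirna_id == "hsa-mir-376b"], "N")
})

test_that("consistent hairpins and ties yield empty labels", {
  tab <- data.frame(premirna_id = c("ok", "tied"),
                    N5p = c(100, 50), N3p = c(10, 50),
                    T5p = c(80, 40), T3p = c(8, 50))
  calls <- mirbase_consistency(tab, mirbase_major = "5p")
  expect_equal(calls$exch_label[1], "")
  expect_equal(calls$major_arm_a[2], "tie")
  expect_equal(calls$exch_label[2], "T")   # only library B contradicts
})

test_that("all published switch rows are recovered; ties are not switches", {
  sw <- gastric_reference("switch")
  calls <- tissue_switch_calls(sw)
  expect_true(all(calls$tissue_switch))
  none <- tissue_switch_calls(data.frame(premirna_id = "flat", N5p = 5,
                                         N3p = 5, T5p = 5, T3p = 5))
  expect_false(none$tissue_switch)
})

test_that("half-up rounding matches the printed presentation", {
  # base round() would give 2 for both of these (round-half-even)
  expect_equal(round_half_up(2.5), 3)
  expect_equal(round_half_up(0.25, 1), 0.3)
  expect_equal(round_half_up(-2.5), -3)
  expect_equal(round_half_up(0.0625, 3), 0.063)
})
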