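test_that("primer efficiency follows E = 10^(-1/m) - 1", {
  # perfect doubling: slope -1/log10(2)
  s <- simulate_dilution_series(amplification = 2, noise_sd = 0)
  eff <- primer_efficiency(s)
  expect_equal(eff$slope, -1 / log10(2), tolerance = 1e-6)
  expect_equal(eff$efficiency, 1.0, tolerance = 1e-4)

  # ten-fold amplification per cycle: slope -1, E = 9
  s10 <- simulate_dilution_series(amplification = 10, noise_sd = 0)
  expect_equal(primer_efficiency(s10)$efficiency, 9.0, tolerance = 1e-9)

  # hand-computed regression oracle: CT = 30 - 3 * log10(ng) exactly
  ng <- c(0.1, 1, 10, 100)
  ct <- 30 - 3 * log10(ng)
  eff3 <- primer_efficiency(ng = ng, ct = ct)
  expect_equal(eff3$slope, -3.0, tolerance = 1e-12)
  expect_equal(eff3$efficiency, 10^(1 / 3) - 1, tolerance = 1e-12)
})

test_that("degenerate dilution series are rejected", {
  expect_error(primer_efficiency(ng = c(1, 10), ct = c(30, 27)), ">= 3")
  expect_error(primer_efficiency(ng = c(1, 2, 3), ct = c(30, 29, 28.5)),
               "log10")
  expect_error(primer_efficiency(ng = c(0.1, 1, 10), ct = c(28, 28, 28)),
               "negative")
  expect_error(primer_efficiency(ng = c(-1, 1, 10), ct = c(30, 28, 26)),
               "positive")
})

test_that("efficiency slope is invariant to CT shifts and input rescaling", {
  ng <- c(0.5, 5, 50, 500)
  ct <- 31.2 - 3.1 * log10(ng)
  base <- primer_efficiency(ng = ng, ct = ct)
  shifted <- primer_efficiency(ng = ng, ct = ct + 4.7)
  expect_equal(shifted$slope, base$slope, tolerance = 1e-12)
  # relabeling the input amounts by a common factor changes only the intercept
  rescaled <- primer_efficiency(ng = ng * 1000, ct = ct)
  expect_equal(rescaled$slope, base$slope, tolerance = 1e-12)
  expect_equal(rescaled$efficiency, base$efficiency, tolerance = 1e-12)
})

test_that("the primer filter is inclusive at the threshold", {
  eff <- c(good = 2.1, edge = 1.6, below = 1.59, poor = 0.9)
  out <- filter_primers(eff)
  expect_identical(out$accepted, c("good", "edge"))
  expect_identical(out$rejected, c("below", "poor"))
  # configurable threshold
  out2 <- filter_primers(eff, threshold = 1.0)
  expect_identical(out2$rejected, "poor")
  empty <- filter_primers(numeric(0))
  expect_identical(empty$accepted, character(0))
  expect_identical(empty$rejected, character(0))
})

test_that("relative expression is 2^-dCT against the reference gene", {
  ref <- ct_measurement("HPRT", "RM", c(18.85, 18.85, 18.85))
  same <- ct_measurement("GENE", "RM", rep(18.85, 3))
  expect_equal(relative_expression(same, ref)$rel_expr, 1.0)
  lower <- ct_measurement("GENE", "RM", rep(21.85, 3))
  expect_equal(relative_expression(lower, ref)$rel_expr, 0.125)
  higher <- ct_measurement("GENE", "RM", rep(15.85, 3))
  expect_equal(relative_expression(higher, ref)$rel_expr, 8.0)

  other_cond <- ct_measurement("GENE", "DM_day2", rep(20, 3))
  expect_error(relative_expression(other_cond, ref), "condition")
})

test_that("fold change is 2^-ddCT with the baseline mapping to 1", {
  ref_a <- ct_measurement("HPRT", "A", rep(19, 3))
  ref_b <- ct_measurement("HPRT", "B", rep(19, 3))
  base <- relative_expression(ct_measurement("G", "A", rep(22, 3)), ref_a)
  expect_equal(fold_change(base, base)$fold_change, 1.0)

  target <- relative_expression(ct_measurement("G", "B", rep(21, 3)), ref_b)
  fc <- fold_change(target, base)
  expect_equal(fc$delta_delta_ct, -1)
  expect_equal(fc$fold_change, 2.0)

  # dCT 4.585 vs baseline 3.0 -> 2^-1.585
  t2 <- relative_expression(ct_measurement("G", "B", rep(19 + 4.585, 3)), ref_b)
  b2 <- relative_expression(ct_measurement("G", "A", rep(22, 3)), ref_a)
  expect_equal(fold_change(t2, b2)$fold_change, 2^(-1.585), tolerance = 1e-12)
  expect_equal(fold_change(t2, b2)$fold_change, 0.3333, tolerance = 1e-3)

  wrong_gene <- relative_expression(ct_measurement("H", "B", rep(21, 3)), ref_b)
  expect_error(fold_change(wrong_gene, base), "same gene")
})

test_that("between-gene ratios follow 2^(dCT_b - dCT_a) and reciprocity", {
  ref <- ct_measurement("HPRT", "RM", rep(19, 3))
  a <- relative_expression(ct_measurement("A", "RM", rep(20, 3)), ref)
  b <- relative_expression(ct_measurement("B", "RM", rep(20, 3)), ref)
  expect_equal(expression_ratio(a, b), 1.0)

  # a CT gap of exactly log2(340) cycles gives a 340-fold ratio
  hi <- relative_expression(ct_measurement("HI", "RM", rep(20, 3)), ref)
  lo <- relative_expression(
    ct_measurement("LO", "RM", rep(20 + log2(340), 3)), ref)
  expect_equal(expression_ratio(hi, lo), 340, tolerance = 1e-9)
  expect_equal(expression_ratio(hi, lo) * expression_ratio(lo, hi), 1,
               tolerance = 1e-12)
})

test_that("comparative-CT algebra holds for random CT tables", {
  set.seed(7)
  for (i in 1:50) {
    ref <- ct_measurement("HPRT", "X", runif(3, 15, 25))
    tgt <- ct_measurement("G", "X", runif(3, 15, 30))
    r <- relative_expression(tgt, ref)
    expect_equal(log2(r$rel_expr), -r$delta_ct, tolerance = 1e-12)
  }
  # the two routes to a fold change agree: 2^-ddCT == ratio of 2^-dCT
  ref_a <- ct_measurement("HPRT", "A", runif(3, 15, 25))
  ref_b <- ct_measurement("HPRT", "B", runif(3, 15, 25))
  base <- relative_expression(ct_measurement("G", "A", runif(3, 18, 30)), ref_a)
  tgt <- relative_expression(ct_measurement("G", "B", runif(3, 18, 30)), ref_b)
  fc <- fold_change(tgt, base)
  expect_equal(fc$fold_change, tgt$rel_expr / base$rel_expr, tolerance = 1e-12)
})

test_that("table-level expression pipeline averages replicates and joins baseline", {
  sim <- simulate_ct_table(
    matrix(c(2, 0.5, 1, 1), nrow = 2,
           dimnames = list(c("GA", "GB"), c("day2", "day6"))),
    ct_noise_sd = 0)
  out <- qpcr_expression(sim$ct_table, baseline = "day2")
  expect_equal(out$rel_expr[out$gene == "GA" & out$condition == "day2"], 2)
  expect_equal(out$fold_change[out$gene == "GA" & out$condition == "day2"], 1)
  expect_equal(out$fold_change[out$gene == "GA" & out$condition == "day6"], 0.5)
  expect_equal(out$fold_change[out$gene == "GB" & out$condition == "day6"], 2)

  expect_error(qpcr_expression(sim$ct_table, reference_gene = "GAPDH"),
               "reference gene")
  expect_error(qpcr_expression(sim$ct_table, baseline = "day9"), "baseline")
})

test_that("control reactions with detectable CT fail QC", {
  tbl <- data.frame(gene = c("G", "G", "G"), condition = "RM",
                    replicate = 1:3, ct = c(20, 39.9, NA),
                    is_reference = FALSE, is_control = c(FALSE, TRUE, TRUE))
  qc <- qc_controls(tbl)
  expect_false(qc$pass)
  expect_identical(nrow(qc$failures), 1L)
  # at or above the cutoff counts as undetermined
  tbl$ct[2] <- 40
  expect_true(qc_controls(tbl)$pass)
})
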