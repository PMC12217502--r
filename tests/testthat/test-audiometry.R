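# Audiometric definitions: PTA variants, SNHL criterion, per-visit
# stability designation, cumulative shift, and inclusion screening, checked
# against direct enumeration of the rules.

test_that("PTA variants average the correct frequency sets", {
  a <- ag(c(10, 20, 30, 40, 50, 60))
  expect_equal(compute_pta(a, "four_freq"), mean(c(20, 30, 40, 50)))
  expect_equal(compute_pta(a, "lf"), 15)
  expect_equal(compute_pta(a, "hf"), 55)
  a4 <- audiogram(c(`0.5` = 20, `1` = 30, `2` = 40, `4` = 50))
  expect_equal(compute_pta(a4, "four_freq"), 35)
  miss <- audiogram(c(`0.25` = 10, `0.5` = 15, `1` = 20, `2` = 25, `8` = 30))
  expect_error(compute_pta(miss, "hf"), "4")
})

test_that("SNHL requires PTA above 25 dB with an air-bone gap at most 10 dB", {
  expect_true(classify_snhl(30, 5))
  expect_false(classify_snhl(25, 5))   # strict >
  expect_false(classify_snhl(40, 15))  # conductive component
  expect_true(classify_snhl(26, 10))   # weak <= on the gap
})

test_that("stability designation follows the quoted shift rules", {
  d20 <- ag_pair(c(0, 0, 20, 0, 0, 0))
  expect_equal(classify_stability(d20$current, d20$prior)$designation,
               "unstable_worsened")
  d15 <- ag_pair(c(0, 0, 15, 15, 0, 0))
  expect_equal(classify_stability(d15$current, d15$prior)$designation,
               "unstable_worsened")
  # 15 dB at non-consecutive frequencies does not trigger
  d15nc <- ag_pair(c(0, 15, 0, 0, 15, 0))
  expect_equal(classify_stability(d15nc$current, d15nc$prior)$designation,
               "stable")
  d19 <- ag_pair(c(0, 0, 19, 0, 0, 0))
  expect_equal(classify_stability(d19$current, d19$prior)$designation, "stable")
  expect_equal(classify_stability(d20$current, NULL)$designation,
               "unknown_baseline")
  # improvement triggers too, and the sign of the cumulative shift splits it
  dneg <- ag_pair(c(0, 0, -20, 0, 0, 0))
  res <- classify_stability(dneg$current, dneg$prior)
  expect_equal(res$designation, "unstable_improved")
  expect_equal(res$cumulative_shift, -20)
  # mismatched grids
  short <- audiogram(c(`0.5` = 10, `1` = 10, `2` = 10, `4` = 10))
  expect_error(classify_stability(short, d20$prior), "grids")
})

test_that("cumulative shift sums signed deltas strictly larger than 10 dB", {
  p <- ag_pair(c(25, -5, 0, 15, 10, 0))
  expect_equal(cumulative_shift(p$current, p$prior), 40)
  p2 <- ag_pair(c(10, -10, 5, 0, 10, -10))
  expect_equal(cumulative_shift(p2$current, p2$prior), 0)
  p3 <- ag_pair(c(-20, 15, 0, 0, 0, 0))
  expect_equal(cumulative_shift(p3$current, p3$prior), -5)
  expect_equal(classify_stability(p3$current, p3$prior)$designation,
               "unstable_improved")
})

test_that("an unstable trigger with exactly cancelling shifts is flagged indeterminate", {
  p <- ag_pair(c(20, 0, 0, -20, 0, 0))
  expect_warning(res <- classify_stability(p$current, p$prior), "indeterminate")
  expect_equal(res$designation, "unstable_indeterminate")
  expect_true(res$unstable)
})

test_that("stability and cumulative shift match brute-force rule enumeration", {
  vals <- c(0, 5, -5, 10, -10, 15, -15, 20, -20, 25, 30)
  set.seed(42)
  for (i in 1:400) {
    delta <- sample(vals, 6, replace = TRUE)
    p <- ag_pair(delta, base = 40)
    orc <- oracle_stability(delta)
    res <- suppressWarnings(classify_stability(p$current, p$prior))
    expect_identical(res$unstable, orc$unstable,
                     label = paste("delta:", paste(delta, collapse = ",")))
    expect_equal(res$cumulative_shift, orc$shift)
    expect_equal(cumulative_shift(p$current, p$prior), orc$shift)
  }
})

test_that("negating all deltas preserves instability and swaps direction", {
  set.seed(43)
  for (i in 1:100) {
    delta <- sample(seq(-30, 30, by = 5), 6, replace = TRUE)
    p <- ag_pair(delta, base = 50)
    n <- ag_pair(-delta, base = 50)
    a <- suppressWarnings(classify_stability(p$current, p$prior))
    b <- suppressWarnings(classify_stability(n$current, n$prior))
    expect_identical(a$unstable, b$unstable)
    expect_equal(a$cumulative_shift, -b$cumulative_shift)
    if (isTRUE(a$unstable) && a$cumulative_shift != 0) {
      swap <- c(unstable_improved = "unstable_worsened",
                unstable_worsened = "unstable_improved")
      expect_identical(a$designation, unname(swap[b$designation]))
    }
  }
})

test_that("self-comparison is always stable with zero shift", {
  a <- ag(c(15, 25, 40, 55, 60, 70))
  expect_equal(classify_stability(a, a)$designation, "stable")
  expect_equal(cumulative_shift(a, a), 0)
})

test_that("inclusion screening applies the fluctuating and sudden criteria", {
  base <- ag(rep(20, 6))
  sudden <- ag(c(20, 20, 50, 55, 55, 20))
  res <- check_hi_inclusion(list(base, sudden))
  expect_true(res$eligible)
  expect_equal(res$criterion, "sudden")
  # 15 dB at two non-adjacent frequencies qualifies (no adjacency in the
  # inclusion rule, unlike the per-visit stability rule)
  fluct <- ag(c(20, 35, 20, 20, 35, 20))
  res2 <- check_hi_inclusion(list(base, fluct))
  expect_true(res2$eligible)
  expect_equal(res2$criterion, "fluctuating")
  expect_equal(suppressWarnings(
    classify_stability(fluct, base))$designation, "stable")
  flat <- check_hi_inclusion(list(base, base, base))
  expect_false(flat$eligible)
  expect_equal(flat$criterion, "none")
  expect_error(check_hi_inclusion(list(base)), "2")
})
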