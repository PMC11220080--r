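test_that("cumulative change matches hand computation on triplicates", {
  tp <- rep(c(0, 6, 12, 18), each = 3)
  v_std <- matrix(c(3, 4, 5, 1, 2, 3, 6, 6, 6, 2, 2, 2,
                    rep(1, 12)), 2, 12, byrow = TRUE,
                  dimnames = list(c("a", "b"), NULL))
  m_std <- toy_matrix(v_std, times = tp, condition = "STD")
  v_ecd <- v_std * 2
  m_ecd <- toy_matrix(v_ecd, times = tp, condition = "ECD")
  cc <- cumulative_change(m_std, m_ecd)
  # hand: S_std(a) = 4 + 2 + 6 + 2 = 14; S_ecd(a) = 28 -> +100%
  expect_equal(unname(cc["a"]), 100)
  expect_equal(unname(cc["b"]), 100)
  # identical series give 0
  expect_equal(unname(cumulative_change(m_std, {
    m <- m_std; m$samples$condition <- "ECD"; m
  })), c(0, 0))
  # zero baseline -> NA
  v0 <- v_std; v0[1, ] <- 0
  m0 <- toy_matrix(v0, times = tp, condition = "STD")
  expect_true(is.na(cumulative_change(m0, m_ecd)["a"]))
})

test_that("cumulative change ignores replicate order and count", {
  tp <- rep(c(0, 6, 12, 18), each = 3)
  set.seed(2)
  v <- matrix(rexp(24) * 10, 2, 12, dimnames = list(c("a", "b"), NULL))
  m_std <- toy_matrix(v, times = tp, condition = "STD")
  m_ecd <- toy_matrix(v * 1.5, times = tp, condition = "ECD")
  base <- cumulative_change(m_std, m_ecd)
  # shuffle replicate columns within timepoints
  perm <- as.vector(vapply(split(seq_len(12), tp), sample,
                           numeric(3)))
  m_shuf <- toy_matrix(v[, perm], times = tp[perm], condition = "STD")
  expect_equal(cumulative_change(m_shuf, m_ecd), base)
  # duplicate every replicate set (same per-timepoint means)
  v2 <- cbind(v, v)
  m_dup <- toy_matrix(v2, times = c(tp, tp), condition = "STD")
  expect_equal(cumulative_change(m_dup, m_ecd), base)
})

test_that("pooled t-test matches the textbook formula and t.test", {
  a <- c(1, 2, 3); b <- c(1, 2, 3, 4, 5)
  out <- compare_populations(a, b)
  # hand-derived pooled-variance computation
  sp2 <- (sum((a - mean(a))^2) + sum((b - mean(b))^2)) / (3 + 5 - 2)
  t_hand <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / 3 + 1 / 5))
  p_hand <- 2 * pt(abs(t_hand), 6, lower.tail = FALSE)
  expect_equal(out$t_statistic, t_hand)
  expect_equal(out$p_value, p_hand)
  expect_equal(out$df, 6)
  ref <- t.test(a, b, var.equal = TRUE)
  expect_equal(out$t_statistic, unname(ref$statistic))
  expect_equal(out$p_value, ref$p.value)
})

test_that("degenerate and symmetric cases behave as documented", {
  x <- c(2, 2, 2)
  same <- compare_populations(x, x)
  expect_identical(same$t_statistic, 0)
  expect_identical(same$p_value, 1)
  shifted <- compare_populations(x, x + 1)
  expect_true(is.infinite(shifted$t_statistic))
  expect_lte(shifted$p_value, .Machine$double.xmin)
  # sign symmetry
  set.seed(5)
  a <- rnorm(10); b <- rnorm(12, 1)
  ab <- compare_populations(a, b)
  ba <- compare_populations(b, a)
  expect_equal(ab$t_statistic, -ba$t_statistic)
  expect_equal(ab$p_value, ba$p_value)
  expect_error(compare_populations(1, c(1, 2)), "at least 2")
})

test_that("null p-values are uniform (KS at alpha 0.01)", {
  set.seed(11)
  p <- replicate(400, {
    compare_populations(rnorm(15), rnorm(15))$p_value
  })
  expect_gt(ks.test(p, "punif")$p.value, 0.01)
})

test_that("phase histogram bins, circular mean and R behave", {
  h <- phase_histogram(rep(7, 5))
  expect_equal(unname(h$counts["CT6"]), 5)
  expect_equal(sum(h$counts), 5)
  expect_equal(h$circular_mean, 7, tolerance = 1e-9)
  expect_equal(h$resultant_length, 1, tolerance = 1e-12)
  # uniform grid phases: equal bins, R = 0 by symmetry
  hu <- phase_histogram(seq(0, 21, 3))
  expect_true(all(hu$counts == 1))
  expect_equal(hu$resultant_length, 0, tolerance = 1e-12)
  # brute-force binning on random phases; half-open bins
  set.seed(3)
  ph <- runif(100, 0, 24)
  hb <- phase_histogram(ph, bin_hours = 3)
  brute <- vapply(seq(0, 21, 3), function(lo) {
    sum(ph >= lo & ph < lo + 3)
  }, numeric(1))
  expect_equal(unname(hb$counts), brute)
  expect_equal(sum(hb$counts), 100)
  # boundary phase lands in the upper bin only
  expect_equal(unname(phase_histogram(c(3))$counts["CT3"]), 1)
  # empty input
  he <- phase_histogram(numeric(0))
  expect_true(is.na(he$resultant_length) || he$n == 0)
  expect_equal(sum(he$counts), 0)
  expect_error(phase_histogram(25), "\\[0, 24\\)")
})
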