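test_that("summaries report interpolated quartiles and a fixed-width histogram", {
  s <- summarize_forces(c(10, 20, 30, 40, 50))
  expect_equal(s$q25, 20)
  expect_equal(s$median, 30)
  expect_equal(s$q75, 40)
  expect_equal(s$n, 5)
  expect_equal(s$histogram$breaks, seq(0, 50, by = 10))
  expect_equal(sum(s$histogram$counts), 5)
  labelled <- summarize_forces(pool_condition(
    data.frame(class = "jump", force_pN = c(45, 55)), "NF-NF",
    velocity_v = 5))
  expect_identical(labelled$condition_label, "NF-NF")
  expect_equal(labelled$velocity_v, 5)
})

test_that("an empty dataset summarizes to an n = 0 sentinel", {
  s <- summarize_forces(numeric(0))
  expect_equal(s$n, 0L)
  expect_true(is.na(s$median))
  expect_length(s$histogram$counts, 0)
})

test_that("velocity trends recover slope and rank correlation", {
  vt <- velocity_trend(c(3, 5, 7.5, 10), 10 + 4 * c(3, 5, 7.5, 10))
  expect_equal(vt$slope, 4, tolerance = 1e-12)
  expect_equal(vt$intercept, 10, tolerance = 1e-12)
  expect_equal(vt$spearman_rho, 1)
  down <- velocity_trend(c(3, 5, 7.5), c(30, 20, 10))
  expect_equal(down$spearman_rho, -1)
  expect_error(velocity_trend(c(3, 5), c(1, 2)), "at least 3")
})

test_that("small-sample rank-sum p-values are exact", {
  cmp <- wilcoxon_ranksum(c(1, 2, 3), c(4, 5, 6))
  expect_equal(cmp$U, 0)
  expect_equal(cmp$p_value, 0.1)       # 2 * 1/choose(6,3)
  expect_identical(cmp$method, "exact enumeration")
  same <- wilcoxon_ranksum(c(5, 6, 7), c(5, 6, 7))
  expect_equal(same$p_value, 1)
})

test_that("exact p-values agree with the tie-free reference implementation", {
  set.seed(33)
  for (rep in 1:10) {
    a <- rnorm(7); b <- rnorm(9, 0.5)
    ours <- wilcoxon_ranksum(a, b)
    ref <- stats::wilcox.test(a, b, exact = TRUE, correct = FALSE)
    expect_equal(ours$p_value, unname(ref$p.value), tolerance = 1e-12)
    expect_equal(ours$U, unname(ref$statistic))
  }
})

test_that("exact p-values match a brute-force oracle in the presence of ties", {
  set.seed(44)
  for (rep in 1:8) {
    a <- sample(1:6, 6, replace = TRUE)
    b <- sample(1:6, 7, replace = TRUE)
    expect_equal(wilcoxon_ranksum(a, b)$p_value, bruteforce_ranksum_p(a, b),
                 tolerance = 1e-12)
  }
})

test_that("the p-value is invariant under swapping the samples", {
  set.seed(55)
  a <- rnorm(6); b <- rnorm(11, 0.3)
  expect_equal(wilcoxon_ranksum(a, b)$p_value,
               wilcoxon_ranksum(b, a)$p_value, tolerance = 1e-12)
})

test_that("the normal approximation tracks the exact enumeration", {
  set.seed(66)
  a <- rnorm(12, 0, 1); b <- rnorm(12, 0.8, 1)
  exact <- wilcoxon_ranksum(a, b, exact_max = 12)
  approx <- wilcoxon_ranksum(a, b)       # min n = 12 > default exact_max
  expect_identical(exact$method, "exact enumeration")
  expect_match(approx$method, "normal approximation")
  expect_lt(abs(exact$p_value - approx$p_value), 0.02)
})

test_that("clear separations earn significance stars", {
  set.seed(77)
  a <- rnorm(20, 50, 5); b <- rnorm(20, 100, 5)
  cmp <- wilcoxon_ranksum(a, b)
  expect_lt(cmp$p_value, 0.005)
  expect_identical(cmp$stars, "**")
  expect_identical(wilcoxon_ranksum(a, a + 0.01)$stars, "")
})

test_that("condition datasets feed the test with their labels", {
  da <- pool_condition(data.frame(class = "jump", force_pN = rnorm(8, 50, 5)),
                       "NF-NF", "none")
  db <- pool_condition(data.frame(class = "jump", force_pN = rnorm(8, 80, 5)),
                       "NF-NF", "ML7")
  cmp <- wilcoxon_ranksum(da, db)
  expect_identical(cmp$label_a, "NF-NF/none")
  expect_identical(cmp$label_b, "NF-NF/ML7")
  expect_error(wilcoxon_ranksum(numeric(0), rnorm(3)), "non-empty")
})

test_that("summary tables are deterministically ordered with fixed columns", {
  s1 <- summarize_forces(pool_condition(
    data.frame(class = "jump", force_pN = c(40, 50)), "NF-NF", "none", 5))
  s2 <- summarize_forces(pool_condition(
    data.frame(class = "jump", force_pN = c(60, 70)), "DF-DF", "none", 3))
  tab <- build_summary_table(list(s1, s2))
  expect_identical(names(tab), c("condition", "treatment", "velocity_um_s",
                                 "n", "q25_pN", "median_pN", "q75_pN"))
  expect_identical(tab$condition, c("DF-DF", "NF-NF"))
  expect_equal(nrow(build_summary_table(list())), 0)
})

test_that("treatment comparison triples are labelled and complete", {
  set.seed(88)
  ctrl <- rnorm(15, 60, 8); veh <- rnorm(15, 60, 8); drug <- rnorm(15, 30, 8)
  trio <- compare_treatments(ctrl, veh, drug)
  expect_identical(names(trio),
                   c("control_vs_dmso", "dmso_vs_drug", "control_vs_drug"))
  expect_gt(trio$control_vs_dmso$p_value, 0.05)
  expect_lt(trio$control_vs_drug$p_value, 0.005)
})
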