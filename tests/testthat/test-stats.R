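# The K^2 reference values below were computed independently with
# SciPy's implementation of the same omnibus test (skew + kurtosis
# z-scores) and frozen here.
test_that("the K^2 omnibus statistic matches independent reference values", {
  r1 <- assess_normality(sin(1:50))
  expect_equal(r1$statistic, 43.26765816707633, tolerance = 1e-10)
  expect_equal(r1$p, 4.022975674741114e-10, tolerance = 1e-6)
  expect_false(r1$pass)
  r2 <- assess_normality((1:20)^2)
  expect_equal(r2$statistic, 2.514697432414396, tolerance = 1e-10)
  expect_equal(r2$p, 0.28440707165007806, tolerance = 1e-10)
  expect_true(r2$pass)
  x3 <- c(2.1, 1.8, 2.4, 2.2, 1.9, 2.0, 2.3, 1.7, 2.5, 2.05, 1.95, 2.15)
  r3 <- assess_normality(x3)
  expect_equal(r3$statistic, 0.1653355462492681, tolerance = 1e-10)
  expect_equal(r3$p, 0.9206569634033698, tolerance = 1e-10)
})

test_that("the normality test enforces its domain", {
  expect_error(assess_normality(rnorm(7)), "n >= 8")
  expect_warning(r <- assess_normality(rep(2, 12)), "constant")
  expect_false(r$pass)
})

test_that("the omnibus test holds its level and detects exponential skew", {
  pass_h0 <- vapply(1:100, function(s) {
    set.seed(s); assess_normality(rnorm(500))$pass
  }, TRUE)
  expect_gte(mean(pass_h0), 0.90)
  fail_h1 <- vapply(1:100, function(s) {
    set.seed(s); !assess_normality(rexp(500))$pass
  }, TRUE)
  expect_gte(mean(fail_h1), 0.99)
})

test_that("branch selection follows the decision tree exactly", {
  set.seed(101)
  g3 <- list(a = rnorm(10), b = rnorm(10), c = rnorm(10))
  expect_equal(select_test(g3)$branch, "anova_tukey")
  # any small group forces the non-parametric branch
  g3s <- g3; g3s$b <- g3s$b[1:6]
  expect_equal(select_test(g3s)$branch, "kruskal_dunn")
  set.seed(202)
  g2 <- list(a = rnorm(12, 5), b = rnorm(12, 6))
  expect_equal(select_test(g2)$branch, "t")
  set.seed(303)
  ge <- list(a = rexp(30), b = rexp(30))  # fails normality
  expect_equal(select_test(ge)$branch, "mann_whitney")
  # paired change scores
  expect_equal(select_test(c(1, 2, 1.5, 0.8, 1.2), paired_change = TRUE)$branch,
               "wilcoxon_signed_rank")
  set.seed(404)
  ch <- rnorm(12, 1)
  expect_equal(select_test(ch, paired_change = TRUE)$branch, "one_sample_t")
  # a group of exactly 7 cannot demonstrate normality
  g7 <- list(a = rnorm(7), b = rnorm(10))
  expect_equal(select_test(g7)$branch, "mann_whitney")
  expect_error(select_test(list(a = rnorm(10))), "paired_change")
})

test_that("identical groups give a Mann-Whitney p of 1", {
  x <- c(1.2, 3.4, 2.2, 5.1, 4.4, 2.9)
  r <- compare_groups(list(a = x, b = x))
  expect_equal(r$branch, "mann_whitney")
  expect_equal(r$p_value, 1)
  expect_false(r$significant)
})

test_that("uniform unit change scores are overwhelmingly significant", {
  set.seed(5)
  ch <- 1 + rnorm(10, 0, 1e-6)
  plan <- structure(list(branch = "one_sample_t", alpha = 0.05,
                         paired_change = TRUE), class = "test_plan")
  r <- run_test(list(change = ch), plan = plan)
  expect_lt(r$p_value, 1e-6)
  expect_true(r$significant)
})

test_that("post-hoc tables cover all pairs with monotone adjustment", {
  set.seed(606)
  g <- list(a = rnorm(10), b = rnorm(10, 0.3), c = rnorm(10, 3))
  r_par <- run_test(g, plan = structure(list(branch = "anova_tukey",
    alpha = 0.05, paired_change = FALSE), class = "test_plan"))
  expect_equal(nrow(r_par$posthoc), 3)
  r_np <- run_test(g, plan = structure(list(branch = "kruskal_dunn",
    alpha = 0.05, paired_change = FALSE), class = "test_plan"))
  expect_equal(nrow(r_np$posthoc), 3)
  expect_true(all(r_np$posthoc$p_adj >= r_np$posthoc$p))
  expect_true(all(r_np$posthoc$p_adj <= 1))
  # the clearly separated group is flagged in both
  expect_true(r_par$significant)
  expect_true(r_np$significant)
})

test_that("Dunn z-scores agree with a hand-computed two-group case", {
  # two groups, no ties: mean ranks 3 and 8 of n = 10,
  # se = sqrt((10 * 11 / 12) * (1/5 + 1/5))
  g <- list(a = c(1, 2, 3, 4, 5), b = c(6, 7, 8, 9, 10))
  d <- dunn_test(g)
  expect_equal(d$z, (3 - 8) / sqrt((10 * 11 / 12) * (2 / 5)))
  expect_equal(d$p_adj, d$p)  # single pair: no multiplicity penalty
})

test_that("degenerate variance falls back to the non-parametric branch", {
  g <- list(a = rep(1, 10), b = rep(1, 10))
  plan <- structure(list(branch = "t", alpha = 0.05, paired_change = FALSE),
                    class = "test_plan")
  expect_warning(r <- run_test(g, plan = plan), "falling back")
  expect_equal(r$branch, "mann_whitney")
})

test_that("branch selection is deterministic given the data", {
  set.seed(42)
  g <- list(a = rnorm(9), b = rexp(9))
  expect_identical(select_test(g)$branch, select_test(g)$branch)
  expect_identical(select_test(g)$reason, select_test(g)$reason)
})

test_that("the report table is tidy across mixed branches", {
  set.seed(7)
  res <- list(
    peak = compare_groups(list(a = rnorm(10, 1300, 100),
                               b = rnorm(10, 1600, 100))),
    dct = compare_groups(list(a = rexp(8), b = rexp(8), c = rexp(8))))
  tab <- report(res)
  expect_equal(nrow(tab), 2)
  expect_equal(tab$endpoint, c("peak", "dct"))
  expect_true(all(tab$branch %in% c("t", "mann_whitney", "anova_tukey",
                                    "kruskal_dunn")))
  empty <- report(list())
  expect_equal(nrow(empty), 0)
  expect_named(empty, c("endpoint", "branch", "n", "statistic", "p_value",
                        "min_adj_p", "significant"))
})
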