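test_that("the decision tree routes by normality and variance homogeneity", {
  withr::with_seed(1, {
    gaussian_hits <- mean(vapply(1:40, function(i) {
      choose_two_group_test(rnorm(20), rnorm(20))$decision == "t_test"
    }, logical(1)))
    lognormal_hits <- mean(vapply(1:40, function(i) {
      choose_two_group_test(rlnorm(20, sdlog = 1),
                            rnorm(20))$decision == "mann_whitney"
    }, logical(1)))
  })
  expect_gt(gaussian_hits, 0.75)
  expect_gt(lognormal_hits, 0.9)

  d <- withr::with_seed(2, choose_two_group_test(rnorm(10), rnorm(10)))
  expect_false(is.na(d$shapiro_p_x))
  expect_false(is.na(d$shapiro_p_y))
  expect_match(d$decision_path, "Shapiro-Wilk")

  small <- choose_two_group_test(c(1, 2), c(3, 4))
  expect_identical(small$decision, "mann_whitney")
  expect_match(small$decision_path, "n < 3")
})

test_that("Mann-Whitney handles overlap, separation and degenerate t input", {
  res <- two_group_test(c(1, 2, 3), c(1, 2, 3), method = "mann_whitney")
  expect_identical(res$p_value, 1)

  res2 <- two_group_test(c(1, 2, 3), c(10, 11, 12), method = "mann_whitney")
  expect_equal(res2$p_value, 0.1, tolerance = 1e-12)  # 2 / C(6,3)

  expect_warning(
    res3 <- two_group_test(c(0, 0, 0, 0), c(1, 1, 1, 1), method = "t_test"),
    "degenerate")
  expect_identical(res3$test_name, "mann_whitney")
})

test_that("exact Mann-Whitney equals full permutation enumeration (n <= 6)", {
  withr::with_seed(5, {
    for (i in 1:20) {
      n1 <- sample(2:6, 1); n2 <- sample(2:6, 1)
      x <- sample(0:6, n1, replace = TRUE)  # integers: ties are frequent
      y <- sample(0:6, n2, replace = TRUE)
      res <- two_group_test(x, y, method = "mann_whitney")
      expect_equal(res$p_value, mw_enum_oracle(x, y), tolerance = 1e-12)
    }
  })
})

test_that("two-group Kruskal-Wallis equals the squared Mann-Whitney z", {
  withr::with_seed(6, {
    for (i in 1:10) {
      x <- round(rnorm(12, 0, 2), 1)  # rounding induces occasional ties
      y <- round(rnorm(15, 0.5, 2), 1)
      kw <- kruskal_dunn(list(a = x, b = y))
      mw <- two_group_test(x, y, method = "mann_whitney", exact_max = 0L)
      z2 <- qnorm(mw$p_value / 2)^2
      expect_equal(unname(kw$test$statistic), z2, tolerance = 1e-8)
      expect_equal(kw$test$p_value, pchisq(z2, 1, lower.tail = FALSE),
                   tolerance = 1e-8)
    }
  })
})

test_that("Kruskal-Wallis H matches the hand-computed rank formula", {
  res <- kruskal_dunn(list(a = c(1, 2, 3), b = c(4, 5, 6), c = c(7, 8, 9)))
  expect_equal(unname(res$test$statistic), 7.2, tolerance = 1e-12)
  # brute-force rank arithmetic oracle (no ties here)
  v <- 1:9; g <- rep(1:3, each = 3)
  r <- rank(v)
  h <- 12 / (9 * 10) * sum(tapply(r, g, sum)^2 / 3) - 3 * 10
  expect_equal(unname(res$test$statistic), h, tolerance = 1e-12)
  expect_identical(nrow(res$posthoc), 3L)
  expect_true(all(res$posthoc$adjusted_p >= res$posthoc$raw_p))
})

test_that("identical constant groups give a degenerate H = 0, p = 1", {
  res <- kruskal_dunn(list(a = c(5, 5), b = c(5, 5), c = c(5, 5)))
  expect_identical(unname(res$test$statistic), 0)
  expect_identical(res$test$p_value, 1)
  expect_match(res$test$decision_path, "degenerate")
})

test_that("group order does not change H or the set of pairwise rows", {
  g <- list(a = c(1, 5, 3), b = c(9, 2, 7), c = c(4, 4, 8))
  r1 <- kruskal_dunn(g)
  r2 <- kruskal_dunn(g[c(3, 1, 2)])
  expect_equal(r1$test$statistic, r2$test$statistic, tolerance = 1e-12)
  key <- function(r) {
    with(r$posthoc, sort(paste(pmin(group_a, group_b),
                               pmax(group_a, group_b),
                               signif(abs(statistic), 10))))
  }
  expect_identical(key(r1), key(r2))
})

test_that("one-way ANOVA F matches direct sums-of-squares computation", {
  groups <- list(a = c(1, 2), b = c(3, 4), c = c(5, 6))
  res <- anova_lsd(groups)
  # independent oracle: direct SS arithmetic
  v <- unlist(groups); g <- rep(1:3, each = 2)
  mi <- tapply(v, g, mean)
  ssb <- sum(2 * (mi - mean(v))^2)            # 16
  ssw <- sum((v - mi[g])^2)                   # 1.5
  f_oracle <- (ssb / 2) / (ssw / 3)           # 16
  expect_equal(unname(res$test$statistic), f_oracle, tolerance = 1e-12)
  expect_equal(unname(res$test$statistic), 16, tolerance = 1e-12)
  # Fisher LSD is unadjusted by definition
  expect_identical(res$posthoc$raw_p, res$posthoc$adjusted_p)
  expect_identical(nrow(res$posthoc), 3L)
})

test_that("equal constant groups give F = 0", {
  res <- anova_lsd(list(a = c(2, 2), b = c(2, 2), c = c(2, 2)))
  expect_identical(unname(res$test$statistic), 0)
})

test_that("two-way ANOVA: pure additive effects give no interaction", {
  d <- expand.grid(genotype = c("control", "Tg"),
                   age_months = c(8, 12, 16), rep = 1:4)
  d$value <- 2 * (d$genotype == "Tg") + 0.5 * d$age_months +
    c(0.001, -0.001)[1 + (d$rep %% 2)]  # tiny jitter, no interaction
  res <- anova_lsd(d)
  expect_identical(nrow(res$test), 3L)
  inter <- res$test[res$test$test_name == "two_way_anova:genotype:age", ]
  main <- res$test[res$test$test_name == "two_way_anova:genotype", ]
  expect_lt(inter$statistic, 1e-6)
  expect_gt(main$statistic, 1e3)
})

test_that("linear trend detects monotone decline and respects preconditions", {
  withr::with_seed(9, {
    groups <- lapply(c(2000, 1700, 1400, 1100), function(m) {
      rnorm(8, m, 20)
    })
  })
  names(groups) <- paste0("g", 1:4)
  res <- linear_trend(groups)
  expect_lt(res$p_value, 0.001)
  expect_lt(res$contrast_estimate, 0)
  expect_error(linear_trend(list(a = 1:3, b = 4:6)), "at least 3")
})

test_that("linear trend is calibrated under the null", {
  reps <- 2000
  rejections <- withr::with_seed(10, {
    mean(vapply(seq_len(reps), function(i) {
      groups <- split(rnorm(32), rep(1:4, each = 8))
      linear_trend(groups)$p_value < 0.05
    }, logical(1)))
  })
  expect_lt(abs(rejections - 0.05), 0.015)
})

test_that("p-values and stars behave", {
  expect_identical(significance_stars(c(0.06, 0.04, 0.009, 0.004, 0.0009)),
                   c("", "*", "**", "***", "****"))
  res <- two_group_test(rnorm(10), rnorm(10), method = "mann_whitney")
  expect_gte(res$p_value, 0)
  expect_lte(res$p_value, 1)
  expect_identical(res$significant, res$p_value < res$alpha)
})
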