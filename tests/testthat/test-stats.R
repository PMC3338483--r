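test_that("Student's t matches the closed form and is antisymmetric", {
  r <- students_t(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$statistic, -3 * sqrt(3 / 2), tolerance = 1e-9)
  expect_equal(r$p_value, 0.021312, tolerance = 1e-4)
  r2 <- students_t(c(4, 5, 6), c(1, 2, 3))
  expect_equal(r2$statistic, -r$statistic)
  expect_equal(r2$p_value, r$p_value)
  ident <- students_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(ident$statistic, 0)
  expect_equal(ident$p_value, 1)
})

test_that("degenerate zero-variance t inputs are handled explicitly", {
  same <- students_t(c(2, 2), c(2, 2))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  diff <- students_t(c(2, 2), c(3, 3))
  expect_equal(diff$p_value, 0)
})

test_that("Wilcoxon rank-sum gives the exact enumeration p for {1,2} vs {3,4}", {
  r <- wilcoxon_rank_sum(c(1, 2), c(3, 4))
  expect_equal(r$p_value, 1 / 3, tolerance = 1e-12)
  expect_equal(enum_wilcoxon_p(c(1, 2), c(3, 4)), 1 / 3, tolerance = 1e-12)
})

test_that("exact Wilcoxon equals the enumeration oracle for tie-free samples", {
  set.seed(14)
  for (sizes in list(c(3, 4), c(2, 6), c(5, 5), c(4, 3))) {
    a <- round(rnorm(sizes[1]), 6)
    b <- round(rnorm(sizes[2], 0.5), 6)
    r <- wilcoxon_rank_sum(a, b)
    expect_equal(r$p_value, enum_wilcoxon_p(a, b), tolerance = 1e-10)
  }
})

test_that("identical samples give p = 1; constant data are flagged", {
  expect_equal(wilcoxon_rank_sum(rep(3, 4), rep(3, 5))$p_value, 1)
  r <- wilcoxon_rank_sum(c(1, 2, 3), c(1, 2, 3))
  expect_gt(r$p_value, 0.9)
})

test_that("exact and normal-approximation Wilcoxon agree at moderate n", {
  set.seed(5)
  a <- rnorm(10)
  b <- rnorm(10, 0.8)
  p_exact <- suppressWarnings(wilcox.test(a, b, exact = TRUE)$p.value)
  p_norm <- suppressWarnings(wilcox.test(a, b, exact = FALSE,
                                         correct = TRUE)$p.value)
  expect_lt(abs(p_exact - p_norm), 0.02)
})

test_that("two-group ANOVA reduces to the squared pooled t", {
  set.seed(6)
  a <- rnorm(12)
  b <- rnorm(10, 0.4)
  an <- one_way_anova(list(a, b))
  tt <- students_t(a, b)
  expect_equal(an$statistic, tt$statistic^2, tolerance = 1e-10)
  expect_equal(an$p_value, tt$p_value, tolerance = 1e-10)
})

test_that("three-group ANOVA matches hand-computed sums of squares", {
  an <- one_way_anova(list(c(1, 2, 3), c(2, 3, 4), c(3, 4, 5)))
  # SSB = 6, MSB = 3; SSW = 6, MSW = 1 -> F = 3 on (2, 6) df; p = (1 + F/3)^-3
  expect_equal(an$statistic, 3, tolerance = 1e-10)
  expect_equal(an$p_value, 0.125, tolerance = 1e-9)
  expect_equal(one_way_anova(list(c(1, 2), c(1, 2), c(1, 2)))$p_value, 1)
})

test_that("describe reports n, mean and sample sd", {
  d <- describe(c(10, 20, 30))
  expect_equal(d$mean, 20)
  expect_equal(d$sd, 10)
  expect_equal(describe(5)$sd, 0)
  # brute-force two-pass oracle
  set.seed(8)
  x <- rnorm(40)
  d2 <- describe(x)
  expect_equal(d2$sd, sqrt(sum((x - sum(x) / 40)^2) / 39), tolerance = 1e-12)
})
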