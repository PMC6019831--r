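# Statistical toolkit: correlation, rho->r conversion, ROC/AUC, group tests.
# stats::cor, wilcox.test, t.test and pROC serve as independent oracles.

test_that("pearson_cor matches hand values and the stats::cor oracle", {
  expect_equal(pearson_cor(1:3 + 0, c(2, 4, 6))$coefficient, 1.0)
  expect_equal(pearson_cor(c(1, 2, 3), c(1, 4, 9))$coefficient,
               cor(c(1, 2, 3), c(1, 4, 9)), tolerance = 1e-14)
  x <- rnorm(50); y <- rnorm(50)
  expect_equal(pearson_cor(x, y)$coefficient, cor(x, y), tolerance = 1e-12)
  expect_equal(pearson_cor(x, x)$coefficient, 1.0)
  expect_error(pearson_cor(rep(1, 5), 1:5 + 0), "constant")
  expect_error(pearson_cor(c(1, 2), c(3, 4)), "n >= 3")
})

test_that("spearman_cor is rank-based and matches the stats oracle with ties", {
  expect_equal(spearman_cor(c(1, 2, 3), c(1, 4, 9))$coefficient, 1.0)
  expect_equal(spearman_cor(c(1, 2, 3), c(9, 4, 1))$coefficient, -1.0)
  set.seed(3)
  x <- rnorm(100)
  expect_equal(spearman_cor(x, exp(x))$coefficient, 1.0)
  # tied data against stats::cor(method = "spearman") (mid-ranks)
  xt <- c(1, 2, 2, 3, 5, 5, 5, 8)
  yt <- c(2, 1, 4, 4, 4, 9, 7, 7)
  expect_equal(spearman_cor(xt, yt)$coefficient,
               cor(xt, yt, method = "spearman"), tolerance = 1e-14)
})

test_that("spearman is invariant under strictly increasing transforms, pearson is not", {
  set.seed(4)
  x <- runif(80, 1, 10)
  y <- runif(80, 1, 10)
  expect_equal(spearman_cor(x, y)$coefficient,
               spearman_cor(x, log(y))$coefficient)
  expect_false(isTRUE(all.equal(pearson_cor(x, exp(y / 2))$coefficient,
                                pearson_cor(x, y)$coefficient)))
})

test_that("spearman_to_pearson is the odd increasing map fixing -1, 0, 1", {
  expect_equal(spearman_to_pearson(0), 0)
  expect_equal(spearman_to_pearson(1), 1.0)
  expect_equal(spearman_to_pearson(-1), -1.0)
  expect_equal(spearman_to_pearson(0.5), 2 * sin(pi / 12))
  rho <- seq(-1, 1, by = 0.01)
  out <- spearman_to_pearson(rho)
  expect_true(all(diff(out) > 0))
  expect_equal(out, -rev(out))
  expect_true(all(abs(out) <= 1))
  expect_error(spearman_to_pearson(1.1), "domain")
})

test_that("roc_curve builds a valid staircase and handles orientation", {
  scores <- c(1, 2, 3, 4)
  labels <- c(TRUE, FALSE, TRUE, FALSE)
  rc <- roc_curve(scores, labels)
  expect_equal(rc$points[1, ], data.frame(fpr = 0, tpr = 0))
  expect_equal(unlist(rc$points[nrow(rc$points), ]), c(fpr = 1, tpr = 1))
  expect_true(all(diff(rc$points$fpr) >= 0))
  expect_true(all(diff(rc$points$tpr) >= 0))
  expect_equal(rc$auc, 0.25)   # one win of four positive-negative pairs

  # perfectly separated scores
  rs <- roc_curve(c(10, 11, 1, 2), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(rs$auc, 1.0)
  expect_true(any(rs$points$fpr == 0 & rs$points$tpr == 1))

  # lower_is_positive negation mirrors the curve
  rl <- roc_curve(-scores, labels, "lower_is_positive")
  expect_equal(rl$points, rc$points)

  expect_error(roc_curve(1:3 + 0, c(TRUE, TRUE, TRUE)), "degenerate labels")
})

test_that("trapezoidal AUC equals the pairwise-probability oracle and pROC", {
  expect_equal(auc_probability_oracle(2, 1), 1.0)
  expect_equal(auc_probability_oracle(1, 1), 0.5)
  for (seed in 1:5) {
    set.seed(seed)
    n <- sample(20:500, 1)
    scores <- round(rnorm(n), 2)  # rounding forces ties
    labels <- runif(n) < 0.4
    if (!any(labels) || all(labels)) next
    rc <- roc_curve(scores, labels)
    expect_equal(rc$auc,
                 auc_probability_oracle(scores[labels], scores[!labels]),
                 tolerance = 1e-12)
    expect_equal(rc$auc,
                 as.numeric(pROC::auc(pROC::roc(labels, scores,
                                                direction = "<",
                                                quiet = TRUE))),
                 tolerance = 1e-12)
  }
})

test_that("ROC point sets are invariant under strictly increasing score maps", {
  set.seed(9)
  scores <- rlnorm(120)
  labels <- runif(120) < 0.3
  ref <- roc_curve(scores, labels)
  for (f in list(log, function(x) 3 * x + 7, function(x) x^3)) {
    expect_equal(roc_curve(f(scores), labels)$points, ref$points)
  }
  # decreasing map with reversed orientation gives the same curve
  expect_equal(roc_curve(1 / scores, labels, "lower_is_positive")$points,
               ref$points)
})

test_that("resistance classification uses the strict cutoff", {
  expect_false(classify_resistant(4.7, 4.7))
  expect_true(classify_resistant(4.69, 4.7))
  expect_false(classify_resistant(100, 4.7))
  expect_identical(classify_resistant(c(1, 4.7, 10)), c(TRUE, FALSE, FALSE))
})

test_that("group_tests matches wilcox.test and t.test oracles", {
  set.seed(5)
  a <- rlnorm(18)
  b <- rlnorm(25, meanlog = 0.6)
  g <- group_tests(a, b)
  wo <- wilcox.test(a, b, exact = FALSE, correct = TRUE)
  expect_equal(g$mann_whitney$statistic, unname(wo$statistic))
  expect_equal(g$mann_whitney$p_value, wo$p.value, tolerance = 1e-12)
  to <- t.test(a, b)  # Welch by default
  expect_equal(g$t_test$statistic, unname(to$statistic), tolerance = 1e-12)
  expect_equal(g$t_test$p_value, to$p.value, tolerance = 1e-12)
  expect_equal(g$t_test$df, unname(to$parameter), tolerance = 1e-12)

  # tied data: the tie-corrected approximation still matches
  at <- c(1, 2, 2, 3, 3, 3, 9)
  bt <- c(2, 3, 3, 4, 4, 5)
  gt <- group_tests(at, bt)
  wt <- wilcox.test(at, bt, exact = FALSE, correct = TRUE)
  expect_equal(gt$mann_whitney$statistic, unname(wt$statistic))
  expect_equal(gt$mann_whitney$p_value, wt$p.value, tolerance = 1e-12)

  # identical groups: centred U, p ~ 1, t = 0
  gi <- group_tests(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_equal(gi$mann_whitney$statistic, 8)  # n^2/2
  expect_equal(gi$mann_whitney$p_value, 1, tolerance = 0.05)
  expect_equal(gi$t_test$statistic, 0)

  expect_error(group_tests(rep(1, 3), rep(1, 4)), "degenerate data")
})

test_that("rank tests agree across monotone-equivalent scores, t-tests need not", {
  set.seed(6)
  g <- runif(60, 3, 12)
  i <- runif(60, 2, 40)
  split <- rep(c(TRUE, FALSE), 30)
  h <- homa_ir(g, i); f <- firi(g, i); q <- quicki(g, i)
  gh <- group_tests(h[split], h[!split])
  gf <- group_tests(f[split], f[!split])
  gq <- group_tests(-q[split], -q[!split])   # orientation-reversed QUICKI
  expect_identical(gh$mann_whitney$statistic, gf$mann_whitney$statistic)
  expect_identical(gh$mann_whitney$statistic, gq$mann_whitney$statistic)
  expect_identical(gh$mann_whitney$p_value, gf$mann_whitney$p_value)
  expect_identical(gh$mann_whitney$p_value, gq$mann_whitney$p_value)
  # two-sided p is orientation-invariant
  gq_raw <- group_tests(q[split], q[!split])
  expect_equal(gq_raw$mann_whitney$p_value, gq$mann_whitney$p_value,
               tolerance = 1e-12)
  # t on HOMA-IR vs FIRI identical (common positive scaling), vs QUICKI not
  expect_equal(gh$t_test$statistic, gf$t_test$statistic, tolerance = 1e-12)
  expect_false(isTRUE(all.equal(abs(gh$t_test$statistic),
                                abs(gq_raw$t_test$statistic))))
})
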