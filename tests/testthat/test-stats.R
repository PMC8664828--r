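test_that("confusion metrics reproduce hand-computed percentages", {
  cm <- confusion_metrics(21, 6, 9, 30)
  expect_equal(round(cm$sensitivity, 1), 70.0)
  expect_equal(round(cm$specificity, 1), 83.3)
  expect_equal(round(cm$ppv, 1), 77.8)
  expect_equal(round(cm$npv, 1), 76.9)
  cm2 <- confusion_metrics(20, 7, 10, 29)
  expect_equal(round(cm2$accuracy, 1), 74.2)
  expect_error(confusion_metrics(-1, 0, 0, 5), "non-negative")
})

test_that("zero denominators yield undefined metrics, not zeros", {
  cm <- confusion_metrics(0, 0, 0, 10)
  expect_true(is.na(cm$sensitivity))
  expect_true(is.na(cm$ppv))
  expect_equal(cm$specificity, 100)
  expect_equal(cm$npv, 100)
})

test_that("the midrank AUC matches enumeration and handles ties", {
  expect_equal(auc(c(3, 1, 2, 0), c(1, 1, 0, 0)), 0.75)
  expect_equal(auc(c(5, 6, 1, 2), c(1, 1, 0, 0)), 1)
  expect_equal(auc(rep(2, 6), c(1, 1, 1, 0, 0, 0)), 0.5)
  expect_error(auc(1:4, rep(1, 4)), "both classes")
})

test_that("AUC respects complement and monotone-transform invariances", {
  set.seed(8)
  for (rep in 1:10) {
    scores <- rnorm(30)
    labels <- rbinom(30, 1, 0.5)
    if (length(unique(labels)) < 2) next
    expect_equal(auc(scores, labels) + auc(-scores, labels), 1)
    expect_equal(auc(exp(scores), labels), auc(scores, labels))
  }
})

test_that("the Youden scan returns midpoint cut-offs with the documented tie-break", {
  y1 <- youden_cutoff(c(3, 2, 1, 0), c(1, 1, 0, 0))
  expect_equal(y1$cutoff, 1.5)
  expect_equal(y1$j, 1)
  # two J = 0.5 optima; the higher-specificity (higher) cut-off wins
  y2 <- youden_cutoff(c(3, 1, 2, 0), c(1, 1, 0, 0))
  expect_equal(y2$j, 0.5)
  expect_equal(y2$cutoff, 2.5)
  expect_equal(y2$specificity, 1)
  y3 <- youden_cutoff(rep(1, 6), c(1, 1, 1, 0, 0, 0))
  expect_equal(y3$j, 0)
})

test_that("Youden operating point reproduces its own confusion metrics", {
  set.seed(15)
  scores <- c(rnorm(20, 1), rnorm(25, 0))
  labels <- rep(c(1, 0), c(20, 25))
  yj <- youden_cutoff(scores, labels)
  cm <- confusion_metrics(sum(scores > yj$cutoff & labels == 1),
                          sum(scores > yj$cutoff & labels == 0),
                          sum(scores <= yj$cutoff & labels == 1),
                          sum(scores <= yj$cutoff & labels == 0))
  expect_equal(cm$sensitivity / 100, yj$sensitivity)
  expect_equal(cm$specificity / 100, yj$specificity)
})

test_that("identical score vectors give a null DeLong comparison", {
  scores <- c(2, 1, 3, 0.5, 1.5, 0.2)
  labels <- c(1, 1, 1, 0, 0, 0)
  dt <- delong_test(scores, scores, labels)
  expect_equal(dt$auc_a, dt$auc_b)
  expect_equal(dt$z, 0)
  expect_equal(dt$p, 1)
  expect_error(delong_test(scores, scores[-1], labels), "equal length")
})

test_that("strongly opposed score pairs are declared different", {
  set.seed(20)
  labels <- rep(c(1, 0), each = 15)
  good <- labels + rnorm(30, sd = 0.3)
  bad <- -labels + rnorm(30, sd = 0.3)
  dt <- delong_test(good, bad, labels)
  expect_gt(dt$auc_a, 0.9)
  expect_lt(dt$auc_b, 0.1)
  expect_lt(dt$p, 0.05)
})

test_that("DeLong AUC, SE and p agree with the pROC reference", {
  skip_if_not_installed("pROC")
  set.seed(31)
  labels <- rep(c(1, 0), c(18, 22))
  a <- labels * 0.8 + rnorm(40)
  b <- labels * 0.4 + rnorm(40)
  dt <- delong_test(a, b, labels)
  ra <- pROC::roc(labels, a, quiet = TRUE, direction = "<")
  rb <- pROC::roc(labels, b, quiet = TRUE, direction = "<")
  ref <- pROC::roc.test(ra, rb, method = "delong", paired = TRUE)
  expect_equal(dt$auc_a, as.numeric(pROC::auc(ra)))
  expect_equal(dt$p, ref$p.value, tolerance = 1e-9)
  ci <- pROC::ci.auc(ra, method = "delong")
  expect_equal(dt$ci_a, as.numeric(ci)[c(1, 3)], tolerance = 1e-9)
})

test_that("per-curve DeLong variance approaches the Hanley-McNeil form", {
  ratios <- sapply(1:20, function(s) {
    set.seed(s)
    scores <- c(rexp(1000, 0.5), rexp(1000, 1))
    labels <- rep(c(1, 0), each = 1000)
    dt <- delong_test(scores, scores, labels)
    A <- dt$auc_a
    q1 <- A / (2 - A); q2 <- 2 * A^2 / (1 + A)
    hm <- (A * (1 - A) + 999 * (q1 - A^2) + 999 * (q2 - A^2)) / 1e6
    dt$se_a^2 / hm
  })
  expect_lt(abs(mean(ratios) - 1), 0.1)
})

test_that("Mann-Whitney is exact on small samples and rank-invariant", {
  expect_equal(mann_whitney(c(1, 2, 3), c(1, 2, 3))$p, 1)
  mw <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(mw$u, 0)
  expect_equal(mw$method, "exact")
  expect_equal(mw$p, 2 / 20)   # enumeration of C(6,3) = 20 assignments
  mw10 <- mann_whitney(10 * c(1, 2, 3), 10 * c(4, 5, 6))
  expect_equal(mw10$u, mw$u)
  expect_equal(mw10$p, mw$p)
  expect_error(mann_whitney(numeric(0), 1:3), "non-empty")
})

test_that("large-sample Mann-Whitney matches the base-R normal approximation", {
  set.seed(40)
  x <- rnorm(20); y <- rnorm(25, 0.5)
  mw <- mann_whitney(x, y)
  ref <- wilcox.test(x, y, exact = FALSE, correct = FALSE)
  expect_equal(mw$u, unname(ref$statistic))
  expect_equal(mw$p, ref$p.value, tolerance = 1e-9)
})

test_that("Fisher exact p-values follow the hypergeometric tails", {
  expect_equal(fisher_exact(5, 0, 0, 5), 2 / choose(10, 5), tolerance = 1e-12)
  expect_equal(fisher_exact(4, 6, 4, 6), 1)
  expect_equal(fisher_exact(7, 2, 3, 8), fisher_exact(7, 3, 2, 8))
  expect_error(fisher_exact(0, 0, 0, 0), "empty")
})

test_that("Spearman correlation handles monotone, mixed and constant input", {
  expect_equal(spearman(1:10, (1:10)^3)$rho, 1)
  expect_equal(spearman(1:10, -(1:10)^3)$rho, -1)
  sp <- spearman(c(1, 2, 3, 4), c(2, 1, 4, 3))
  expect_equal(sp$rho, 0.6)
  ref <- suppressWarnings(cor.test(c(1, 2, 3, 4), c(2, 1, 4, 3),
                                   method = "spearman"))
  expect_equal(sp$rho, unname(ref$estimate))
  expect_warning(spc <- spearman(rep(1, 5), 1:5), "constant")
  expect_true(is.na(spc$rho))
})

test_that("Bonferroni thresholds match the reported rounding", {
  expect_equal(round(bonferroni_alpha(26, 0.05), 3), 0.002)
  expect_equal(bonferroni_alpha(1, 0.05), 0.05)
  expect_equal(bonferroni_alpha(32, 0.05), 0.0015625)
  expect_error(bonferroni_alpha(0), "at least 1")
})
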