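test_that("risk classification is strict at the threshold", {
  expect_equal(as.character(classify_risk(c(0, 34, 35, 40))),
               c("low_risk", "low_risk", "high_risk", "high_risk"))
  expect_error(classify_risk(-1), "non-negative")
})

test_that("separable counts give a perfect threshold at the smallest tie", {
  m <- youden_threshold(c(1, 2, 3, 10, 11, 12), c(0, 0, 0, 1, 1, 1))
  expect_equal(m$threshold, 3)
  expect_equal(m$sensitivity, 1)
  expect_equal(m$specificity, 1)
  expect_equal(m$auc, 1)
})

test_that("trained threshold attains the brute-force Youden maximum", {
  set.seed(21)
  for (rep in 1:50) {
    n <- 200
    labels <- rbinom(n, 1, 0.3)
    counts <- rnbinom(n, mu = 8 + 25 * labels * runif(1), size = 2)
    m <- youden_threshold(counts, labels)
    oracle <- youden_brute_force(counts, labels)
    expect_equal(m$youden_j, oracle$j, tolerance = 1e-12)
    expect_equal(m$threshold, oracle$threshold)
    # J at the chosen cut-off dominates J at every other cut-off
    j_all <- with(m$roc, tpr + (1 - fpr) - 1)
    expect_true(all(m$youden_j >= j_all - 1e-12))
  }
})

test_that("the Youden threshold rule is invariant under monotone transforms", {
  set.seed(22)
  labels <- rbinom(120, 1, 0.4)
  counts <- rnbinom(120, mu = 10 + 20 * labels, size = 3)
  m1 <- youden_threshold(counts, labels)
  m2 <- youden_threshold(counts^2 + counts, labels)  # strictly monotone on counts
  expect_equal(m2$sensitivity, m1$sensitivity)
  expect_equal(m2$specificity, m1$specificity)
  expect_equal(m2$threshold, m1$threshold^2 + m1$threshold)
  expect_equal(m2$auc, m1$auc)
})

test_that("AUC equals the pairwise rank oracle and flips under label swap", {
  set.seed(23)
  scores <- c(rnorm(60, 1), rnorm(40))
  labels <- rep(c(1, 0), c(60, 40))
  a <- roc_auc(scores, labels)
  expect_equal(a$auc, auc_pairwise(scores, labels), tolerance = 1e-12)
  b <- roc_auc(scores, 1 - labels)
  expect_equal(b$auc, 1 - a$auc, tolerance = 1e-12)
  # ties counted one half
  sc <- c(1, 1, 2, 2)
  expect_equal(roc_auc(sc, c(0, 1, 0, 1))$auc, 0.5)
})

test_that("AUC and DeLong interval agree with an independent implementation", {
  skip_if_not_installed("pROC")
  set.seed(24)
  scores <- c(rnbinom(50, mu = 8, size = 2), rnbinom(30, mu = 35, size = 3))
  labels <- rep(c(0, 1), c(50, 30))
  mine <- roc_auc(scores, labels)
  ref <- pROC::roc(labels, scores, quiet = TRUE, direction = "<")
  expect_equal(mine$auc, as.numeric(pROC::auc(ref)), tolerance = 1e-10)
  ci <- as.numeric(pROC::ci.auc(ref, method = "delong"))
  expect_equal(c(mine$ci_low, mine$ci_high), ci[c(1, 3)], tolerance = 1e-6)
})

test_that("labels independent of counts give AUC near one half", {
  set.seed(25)
  aucs <- vapply(1:50, function(i) {
    roc_auc(rnbinom(100, mu = 15, size = 2), rbinom(100, 1, 0.4))$auc
  }, numeric(1))
  expect_lt(abs(mean(aucs) - 0.5), 0.1)
})

test_that("contingency statistics use Wald intervals truncated to [0, 1]", {
  s <- contingency_stats(10, 0, 0, 10)
  expect_equal(s$estimate, c(1, 1))
  expect_equal(s$ci_high, c(1, 1))
  expect_error(contingency_stats(0, 0, 5, 5), "positive")
  expect_error(contingency_stats(1.5, 2, 3, 4), "integers")
})

test_that("degenerate classifier inputs error", {
  expect_error(youden_threshold(1:5, rep(1, 5)), "both outcome classes")
  expect_error(roc_auc(1:5, rep(0, 5)), "both outcome classes")
  expect_error(youden_threshold(c(-1, 2), c(0, 1)), "non-negative")
})
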