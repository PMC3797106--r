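test_that("product-limit estimate matches hand computation", {
  d <- tibble::tibble(time = c(1, 2, 3), event = c(1, 1, 1))
  km <- km_curve(d)
  expect_equal(km$survival, c(2 / 3, 1 / 3, 0))

  # no events: survival identically 1
  d2 <- tibble::tibble(time = c(2, 4, 6), event = c(0, 0, 0))
  expect_true(all(km_curve(d2)$survival == 1))

  # censoring after the last event leaves the curve at event times unchanged
  d3 <- tibble::tibble(time = c(1, 2, 3, 9), event = c(1, 1, 1, 0))
  km3 <- km_curve(d3)
  expect_equal(km3$survival[km3$n_event > 0], c(3 / 4, 2 / 4, 1 / 4))

  set.seed(41)
  tt <- rexp(40); ev <- rbinom(40, 1, 0.7)
  km4 <- km_curve(tibble::tibble(time = tt, event = ev))
  hand <- km_by_hand(tt, ev)
  got <- km4[km4$n_event > 0, c("time", "survival")]
  expect_equal(got$survival, hand$survival, tolerance = 1e-12)
})

test_that("survival curves are non-increasing and start at 1", {
  set.seed(42)
  d <- tibble::tibble(time = rexp(60, 0.2), event = rbinom(60, 1, 0.6),
                      group = rep(c("a", "b"), 30))
  km <- km_curve(d, group = "group")
  for (g in c("a", "b")) {
    s <- km$survival[km$group == g]
    expect_true(all(diff(s) <= 1e-12))
    expect_true(all(s <= 1))
  }
})

test_that("log-rank statistic matches direct tabulation and is 0 for identical groups", {
  set.seed(43)
  d <- tibble::tibble(time = rexp(20, 0.3) + 0.01,
                      event = rbinom(20, 1, 0.8),
                      group = rep(c("x", "y"), 10))
  lr <- logrank_test(d)
  expect_equal(lr$statistic, logrank_by_hand(d$time, d$event, d$group),
               tolerance = 1e-9)

  # label permutation of one duplicated sample: statistic 0, p 1
  base <- tibble::tibble(time = c(1, 2, 3, 4), event = c(1, 0, 1, 1))
  dd <- dplyr::bind_rows(dplyr::mutate(base, group = "a"),
                         dplyr::mutate(base, group = "b"))
  lr0 <- logrank_test(dd)
  expect_equal(lr0$statistic, 0, tolerance = 1e-12)
  expect_equal(lr0$p_value, 1, tolerance = 1e-12)
})

test_that("log-rank and KM are invariant to time-unit rescaling", {
  set.seed(44)
  d <- tibble::tibble(time = rexp(50, 0.2), event = rbinom(50, 1, 0.7),
                      group = rep(c("a", "b"), 25))
  lr1 <- logrank_test(d)
  d2 <- dplyr::mutate(d, time = time * 365.25)
  lr2 <- logrank_test(d2)
  expect_equal(lr1$statistic, lr2$statistic, tolerance = 1e-12)
  expect_equal(km_curve(d, group = "group")$survival,
               km_curve(d2, group = "group")$survival, tolerance = 1e-12)
})

test_that("Cox fit recovers a true hazard ratio of 3.5 at n = 1000", {
  set.seed(45)
  x <- rbinom(1000, 1, 0.3)
  t_event <- rexp(1000, rate = 0.05 * 3.5^x)
  cens <- runif(1000, 5, 15)
  d <- tibble::tibble(time = pmin(t_event, cens),
                      event = as.integer(t_event <= cens),
                      high = factor(x))
  td <- tidy(cox_fit(d, terms = "high"))
  expect_gt(td$rr, 3.0)
  expect_lt(td$rr, 4.0)
  expect_lt(td$p_value, 1e-6)
})

test_that("null covariates give mean log-HR near 0", {
  set.seed(46)
  lhr <- vapply(1:50, function(i) {
    d <- tibble::tibble(time = rexp(150, 0.1), event = rbinom(150, 1, 0.8),
                        x = rnorm(150))
    tidy(cox_fit(d, terms = "x"))$log_rr
  }, numeric(1))
  expect_lt(abs(mean(lhr)), 0.1)
})

test_that("univariate and multivariate modes behave per the fitting contract", {
  set.seed(47)
  sim <- simulate_cohort(seed = 47)
  co <- add_risk_classes(sim$cohort)
  uni <- cox_fit(co, "dfi_time", "dfi_event",
                 terms = c("breakpoint_class", "ki67_high"))
  expect_equal(nrow(tidy(uni)), 2)
  expect_false(tidy(uni)$n[1] == 0)
  multi <- cox_fit(co, "dfi_time", "dfi_event",
                   terms = c("breakpoint_class", "ki67_high", "gg3",
                             "grade_high"),
                   multivariate = TRUE)
  expect_equal(nrow(tidy(multi)), 4)
  expect_true(all(tidy(multi)$ci_low <= tidy(multi)$rr),
              all(tidy(multi)$rr <= tidy(multi)$ci_high))

  expect_error(cox_fit(co, "dfi_time", "dfi_event",
                       terms = c("breakpoint_class", "breakpoint_class"),
                       multivariate = TRUE), "duplicated")
  co$const <- 1
  expect_error(cox_fit(co, "dfi_time", "dfi_event", terms = "const"),
               "constant")
})

test_that("survival input validation rejects malformed data", {
  d <- tibble::tibble(time = c(1, -1), event = c(0, 1), group = c("a", "b"))
  expect_error(km_curve(d), "positive")
  d2 <- tibble::tibble(time = c(1, 2), event = c(0, 2), group = c("a", "b"))
  expect_error(logrank_test(d2), "0/1")
  d3 <- tibble::tibble(time = c(1, 2), event = c(0, 1), group = c("a", "a"))
  expect_error(logrank_test(d3), "two observed levels")
})
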