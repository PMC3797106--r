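test_that("profile generator is a pure function of its seed", {
  a <- simulate_profile(seed = 99)
  b <- simulate_profile(seed = 99)
  expect_identical(a, b)
  c <- simulate_profile(seed = 100)
  expect_false(identical(a$probes$signal, c$probes$signal))
})

test_that("noiseless-limit profiles are recovered exactly by segmentation", {
  sim <- simulate_profile(n_probes = c(chr1 = 80, chr2 = 80),
                          breakpoints = list(c(30L), c(20L, 55L)),
                          segment_means = list(c(0, 1), c(0, -1, 0.5)),
                          noise_sd = 1e-4, seed = 61)
  prof <- segment_tumor(sim$probes)
  expect_equal(prof$n_breakpoints, 3L)
  seg1 <- prof$segments[prof$segments$chrom == "chr1", ]
  expect_equal(seg1$end_probe[1], 30L)
})

test_that("profile truth records match the generated signal layout", {
  sim <- simulate_profile(n_probes = c(chrA = 100), breakpoints = 4L,
                          outlier_rate = 0.05, seed = 62)
  bp <- sim$truth$breakpoints$chrA
  expect_length(bp, 4)
  expect_true(all(diff(bp) > 0) && all(bp >= 1 & bp <= 99))
  expect_equal(sim$truth$n_breakpoints, 4L)
  expect_true(all(sim$truth$outliers$chrA %in% 1:100))
})

test_that("generator validates its spec", {
  expect_error(simulate_profile(n_probes = c(chr1 = 10),
                                breakpoints = list(c(3L, 2L)), seed = 1),
               "strictly increasing")
  expect_error(simulate_profile(n_probes = c(chr1 = 10),
                                breakpoints = list(5L),
                                segment_means = list(c(0, 1, 2)), seed = 1),
               "means for")
  expect_error(simulate_cohort(target_spearman = 0.9999, seed = 1),
               "infeasible")
})

test_that("cohort generator hits the calibrated group medians", {
  med_good <- numeric(50); med_poor <- numeric(50)
  for (s in 1:50) {
    co <- simulate_cohort(seed = s)$cohort
    med_good[s] <- median(co$breakpoint_count[co$group == "good"])
    med_poor[s] <- median(co$breakpoint_count[co$group == "poor"])
  }
  expect_gte(median(med_good), 5)
  expect_lte(median(med_good), 9)
  expect_gte(median(med_poor), 35)
  expect_lte(median(med_poor), 46)
})

test_that("cohort generator hits the genomic-grade-index correlation target", {
  rho <- vapply(1:50, function(s) {
    co <- simulate_cohort(seed = s)$cohort
    cor(co$ggi, co$breakpoint_count, method = "spearman")
  }, numeric(1))
  expect_lt(abs(mean(rho) - 0.54), 0.10)
})

test_that("a null hazard ratio gives log-rank rejections near the alpha level", {
  rej <- 0; valid <- 0
  for (s in 1:200) {
    sim <- simulate_cohort(n_good = 75, n_poor = 30, hr_highclass = 1,
                           seed = 3000 + s)
    co <- add_risk_classes(sim$cohort)
    if (dplyr::n_distinct(co$breakpoint_class) < 2) next
    valid <- valid + 1
    p <- logrank_test(co, "dfi_time", "dfi_event", "breakpoint_class")$p_value
    if (p < 0.05) rej <- rej + 1
  }
  expect_gt(valid, 150)
  expect_lt(abs(rej / valid - 0.05), 0.05)
})

test_that("cohort output passes the cohort-schema validator round trip", {
  co <- simulate_cohort(seed = 64)$cohort
  path <- tempfile(fileext = ".csv")
  readr::write_csv(dplyr::select(co, -"group"), path)
  expect_silent(back <- read_cohort(path))
  expect_equal(nrow(back), nrow(co))
})

test_that("expression generator anchors both grades and encodes the contrast", {
  sim <- simulate_expression(n_samples = 30, seed = 65)
  expect_true(all(c(1, 3) %in% sim$grade))
  expect_equal(dim(sim$expression), c(30, 128))
  raw <- ggi_raw(sim$expression, sim$up_in_grade3, sim$up_in_grade1)
  expect_gt(mean(raw$ggi_raw[sim$grade == 3]),
            mean(raw$ggi_raw[sim$grade == 1]))
})
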