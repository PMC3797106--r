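test_that("trivial signals segment exactly", {
  cc <- optimal_segmentation(c(2, 2, 2, 2), k_max = 0)
  expect_equal(cc$rss[1], 0)
  expect_identical(cc$breakpoints[[1]], integer(0))

  cc <- optimal_segmentation(c(0, 0, 0, 5, 5, 5), k_max = 1)
  expect_equal(cc$rss[2], 0)
  expect_identical(cc$breakpoints[[2]], 3L)
})

test_that("both engines match brute-force enumeration on random instances", {
  set.seed(101)
  for (rep in 1:25) {
    n <- sample(6:18, 1)
    y <- rnorm(n) + rep(c(0, sample(c(0, 2), 1)), length.out = n)
    k_max <- sample(1:4, 1)
    naive <- optimal_segmentation(y, k_max, method = "naive")
    pruned <- optimal_segmentation(y, k_max, method = "pruned")
    for (k in 0:k_max) {
      oracle <- brute_force_segmentation(y, k)
      expect_equal(naive$rss[k + 1], oracle$rss, tolerance = 1e-9)
      expect_identical(naive$breakpoints[[k + 1]], oracle$breakpoints)
      expect_equal(pruned$rss[k + 1], oracle$rss, tolerance = 1e-9)
      expect_identical(pruned$breakpoints[[k + 1]], oracle$breakpoints)
    }
  }
})

test_that("pruned and naive dynamic programs agree up to n = 200", {
  set.seed(202)
  for (rep in 1:12) {
    n <- sample(c(50, 120, 200), 1)
    segs <- sample(2:8, 1)
    y <- rnorm(n) + rep(sample(c(0, 1, 3, -2), segs, replace = TRUE),
                        length.out = n, each = ceiling(n / segs))[1:n]
    k_max <- min(25, n - 1)
    a <- optimal_segmentation(y, k_max, method = "naive")
    b <- optimal_segmentation(y, k_max, method = "pruned")
    expect_equal(a$rss, b$rss, tolerance = 1e-8)
    expect_identical(a$breakpoints, b$breakpoints)
  }
})

test_that("rss is non-increasing in k and breakpoints are valid", {
  set.seed(303)
  for (rep in 1:10) {
    y <- rnorm(80) + rep(c(0, 2, 0), length.out = 80, each = 27)[1:80]
    cc <- optimal_segmentation(y, 15)
    expect_true(all(diff(cc$rss) <= 1e-10))
    expect_true(all(cc$rss >= -1e-12))
    for (k in 0:15) {
      bp <- cc$breakpoints[[k + 1]]
      expect_length(bp, k)
      if (k > 0) {
        expect_true(all(bp >= 1 & bp <= length(y) - 1))
        expect_true(all(diff(bp) > 0))
      }
    }
  }
})

test_that("segmentation is equivariant under shift and scale", {
  set.seed(404)
  y <- rnorm(120) + rep(c(0, 3, 1), each = 40)
  base <- optimal_segmentation(y, 10)
  shifted <- optimal_segmentation(y + 57.3, 10)
  scaled <- optimal_segmentation(y * 4.2, 10)
  expect_identical(base$breakpoints, shifted$breakpoints)
  expect_identical(base$breakpoints, scaled$breakpoints)
  expect_equal(base$rss, shifted$rss, tolerance = 1e-6)
  expect_equal(base$rss * 4.2^2, scaled$rss, tolerance = 1e-6)
})

test_that("input validation: k_max capping and non-finite rejection", {
  expect_warning(cc <- optimal_segmentation(rnorm(5), k_max = 10),
                 "capped")
  expect_equal(cc$k_max, 4L)
  expect_error(optimal_segmentation(c(1, NA, 3), 1), "non-finite")
  expect_error(optimal_segmentation(3, 0), "at least 2")
})

test_that("singleton-outlier screen removes spikes and nothing else on clean data", {
  r <- remove_singleton_outliers(rep(0, 7))
  expect_length(r$removed, 0)

  y <- c(0, 0, 0, 8, 0, 0, 0)
  r <- remove_singleton_outliers(y)
  expect_identical(r$removed, 4L)
  expect_equal(r$round1_k, 2L)
  cc2 <- optimal_segmentation(r$track$signal, 2)
  expect_equal(select_k(cc2)$k_selected, 0L)
})

test_that("outlier screen catches >=90% of 6-sigma spikes with <2% false removals", {
  set.seed(505)
  caught <- 0; false_rm <- 0; n_spikes <- 0; n_clean <- 0
  for (rep in 1:50) {
    y <- rnorm(500)
    idx <- sample(500, 5)
    y[idx] <- y[idx] + 6 * sample(c(-1, 1), 5, replace = TRUE)
    r <- remove_singleton_outliers(y)
    caught <- caught + length(intersect(r$removed, idx))
    false_rm <- false_rm + length(setdiff(r$removed, idx))
    n_spikes <- n_spikes + 5
    n_clean <- n_clean + 495
  }
  expect_gte(caught / n_spikes, 0.90)
  expect_lt(false_rm / n_clean, 0.02)
})

test_that("outlier screen is idempotent when no new singletons arise", {
  set.seed(606)
  y <- rnorm(300)
  y[c(50, 151)] <- y[c(50, 151)] + 7
  r1 <- remove_singleton_outliers(y)
  r2 <- remove_singleton_outliers(r1$track$signal)
  expect_length(r2$removed, 0)
})

test_that("segment_tumor counts breakpoints per chromosome, never across", {
  t1 <- make_step_track(c(0, 2), 20, chrom = "chr1")
  t2 <- make_step_track(c(1, -1), 20, chrom = "chr2")
  prof <- segment_tumor(dplyr::bind_rows(t1, t2))
  expect_equal(prof$n_breakpoints, 2L)
  expect_s3_class(prof$segments, "tbl_df")
  # segments tile each chromosome contiguously
  seg1 <- prof$segments[prof$segments$chrom == "chr1", ]
  expect_equal(seg1$start_probe[1], 1L)
  expect_equal(seg1$start_probe[-1], head(seg1$end_probe, -1) + 1L)

  # 23 constant chromosomes: zero breakpoints despite different levels,
  # because chromosome junctions are never counted
  tracks <- dplyr::bind_rows(lapply(1:23, function(i) {
    make_step_track(i / 3, 10, chrom = paste0("chr", i))
  }))
  prof <- segment_tumor(tracks)
  expect_equal(prof$n_breakpoints, 0L)
})

test_that("segment_tumor warns on chromosomes with fewer than 2 probes", {
  probes <- dplyr::bind_rows(
    make_step_track(c(0, 2), 15, chrom = "chr1"),
    tibble::tibble(tumor_id = "t1", chrom = "chr2", pos = 1000L, signal = 0))
  expect_warning(prof <- segment_tumor(probes), "fewer than 2")
  expect_equal(prof$n_breakpoints, 1L)
})

test_that("simulated genomes with 40 true breakpoints are recovered within +/-2", {
  # 8 chromosomes x 5 breakpoints at jittered near-equal spacing, all jumps
  # exactly 5 sigma (0.4 at noise_sd 0.08)
  set.seed(707)
  hits <- 0
  for (rep in 1:20) {
    bps <- lapply(1:8, function(i) {
      sort(as.integer(round(seq(1, 5) * 250 / 6) + sample(-10:10, 5)))
    })
    sim <- simulate_profile(
      n_probes = setNames(rep(250L, 8), paste0("chr", 1:8)),
      breakpoints = bps,
      segment_means = rep(list(c(0, 0.4, 0, 0.4, 0, 0.4)), 8),
      noise_sd = 0.08, seed = 7000 + rep)
    prof <- segment_tumor(sim$probes, k_max = 30)
    if (abs(prof$n_breakpoints - 40L) <= 2) hits <- hits + 1
  }
  expect_gte(hits / 20, 0.90)
})
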