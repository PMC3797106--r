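# Independent oracles used across the suite. Each reimplements the target
# quantity by direct enumeration or tabulation, sharing no code with the
# package internals it checks.

# global minimum over all placements of k breakpoints, by enumeration
brute_force_segmentation <- function(y, k) {
  n <- length(y)
  seg_rss <- function(seg) sum((seg - mean(seg))^2)
  if (k == 0) return(list(rss = seg_rss(y), breakpoints = integer(0)))
  best <- Inf
  best_bp <- NULL
  for (bp in utils::combn(n - 1, k, simplify = FALSE)) {
    bounds <- c(0, bp, n)
    r <- sum(vapply(seq_len(k + 1), function(i) {
      seg_rss(y[(bounds[i] + 1):bounds[i + 1]])
    }, numeric(1)))
    if (r < best) {
      best <- r
      best_bp <- bp
    }
  }
  list(rss = best, breakpoints = as.integer(best_bp))
}

# direct evaluation of the modified BIC from its definition; no shared code
mbic_by_hand <- function(y, breakpoints) {
  n <- length(y)
  k <- length(breakpoints)
  bounds <- c(0, breakpoints, n)
  rss_of <- function(b) {
    sum(vapply(seq_len(length(b) - 1), function(i) {
      seg <- y[(b[i] + 1):b[i + 1]]
      sum((seg - mean(seg))^2)
    }, numeric(1)))
  }
  ss0 <- rss_of(c(0, n))
  ssk <- rss_of(bounds)
  lens <- diff(bounds)
  (n / 2) * log(ss0 / ssk) - 0.5 * sum(log(lens)) - (k - 0.5) * log(n)
}

# O(n_pos * n_neg) pairwise AUC, ties counted one half
auc_pairwise <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (x in pos) total <- total + sum(x > neg) + 0.5 * sum(x == neg)
  total / (length(pos) * length(neg))
}

# best sensitivity + specificity over every integer cut-off (strict > rule)
youden_brute_force <- function(counts, labels) {
  cands <- (min(counts) - 1):max(counts)
  best_j <- -Inf
  best_t <- NA
  for (t in cands) {
    sens <- mean(counts[labels == 1] > t)
    spec <- mean(counts[labels == 0] <= t)
    if (sens + spec > best_j + 1e-12) {
      best_j <- sens + spec
      best_t <- t
    }
  }
  list(threshold = best_t, j = best_j - 1)
}

# two-group log-rank chi-square by direct tabulation over event times
logrank_by_hand <- function(time, event, group) {
  g <- as.integer(factor(group)) - 1L  # 0/1
  o_minus_e <- 0
  v <- 0
  for (t in sort(unique(time[event == 1]))) {
    at_risk <- time >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & g == 1)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & g == 1)
    o_minus_e <- o_minus_e + (d1 - d * n1 / n)
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  o_minus_e^2 / v
}

# step-by-step product-limit estimate
km_by_hand <- function(time, event) {
  s <- 1
  out <- numeric(0)
  times <- sort(unique(time[event == 1]))
  for (t in times) {
    n_risk <- sum(time >= t)
    d <- sum(time == t & event == 1)
    s <- s * (1 - d / n_risk)
    out <- c(out, s)
  }
  tibble::tibble(time = times, survival = out)
}

make_step_track <- function(means, len, noise_sd = 0, seed = NULL,
                            chrom = "chr1", tumor_id = "t1",
                            pos_step = 1000L) {
  sig <- rep(means, each = len)
  if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    sig <- sig + rnorm(length(sig), sd = noise_sd)
  }
  tibble::tibble(tumor_id = tumor_id, chrom = chrom,
                 pos = seq_along(sig) * pos_step, signal = sig)
}
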