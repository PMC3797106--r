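#' Modified BIC for the number of breakpoints
#'
#' Evaluates the modified Bayes information criterion for the optimal
#' `k`-breakpoint segmentation stored in a cost curve. The criterion applies
#' to the Gaussian mean-shift model with a common variance profiled out:
#'
#' \deqn{mBIC(k) = \frac{n}{2}\log\frac{SS_0}{SS_k}
#'   - \frac{1}{2}\sum_{i=1}^{k+1}\log n_i - \left(k - \frac12\right)\log n}
#'
#' where \eqn{SS_k} is the optimal residual sum of squares with `k`
#' breakpoints and \eqn{n_i} are the lengths of the optimal segments. The
#' penalty is equivalently \eqn{\frac{3k}{2}\log n +
#' \frac12\sum\log(n_i/n)}: each breakpoint costs a location term
#' \eqn{\log n} plus half a \eqn{\log n} for its segment mean, and segment
#' means estimated on short segments are charged less through the
#' \eqn{\log n_i} terms. By construction \eqn{mBIC(0) = 0}. The criterion
#' depends on the data only through the ratio \eqn{SS_0/SS_k} and the segment
#' lengths, so it is invariant to shifting and to positive rescaling of the
#' signal. See the package vignette for the derivation.
#'
#' A floor of `1e-12 * n * var(signal)` (computed from `rss[1]`) is applied to
#' \eqn{SS_k} so that noiseless toy signals with an exact fit do not produce
#' `log(0)`; when `SS_0` itself is (near) zero the likelihood term is defined
#' as 0 and the penalty alone ranks the models.
#'
#' @param cost A `breakscan_cost_curve` from [optimal_segmentation()].
#' @param k Number of breakpoints, `0 <= k <= k_max` (vectorised).
#' @param penalty_scale Multiplier on the penalty term (default 1). Used by
#'   the liberal round-1 outlier screen.
#' @return Numeric criterion value(s); larger is better.
#' @export
mbic_criterion <- function(cost, k, penalty_scale = 1) {
  stopifnot(inherits(cost, "breakscan_cost_curve"))
  k <- as.integer(k)
  if (any(k < 0 | k > cost$k_max)) stop("k out of range 0..k_max")
  n <- cost$n
  rss0 <- cost$rss[1]
  eps <- 1e-12 * n * rss0 / max(n - 1, 1)
  vapply(k, function(kk) {
    rssk <- max(cost$rss[kk + 1], eps)
    ll <- if (rss0 <= eps || rss0 <= 0) 0 else (n / 2) * log(rss0 / rssk)
    len <- segment_lengths(cost$breakpoints[[kk + 1]], n)
    pen <- 0.5 * sum(log(len)) + (kk - 0.5) * log(n)
    ll - penalty_scale * pen
  }, numeric(1))
}

#' Select the number of breakpoints by modified BIC
#'
#' Evaluates [mbic_criterion()] for every `k = 0..k_max` of a cost curve and
#' returns the maximiser (ties resolved towards the smallest `k`).
#'
#' @inheritParams mbic_criterion
#' @return A list with `k_selected`, `criterion` (numeric vector over
#'   `k = 0..k_max`) and `breakpoints` (the selected positions).
#' @examples
#' cc <- optimal_segmentation(c(rnorm(50), rnorm(50, 4)), k_max = 10)
#' select_k(cc)$k_selected
#' @export
select_k <- function(cost, penalty_scale = 1) {
  stopifnot(inherits(cost, "breakscan_cost_curve"))
  crit <- mbic_criterion(cost, 0:cost$k_max, penalty_scale = penalty_scale)
  k <- which.max(crit) - 1L  # which.max returns the first (smallest) maximiser
  list(k_selected = k, criterion = crit,
       breakpoints = cost$breakpoints[[k + 1]])
}
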