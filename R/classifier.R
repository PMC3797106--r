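#' Assign a genomic-complexity risk class
#'
#' A tumor with strictly more than `threshold` breakpoints is classified
#' high-risk; a count equal to the threshold is low-risk.
#'
#' @param count Non-negative integer breakpoint count(s).
#' @param threshold Integer cut-off, default 34.
#' @return Factor with levels `low_risk`, `high_risk`.
#' @examples
#' classify_risk(c(0, 34, 40))
#' @export
classify_risk <- function(count, threshold = 34L) {
  if (any(!is.finite(count)) || any(count < 0)) {
    stop("breakpoint counts must be non-negative")
  }
  factor(ifelse(count > threshold, "high_risk", "low_risk"),
         levels = c("low_risk", "high_risk"))
}

wald_ci <- function(p, n) {
  half <- 1.96 * sqrt(p * (1 - p) / n)
  c(max(0, p - half), min(1, p + half))
}

mw_auc <- function(pos, neg) {
  # Mann-Whitney AUC via midranks: ties count 1/2
  r <- rank(c(pos, neg), ties.method = "average")
  m <- length(pos)
  (sum(r[seq_len(m)]) - m * (m + 1) / 2) / (m * length(neg))
}

delong_ci <- function(pos, neg, level = 0.95) {
  m <- length(pos); n <- length(neg)
  auc <- mw_auc(pos, neg)
  # placement values
  v10 <- vapply(pos, function(x) mean((x > neg) + 0.5 * (x == neg)),
                numeric(1))
  v01 <- vapply(neg, function(y) mean((pos > y) + 0.5 * (pos == y)),
                numeric(1))
  v <- (if (m > 1) var(v10) / m else 0) + (if (n > 1) var(v01) / n else 0)
  z <- qnorm(1 - (1 - level) / 2)
  list(auc = auc, se = sqrt(v),
       ci = c(max(0, auc - z * sqrt(v)), min(1, auc + z * sqrt(v))))
}

#' Empirical AUC with DeLong confidence interval
#'
#' Area under the ROC curve for a score (e.g. a breakpoint count) against a
#' binary outcome, computed as the Mann-Whitney rank statistic with ties
#' counted one half, with a 95% confidence interval from the DeLong
#' placement-value variance estimator.
#'
#' @param counts Numeric scores; larger values indicate the positive class.
#' @param labels Binary outcome (logical, 0/1, or a two-level factor whose
#'   second level is the positive class).
#' @return A tibble with `auc`, `ci_low`, `ci_high`, `n_pos`, `n_neg`.
#' @export
roc_auc <- function(counts, labels) {
  lab <- as_binary_label(labels)
  if (length(unique(lab)) < 2) stop("both outcome classes must be present")
  pos <- counts[lab == 1]; neg <- counts[lab == 0]
  d <- delong_ci(pos, neg)
  tibble::tibble(auc = d$auc, ci_low = d$ci[1], ci_high = d$ci[2],
                 n_pos = length(pos), n_neg = length(neg))
}

as_binary_label <- function(labels) {
  if (is.factor(labels)) {
    if (nlevels(labels) != 2) stop("labels must have exactly two levels")
    as.integer(labels == levels(labels)[2])
  } else if (is.logical(labels)) {
    as.integer(labels)
  } else {
    u <- unique(labels)
    if (!all(u %in% c(0, 1))) stop("numeric labels must be 0/1")
    as.integer(labels)
  }
}

#' Train a breakpoint-count threshold by the Youden index
#'
#' Scans every achievable integer cut-off (all distinct observed counts plus
#' a cut-off below the minimum) under the strict rule `count > threshold` is
#' positive, and returns the threshold maximising sensitivity + specificity.
#' Ties are resolved towards the smallest threshold. The fitted model stores
#' the full ROC curve, the Mann-Whitney AUC with DeLong 95% CI, and Wald 95%
#' CIs for sensitivity and specificity at the chosen cut-off.
#'
#' @param counts Non-negative breakpoint counts.
#' @param labels Binary outcome; the positive class is the poor-prognosis
#'   group (higher counts are expected in it).
#' @return A `breakscan_threshold` object; see [tidy.breakscan_threshold()]
#'   and [autoplot.breakscan_threshold()].
#' @examples
#' m <- youden_threshold(c(1, 2, 3, 10, 11, 12), c(0, 0, 0, 1, 1, 1))
#' m$threshold
#' @export
youden_threshold <- function(counts, labels) {
  if (any(!is.finite(counts)) || any(counts < 0)) {
    stop("counts must be non-negative and finite")
  }
  lab <- as_binary_label(labels)
  if (length(unique(lab)) < 2) stop("both outcome classes must be present")
  n_pos <- sum(lab == 1); n_neg <- sum(lab == 0)

  cand <- sort(unique(c(min(counts) - 1, counts)))
  stats <- lapply(cand, function(t) {
    pred <- counts > t
    sens <- sum(pred & lab == 1) / n_pos
    spec <- sum(!pred & lab == 0) / n_neg
    c(sens = sens, spec = spec)
  })
  sens <- vapply(stats, `[[`, numeric(1), "sens")
  spec <- vapply(stats, `[[`, numeric(1), "spec")
  j <- sens + spec
  best <- which.max(j)  # first max = smallest threshold on ties
  thr <- cand[best]

  d <- delong_ci(counts[lab == 1], counts[lab == 0])
  structure(
    list(
      threshold = thr,
      sensitivity = sens[best], sensitivity_ci = wald_ci(sens[best], n_pos),
      specificity = spec[best], specificity_ci = wald_ci(spec[best], n_neg),
      youden_j = j[best] - 1,
      auc = d$auc, auc_ci = d$ci,
      roc = tibble::tibble(threshold = cand, fpr = 1 - spec, tpr = sens),
      table = matrix(
        c(sum(counts <= thr & lab == 0), sum(counts > thr & lab == 0),
          sum(counts <= thr & lab == 1), sum(counts > thr & lab == 1)),
        nrow = 2, byrow = TRUE,
        dimnames = list(group = c("good", "poor"),
                        call = c("low_risk", "high_risk"))),
      n_pos = n_pos, n_neg = n_neg
    ),
    class = "breakscan_threshold"
  )
}

#' @export
print.breakscan_threshold <- function(x, ...) {
  cat("<breakscan_threshold> cut-off >", x$threshold, "breakpoints\n")
  cat(sprintf("  sensitivity %.2f (%.2f-%.2f)  specificity %.2f (%.2f-%.2f)\n",
              x$sensitivity, x$sensitivity_ci[1], x$sensitivity_ci[2],
              x$specificity, x$specificity_ci[1], x$specificity_ci[2]))
  cat(sprintf("  AUC %.2f (95%% CI %.2f-%.2f)\n", x$auc, x$auc_ci[1],
              x$auc_ci[2]))
  invisible(x)
}

#' Tidy a trained threshold model
#'
#' @param x A `breakscan_threshold` object.
#' @param ... Unused.
#' @return One-row tibble with the threshold, operating characteristics and
#'   their 95% confidence bounds.
#' @export
tidy.breakscan_threshold <- function(x, ...) {
  tibble::tibble(
    threshold = x$threshold,
    sensitivity = x$sensitivity,
    sensitivity_low = x$sensitivity_ci[1],
    sensitivity_high = x$sensitivity_ci[2],
    specificity = x$specificity,
    specificity_low = x$specificity_ci[1],
    specificity_high = x$specificity_ci[2],
    youden_j = x$youden_j,
    auc = x$auc, auc_low = x$auc_ci[1], auc_high = x$auc_ci[2]
  )
}

#' @rdname tidy.breakscan_threshold
#' @export
glance.breakscan_threshold <- function(x, ...) {
  tibble::tibble(threshold = x$threshold, auc = x$auc,
                 n_pos = x$n_pos, n_neg = x$n_neg)
}

#' ROC curve of a trained threshold model
#'
#' @param object A `breakscan_threshold` object.
#' @param ... Unused.
#' @return A ggplot: empirical ROC curve with the Youden point marked.
#' @export
autoplot.breakscan_threshold <- function(object, ...) {
  roc <- dplyr::arrange(object$roc, .data$fpr, .data$tpr)
  pt <- tibble::tibble(fpr = 1 - object$specificity, tpr = object$sensitivity)
  ggplot2::ggplot(roc, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted",
                         colour = "grey60") +
    ggplot2::geom_step(direction = "vh") +
    ggplot2::geom_point(data = pt, colour = "red", size = 2) +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "1 - specificity", y = "Sensitivity",
      title = sprintf("ROC, AUC %.2f (%.2f-%.2f), Youden cut-off > %s",
                      object$auc, object$auc_ci[1], object$auc_ci[2],
                      format(object$threshold))) +
    ggplot2::theme_minimal()
}

#' Sensitivity and specificity of a 2x2 classification table
#'
#' Computes specificity (true low-risk calls among good-prognosis tumors) and
#' sensitivity (true high-risk calls among poor-prognosis tumors) with Wald
#' 95% confidence intervals `p +/- 1.96 sqrt(p(1-p)/n)` truncated to
#' \[0, 1\].
#'
#' @param good_low,good_high Counts of good-prognosis tumors called low/high
#'   risk.
#' @param poor_low,poor_high Counts of poor-prognosis tumors called low/high
#'   risk.
#' @return A tibble with one row per statistic: `estimate`, `ci_low`,
#'   `ci_high`, `n`.
#' @examples
#' contingency_stats(74, 5, 13, 17)
#' @export
contingency_stats <- function(good_low, good_high, poor_low, poor_high) {
  counts <- c(good_low, good_high, poor_low, poor_high)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("table entries must be non-negative integers")
  }
  n_good <- good_low + good_high
  n_poor <- poor_low + poor_high
  if (n_good == 0 || n_poor == 0) stop("both group totals must be positive")
  spec <- good_low / n_good
  sens <- poor_high / n_poor
  sci <- wald_ci(spec, n_good)
  nci <- wald_ci(sens, n_poor)
  tibble::tibble(
    statistic = c("specificity", "sensitivity"),
    estimate = c(spec, sens),
    ci_low = c(sci[1], nci[1]),
    ci_high = c(sci[2], nci[2]),
    n = c(n_good, n_poor)
  )
}
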