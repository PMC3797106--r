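#' Kaplan-Meier curves as a tidy table
#'
#' Product-limit estimate of the survival function, overall or per group,
#' via [survival::survfit()].
#'
#' @param data Data frame of one row per patient.
#' @param time,event Column names (strings) of the follow-up time (positive)
#'   and the event indicator (0/1).
#' @param group Optional column name of a grouping factor.
#' @return A `breakscan_km` tibble: `group`, `time`, `n_risk`, `n_event`,
#'   `n_censor`, `survival`, `ci_low`, `ci_high`. Survival is 1 at time 0 and
#'   non-increasing within each group.
#' @export
km_curve <- function(data, time = "time", event = "event", group = NULL) {
  check_surv_cols(data, time, event)
  rhs <- if (is.null(group)) "1" else group
  fit <- survival::survfit(
    as.formula(paste0("survival::Surv(", time, ", ", event, ") ~ ", rhs)),
    data = data)
  s <- summary(fit, censored = TRUE)
  grp <- if (is.null(group)) {
    rep("all", length(s$time))
  } else {
    sub("^.*=", "", as.character(s$strata))
  }
  out <- tibble::tibble(
    group = grp, time = s$time, n_risk = s$n.risk, n_event = s$n.event,
    n_censor = s$n.censor, survival = s$surv,
    ci_low = s$lower, ci_high = s$upper)
  class(out) <- c("breakscan_km", class(out))
  out
}

check_surv_cols <- function(data, time, event) {
  stopifnot(all(c(time, event) %in% names(data)))
  tt <- data[[time]]; ee <- data[[event]]
  if (any(!is.finite(tt)) || any(tt <= 0)) stop("times must be positive")
  if (!all(ee %in% c(0, 1))) stop("event indicators must be 0/1")
  if (nrow(data) == 0) stop("empty data")
  invisible(TRUE)
}

#' Kaplan-Meier plot
#'
#' @param object A `breakscan_km` tibble from [km_curve()].
#' @param ... Unused.
#' @return A ggplot step plot of the survival curves.
#' @export
autoplot.breakscan_km <- function(object, ...) {
  # prepend S(0) = 1 per group so every step starts at the origin
  origins <- dplyr::summarise(dplyr::group_by(object, .data$group),
                              time = 0, survival = 1, .groups = "drop")
  df <- dplyr::bind_rows(
    origins, object[, c("group", "time", "survival")])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$survival,
                                   colour = .data$group)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Time (years)", y = "Survival probability",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Two-group log-rank test
#'
#' Standard log-rank chi-square test with one degree of freedom, via
#' [survival::survdiff()].
#'
#' @inheritParams km_curve
#' @param group Column name of a two-level grouping variable.
#' @return One-row tibble: `statistic`, `df`, `p_value`, and the per-group
#'   observed and expected event counts as list-columns.
#' @export
logrank_test <- function(data, time = "time", event = "event",
                         group = "group") {
  check_surv_cols(data, time, event)
  g <- data[[group]]
  if (length(unique(g[!is.na(g)])) != 2) {
    stop("the grouping variable must have exactly two observed levels")
  }
  sd <- survival::survdiff(
    as.formula(paste0("survival::Surv(", time, ", ", event, ") ~ ", group)),
    data = data)
  tibble::tibble(
    statistic = sd$chisq, df = 1,
    p_value = stats::pchisq(sd$chisq, df = 1, lower.tail = FALSE),
    observed = list(sd$obs), expected = list(sd$exp))
}

#' Univariate or multivariate Cox proportional-hazards fits
#'
#' Partial-likelihood proportional-hazards fits with Efron handling of tied
#' event times, via [survival::coxph()]. In univariate mode each term is fit
#' alone; in multivariate mode all terms enter jointly. Relative risks are
#' hazard ratios with Wald 95% confidence intervals and Wald p-values.
#'
#' @inheritParams km_curve
#' @param terms Character vector of covariate column names (factors or
#'   numerics). None may be constant; duplicated/collinear terms are an
#'   error in multivariate mode.
#' @param multivariate Fit all terms jointly (default `FALSE`).
#' @return A `breakscan_cox` object; `tidy()` returns a tibble with one row
#'   per estimated coefficient: `variable`, `term`, `rr`, `ci_low`,
#'   `ci_high`, `p_value`, `n`, `n_events`.
#' @export
cox_fit <- function(data, time = "time", event = "event", terms,
                    multivariate = FALSE) {
  check_surv_cols(data, time, event)
  stopifnot(length(terms) >= 1, all(terms %in% names(data)))
  for (tm in terms) {
    v <- data[[tm]]
    if (length(unique(v[!is.na(v)])) < 2) {
      stop("covariate '", tm, "' is constant")
    }
  }
  if (multivariate && anyDuplicated(terms)) {
    stop("duplicated covariates in the multivariate set (collinear design)")
  }
  fit_one <- function(tms) {
    f <- as.formula(paste0("survival::Surv(", time, ", ", event, ") ~ ",
                           paste(tms, collapse = " + ")))
    fit <- withCallingHandlers(
      survival::coxph(f, data = data, ties = "efron"),
      warning = function(w) {
        warning("coxph [", paste(tms, collapse = "+"), "]: ",
                conditionMessage(w), call. = FALSE)
        invokeRestart("muffleWarning")
      })
    if (any(!is.finite(coef(fit)))) {
      stop("Cox fit failed for '", paste(tms, collapse = " + "),
           "': non-finite coefficient (collinear or separated design)")
    }
    se <- sqrt(diag(fit$var))
    if (any(abs(coef(fit)) > 15) || any(se > 100)) {
      warning("possible separation in Cox fit for '",
              paste(tms, collapse = " + "), "' (extreme coefficient or SE)")
    }
    fit
  }
  fits <- if (multivariate) {
    list(joint = fit_one(terms))
  } else {
    setNames(lapply(terms, fit_one), terms)
  }
  structure(list(fits = fits, terms = terms, multivariate = multivariate,
                 time = time, event = event),
            class = "breakscan_cox")
}

#' @export
print.breakscan_cox <- function(x, ...) {
  cat("<breakscan_cox>", if (x$multivariate) "multivariate" else "univariate",
      "fit of:", paste(x$terms, collapse = ", "), "\n")
  print(tidy(x))
  invisible(x)
}

#' @rdname cox_fit
#' @param x A `breakscan_cox` object.
#' @param ... Unused.
#' @export
tidy.breakscan_cox <- function(x, ...) {
  rows <- lapply(names(x$fits), function(nm) {
    fit <- x$fits[[nm]]
    co <- coef(fit)
    se <- sqrt(diag(fit$var))
    z <- co / se
    tibble::tibble(
      variable = if (x$multivariate) names(co) else nm,
      term = names(co),
      log_rr = unname(co),
      rr = exp(unname(co)),
      ci_low = exp(unname(co - 1.96 * se)),
      ci_high = exp(unname(co + 1.96 * se)),
      p_value = 2 * pnorm(-abs(unname(z))),
      n = fit$n, n_events = fit$nevent)
  })
  dplyr::bind_rows(rows)
}

#' @rdname cox_fit
#' @export
glance.breakscan_cox <- function(x, ...) {
  tibble::tibble(
    multivariate = x$multivariate,
    n_terms = length(x$terms),
    n = x$fits[[1]]$n,
    n_events = x$fits[[1]]$nevent)
}

#' Attach the standard risk-class covariates to a cohort
#'
#' Adds the dichotomized covariates used in the prognostic models:
#' `breakpoint_class` (strictly more than `threshold` breakpoints),
#' `ki67_high` (>= 14%), `gg3` (standardized genomic grade index > 0) and
#' `grade_high` (histologic grade II/III vs I).
#'
#' @param cohort Cohort tibble (see [read_cohort()] / [simulate_cohort()]).
#' @param threshold Breakpoint cut-off, default 34.
#' @return The cohort with the four factor columns appended.
#' @export
add_risk_classes <- function(cohort, threshold = 34L) {
  dplyr::mutate(
    cohort,
    breakpoint_class = classify_risk(.data$breakpoint_count, threshold),
    ki67_high = ki67_class(.data$ki67_fraction),
    gg3 = genomic_grade(.data$ggi),
    grade_high = factor(
      ifelse(is.na(.data$grade), NA_character_,
             ifelse(.data$grade >= 2, "II_III", "I")),
      levels = c("I", "II_III")))
}
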