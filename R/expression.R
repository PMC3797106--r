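#' Raw genomic grade index
#'
#' Contrasts expression over two probe-set panels: the sum over probe sets
#' up-regulated in histologic grade-3 tumors minus the sum over probe sets
#' up-regulated in grade-1 tumors, per sample. The canonical panels contain
#' 112 and 16 probe sets; other sizes are accepted with a warning so that
#' user-supplied lists can be audited.
#'
#' @param expression Numeric matrix or data frame, samples in rows, probe
#'   sets in columns (column names are probe-set identifiers). A `sample`
#'   column is allowed in data-frame input and used as the sample identifier.
#' @param up_in_grade3,up_in_grade1 Character vectors of probe-set
#'   identifiers; must be disjoint and present in `expression`.
#' @return A tibble with `sample` and `ggi_raw`.
#' @export
ggi_raw <- function(expression, up_in_grade3, up_in_grade1) {
  up_in_grade3 <- unique(as.character(up_in_grade3))
  up_in_grade1 <- unique(as.character(up_in_grade1))
  if (length(intersect(up_in_grade3, up_in_grade1))) {
    stop("the grade-3 and grade-1 panels must be disjoint")
  }
  if (length(up_in_grade3) != 112 || length(up_in_grade1) != 16) {
    warning("panel sizes ", length(up_in_grade3), "/", length(up_in_grade1),
            " differ from the canonical 112/16")
  }
  samples <- NULL
  if (is.data.frame(expression)) {
    if ("sample" %in% names(expression)) {
      samples <- as.character(expression$sample)
      expression$sample <- NULL
    }
    expression <- as.matrix(expression)
  }
  if (is.null(samples)) {
    samples <- rownames(expression) %||% as.character(seq_len(nrow(expression)))
  }
  missing <- setdiff(c(up_in_grade3, up_in_grade1), colnames(expression))
  if (length(missing)) {
    stop("probe sets absent from the expression matrix: ",
         paste(missing, collapse = ", "))
  }
  if (any(!is.finite(expression[, c(up_in_grade3, up_in_grade1)]))) {
    stop("expression values for panel probe sets must be finite")
  }
  raw <- rowSums(expression[, up_in_grade3, drop = FALSE]) -
    rowSums(expression[, up_in_grade1, drop = FALSE])
  tibble::tibble(sample = samples, ggi_raw = unname(raw))
}

#' Fit the -1/+1 genomic grade standardization
#'
#' Finds the affine transformation `scale * (raw - offset)` mapping the mean
#' raw genomic grade index of histologic grade-1 tumors to -1 and that of
#' grade-3 tumors to +1: `scale = 2 / (m3 - m1)`, `offset = (m3 + m1) / 2`.
#' Tumors of other grades (or missing grade) are ignored during the fit but
#' can be standardized with the fitted model.
#'
#' @param raw Numeric vector of raw genomic grade index values.
#' @param grade Histologic grade per sample; only values 1 and 3 anchor the
#'   fit (at least one sample of each is required).
#' @return A `ggi_model` object with `scale`, `offset` and a `predict()`
#'   method returning standardized values.
#' @examples
#' m <- fit_ggi_standardization(c(0, 0, 4, 4), c(1, 1, 3, 3))
#' predict(m, c(0, 2, 4))
#' @export
fit_ggi_standardization <- function(raw, grade) {
  stopifnot(length(raw) == length(grade))
  g1 <- raw[!is.na(grade) & grade == 1]
  g3 <- raw[!is.na(grade) & grade == 3]
  if (!length(g1) || !length(g3)) {
    stop("at least one grade-1 and one grade-3 sample are required")
  }
  m1 <- mean(g1); m3 <- mean(g3)
  if (isTRUE(all.equal(m1, m3))) {
    stop("degenerate anchors: grade-1 and grade-3 raw means coincide")
  }
  structure(list(scale = 2 / (m3 - m1), offset = (m3 + m1) / 2,
                 n_grade1 = length(g1), n_grade3 = length(g3)),
            class = "ggi_model")
}

#' @export
print.ggi_model <- function(x, ...) {
  cat(sprintf("<ggi_model> scale %.4g, offset %.4g (fit on %d grade-1, %d grade-3)\n",
              x$scale, x$offset, x$n_grade1, x$n_grade3))
  invisible(x)
}

#' @export
predict.ggi_model <- function(object, newdata, ...) {
  object$scale * (as.numeric(newdata) - object$offset)
}

#' @rdname fit_ggi_standardization
#' @param x A `ggi_model` object.
#' @param ... Unused.
#' @export
tidy.ggi_model <- function(x, ...) {
  tibble::tibble(scale = x$scale, offset = x$offset,
                 n_grade1 = x$n_grade1, n_grade3 = x$n_grade3)
}

#' Genomic grade call from a standardized index
#'
#' Dichotomizes the standardized genomic grade index at 0: strictly positive
#' values are called GG3, all others (including exactly 0, a conservative
#' lower-risk tie rule) GG1. Missing values stay missing.
#'
#' @param ggi Standardized genomic grade index values.
#' @return Factor with levels `GG1`, `GG3`.
#' @export
genomic_grade <- function(ggi) {
  out <- ifelse(is.na(ggi), NA_character_, ifelse(ggi > 0, "GG3", "GG1"))
  factor(out, levels = c("GG1", "GG3"))
}

#' KI67 dichotomization at 14%
#'
#' @param fraction KI67 positive-cell fraction in \[0, 1\] (missing allowed).
#' @return Factor with levels `low`, `high`; `high` iff `fraction >= 0.14`
#'   (the boundary value is called high).
#' @export
ki67_class <- function(fraction) {
  bad <- !is.na(fraction) & (fraction < 0 | fraction > 1)
  if (any(bad)) stop("ki67 fraction out of [0, 1]")
  out <- ifelse(is.na(fraction), NA_character_,
                ifelse(fraction >= 0.14, "high", "low"))
  factor(out, levels = c("low", "high"))
}

ihc3_coefficients <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      path <- system.file("extdata", "ihc3_coefficients.json",
                          package = "breakscan")
      cache <<- jsonlite::read_json(path, simplifyVector = TRUE)
    }
    cache
  }
})

#' IHC3 prognostic score
#'
#' The IHC4 linear score restricted to HER2-negative tumors (HER2 term
#' dropped): `94.7 * (-0.100 ER10 - 0.079 PR10 + 0.240 ln(1 + 10 Ki67))`,
#' with ER and PR on 0-10 immunohistochemistry scales and KI67 as a fraction
#' in \[0, 1\] so that `10 * Ki67` shares the 0-10 scale. The coefficients are
#' shipped as data in `inst/extdata/ihc3_coefficients.json` with their
#' citation. Manually assessed KI67 can be rescaled by a calibration divisor
#' (`ki67_rescale`); a value other than 1 is reported with a message so the
#' calibration is always visible in the output log.
#'
#' @param er10,pr10 Integer scores 0-10 (missing allowed).
#' @param ki67_fraction KI67 fraction in \[0, 1\].
#' @param ki67_rescale Calibration divisor applied to the KI67 value before
#'   the log transform. Default 1.
#' @return Numeric score (monotone increasing in KI67 at fixed ER/PR).
#' @examples
#' ihc3_score(10, 10, 0.14)
#' @export
ihc3_score <- function(er10, pr10, ki67_fraction, ki67_rescale = 1) {
  chk_range <- function(x, lo, hi, what) {
    if (any(!is.na(x) & (x < lo | x > hi))) {
      stop(what, " out of [", lo, ", ", hi, "]")
    }
  }
  chk_range(er10, 0, 10, "er10")
  chk_range(pr10, 0, 10, "pr10")
  chk_range(ki67_fraction, 0, 1, "ki67_fraction")
  if (ki67_rescale <= 0) stop("ki67_rescale must be positive")
  if (ki67_rescale != 1) {
    message("ihc3_score: KI67 rescaled by a factor of ", ki67_rescale)
  }
  k <- ihc3_coefficients()
  k$multiplier * (k$er10 * er10 + k$pr10 * pr10 +
                    k$ki67 * log(1 + 10 * ki67_fraction / ki67_rescale))
}
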