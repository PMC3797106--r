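#' Run the full analysis pipeline on synthetic data
#'
#' One call exercising every stage: simulate per-patient probe-level profiles
#' whose true breakpoint counts come from a simulated survival cohort,
#' segment them (two rounds, modified-BIC selection), count breakpoints,
#' classify at the breakpoint threshold, and validate the classifier with
#' log-rank and Cox analyses of the disease-free interval. All randomness is
#' governed by `seed`; re-running with the same seed reproduces every
#' artifact byte for byte.
#'
#' Problem sizes are deliberately modest (default 40 patients, 6 chromosomes
#' of 120 probes) so the pipeline runs in seconds; they are arguments, not
#' constants.
#'
#' @param out_dir Directory for the artifacts (created if needed):
#'   `probes.tsv`, `segments.bed`, `counts.csv`, `cohort.csv`, `fits.json`,
#'   `km_dfi.csv`.
#' @param seed Integer seed for all stages.
#' @param n_patients Number of patients (profiles + outcomes).
#' @param n_chrom,probes_per_chrom Genome size of each simulated profile.
#' @param noise_sd,outlier_rate Profile noise model (jump sizes come from the
#'   level pool of [simulate_profile()]).
#' @param threshold Breakpoint cut-off for the risk classes.
#' @return A list with `counts` (tibble), `logrank` (tibble), `cox`
#'   (tibble), and the artifact paths, invisibly returned components
#'   included.
#' @export
run_pipeline <- function(out_dir, seed = 1L, n_patients = 40L,
                         n_chrom = 6L, probes_per_chrom = 120L,
                         noise_sd = 0.08, outlier_rate = 0.005,
                         threshold = 34L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(seed)

  # cohort first: its breakpoint counts are the truth the profiles encode
  n_poor <- max(2L, round(n_patients * 30 / 109))
  sim <- simulate_cohort(n_good = n_patients - n_poor, n_poor = n_poor,
                         threshold = threshold, seed = seed)
  cohort <- sim$cohort

  # one profile per patient carrying its true breakpoint count; counts beyond
  # what the genome size can resolve (mean segment length < 8 probes) are
  # truncated and the injected number recorded
  injected <- integer(nrow(cohort))
  probes <- with_seed(seed + 1L, {
    dplyr::bind_rows(lapply(seq_len(nrow(cohort)), function(i) {
      k_total <- cohort$breakpoint_count[i]
      base <- rep(k_total %/% n_chrom, n_chrom)
      extra <- k_total %% n_chrom
      if (extra > 0) base[seq_len(extra)] <- base[seq_len(extra)] + 1L
      base <- pmin(base, probes_per_chrom %/% 8L)
      injected[i] <<- sum(base)
      # jittered near-equal spacing keeps every segment resolvable
      bps <- lapply(base, function(k) {
        if (k == 0) return(integer(0))
        anchors <- round(seq_len(k) * probes_per_chrom / (k + 1))
        jit <- anchors + sample(-2:2, k, replace = TRUE)
        sort(as.integer(pmin(pmax(jit, 1), probes_per_chrom - 1L)))
      })
      simulate_profile(
        n_probes = setNames(rep(probes_per_chrom, n_chrom),
                            paste0("chr", seq_len(n_chrom))),
        breakpoints = bps,
        noise_sd = noise_sd, outlier_rate = outlier_rate,
        tumor_id = cohort$patient_id[i], seed = NULL)$probes
    }))
  })
  probes_path <- file.path(out_dir, "probes.tsv")
  readr::write_tsv(probes, probes_path, progress = FALSE)

  profiles <- segment_profiles(probes, threshold = threshold)
  seg_path <- file.path(out_dir, "segments.bed")
  write_segments(profiles, seg_path)
  counts <- profiles$counts
  counts_path <- file.path(out_dir, "counts.csv")
  readr::write_csv(counts, counts_path, progress = FALSE)

  # measured counts replace the generated ones downstream
  cohort_out <- dplyr::left_join(
    dplyr::select(cohort, -"breakpoint_count"),
    dplyr::select(counts, "tumor_id", "n_breakpoints"),
    by = c(patient_id = "tumor_id"))
  cohort_out <- dplyr::rename(cohort_out, breakpoint_count = "n_breakpoints")
  cohort_out <- add_risk_classes(cohort_out, threshold = threshold)
  cohort_path <- file.path(out_dir, "cohort.csv")
  readr::write_csv(cohort_out, cohort_path, progress = FALSE)

  both_classes <- dplyr::n_distinct(cohort_out$breakpoint_class) == 2
  if (both_classes) {
    lr <- logrank_test(cohort_out, time = "dfi_time", event = "dfi_event",
                       group = "breakpoint_class")
    cox <- tidy(cox_fit(cohort_out, time = "dfi_time", event = "dfi_event",
                        terms = "breakpoint_class"))
    km <- km_curve(cohort_out, time = "dfi_time", event = "dfi_event",
                   group = "breakpoint_class")
  } else {
    message("only one risk class observed; survival comparison skipped")
    lr <- tibble::tibble(statistic = NA_real_, df = 1, p_value = NA_real_)
    cox <- tibble::tibble(rr = NA_real_, ci_low = NA_real_,
                          ci_high = NA_real_, p_value = NA_real_)
    km <- km_curve(cohort_out, time = "dfi_time", event = "dfi_event")
  }
  km_path <- file.path(out_dir, "km_dfi.csv")
  readr::write_csv(km, km_path, progress = FALSE)

  fits <- list(
    seed = seed,
    threshold = threshold,
    n_patients = nrow(cohort_out),
    n_high_risk = sum(cohort_out$breakpoint_class == "high_risk"),
    logrank = list(statistic = lr$statistic, p_value = lr$p_value),
    cox = list(rr = cox$rr, ci_low = cox$ci_low, ci_high = cox$ci_high,
               p_value = cox$p_value))
  fits_path <- file.path(out_dir, "fits.json")
  jsonlite::write_json(fits, fits_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)

  invisible(list(counts = counts, cohort = cohort_out,
                 injected_counts = tibble::tibble(
                   patient_id = cohort$patient_id, injected = injected),
                 logrank = lr, cox = cox, km = km,
                 paths = c(probes = probes_path, segments = seg_path,
                           counts = counts_path, cohort = cohort_path,
                           km = km_path, fits = fits_path)))
}

#' Plot a segmented chromosome profile
#'
#' @param object A `breakscan_profile` from [segment_tumor()].
#' @param probes The probe tibble the profile was fitted on (for the raw
#'   points); optional.
#' @param ... Unused.
#' @return A ggplot with per-probe signal and fitted segment means.
#' @export
autoplot.breakscan_profile <- function(object, probes = NULL, ...) {
  p <- ggplot2::ggplot()
  if (!is.null(probes)) {
    p <- p + ggplot2::geom_point(
      data = probes,
      ggplot2::aes(x = .data$pos, y = .data$signal),
      size = 0.4, alpha = 0.5)
  }
  p +
    ggplot2::geom_segment(
      data = object$segments,
      ggplot2::aes(x = .data$start_bp, xend = .data$end_bp,
                   y = .data$mean_signal, yend = .data$mean_signal),
      colour = "red", linewidth = 0.8) +
    ggplot2::facet_wrap(~chrom, scales = "free_x") +
    ggplot2::labs(x = "Position (bp)", y = "Log-scale signal",
                  title = sprintf("%s: %d breakpoints (%s)", object$tumor_id,
                                  object$n_breakpoints,
                                  as.character(object$risk_class))) +
    ggplot2::theme_minimal()
}
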