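#' Read a per-probe signal table
#'
#' Reads a delimited text file with columns `tumor_id`, `chrom`, `pos`,
#' `signal` (one row per SNP probe). Within each (tumor, chromosome) track the
#' probes are sorted by ascending position, rows with a non-finite signal are
#' rejected with a warning, and duplicated positions are collapsed to their
#' mean signal with a warning (deterministic and order-independent). Tumor
#' order follows first appearance in the file; chromosomes are ordered
#' 1..22, X, Y.
#'
#' @param path Path to a TSV (default) or CSV file; the delimiter is guessed
#'   from the extension unless `delim` is given.
#' @param delim Optional field delimiter.
#' @return A tibble with columns `tumor_id`, `chrom` (ordered factor), `pos`
#'   (integer), `signal` (double). One ProbeTrack = one (tumor_id, chrom)
#'   group.
#' @export
read_probe_table <- function(path, delim = NULL) {
  delim <- delim %||% if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  raw <- readr::read_delim(
    path, delim = delim, show_col_types = FALSE, progress = FALSE,
    col_types = readr::cols(
      tumor_id = readr::col_character(),
      chrom = readr::col_character(),
      pos = readr::col_double(),
      signal = readr::col_double()))
  need <- c("tumor_id", "chrom", "pos", "signal")
  missing <- setdiff(need, names(raw))
  if (length(missing)) {
    stop("probe table is missing required column(s): ",
         paste(missing, collapse = ", "))
  }
  prob <- readr::problems(raw)
  if (nrow(prob) > 0) {
    stop("unparseable value(s) in probe table at line(s) ",
         paste(unique(prob$row + 1L), collapse = ", "),
         " (file ", path, ")")
  }
  if (nrow(raw) == 0) {
    warning("probe table ", path, " contains a header only")
    return(tibble::tibble(tumor_id = character(), chrom = factor(),
                          pos = integer(), signal = double()))
  }
  bad <- !is.finite(raw$signal) | !is.finite(raw$pos)
  if (any(bad)) {
    warning(sum(bad), " probe row(s) with non-finite values rejected at load")
    raw <- raw[!bad, , drop = FALSE]
  }
  raw$tumor_id <- factor(raw$tumor_id, levels = unique(raw$tumor_id))
  raw$chrom <- chrom_factor(raw$chrom)
  out <- dplyr::arrange(raw, .data$tumor_id, .data$chrom, .data$pos)
  dup <- dplyr::summarise(
    dplyr::group_by(out, .data$tumor_id, .data$chrom, .data$pos),
    n = dplyr::n(), signal = mean(.data$signal), .groups = "drop")
  if (any(dup$n > 1)) {
    warning(sum(dup$n > 1), " duplicated probe position(s) collapsed to ",
            "their mean signal")
  }
  small <- dplyr::count(dup, .data$tumor_id, .data$chrom)
  if (any(small$n < 2)) {
    warning("some (tumor, chromosome) tracks have fewer than 2 probes")
  }
  out <- dplyr::select(dup, "tumor_id", "chrom", "pos", "signal")
  out$tumor_id <- as.character(out$tumor_id)
  out$pos <- as.integer(out$pos)
  out
}

#' Write segments as a BED-like table
#'
#' Writes segment records with BED coordinate conventions: internal probe
#' coordinates are 1-based inclusive base pairs, the output `start` column is
#' 0-based and `end` half-open, so a segment spanning probes at positions
#' 100..500 is written as `start 99, end 500`. Columns: `chrom`, `start`,
#' `end`, `tumor_id`, `mean_signal` (full precision), `n_probes`. Adjacent
#' segments of one chromosome share a boundary (`end[i] == start[i + 1]`).
#'
#' @param profiles A `breakscan_profiles` / `breakscan_profile` object or a
#'   segments tibble as produced by [segment_profiles()].
#' @param path Output path (tab-delimited, with header).
#' @return `path`, invisibly.
#' @export
write_segments <- function(profiles, path) {
  seg <- if (inherits(profiles, c("breakscan_profiles", "breakscan_profile"))) {
    profiles$segments
  } else {
    profiles
  }
  stopifnot(all(c("tumor_id", "chrom", "start_bp", "end_bp", "mean_signal",
                  "n_probes") %in% names(seg)))
  out <- data.frame(
    chrom = as.character(seg$chrom),
    start = format(seg$start_bp - 1, scientific = FALSE, trim = TRUE),
    end = format(seg$end_bp, scientific = FALSE, trim = TRUE),
    tumor_id = seg$tumor_id,
    mean_signal = sprintf("%.17g", seg$mean_signal),
    n_probes = seg$n_probes,
    stringsAsFactors = FALSE)
  con <- tryCatch(suppressWarnings(file(path, "w")), error = function(e) {
    stop("cannot open '", path, "' for writing: ", conditionMessage(e))
  })
  on.exit(close(con))
  writeLines(paste(names(out), collapse = "\t"), con)
  if (nrow(out)) {
    writeLines(do.call(paste, c(unname(out), sep = "\t")), con)
  }
  invisible(path)
}

#' Read a BED-like segment table written by [write_segments()]
#'
#' Restores the internal 1-based inclusive coordinates (`start_bp`,
#' `end_bp`) from the 0-based half-open BED columns.
#'
#' @param path Path to the file.
#' @return A tibble with `tumor_id`, `chrom`, `start_bp`, `end_bp`,
#'   `mean_signal`, `n_probes`.
#' @export
read_segments <- function(path) {
  raw <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                         col_types = "cddcdi")
  tibble::tibble(
    tumor_id = raw$tumor_id,
    chrom = raw$chrom,
    start_bp = as.numeric(raw$start) + 1,
    end_bp = as.numeric(raw$end),
    mean_signal = raw$mean_signal,
    n_probes = raw$n_probes)
}

#' Read and validate a patient cohort table
#'
#' Reads a CSV with one row per patient and columns `patient_id`,
#' `breakpoint_count`, `ki67_fraction`, `ggi`, `grade`, `er10`, `pr10`,
#' `dfi_time`, `dfi_event`, `mfi_time`, `mfi_event`. Rows violating the
#' invariants (negative or zero follow-up time, non-binary event flag,
#' grade outside 1..3, ER/PR outside 0..10, KI67 outside \[0, 1\], negative
#' breakpoint count) are rejected with a per-row warning. Missing values are
#' allowed for `ki67_fraction`, `ggi`, `grade`, `er10`, `pr10` and kept as
#' explicit `NA`, never imputed.
#'
#' @param path Path to the CSV file.
#' @return A validated tibble.
#' @export
read_cohort <- function(path) {
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("patient_id", "breakpoint_count", "ki67_fraction", "ggi",
            "grade", "er10", "pr10", "dfi_time", "dfi_event",
            "mfi_time", "mfi_event")
  missing <- setdiff(need, names(raw))
  if (length(missing)) {
    stop("cohort table is missing required column(s): ",
         paste(missing, collapse = ", "))
  }
  ok_event <- function(x) is.na(x) | x %in% c(0, 1)
  reasons <- list(
    "non-positive or missing follow-up time" =
      !(is.finite(raw$dfi_time) & raw$dfi_time > 0 &
          is.finite(raw$mfi_time) & raw$mfi_time > 0),
    "event flag not 0/1" =
      !(raw$dfi_event %in% c(0, 1) & raw$mfi_event %in% c(0, 1)),
    "negative or non-integer breakpoint count" =
      !(is.finite(raw$breakpoint_count) & raw$breakpoint_count >= 0 &
          raw$breakpoint_count == round(raw$breakpoint_count)),
    "grade outside 1..3" = !(is.na(raw$grade) | raw$grade %in% 1:3),
    "ki67 outside [0, 1]" =
      !(is.na(raw$ki67_fraction) |
          (raw$ki67_fraction >= 0 & raw$ki67_fraction <= 1)),
    "ER/PR outside 0..10" =
      !((is.na(raw$er10) | (raw$er10 >= 0 & raw$er10 <= 10)) &
          (is.na(raw$pr10) | (raw$pr10 >= 0 & raw$pr10 <= 10)))
  )
  bad <- Reduce(`|`, reasons)
  if (any(bad)) {
    msgs <- vapply(which(bad), function(i) {
      why <- names(reasons)[vapply(reasons, `[[`, logical(1), i)]
      paste0("row ", i, ": ", paste(why, collapse = "; "))
    }, character(1))
    warning("rejected ", sum(bad), " cohort row(s):\n  ",
            paste(msgs, collapse = "\n  "))
    raw <- raw[!bad, , drop = FALSE]
  }
  raw$grade <- as.integer(raw$grade)
  tibble::as_tibble(raw)
}

#' Default analysis configuration
#'
#' Returns the segmentation and classifier parameters used across the
#' pipeline, optionally overridden from a YAML file with the same keys.
#'
#' @param path Optional YAML file; keys not present fall back to defaults.
#' @return Named list: `k_max` (NULL = automatic), `penalty_scale` (round-1
#'   outlier screen), `threshold` (breakpoint cut-off), `ki67_rescale`,
#'   `seed`.
#' @export
breakscan_config <- function(path = NULL) {
  cfg <- list(k_max = NULL, penalty_scale = 0.5, threshold = 34L,
              ki67_rescale = 1, seed = 1L)
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    unknown <- setdiff(names(user), names(cfg))
    if (length(unknown)) {
      stop("unknown config key(s): ", paste(unknown, collapse = ", "))
    }
    cfg[names(user)] <- user
  }
  cfg
}
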