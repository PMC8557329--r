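# Section- and subject-level aggregation of fiber records.

#' Empirical cumulative distribution points
#'
#' Right-continuous ECDF of a sample, returned as plottable points: the
#' sorted values with cumulative fractions i/n (ties keep all points; the
#' last fraction is 1).
#'
#' @param values numeric vector, length >= 1.
#' @return data.frame with columns `value` and `frac`.
#' @export
ecdf_points <- function(values) {
  if (length(values) == 0L) stopf("ecdf of an empty sample")
  v <- sort(values)
  data.frame(value = v, frac = seq_along(v) / length(v))
}

#' Summarize a section's fiber records
#'
#' Whole-section metrics at per-fiber granularity: the unweighted mean of
#' per-fiber sarcolemmal intensities, the percentage of dystrophin-positive
#' fibers, the four coverage-bin fractions with their per-bin mean
#' intensities, and the intensity and coverage ECDFs.
#'
#' @param records data.frame of fiber records from [quantify_fibers()].
#' @return object of class `section_summary`.
#' @export
summarize_section <- function(records) {
  if (is.null(records) || nrow(records) == 0L) {
    stopf("cannot summarize a section with no fiber records")
  }
  stopifnot(all(c("mean_intensity_au", "coverage_pct", "positive", "bin")
                %in% names(records)))
  bin_n <- table(factor(records$bin, levels = COVERAGE_BINS))
  bin_fractions <- as.numeric(bin_n) / nrow(records)
  names(bin_fractions) <- COVERAGE_BINS
  bin_mean_intensity <- vapply(COVERAGE_BINS, function(b) {
    sel <- records$bin == b
    if (any(sel)) mean(records$mean_intensity_au[sel]) else NA_real_
  }, numeric(1))
  meta <- attr(records, "meta")
  structure(list(
    n_fibers = nrow(records),
    mean_intensity = mean(records$mean_intensity_au),
    pct_positive = 100 * mean(records$positive),
    bin_fractions = bin_fractions,
    bin_mean_intensity = bin_mean_intensity,
    ecdf_intensity = ecdf_points(records$mean_intensity_au),
    ecdf_coverage = ecdf_points(records$coverage_pct),
    meta = meta), class = "section_summary")
}

#' @export
print.section_summary <- function(x, ...) {
  cat(sprintf("<section_summary> %d fibers | mean intensity %.0f AU | %.1f%% positive\n",
              x$n_fibers, x$mean_intensity, x$pct_positive))
  cat(sprintf("  bin fractions: %s\n",
              paste(sprintf("%s=%.3f", names(x$bin_fractions), x$bin_fractions),
                    collapse = " ")))
  invisible(x)
}

#' Aggregate the two replicate sections of a subject
#'
#' The study design analyzes exactly two serial sections per subject;
#' subject-level values are the mean and sample SD (n-1) across the two
#' replicate section values.
#'
#' @param rep1,rep2 `section_summary` objects of the two serial sections.
#' @param subject_id,phenotype labels carried into the record.
#' @return object of class `subject_record` with `mean_intensity` and
#'   `pct_positive` entries, each `c(mean, sd)`.
#' @export
summarize_subject <- function(rep1, rep2, subject_id = NA, phenotype = NA) {
  if (missing(rep2)) stopf("subject '%s' must have exactly 2 replicate sections",
                           subject_id)
  stopifnot(inherits(rep1, "section_summary"), inherits(rep2, "section_summary"))
  two <- function(a, b) c(mean = mean(c(a, b)), sd = stats::sd(c(a, b)))
  structure(list(
    subject_id = subject_id, phenotype = phenotype,
    replicates = list(rep1, rep2),
    mean_intensity = two(rep1$mean_intensity, rep2$mean_intensity),
    pct_positive = two(rep1$pct_positive, rep2$pct_positive)),
    class = "subject_record")
}

#' @export
print.subject_record <- function(x, ...) {
  cat(sprintf("<subject_record> %s (%s): intensity %.0f +/- %.0f AU, %.1f +/- %.1f %% positive\n",
              x$subject_id, x$phenotype,
              x$mean_intensity["mean"], x$mean_intensity["sd"],
              x$pct_positive["mean"], x$pct_positive["sd"]))
  invisible(x)
}

#' Section summary as a one-row data.frame
#'
#' @param s a `section_summary`.
#' @return one-row data.frame (bin fractions and per-bin intensities as
#'   columns), suitable for CSV export.
#' @export
as.data.frame.section_summary <- function(x, ...) {
  s <- x
  out <- data.frame(n_fibers = s$n_fibers, mean_intensity_au = s$mean_intensity,
                    pct_positive = s$pct_positive)
  for (i in 1:4) {
    out[[paste0("frac_", COVERAGE_BINS[i])]] <- s$bin_fractions[i]
    out[[paste0("mean_intensity_", COVERAGE_BINS[i])]] <- s$bin_mean_intensity[i]
  }
  out
}
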