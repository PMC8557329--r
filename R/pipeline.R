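# Pipeline orchestration: resolved configuration, provenance-logged runs,
# and the batch entry points used by the command line interface.

#' Pipeline configuration
#'
#' All tunables of the quantification pipeline in one serializable object.
#' Every run writes the resolved configuration next to its outputs (JSON),
#' so results are reproducible from the output directory alone.
#'
#' @param dys_channel,lam_channel channel names or 1-based page indices in
#'   the input TIFF.
#' @param min_area minimum fiber interior area, pixels.
#' @param laminin_threshold AU or "auto" (Otsu).
#' @param ring_width sarcolemmal band width, pixels.
#' @param K arc segments per circumference.
#' @param smoothing_w circular majority window, arc segments.
#' @param positivity_threshold AU or "auto" (interstitial mode + 3 MAD).
#' @param seed integer seed for any stochastic step.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(dys_channel = "DYS", lam_channel = "LAMA2",
                            min_area = 100L, laminin_threshold = "auto",
                            ring_width = 3L, K = 360L, smoothing_w = 3L,
                            positivity_threshold = "auto", seed = 1L) {
  if (!identical(laminin_threshold, "auto")) {
    laminin_threshold <- as.numeric(laminin_threshold)
  }
  if (!identical(positivity_threshold, "auto")) {
    positivity_threshold <- as.numeric(positivity_threshold)
  }
  cfg <- list(dys_channel = dys_channel, lam_channel = lam_channel,
              min_area = as.integer(min_area),
              laminin_threshold = laminin_threshold,
              ring_width = as.integer(ring_width), K = as.integer(K),
              smoothing_w = as.integer(smoothing_w),
              positivity_threshold = positivity_threshold,
              seed = as.integer(seed))
  if (cfg$min_area < 1L || cfg$ring_width < 1L || cfg$K < 4L) {
    stopf("invalid pipeline configuration (min_area/ring_width/K)")
  }
  structure(cfg, class = "pipeline_config")
}

#' Write / read a pipeline configuration as JSON
#' @param config a `pipeline_config`.
#' @param path JSON file path.
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(pipeline_config, raw)
}

#' Quantify one section image end to end
#'
#' Reads the two-channel TIFF, segments fibers, measures per-fiber metrics,
#' and writes `fibers.csv`, `summary.csv`, ECDF curves, the resolved
#' configuration and a provenance log to `out_dir`. Outputs are
#' deterministic given image + configuration.
#'
#' @param image_path multi-channel TIFF path, or a `section_image`.
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if needed); `NULL` skips writing.
#' @return list with `records` (per-fiber data.frame) and `summary`
#'   (`section_summary`), invisibly when writing.
#' @export
run_quantify <- function(image_path, config = pipeline_config(),
                         out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (inherits(image_path, "section_image")) {
    image <- image_path
    source_id <- "<in-memory section_image>"
    checksum <- NA_character_
  } else {
    if (!file.exists(image_path)) stopf("image file not found: %s", image_path)
    image <- read_section_tiff(image_path, config$dys_channel,
                               config$lam_channel)
    source_id <- image_path
    checksum <- unname(tools::md5sum(image_path))
  }
  records <- quantify_fibers(image,
                             min_area = config$min_area,
                             laminin_threshold = config$laminin_threshold,
                             ring_width = config$ring_width, K = config$K,
                             positivity_threshold = config$positivity_threshold,
                             w = config$smoothing_w)
  summary <- summarize_section(records)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_csv(format_fiber_csv(records), file.path(out_dir, "fibers.csv"))
    write_csv(as.data.frame(summary), file.path(out_dir, "summary.csv"))
    write_csv(summary$ecdf_intensity, file.path(out_dir, "ecdf_intensity.csv"))
    write_csv(summary$ecdf_coverage, file.path(out_dir, "ecdf_coverage.csv"))
    write_config(config, file.path(out_dir, "config.json"))
    meta <- attr(records, "meta")
    log_lines <- c(
      sprintf("input: %s", source_id),
      sprintf("md5: %s", checksum),
      sprintf("n_fibers: %d", nrow(records)),
      sprintf("excluded_border: %d", meta$n_excluded_border),
      sprintf("excluded_small: %d", meta$n_excluded_small),
      sprintf("laminin_threshold: %.4f", meta$laminin_threshold),
      sprintf("positivity_threshold: %.4f", meta$positivity_threshold),
      sprintf("whole_fiber_flags: %d", meta$whole_fiber_flags))
    writeLines(log_lines, file.path(out_dir, "run.log"))
    return(invisible(list(records = records, summary = summary)))
  }
  list(records = records, summary = summary)
}

format_fiber_csv <- function(records) {
  data.frame(fiber_id = records$fiber_id,
             cx = round(records$cx, 3), cy = round(records$cy, 3),
             area_px = records$area_px,
             mean_intensity_au = round(records$mean_intensity_au, 3),
             coverage_pct = round(records$coverage_pct, 3),
             positive = records$positive,
             bin = as.character(records$bin))
}

# fixed CSV dialect: UTF-8, comma, "." decimal, header, no quotes for
# numerics -- keeps reruns byte-stable
write_csv <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Run a subject manifest through the cohort pipeline
#'
#' The manifest has one row per replicate section: columns `subject_id`,
#' `phenotype`, `path` (section TIFF). Every subject must have exactly two
#' replicate rows (the study design: two serial sections per sample).
#' Writes a subject table (Table-2 style: per-subject mean +/- SD) and,
#' when two or more phenotype groups are present, a pairwise comparison
#' table (Table-3 style: group means +/- SD, U, exact p) computed on
#' replicate-level values.
#'
#' @param manifest data.frame or CSV path.
#' @param config a [pipeline_config()].
#' @param out_dir output directory, or `NULL` to skip writing.
#' @return list with `subjects` (data.frame), `comparisons` (data.frame or
#'   NULL), and `summaries` (per-replicate `section_summary` list).
#' @export
run_cohort <- function(manifest, config = pipeline_config(), out_dir = NULL) {
  if (is.character(manifest)) manifest <- utils::read.csv(manifest)
  need <- c("subject_id", "phenotype", "path")
  if (!all(need %in% names(manifest))) {
    stopf("manifest must have columns: %s", paste(need, collapse = ", "))
  }
  manifest <- manifest[order(manifest$subject_id, manifest$path), , drop = FALSE]
  counts <- table(manifest$subject_id)
  bad <- names(counts)[counts != 2L]
  if (length(bad) > 0L) {
    stopf("subjects without exactly 2 replicate sections: %s",
          paste(bad, collapse = ", "))
  }
  summaries <- list()
  subject_rows <- list()
  replicate_rows <- list()
  for (sid in names(counts)) {
    rows <- manifest[manifest$subject_id == sid, ]
    reps <- lapply(rows$path, function(p) run_quantify(p, config)$summary)
    summaries[[sid]] <- reps
    rec <- summarize_subject(reps[[1]], reps[[2]], subject_id = sid,
                             phenotype = rows$phenotype[1])
    subject_rows[[sid]] <- subjects_as_table(list(rec))
    replicate_rows[[sid]] <- data.frame(
      subject_id = sid, phenotype = rows$phenotype[1], replicate = 1:2,
      mean_intensity_au = vapply(reps, `[[`, numeric(1), "mean_intensity"),
      pct_positive = vapply(reps, `[[`, numeric(1), "pct_positive"))
  }
  subjects <- do.call(rbind, subject_rows)
  rownames(subjects) <- NULL
  replicates <- do.call(rbind, replicate_rows)
  rownames(replicates) <- NULL
  comparisons <- NULL
  groups <- unique(subjects$phenotype)
  if (length(groups) >= 2L) {
    pairs <- utils::combn(sort(groups), 2L, simplify = FALSE)
    comparisons <- do.call(rbind, lapply(pairs, function(pr) {
      do.call(rbind, lapply(c("mean_intensity_au", "pct_positive"), function(m) {
        xs <- replicates[[m]][replicates$phenotype == pr[1]]
        ys <- replicates[[m]][replicates$phenotype == pr[2]]
        mw <- exact_mann_whitney(xs, ys)
        data.frame(group1 = pr[1], group2 = pr[2], metric = m,
                   n1 = mw$n1, n2 = mw$n2,
                   mean1 = mean(xs), sd1 = stats::sd(xs),
                   mean2 = mean(ys), sd2 = stats::sd(ys),
                   U = mw$U, p = mw$p, method = mw$method)
      }))
    }))
    rownames(comparisons) <- NULL
  } else {
    message("single phenotype group: comparison table skipped")
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_csv(subjects, file.path(out_dir, "subjects.csv"))
    write_csv(replicates, file.path(out_dir, "replicates.csv"))
    if (!is.null(comparisons)) {
      write_csv(comparisons, file.path(out_dir, "comparisons.csv"))
    }
    write_config(config, file.path(out_dir, "config.json"))
  }
  list(subjects = subjects, replicates = replicates,
       comparisons = comparisons, summaries = summaries)
}
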