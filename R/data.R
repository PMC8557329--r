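#' Published cohort reference table
#'
#' Per-subject dystrophin results of the 14-patient dystrophinopathy cohort
#' plus the pediatric control average: mean sarcolemmal dystrophin intensity
#' (AU, mean of 2 replicate sections +/- SD), percentage of
#' dystrophin-positive fibers, and Western-blot percent of control where a
#' blot was run (`NA` = not done). These printed values are inputs for the
#' cohort arithmetic (group means, correlations, replicate reconstruction);
#' the underlying biopsy images are not public.
#'
#' @param include_control keep the CTRL row (default TRUE).
#' @return data.frame with columns subject_id, phenotype,
#'   mean_intensity_au, intensity_sd, pct_positive, pct_positive_sd,
#'   wb_pct_of_ctrl.
#' @export
cohort_reference <- function(include_control = TRUE) {
  path <- system.file("extdata", "cohort_dystrophin.csv", package = "dysquant",
                      mustWork = TRUE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!include_control) tab <- tab[tab$phenotype != "CTRL", , drop = FALSE]
  tab
}

#' Reconstruct replicate-level values from a mean and SD of two replicates
#'
#' With exactly two replicates a and b, mean m and sample SD s determine the
#' pair up to order: a, b = m +/- s / sqrt(2). Used to recover the
#' replicate-level values on which the cohort's rank tests operate from the
#' published per-subject summaries.
#'
#' @param mean,sd per-subject mean and sample SD of the two replicates.
#' @return 2-column matrix of replicate values.
#' @export
replicates_from_mean_sd <- function(mean, sd) {
  cbind(rep1 = mean - sd / sqrt(2), rep2 = mean + sd / sqrt(2))
}
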