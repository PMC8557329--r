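# Western-blot quantification bookkeeping: dystrophin band intensity
# normalized to the alpha-actinin loading control, expressed as percent of
# control, averaged over technical repeats.

#' Normalize one lane to percent of control
#'
#' `100 * (dystrophin_band / actinin_band) / control_ratio`, where
#' `control_ratio` is the mean dystrophin/actinin ratio of the control lanes
#' on the same blot.
#'
#' @param dystrophin_band,actinin_band band intensities in AU (vectors
#'   allowed; actinin must be > 0).
#' @param control_ratio mean control dystrophin/actinin ratio (> 0).
#' @return percent of control.
#' @export
normalize_lane <- function(dystrophin_band, actinin_band, control_ratio) {
  if (any(actinin_band <= 0)) stopf("actinin band intensity must be > 0")
  if (any(dystrophin_band < 0)) stopf("band intensities must be >= 0")
  if (length(control_ratio) != 1L || control_ratio <= 0) {
    stopf("control_ratio must be a single value > 0")
  }
  100 * (dystrophin_band / actinin_band) / control_ratio
}

#' Summarize a blot's lane table into per-sample percent of control
#'
#' @param lanes data.frame with columns `sample_id`, `repeat_index`,
#'   `dys_au`, `actinin_au`, `is_control` (logical or 0/1).
#' @return data.frame: sample_id, pct_of_control_mean, pct_sd, n_repeats,
#'   not_detected (TRUE when every repeat's dystrophin band is 0).
#' @export
summarize_wb <- function(lanes) {
  need <- c("sample_id", "repeat_index", "dys_au", "actinin_au", "is_control")
  if (!all(need %in% names(lanes))) {
    stopf("lane table must have columns: %s", paste(need, collapse = ", "))
  }
  ctrl <- lanes[as.logical(lanes$is_control), ]
  if (nrow(ctrl) == 0L) stopf("no control lanes on the blot")
  control_ratio <- mean(ctrl$dys_au / ctrl$actinin_au)
  pct <- normalize_lane(lanes$dys_au, lanes$actinin_au, control_ratio)
  groups <- split(seq_len(nrow(lanes)), lanes$sample_id)
  out <- do.call(rbind, lapply(names(groups), function(id) {
    i <- groups[[id]]
    data.frame(sample_id = id,
               pct_of_control_mean = mean(pct[i]),
               pct_sd = if (length(i) > 1) stats::sd(pct[i]) else 0,
               n_repeats = length(i),
               not_detected = all(lanes$dys_au[i] == 0))
  }))
  rownames(out) <- NULL
  out[order(out$sample_id), , drop = FALSE]
}
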