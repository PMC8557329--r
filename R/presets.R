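#' Phenotype presets for the section simulator
#'
#' Each preset states the coverage-bin composition and the sarcolemmal
#' dystrophin intensity law of one clinical phenotype, on the 16-bit
#' acquisition scale (0--65535 AU). Bin fractions refer to the four
#' circumference-coverage classes \[0,25), \[25,50), \[50,75), \[75,100\]
#' and must sum to 1.
#'
#' Compositions follow the published group profiles: controls have
#' essentially all fibers in the 75--100\% class at ~50,387 AU; Duchenne
#' (DMD) sections split roughly 52/30/12/6\% across the four classes at
#' ~11,947 AU; mild Becker (BMD) sections keep ~85\% of fibers in the top
#' class at ~28,477 AU but reduced intensity; the two severe-BMD patterns
#' bracket the mild-BMD-like and DMD-like extremes; intermediate (IMD)
#' follows the majority (mild-like) pattern at ~18,319 AU.
#'
#' @param name one of `"CTRL"`, `"mildBMD"`, `"severeBMD-like-mild"`,
#'   `"severeBMD-like-DMD"`, `"IMD"`, `"DMD"`.
#' @param bin_fractions,intensity_mean,intensity_cv optional overrides of the
#'   named preset's fields.
#' @return an object of class `phenotype_preset` with fields `name`,
#'   `bin_fractions` (length 4, sums to 1), `intensity_mean` (AU) and
#'   `intensity_cv` (unitless coefficient of variation of the per-fiber
#'   intensity law).
#' @export
#' @examples
#' phenotype_preset("DMD")$bin_fractions
phenotype_preset <- function(name, bin_fractions = NULL,
                             intensity_mean = NULL, intensity_cv = NULL) {
  presets <- list(
    CTRL = list(bin_fractions = c(0, 0, 0, 1),
                intensity_mean = 50387),
    mildBMD = list(bin_fractions = c(0.01, 0.05, 0.09, 0.85),
                   intensity_mean = 28477),
    `severeBMD-like-mild` = list(bin_fractions = c(0, 0.01, 0.01, 0.98),
                                 intensity_mean = 30798),
    `severeBMD-like-DMD` = list(bin_fractions = c(19, 24, 27, 32) / 102,
                                intensity_mean = 13657),
    IMD = list(bin_fractions = c(0.015, 0.05, 0.075, 0.86),
               intensity_mean = 18319),
    DMD = list(bin_fractions = c(0.52, 0.30, 0.12, 0.06),
               intensity_mean = 11947)
  )
  if (!name %in% names(presets)) {
    stopf("unknown phenotype preset '%s' (choose one of: %s)",
          name, paste(names(presets), collapse = ", "))
  }
  p <- presets[[name]]
  p$name <- name
  p$intensity_cv <- 0.2
  if (!is.null(bin_fractions)) p$bin_fractions <- bin_fractions
  if (!is.null(intensity_mean)) p$intensity_mean <- intensity_mean
  if (!is.null(intensity_cv)) p$intensity_cv <- intensity_cv
  validate_preset(p)
  structure(p, class = "phenotype_preset")
}

validate_preset <- function(p) {
  stopifnot(length(p$bin_fractions) == 4, all(p$bin_fractions >= 0))
  if (abs(sum(p$bin_fractions) - 1) > 1e-9) {
    stopf("preset bin_fractions must sum to 1 (got %.12f)", sum(p$bin_fractions))
  }
  if (p$intensity_mean < 0 || p$intensity_mean > MAX_AU) {
    stopf("preset intensity_mean must lie in [0, %d] AU", MAX_AU)
  }
  if (p$intensity_cv < 0) stopf("preset intensity_cv must be >= 0")
  invisible(p)
}

#' @export
print.phenotype_preset <- function(x, ...) {
  cat(sprintf("<phenotype_preset> %s\n", x$name))
  cat(sprintf("  bin fractions [0,25)/[25,50)/[50,75)/[75,100]: %s\n",
              paste(signif(x$bin_fractions, 3), collapse = " / ")))
  cat(sprintf("  intensity: %.0f AU (CV %.2f)\n", x$intensity_mean, x$intensity_cv))
  invisible(x)
}
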