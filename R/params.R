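#' Classification parameters
#'
#' Bundles the tunable constants of the specificity classification.
#'
#' @param detection_cutoff FPKM level at or above which a gene counts as
#'   detected (expressed) in a tissue. Default 1 FPKM, roughly one mRNA
#'   molecule per average cell.
#' @param fold_factor Fold-change required by the enriched, group-enriched
#'   and enhanced rules. Default 5. Comparisons are non-strict (`>=`), so a
#'   gene exactly at 5-fold qualifies.
#' @param group_min,group_max Allowed size range of an enriched group of
#'   tissues (target included). Defaults 2 and 7.
#' @param ts_floor Floor applied to the denominator of the TS score so that
#'   genes expressed nowhere else still get a finite score. Default 0.1 FPKM.
#' @param enhanced_baseline Whether the tissue-enhanced rule compares the
#'   target against the mean FPKM of `"all_tissues"` (default, target
#'   included) or of the `"other_tissues"` only. The two readings differ
#'   slightly; both are supported.
#'
#' @return A list of class `classification_params`.
#' @examples
#' classification_params()
#' classification_params(fold_factor = 4, enhanced_baseline = "other_tissues")
#' @export
classification_params <- function(detection_cutoff = 1,
                                  fold_factor = 5,
                                  group_min = 2L,
                                  group_max = 7L,
                                  ts_floor = 0.1,
                                  enhanced_baseline = c("all_tissues", "other_tissues")) {
  enhanced_baseline <- match.arg(enhanced_baseline)
  if (!is.numeric(detection_cutoff) || length(detection_cutoff) != 1 ||
      !is.finite(detection_cutoff) || detection_cutoff <= 0) {
    abort_config("`detection_cutoff` must be a single positive number.")
  }
  if (!is.numeric(fold_factor) || length(fold_factor) != 1 ||
      !is.finite(fold_factor) || fold_factor <= 1) {
    abort_config("`fold_factor` must be a single number > 1.")
  }
  group_min <- as.integer(group_min)
  group_max <- as.integer(group_max)
  if (is.na(group_min) || is.na(group_max) || group_min < 2L ||
      group_min > group_max) {
    abort_config("Need 2 <= `group_min` <= `group_max`.")
  }
  if (!is.numeric(ts_floor) || length(ts_floor) != 1 ||
      !is.finite(ts_floor) || ts_floor <= 0) {
    abort_config("`ts_floor` must be a single positive number.")
  }
  structure(
    list(
      detection_cutoff = detection_cutoff,
      fold_factor = fold_factor,
      group_min = group_min,
      group_max = group_max,
      ts_floor = ts_floor,
      enhanced_baseline = enhanced_baseline
    ),
    class = "classification_params"
  )
}

#' @export
print.classification_params <- function(x, ...) {
  cat("<classification_params>\n")
  cat("  detection cutoff :", x$detection_cutoff, "FPKM\n")
  cat("  fold factor      :", x$fold_factor, "\n")
  cat("  group size       :", x$group_min, "-", x$group_max, "\n")
  cat("  TS denominator floor:", x$ts_floor, "FPKM\n")
  cat("  enhanced baseline:", x$enhanced_baseline, "\n")
  invisible(x)
}

as_classification_params <- function(params) {
  if (inherits(params, "classification_params")) {
    return(params)
  }
  if (is.list(params)) {
    return(do.call(classification_params, params))
  }
  abort_config("`params` must be a classification_params object or a list.")
}
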