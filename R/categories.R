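#' Expression-specificity categories
#'
#' The seven mutually exclusive categories a gene can receive relative to a
#' target tissue, in precedence order: `tissue_enriched` (>= fold_factor
#' times every other tissue), `group_enriched` (group of tissues including
#' the target whose mean is >= fold_factor times every outside tissue),
#' `tissue_enhanced` (>= fold_factor times the baseline mean),
#' `expressed_in_all`, `mixed`, `not_detected_target` and
#' `not_detected_any`. The first three together form the "elevated" set.
#'
#' @return `spec_categories()`: character vector of the seven category names.
#'   `elevated_categories()`: the three elevated ones.
#' @export
spec_categories <- function() {
  c(
    "tissue_enriched", "group_enriched", "tissue_enhanced",
    "expressed_in_all", "mixed", "not_detected_target", "not_detected_any"
  )
}

#' @rdname spec_categories
#' @export
elevated_categories <- function() {
  c("tissue_enriched", "group_enriched", "tissue_enhanced")
}

# Broad (pie-chart level) category for each detailed category.
broad_category <- function(category) {
  category <- as.character(category)
  ifelse(category %in% elevated_categories(), "elevated", category)
}

category_factor <- function(x) {
  factor(as.character(x), levels = spec_categories())
}
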