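#' Tidy and summarise classification results
#'
#' `tidy()` returns the per-gene classification as a plain tibble with the
#' tissue group flattened to a semicolon-joined string; `glance()` returns a
#' one-row summary with the gene total, one column per category count and
#' the elevated total.
#'
#' @param x A `gene_classification` tibble from [classify_specificity()].
#' @param ... Unused.
#' @return A tibble.
#' @method tidy gene_classification
#' @export
tidy.gene_classification <- function(x, ...) {
  tibble(
    gene_id = x$gene_id,
    category = as.character(x$category),
    group_tissues = vapply(
      x$group_tissues,
      function(g) paste(sort(g %||% character()), collapse = ";"),
      character(1)
    ),
    target_fpkm = x$target_fpkm,
    ts_score = x$ts_score
  )
}

#' @rdname tidy.gene_classification
#' @method glance gene_classification
#' @export
glance.gene_classification <- function(x, ...) {
  counts <- category_counts(x)
  wide <- as.list(counts$n)
  names(wide) <- as.character(counts$category)
  tibble(
    target = attr(x, "target") %||% NA_character_,
    n_genes = nrow(x),
    !!!wide,
    elevated_total = elevated_total(counts)
  )
}
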