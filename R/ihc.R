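#' Immunohistochemistry compartment vocabulary
#'
#' Urothelial staining patterns used for compartment annotation:
#' `whole_urothelium` (all cell layers), `umbrella` (superficial umbrella
#' cells only), `intermediate_basal` (intermediate/basal layers), `other`
#' (present but not localised to one of those patterns) and `not_analyzed`
#' (no antibody data).
#'
#' @return Character vector of the five compartment labels.
#' @export
ihc_compartments <- function() {
  c("whole_urothelium", "umbrella", "intermediate_basal", "other", "not_analyzed")
}

#' Bin a fraction of positive cells into the 0-3 IHC score
#'
#' Manual IHC scoring reports the fraction of positively stained cells on a
#' four-level scale: 0 for 0-1%, 1 for 2-25%, 2 for 26-75%, 3 for >75%.
#' Non-integer percentages fall in the half-open intervals (1,25], (25,75]
#' and (75,100], which keeps the binning total and monotone while agreeing
#' with the integer anchors.
#'
#' @param percent_positive Percentage(s) of positive cells in [0, 100].
#' @return Integer bin(s) in 0-3.
#' @examples
#' fraction_to_bin(c(0.5, 2, 50, 75, 75.0001))
#' @export
fraction_to_bin <- function(percent_positive) {
  if (!is.numeric(percent_positive) || anyNA(percent_positive) ||
      any(percent_positive < 0 | percent_positive > 100)) {
    abort_value("`percent_positive` must be numeric in [0, 100].")
  }
  as.integer(
    (percent_positive > 1) + (percent_positive > 25) + (percent_positive > 75)
  )
}

#' Read IHC annotations from TSV
#'
#' Expects columns `gene_id`, `antibody_id`, `compartment` (one of
#' [ihc_compartments()]), `fraction_bin` and `intensity` (integers 0-3,
#' empty for `not_analyzed` rows).
#'
#' @param path Annotation TSV path.
#' @return Tibble of validated annotations.
#' @export
read_ihc_annotations <- function(path) {
  ann <- readr::read_tsv(
    path,
    col_types = readr::cols(
      gene_id = readr::col_character(),
      antibody_id = readr::col_character(),
      compartment = readr::col_character(),
      fraction_bin = readr::col_integer(),
      intensity = readr::col_integer()
    ),
    show_col_types = FALSE, progress = FALSE
  )
  validate_ihc(ann)
}

validate_ihc <- function(ann) {
  required <- c("gene_id", "antibody_id", "compartment", "fraction_bin", "intensity")
  if (!all(required %in% names(ann))) {
    abort_format(paste0(
      "IHC annotations need columns: ", paste(required, collapse = ", ")
    ))
  }
  bad <- !ann$compartment %in% ihc_compartments()
  if (any(bad)) {
    abort_value(paste0(
      "Unknown compartment label(s): ",
      paste(unique(ann$compartment[bad]), collapse = ", ")
    ))
  }
  scored <- ann$compartment != "not_analyzed"
  ok_score <- function(v) is.na(v) | (v %in% 0:3)
  if (any(!ok_score(ann$fraction_bin)) || any(!ok_score(ann$intensity))) {
    abort_value("`fraction_bin` and `intensity` must be integers in 0-3.")
  }
  if (any(!scored & (!is.na(ann$fraction_bin) | !is.na(ann$intensity)))) {
    abort_value("`not_analyzed` rows must not carry fraction or intensity scores.")
  }
  as_tibble(ann)
}

# One consensus compartment per gene. Conflicting compartments are an error
# unless consensus = "max_staining", which keeps the most strongly stained
# annotation (highest intensity, then highest fraction bin, then the first
# compartment in vocabulary order as a deterministic tie-break).
ihc_consensus <- function(annotations, consensus = c("error", "max_staining")) {
  consensus <- match.arg(consensus)
  annotations <- validate_ihc(annotations)
  split_rows <- split(seq_len(nrow(annotations)), annotations$gene_id)
  pick <- vapply(split_rows, function(idx) {
    comps <- unique(annotations$compartment[idx])
    if (length(comps) == 1) {
      return(idx[1])
    }
    if (consensus == "error") {
      abort_consistency(paste0(
        "Conflicting compartments for gene '",
        annotations$gene_id[idx[1]], "': ", paste(comps, collapse = ", "),
        ". Set consensus = \"max_staining\" to resolve."
      ))
    }
    o <- order(
      -replace(annotations$intensity[idx], is.na(annotations$intensity[idx]), -1L),
      -replace(annotations$fraction_bin[idx], is.na(annotations$fraction_bin[idx]), -1L),
      match(annotations$compartment[idx], ihc_compartments())
    )
    idx[o[1]]
  }, integer(1))
  annotations[pick, c("gene_id", "compartment"), drop = FALSE]
}

#' Count elevated genes per urothelial compartment
#'
#' Tallies a consensus compartment for each elevated gene; elevated genes
#' with no annotation are counted as `not_analyzed`. Counts always sum to
#' the number of elevated genes.
#'
#' @param annotations IHC annotation tibble ([read_ihc_annotations()]).
#' @param elevated_genes Character vector of elevated gene ids.
#' @param consensus How to resolve conflicting compartments for one gene:
#'   `"error"` (default) or `"max_staining"`.
#' @return Tibble with columns `compartment`, `n` (all five compartments,
#'   zero-filled).
#' @export
compartment_counts <- function(annotations, elevated_genes,
                               consensus = c("error", "max_staining")) {
  cons <- ihc_consensus(annotations, consensus)
  elevated_genes <- unique(as.character(elevated_genes))
  comp <- cons$compartment[match(elevated_genes, cons$gene_id)]
  comp[is.na(comp)] <- "not_analyzed"
  tibble(
    compartment = ihc_compartments(),
    n = as.integer(table(factor(comp, levels = ihc_compartments())))
  )
}

#' Transcript-protein concordance report for elevated genes
#'
#' Joins the elevated genes of a classification with their consensus IHC
#' compartment: per gene the category, TS score, compartment and whether
#' antibody data exist. The analyzed / not-analyzed split is attached and
#' available through [glance()].
#'
#' @param rows Classification tibble.
#' @param annotations IHC annotation tibble.
#' @inheritParams compartment_counts
#' @return Tibble of class `ihc_concordance` with columns `gene_id`,
#'   `category`, `ts_score`, `compartment`, `analyzed`.
#' @export
concordance_report <- function(rows, annotations,
                               consensus = c("error", "max_staining")) {
  elev <- rows[as.character(rows$category) %in% elevated_categories(), , drop = FALSE]
  cons <- ihc_consensus(annotations, consensus)
  comp <- cons$compartment[match(elev$gene_id, cons$gene_id)]
  comp[is.na(comp)] <- "not_analyzed"
  out <- tibble(
    gene_id = elev$gene_id,
    category = as.character(elev$category),
    ts_score = elev$ts_score,
    compartment = comp,
    analyzed = comp != "not_analyzed"
  )
  structure(
    out,
    n_analyzed = sum(out$analyzed),
    n_not_analyzed = sum(!out$analyzed),
    class = c("ihc_concordance", class(tibble()))
  )
}

#' @method glance ihc_concordance
#' @export
glance.ihc_concordance <- function(x, ...) {
  tibble(
    n_elevated = nrow(x),
    n_analyzed = attr(x, "n_analyzed"),
    n_not_analyzed = attr(x, "n_not_analyzed")
  )
}
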