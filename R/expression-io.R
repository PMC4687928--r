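#' Construct a replicate-level FPKM matrix
#'
#' An `fpkm_matrix` is a wide tibble — one `gene_id` column followed by one
#' numeric column per sample — carrying the sample-to-tissue assignment as
#' metadata. All values must be finite, non-negative FPKM; missing values are
#' not permitted (an absent measurement must be encoded as an explicit 0 by
#' the producer).
#'
#' @param values A data frame whose first column holds unique gene
#'   identifiers and whose remaining columns hold non-negative FPKM values,
#'   one column per sample.
#' @param samples Sample metadata: either a two-column data frame
#'   (`sample_id`, `tissue`) or a named character vector mapping sample id
#'   to tissue. Every sample column of `values` must be mapped; map entries
#'   without a matching column are dropped with a warning.
#'
#' @return A tibble of class `fpkm_matrix`. `sample_info()` returns its
#'   sample-to-tissue table.
#' @examples
#' m <- fpkm_matrix(
#'   data.frame(gene_id = c("g1", "g2"), s1 = c(10, 0), s2 = c(30, 2)),
#'   c(s1 = "bladder", s2 = "bladder")
#' )
#' sample_info(m)
#' @export
fpkm_matrix <- function(values, samples) {
  if (!is.data.frame(values) || ncol(values) < 2) {
    abort_format("`values` must be a data frame with a gene id column and at least one sample column.")
  }
  values <- as_tibble(values, .name_repair = "minimal")
  names(values)[1] <- "gene_id"
  gene_ids <- as.character(values$gene_id)
  if (anyDuplicated(gene_ids)) {
    abort_format(paste0(
      "Duplicate gene ids: ",
      paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", ")
    ))
  }
  sample_ids <- names(values)[-1]
  if (anyDuplicated(sample_ids)) {
    abort_format(paste0(
      "Duplicate sample ids: ",
      paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", ")
    ))
  }

  for (s in sample_ids) {
    v <- values[[s]]
    if (!is.numeric(v)) {
      abort_value(paste0("Sample column '", s, "' is not numeric."))
    }
    if (anyNA(v) || any(!is.finite(v))) {
      abort_value(paste0("Sample column '", s, "' contains missing or non-finite FPKM values."))
    }
    if (any(v < 0)) {
      abort_value(paste0("Sample column '", s, "' contains negative FPKM values."))
    }
  }

  samples <- as_sample_table(samples)
  if (anyDuplicated(samples$sample_id)) {
    abort_format("Duplicate sample ids in the sample map.")
  }
  unmapped <- setdiff(sample_ids, samples$sample_id)
  if (length(unmapped) > 0) {
    abort_metadata(paste0(
      "Samples present in the matrix but missing from the sample map: ",
      paste(unmapped, collapse = ", ")
    ))
  }
  extra <- setdiff(samples$sample_id, sample_ids)
  if (length(extra) > 0) {
    warn(paste0(
      "Ignoring sample-map entries with no matrix column: ",
      paste(extra, collapse = ", ")
    ))
  }
  samples <- samples[match(sample_ids, samples$sample_id), , drop = FALSE]

  values$gene_id <- gene_ids
  structure(
    values,
    samples = samples,
    class = c("fpkm_matrix", class(tibble()))
  )
}

as_sample_table <- function(samples) {
  if (is.data.frame(samples)) {
    if (!all(c("sample_id", "tissue") %in% names(samples))) {
      abort_format("Sample metadata must have columns `sample_id` and `tissue`.")
    }
    return(tibble(
      sample_id = as.character(samples$sample_id),
      tissue = as.character(samples$tissue)
    ))
  }
  if (is.character(samples) && !is.null(names(samples))) {
    return(tibble(sample_id = names(samples), tissue = unname(samples)))
  }
  abort_format("`samples` must be a data frame (sample_id, tissue) or a named character vector.")
}

#' @rdname fpkm_matrix
#' @param x An `fpkm_matrix`.
#' @export
sample_info <- function(x) {
  s <- attr(x, "samples")
  if (is.null(s)) {
    abort_metadata("Object carries no sample-to-tissue metadata; pass `samples` explicitly.")
  }
  s
}

#' Read an FPKM matrix and its sample map from TSV files
#'
#' The matrix file is tab-separated with a header row of sample identifiers
#' and a first column of gene identifiers (first header cell `gene_id`); the
#' sample map is a two-column TSV with header `sample_id`, `tissue`. UTF-8,
#' `.` decimal separator, no quoting.
#'
#' @param matrix_path Path to the FPKM matrix TSV.
#' @param sample_map_path Path to the sample map TSV.
#' @return An [fpkm_matrix()].
#' @export
read_fpkm_matrix <- function(matrix_path, sample_map_path) {
  raw <- readr::read_tsv(
    matrix_path,
    col_types = readr::cols(.default = readr::col_character()),
    name_repair = "minimal", show_col_types = FALSE, progress = FALSE
  )
  if (ncol(raw) < 2) {
    abort_format("FPKM matrix must have a gene id column and at least one sample column.")
  }
  parsed <- raw[1]
  for (j in seq(2, ncol(raw))) {
    chr <- raw[[j]]
    num <- suppressWarnings(as.numeric(chr))
    bad <- is.na(num) | is.na(chr)
    if (any(bad)) {
      abort_value(paste0(
        "Non-numeric or missing FPKM in column '", names(raw)[j], "' (e.g. '",
        chr[which(bad)[1]], "')."
      ))
    }
    parsed[[names(raw)[j]]] <- num
  }

  map <- readr::read_tsv(
    sample_map_path,
    col_types = readr::cols(.default = readr::col_character()),
    show_col_types = FALSE, progress = FALSE
  )
  if (!all(c("sample_id", "tissue") %in% names(map))) {
    abort_format("Sample map must be a TSV with header columns `sample_id` and `tissue`.")
  }

  fpkm_matrix(parsed, map)
}

#' Write an FPKM matrix (and optionally its sample map) to TSV
#'
#' @param x An [fpkm_matrix()].
#' @param matrix_path Output path for the matrix TSV.
#' @param samples_path Optional output path for the sample map TSV.
#' @return `x`, invisibly.
#' @export
write_fpkm_matrix <- function(x, matrix_path, samples_path = NULL) {
  readr::write_tsv(as_tibble(as.data.frame(x)), matrix_path, progress = FALSE)
  if (!is.null(samples_path)) {
    readr::write_tsv(sample_info(x), samples_path, progress = FALSE)
  }
  invisible(x)
}

#' Average replicate samples into per-tissue mean FPKM profiles
#'
#' Replicates are averaged arithmetically on the FPKM scale. The result is a
#' tissue profile tibble: `gene_id` plus one column per tissue, tissues in
#' lexicographic order, genes in input order.
#'
#' @param x An [fpkm_matrix()], or any wide data frame (`gene_id` + sample
#'   columns) if `samples` is given.
#' @param samples Optional sample-to-tissue table overriding the metadata
#'   attached to `x`.
#' @return A tibble with one mean-FPKM column per tissue.
#' @examples
#' m <- fpkm_matrix(
#'   data.frame(gene_id = "g1", b1 = 10, b2 = 30, t1 = 5),
#'   c(b1 = "bladder", b2 = "bladder", t1 = "testis")
#' )
#' average_by_tissue(m)
#' @export
average_by_tissue <- function(x, samples = NULL) {
  samples <- if (is.null(samples)) sample_info(x) else as_sample_table(samples)
  sample_ids <- setdiff(names(x), "gene_id")
  samples <- samples[samples$sample_id %in% sample_ids, , drop = FALSE]
  if (!setequal(samples$sample_id, sample_ids)) {
    abort_metadata("Every sample column must have a tissue assignment.")
  }
  m <- as.matrix(as.data.frame(x)[, samples$sample_id, drop = FALSE])
  tissues <- sort(unique(samples$tissue))
  out <- tibble(gene_id = as.character(x$gene_id))
  for (t in tissues) {
    cols <- samples$sample_id[samples$tissue == t]
    out[[t]] <- rowMeans(m[, cols, drop = FALSE])
  }
  out
}

#' Read and write classification tables
#'
#' The on-disk format is a TSV with columns `gene_id`, `category` (broad:
#' elevated / expressed_in_all / mixed / not_detected_target /
#' not_detected_any), `subcategory` (tissue_enriched / group_enriched /
#' tissue_enhanced for elevated genes, empty otherwise), `group_tissues`
#' (semicolon-joined, empty if none), `target_fpkm` and `ts_score`. The pair
#' round-trips classification results losslessly.
#'
#' @param rows A classification tibble from [classify_specificity()].
#' @param path File path.
#' @return `write_classification_table()` returns `rows` invisibly;
#'   `read_classification_table()` returns the classification tibble.
#' @export
write_classification_table <- function(rows, path) {
  if (!is.data.frame(rows) || nrow(rows) == 0) {
    abort_value("`rows` must be a non-empty classification table.")
  }
  detailed <- as.character(rows$category)
  out <- tibble(
    gene_id = rows$gene_id,
    category = broad_category(detailed),
    subcategory = ifelse(detailed %in% elevated_categories(), detailed, ""),
    group_tissues = vapply(
      rows$group_tissues,
      function(g) paste(sort(g %||% character()), collapse = ";"),
      character(1)
    ),
    target_fpkm = rows$target_fpkm,
    ts_score = rows$ts_score
  )
  readr::write_tsv(out, path, progress = FALSE)
  invisible(rows)
}

#' @rdname write_classification_table
#' @export
read_classification_table <- function(path) {
  raw <- readr::read_tsv(
    path,
    col_types = readr::cols(
      gene_id = readr::col_character(),
      category = readr::col_character(),
      subcategory = readr::col_character(),
      group_tissues = readr::col_character(),
      target_fpkm = readr::col_double(),
      ts_score = readr::col_double()
    ),
    show_col_types = FALSE, progress = FALSE
  )
  subcat <- ifelse(is.na(raw$subcategory), "", raw$subcategory)
  detailed <- ifelse(subcat != "", subcat, raw$category)
  groups <- lapply(
    ifelse(is.na(raw$group_tissues), "", raw$group_tissues),
    function(s) if (nzchar(s)) strsplit(s, ";", fixed = TRUE)[[1]] else NULL
  )
  new_gene_classification(
    tibble(
      gene_id = raw$gene_id,
      category = category_factor(detailed),
      group_tissues = groups,
      target_fpkm = raw$target_fpkm,
      ts_score = raw$ts_score
    ),
    target = NULL, params = NULL
  )
}
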