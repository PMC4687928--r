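#' Transcript-pool fractions per category
#'
#' Partitions the summed target-tissue FPKM (the transcript pool of the
#' target tissue) across the specificity categories: for each category, the
#' sum of target-tissue FPKM over its genes divided by the sum over all
#' genes. Answers "what share of the tissue's mRNA molecules comes from
#' genes of each category" — dominated in practice by the expressed-in-all
#' set even though elevated genes define the tissue's identity.
#'
#' @param te Tissue profile tibble ([average_by_tissue()]).
#' @param rows Classification tibble aligned with `te` (same genes, same
#'   order), from [classify_specificity()].
#' @param target Target tissue column of `te`.
#' @return Tibble with columns `category`, `fpkm_sum`, `fraction`.
#'   Fractions sum to 1 when the total is positive; a zero-total pool
#'   yields all-zero fractions with a warning.
#' @export
pool_fractions <- function(te, rows, target) {
  if (!target %in% names(te)) {
    abort_key(paste0("Target tissue '", target, "' is not a column of `te`."))
  }
  if (!identical(as.character(te$gene_id), as.character(rows$gene_id))) {
    abort_consistency("`te` and `rows` must cover the same genes in the same order.")
  }
  fpkm <- te[[target]]
  cat <- category_factor(rows$category)
  sums <- vapply(
    spec_categories(),
    function(cc) sum(fpkm[cat == cc]),
    numeric(1)
  )
  total <- sum(sums)
  if (total <= 0) {
    warn("Total target-tissue FPKM is zero; pool fractions are all zero.")
    frac <- rep(0, length(sums))
  } else {
    frac <- sums / total
  }
  tibble(
    category = category_factor(spec_categories()),
    fpkm_sum = unname(sums),
    fraction = unname(frac)
  )
}

#' Pairwise Spearman correlation between samples or tissues
#'
#' Computes the pairwise Spearman rank correlation between expression
#' columns on log2(FPKM + 1) values (rank-equivalent to raw FPKM; the
#' pseudo-count keeps the transform defined at zero). Ties receive average
#' ranks. A constant column has no defined rank correlation: its
#' off-diagonal entries are returned as `NA` with a warning.
#'
#' @param x An [fpkm_matrix()] (for `level = "sample"`, or averaged first
#'   for `level = "tissue"`), or a tissue profile tibble.
#' @param level Correlate raw sample columns or tissue-averaged profiles.
#' @param samples Optional sample map when `x` carries none.
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
spearman_matrix <- function(x, level = c("sample", "tissue"), samples = NULL) {
  level <- match.arg(level)
  if (level == "tissue" && (inherits(x, "fpkm_matrix") || !is.null(samples))) {
    x <- average_by_tissue(x, samples = samples)
  }
  m <- as.matrix(as.data.frame(x)[, setdiff(names(x), "gene_id"), drop = FALSE])
  if (ncol(m) < 2) {
    abort_value("Need at least two columns to correlate.")
  }
  l <- log2(m + 1)
  const <- apply(l, 2, function(v) diff(range(v)) == 0)
  if (any(const)) {
    warn(paste0(
      "Constant columns have undefined rank correlations (recorded as NA): ",
      paste(colnames(l)[const], collapse = ", ")
    ))
  }
  cc <- suppressWarnings(cor(l, method = "spearman"))
  diag(cc) <- 1
  cc
}

#' Tissue-sharing network of group-enriched genes
#'
#' Builds the bipartite network connecting each distinct enriched tissue
#' combination (one node per exact set of `group_tissues`, weighted by the
#' number of genes sharing it) to its member tissues. Node size is the
#' square root of the gene count. Tissue nodes are restricted to tissues
#' appearing in at least one group.
#'
#' @param rows Classification tibble.
#' @return An object of class `tissue_sharing_network`: a list of tibbles
#'   `tissues` (`tissue`), `groups` (`combo_id`, `tissues` list column,
#'   `n_genes`, `node_size`) and `edges` (`combo_id`, `tissue`). Convert
#'   with [as_igraph()] or export with [write_network_graphml()]. A
#'   classification with no group-enriched genes yields an empty network.
#' @export
build_network <- function(rows) {
  grouped <- rows[as.character(rows$category) == "group_enriched", , drop = FALSE]
  keys <- vapply(
    grouped$group_tissues,
    function(g) paste(sort(g), collapse = ";"),
    character(1)
  )
  tab <- sort(table(keys), decreasing = TRUE)
  combo_ids <- as.character(names(tab) %||% character())
  groups <- tibble(
    combo_id = combo_ids,
    tissues = lapply(combo_ids, function(k) strsplit(k, ";", fixed = TRUE)[[1]]),
    n_genes = as.integer(tab),
    node_size = sqrt(as.integer(tab))
  )
  edges <- tibble(
    combo_id = rep(groups$combo_id, lengths(groups$tissues)),
    tissue = unlist(groups$tissues) %||% character()
  )
  structure(
    list(
      tissues = tibble(tissue = sort(unique(edges$tissue))),
      groups = groups,
      edges = edges
    ),
    class = "tissue_sharing_network"
  )
}

#' @export
print.tissue_sharing_network <- function(x, ...) {
  cat(
    "<tissue_sharing_network>", nrow(x$groups), "tissue combinations,",
    nrow(x$tissues), "tissues,", sum(x$groups$n_genes), "group-enriched genes\n"
  )
  invisible(x)
}

#' Convert or export a tissue-sharing network
#'
#' `as_igraph()` turns the network into a bipartite igraph object with node
#' attributes `kind` ("tissue" or "group"), `count` and `size`;
#' `write_network_graphml()` writes that graph as GraphML.
#'
#' @param net A `tissue_sharing_network` from [build_network()].
#' @param path Output path for the GraphML file.
#' @return `as_igraph()`: an igraph object. `write_network_graphml()`:
#'   `net`, invisibly.
#' @export
as_igraph <- function(net) {
  stopifnot(inherits(net, "tissue_sharing_network"))
  vertices <- rbind(
    data.frame(
      name = net$tissues$tissue, kind = "tissue",
      count = NA_integer_, size = 1, stringsAsFactors = FALSE
    ),
    data.frame(
      name = net$groups$combo_id, kind = "group",
      count = net$groups$n_genes, size = net$groups$node_size,
      stringsAsFactors = FALSE
    )
  )
  igraph::graph_from_data_frame(
    data.frame(from = net$edges$combo_id, to = net$edges$tissue),
    directed = FALSE, vertices = vertices
  )
}

#' @rdname as_igraph
#' @export
write_network_graphml <- function(net, path) {
  igraph::write_graph(as_igraph(net), path, format = "graphml")
  invisible(net)
}

#' Top elevated genes ordered by TS score
#'
#' Report of the most tissue-specific elevated genes: tissue-enriched,
#' group-enriched and tissue-enhanced genes sorted by TS score descending
#' (ties broken by gene id), with the target FPKM rounded to integer and
#' the TS score to one decimal, matching the conventions of printed
#' top-gene tables.
#'
#' @param rows Classification tibble.
#' @param n Number of genes to report; capped at the elevated count.
#' @return Tibble with columns `gene_id`, `category`, `group_tissues`
#'   (semicolon-joined), `target_fpkm`, `ts_score`.
#' @export
top_elevated_report <- function(rows, n = 20L) {
  if (!is.numeric(n) || length(n) != 1 || n < 1) {
    abort_value("`n` must be a single integer >= 1.")
  }
  elev <- rows[as.character(rows$category) %in% elevated_categories(), , drop = FALSE]
  ord <- order(-elev$ts_score, elev$gene_id)
  elev <- elev[ord[seq_len(min(n, nrow(elev)))], , drop = FALSE]
  tibble(
    gene_id = elev$gene_id,
    category = as.character(elev$category),
    group_tissues = vapply(
      elev$group_tissues,
      function(g) paste(sort(g %||% character()), collapse = ";"),
      character(1)
    ),
    target_fpkm = round(elev$target_fpkm),
    ts_score = round(elev$ts_score, 1)
  )
}
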