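#' Tissue-specificity (TS) score
#'
#' The TS score of a gene is its FPKM in the target tissue divided by the
#' maximum FPKM across all other tissues. The denominator is floored at
#' `params$ts_floor` so that genes expressed nowhere outside the target
#' still receive a finite score.
#'
#' @param profile Named numeric vector of per-tissue mean FPKM.
#' @param target Name of the target tissue.
#' @param params [classification_params()].
#' @return A single non-negative number.
#' @examples
#' p <- c(bladder = 54, esophagus = 1.4, skin = 1.0)
#' ts_score(p, "bladder") # 54 / 1.4
#' @export
ts_score <- function(profile, target, params = classification_params()) {
  params <- as_classification_params(params)
  check_profile(profile, target, min_tissues = 2L)
  others <- profile[names(profile) != target]
  unname(profile[[target]] / max(max(others), params$ts_floor))
}

check_profile <- function(profile, target, min_tissues) {
  if (!is.numeric(profile) || is.null(names(profile)) || any(!nzchar(names(profile)))) {
    abort_value("`profile` must be a named numeric vector of per-tissue FPKM.")
  }
  if (anyDuplicated(names(profile))) {
    abort_format("Duplicate tissue names in `profile`.")
  }
  if (length(profile) < min_tissues) {
    abort_value(paste0("`profile` must cover at least ", min_tissues, " tissues."))
  }
  if (!target %in% names(profile)) {
    abort_key(paste0("Target tissue '", target, "' is not in the profile."))
  }
  if (anyNA(profile) || any(!is.finite(profile)) || any(profile < 0)) {
    abort_value("FPKM values must be finite and non-negative.")
  }
  invisible(profile)
}

#' Find the smallest enriched group of tissues for one gene
#'
#' Searches for a group of `group_min`–`group_max` tissues, containing the
#' target, whose mean FPKM is at least `fold_factor` times the maximum FPKM
#' of every tissue outside the group. Candidate groups take the target plus
#' a prefix of the other tissues ordered by descending FPKM (ties broken
#' lexicographically by tissue name). For each group size this candidate
#' simultaneously maximises the group mean and minimises the out-of-group
#' maximum among all groups of that size containing the target, so the
#' search agrees with exhaustive subset enumeration on whether a qualifying
#' group exists. The smallest qualifying candidate is returned.
#'
#' Precedence between the single-tissue enriched rule and the group rule is
#' applied by [classify_gene()], not here: called directly, this function
#' may return a group for a gene that classification labels tissue enriched.
#'
#' @inheritParams ts_score
#' @return Sorted character vector of tissue names, or `NULL` when no
#'   qualifying group exists.
#' @examples
#' p <- c(bladder = 26, esophagus = 24, skin = 1, lung = 0.5)
#' find_enriched_group(p, "bladder", classification_params(group_max = 3))
#' @export
find_enriched_group <- function(profile, target, params = classification_params()) {
  params <- as_classification_params(params)
  check_profile(profile, target, min_tissues = 3L)
  nt <- length(profile)
  others <- profile[names(profile) != target]
  ord <- order(-others, names(others))
  vals <- unname(others[ord])
  onames <- names(others)[ord]
  k_max <- min(params$group_max, nt - 1L)
  for (k in params$group_min:k_max) {
    g_mean <- (profile[[target]] + sum(vals[seq_len(k - 1L)])) / k
    if (g_mean >= params$fold_factor * max(vals[k:(nt - 1L)])) {
      return(sort(c(target, onames[seq_len(k - 1L)])))
    }
  }
  NULL
}

#' Classify one gene's tissue profile
#'
#' Assigns exactly one of the seven specificity categories by precedence:
#' (a) every tissue below the detection cutoff — not detected in any tissue;
#' (b) target below the cutoff — not detected in the target;
#' (c) target >= fold_factor times the maximum of all other tissues —
#' tissue enriched; (d) a qualifying group exists
#' ([find_enriched_group()]) — group enriched; (e) target >= fold_factor
#' times the baseline mean — tissue enhanced; (f) every tissue at or above
#' the cutoff — expressed in all; (g) otherwise mixed. Detection is
#' non-strict (FPKM >= cutoff counts as detected) and all fold comparisons
#' are non-strict. The TS score is computed for every gene regardless of
#' category.
#'
#' @inheritParams ts_score
#' @param gene_id Optional gene identifier carried into the result.
#' @return A one-row classification tibble with columns `gene_id`,
#'   `category`, `group_tissues` (list column), `target_fpkm`, `ts_score`.
#' @examples
#' p <- c(bladder = 54, setNames(rep(1.4, 8), paste0("t", 1:8)))
#' classify_gene(p, "bladder")$category
#' @export
classify_gene <- function(profile, target, params = classification_params(),
                          gene_id = NA_character_) {
  params <- as_classification_params(params)
  check_profile(profile, target, min_tissues = params$group_max + 1L)
  q <- params$detection_cutoff
  f <- params$fold_factor
  tv <- profile[[target]]
  others <- profile[names(profile) != target]
  max_oth <- max(others)
  baseline <- switch(params$enhanced_baseline,
    all_tissues = mean(profile),
    other_tissues = mean(others)
  )

  group <- NULL
  if (max(profile) < q) {
    category <- "not_detected_any"
  } else if (tv < q) {
    category <- "not_detected_target"
  } else if (tv >= f * max_oth) {
    category <- "tissue_enriched"
  } else if (!is.null(group <- find_enriched_group(profile, target, params))) {
    category <- "group_enriched"
  } else if (tv >= f * baseline) {
    category <- "tissue_enhanced"
  } else if (min(profile) >= q) {
    category <- "expressed_in_all"
  } else {
    category <- "mixed"
  }

  new_gene_classification(
    tibble(
      gene_id = gene_id,
      category = category_factor(category),
      group_tissues = list(group),
      target_fpkm = unname(tv),
      ts_score = ts_score(profile, target, params)
    ),
    target = target, params = params
  )
}

new_gene_classification <- function(tbl, target, params) {
  structure(
    tbl,
    target = target,
    params = params,
    class = c("gene_classification", class(tibble()))
  )
}

#' Classify every gene of a tissue-expression profile table
#'
#' Vectorised classification of a whole gene set against a target tissue.
#' Rules and precedence are those of [classify_gene()]; the per-gene group
#' search only runs for genes that are detected in the target and not
#' already tissue enriched.
#'
#' @param te Tissue profile tibble from [average_by_tissue()]: `gene_id`
#'   plus one mean-FPKM column per tissue.
#' @param target Name of the target tissue (must be a column of `te`).
#' @param params [classification_params()].
#' @return A classification tibble (class `gene_classification`) with one
#'   row per gene in input order and columns `gene_id`, `category`,
#'   `group_tissues`, `target_fpkm`, `ts_score`. The target tissue and the
#'   parameters used are attached as attributes; [glance()] summarises the
#'   category counts.
#' @examples
#' m <- fpkm_matrix(
#'   data.frame(gene_id = c("g1", "g2"),
#'              b = c(50, 2), t1 = c(1, 2), t2 = c(1, 2), t3 = c(0, 2),
#'              t4 = c(0, 2), t5 = c(0, 2), t6 = c(0, 2), t7 = c(0, 2)),
#'   setNames(c("bladder", paste0("tissue", 1:7)),
#'            c("b", paste0("t", 1:7)))
#' )
#' classify_specificity(average_by_tissue(m), "bladder")
#' @export
classify_specificity <- function(te, target, params = classification_params()) {
  params <- as_classification_params(params)
  if (!is.data.frame(te) || !"gene_id" %in% names(te)) {
    abort_format("`te` must be a tissue profile tibble with a `gene_id` column.")
  }
  tissues <- setdiff(names(te), "gene_id")
  if (!target %in% tissues) {
    abort_key(paste0("Target tissue '", target, "' is not a column of `te`."))
  }
  if (length(tissues) < params$group_max + 1L) {
    abort_config(paste0(
      "Need more than `group_max` = ", params$group_max,
      " tissues; got ", length(tissues), "."
    ))
  }

  m <- as.matrix(as.data.frame(te)[, tissues, drop = FALSE])
  if (anyNA(m) || any(!is.finite(m)) || any(m < 0)) {
    abort_value("FPKM values must be finite and non-negative.")
  }
  n <- nrow(m)
  q <- params$detection_cutoff
  f <- params$fold_factor

  tv <- m[, target]
  oth <- m[, setdiff(tissues, target), drop = FALSE]
  max_oth <- if (n > 0) row_max(oth) else numeric(0)
  max_all <- if (n > 0) pmax(max_oth, tv) else numeric(0)
  min_all <- if (n > 0) pmin(row_min(oth), tv) else numeric(0)
  baseline <- switch(params$enhanced_baseline,
    all_tissues = rowMeans(m),
    other_tissues = rowMeans(oth)
  )
  ts <- tv / pmax(max_oth, params$ts_floor)

  category <- rep(NA_character_, n)
  groups <- vector("list", n)

  category[max_all < q] <- "not_detected_any"
  category[is.na(category) & tv < q] <- "not_detected_target"
  category[is.na(category) & tv >= f * max_oth] <- "tissue_enriched"

  for (i in which(is.na(category))) {
    g <- find_enriched_group(m[i, ], target, params)
    if (!is.null(g)) {
      category[i] <- "group_enriched"
      groups[[i]] <- g
    }
  }

  category[is.na(category) & tv >= f * baseline] <- "tissue_enhanced"
  category[is.na(category) & min_all >= q] <- "expressed_in_all"
  category[is.na(category)] <- "mixed"

  new_gene_classification(
    tibble(
      gene_id = as.character(te$gene_id),
      category = category_factor(category),
      group_tissues = groups,
      target_fpkm = unname(tv),
      ts_score = unname(ts)
    ),
    target = target, params = params
  )
}

#' Category counts and the elevated total
#'
#' `category_counts()` tallies a classification table over the seven
#' categories (zero-filled); `elevated_total()` sums the tissue-enriched,
#' group-enriched and tissue-enhanced counts.
#'
#' @param rows A classification tibble, or (for `elevated_total()` and
#'   [category_percentages()]) a counts tibble with columns `category`, `n`.
#' @return `category_counts()`: tibble with columns `category` and `n`,
#'   one row per category. `elevated_total()`: a single integer.
#' @examples
#' counts <- tibble::tibble(
#'   category = spec_categories(),
#'   n = c(1, 23, 66, 8874, 4954, 4594, 1832)
#' )
#' elevated_total(counts)
#' @export
category_counts <- function(rows) {
  cat <- category_factor(rows$category)
  tibble(
    category = category_factor(spec_categories()),
    n = as.integer(table(cat))
  )
}

#' @rdname category_counts
#' @export
elevated_total <- function(rows) {
  if (all(c("category", "n") %in% names(rows))) {
    sum(rows$n[as.character(rows$category) %in% elevated_categories()])
  } else {
    sum(as.character(rows$category) %in% elevated_categories())
  }
}

#' Percentage reporting of category counts
#'
#' Converts counts to percentages of the gene total, rounded the way
#' multi-tissue expression studies print them: whole percent when at least
#' 1%, one decimal below 1% (so 90 of 20,344 genes reports as 0.4).
#'
#' @param counts Counts tibble (`category`, `n`) from [category_counts()].
#' @param total Gene total the percentages refer to; defaults to `sum(n)`.
#' @return `counts` with a `percent` column added.
#' @export
category_percentages <- function(counts, total = sum(counts$n)) {
  counts$percent <- percent_reported(counts$n, total)
  counts
}

#' @rdname category_percentages
#' @param n Count or vector of counts.
#' @export
percent_reported <- function(n, total) {
  if (!is.numeric(total) || length(total) != 1 || !is.finite(total) || total <= 0) {
    abort_value("`total` must be a single positive number.")
  }
  p <- 100 * n / total
  ifelse(p >= 1, round(p), round(p, 1))
}
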