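# Independent oracles and small random-instance builders used across the
# suite. These deliberately avoid the package's own code paths.

`%||%` <- function(x, y) if (is.null(x)) y else x

# Exhaustive group search: enumerate every subset of 2..group_max tissues
# containing the target and test mean(G) >= fold * max(outside G) directly.
# Returns one qualifying subset (sorted) or NULL.
exhaustive_group_search <- function(profile, target, params = classification_params()) {
  tissues <- names(profile)
  others <- setdiff(tissues, target)
  for (k in params$group_min:min(params$group_max, length(tissues) - 1L)) {
    combos <- utils::combn(others, k - 1L, simplify = FALSE)
    for (cmb in combos) {
      g <- c(target, cmb)
      out <- setdiff(tissues, g)
      if (mean(profile[g]) >= params$fold_factor * max(profile[out])) {
        return(sort(g))
      }
    }
  }
  NULL
}

# Precomputed-subset variant fast enough for tens of thousands of profiles:
# qualification existence only.
make_subset_matrix <- function(nt, params = classification_params()) {
  # target is position 1; rows = candidate groups as logical masks
  masks <- list()
  for (k in params$group_min:min(params$group_max, nt - 1L)) {
    combos <- utils::combn(2:nt, k - 1L)
    for (j in seq_len(ncol(combos))) {
      m <- logical(nt)
      m[c(1L, combos[, j])] <- TRUE
      masks[[length(masks) + 1L]] <- m
    }
  }
  do.call(rbind, masks)
}

exhaustive_group_exists <- function(v, S, fold = 5) {
  sizes <- rowSums(S)
  means <- as.vector(S %*% v) / sizes
  vm <- matrix(v, nrow = nrow(S), ncol = length(v), byrow = TRUE)
  vm[S] <- -Inf
  outmax <- vm[cbind(seq_len(nrow(S)), max.col(vm, ties.method = "first"))]
  any(means >= fold * outmax)
}

# Rank-then-Pearson Spearman oracle written from the definition: average
# ranks, then the closed-form Pearson correlation of the rank vectors.
spearman_oracle <- function(m) {
  r <- apply(m, 2, rank, ties.method = "average")
  nc <- ncol(r)
  out <- matrix(1, nc, nc, dimnames = list(colnames(m), colnames(m)))
  for (i in seq_len(nc)) {
    for (j in seq_len(nc)) {
      x <- r[, i] - mean(r[, i])
      y <- r[, j] - mean(r[, j])
      out[i, j] <- sum(x * y) / sqrt(sum(x^2) * sum(y^2))
    }
  }
  out
}

# Random tissue profile on a fixed small FPKM value grid.
random_grid_profile <- function(nt, grid = c(0, 0.5, 1, 3, 20, 100)) {
  stats::setNames(
    sample(grid, nt, replace = TRUE),
    c("bladder", sprintf("t%02d", seq_len(nt - 1L)))
  )
}

# Random classification tibble for round-trip and tally tests.
random_classification <- function(n, tissues = c("bladder", sprintf("t%02d", 1:9))) {
  cats <- sample(spec_categories(), n, replace = TRUE)
  groups <- lapply(cats, function(cc) {
    if (cc == "group_enriched") {
      pool <- setdiff(tissues, "bladder")
      sort(c("bladder", sample(pool, sample(seq_len(min(6, length(pool))), 1))))
    } else {
      NULL
    }
  })
  structure(
    tibble::tibble(
      gene_id = sprintf("g%05d", seq_len(n)),
      category = factor(cats, levels = spec_categories()),
      group_tissues = groups,
      target_fpkm = round(stats::runif(n, 0, 300), 4),
      ts_score = round(stats::runif(n, 0, 50), 4)
    ),
    class = c("gene_classification", class(tibble::tibble()))
  )
}

# Small deterministic FPKM study written to temp files.
write_demo_matrix <- function(dir = withr::local_tempdir(.local_envir = parent.frame())) {
  matrix_path <- file.path(dir, "matrix.tsv")
  map_path <- file.path(dir, "samples.tsv")
  writeLines(
    c(
      "gene_id\ts1\ts2\ts3\ts4",
      "g1\t10\t30\t1\t3",
      "g2\t0\t0\t5\t7",
      "g3\t2\t2\t2\t2"
    ),
    matrix_path
  )
  writeLines(
    c(
      "sample_id\ttissue",
      "s1\tbladder", "s2\tbladder", "s3\ttestis", "s4\ttestis"
    ),
    map_path
  )
  list(matrix = matrix_path, samples = map_path)
}
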