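make_profile <- function(target_val, other_vals) {
  stats::setNames(
    c(target_val, other_vals),
    c("bladder", sprintf("t%02d", seq_along(other_vals)))
  )
}

test_that("ts_score is the target-over-max-other ratio with a floored denominator", {
  # printed pair: target 54 with TS 38.6 implies max other ~1.4
  p <- make_profile(54, rep(1.4, 31))
  expect_equal(signif(ts_score(p, "bladder"), 3), 38.6)

  expect_equal(ts_score(make_profile(0, rep(3, 31)), "bladder"), 0)

  # all other tissues silent: denominator floored at 0.1
  expect_equal(ts_score(make_profile(10, rep(0, 31)), "bladder"), 100)

  expect_error(ts_score(p, "kidney"), class = "tissuespec_key_error")
})

test_that("hand-built profiles land in each of the seven categories", {
  cases <- list(
    tissue_enriched = make_profile(54, rep(1.4, 31)),
    group_enriched = make_profile(20, c(18, rep(0.5, 30))),
    tissue_enhanced = make_profile(30, c(rep(9, 7), rep(0, 24))),
    expressed_in_all = make_profile(2.5, runif(31, 2, 3)),
    mixed = make_profile(2, c(rep(2, 19), rep(0, 12))),
    not_detected_target = make_profile(0.5, rep(2, 31)),
    not_detected_any = make_profile(0.3, rep(0.3, 31))
  )
  for (expected in names(cases)) {
    got <- classify_gene(cases[[expected]], "bladder")
    expect_equal(as.character(got$category), expected, label = expected)
  }
  expect_equal(
    as.character(classify_gene(make_profile(0, rep(0, 31)), "bladder")$category),
    "not_detected_any"
  )
})

test_that("the group-enriched example picks the smallest qualifying prefix", {
  # target 20 alone fails 5 x 18, but {target, t01} has mean 19 >= 5 x 0.5
  p <- make_profile(20, c(18, rep(0.5, 30)))
  cls <- classify_gene(p, "bladder")
  expect_equal(as.character(cls$category), "group_enriched")
  expect_equal(cls$group_tissues[[1]], c("bladder", "t01"))
  expect_equal(cls$group_tissues[[1]], exhaustive_group_search(p, "bladder"))
})

test_that("precedence between enriched and group rules lives in classify_gene", {
  # target alone 5-fold above everything: classification says enriched, but
  # the group search called directly may still return a qualifying prefix
  p <- make_profile(100, rep(1, 31))
  expect_equal(as.character(classify_gene(p, "bladder")$category), "tissue_enriched")
  g <- find_enriched_group(p, "bladder")
  expect_false(is.null(g))
  expect_true("bladder" %in% g)
  expect_gte(mean(p[g]), 5 * max(p[setdiff(names(p), g)]))
})

test_that("prefix group search agrees with exhaustive subset enumeration", {
  withr::local_seed(101)
  params <- classification_params()
  for (i in 1:400) {
    nt <- sample(8:10, 1)
    p <- random_grid_profile(nt)
    mine <- find_enriched_group(p, "bladder", params)
    oracle <- exhaustive_group_search(p, "bladder", params)
    expect_equal(is.null(mine), is.null(oracle))
    if (!is.null(mine)) {
      # the returned prefix itself must qualify
      expect_gte(mean(p[mine]), params$fold_factor * max(p[setdiff(names(p), mine)]))
      expect_true("bladder" %in% mine)
      expect_true(length(mine) >= params$group_min && length(mine) <= params$group_max)
    }
  }
})

test_that("classification is a partition satisfying the category invariants", {
  withr::local_seed(55)
  params <- classification_params()
  n <- 500
  te <- tibble::as_tibble(
    as.data.frame(matrix(sample(c(0, 0.5, 1, 3, 20, 100), n * 10, replace = TRUE),
                         nrow = n))
  )
  names(te) <- c("bladder", sprintf("t%02d", 1:9))
  te <- cbind(tibble::tibble(gene_id = sprintf("g%04d", 1:n)), te)
  rows <- classify_specificity(te, "bladder", params)

  expect_false(anyNA(rows$category))
  expect_equal(sum(category_counts(rows)$n), n)

  grp <- as.character(rows$category) == "group_enriched"
  expect_true(all(vapply(rows$group_tissues[grp], function(g) {
    "bladder" %in% g && length(g) >= 2 && length(g) <= 7
  }, logical(1))))
  expect_true(all(vapply(rows$group_tissues[!grp], is.null, logical(1))))

  enr <- as.character(rows$category) == "tissue_enriched"
  expect_true(all(rows$ts_score[enr] >= params$fold_factor))

  nd <- rows$target_fpkm < params$detection_cutoff
  expect_true(all(
    as.character(rows$category)[nd] %in% c("not_detected_any", "not_detected_target")
  ))
})

test_that("vectorised classification matches the per-gene reference path", {
  withr::local_seed(77)
  n <- 120
  te <- tibble::as_tibble(as.data.frame(matrix(runif(n * 9, 0, 40), nrow = n)))
  names(te) <- c("bladder", sprintf("t%02d", 1:8))
  te <- cbind(tibble::tibble(gene_id = sprintf("g%03d", 1:n)), te)
  rows <- classify_specificity(te, "bladder")
  for (i in seq_len(n)) {
    p <- unlist(te[i, -1])
    single <- classify_gene(p, "bladder")
    expect_equal(as.character(rows$category[i]), as.character(single$category))
    expect_equal(rows$ts_score[i], single$ts_score)
    expect_equal(rows$group_tissues[[i]], single$group_tissues[[1]])
  }
})

test_that("raising only the target FPKM never de-elevates a gene", {
  withr::local_seed(31)
  for (i in 1:200) {
    p <- random_grid_profile(10)
    before <- as.character(classify_gene(p, "bladder")$category)
    if (before %in% elevated_categories()) {
      p["bladder"] <- p[["bladder"]] * runif(1, 1, 10) + 1
      after <- as.character(classify_gene(p, "bladder")$category)
      expect_true(after %in% elevated_categories())
    }
  }
})

test_that("fold decisions are invariant to a detection-preserving global rescale", {
  withr::local_seed(13)
  for (i in 1:100) {
    # zeros stay zero and detected values stay detected under c >= 1
    p <- random_grid_profile(10, grid = c(0, 1, 3, 20, 100))
    cc <- runif(1, 1, 20)
    expect_equal(
      as.character(classify_gene(p, "bladder")$category),
      as.character(classify_gene(p * cc, "bladder")$category)
    )
  }
})

test_that("tissue enriched coincides with TS score >= fold when the floor is inactive", {
  withr::local_seed(91)
  params <- classification_params()
  for (i in 1:200) {
    p <- make_profile(runif(1, 1, 100), runif(9, 0.2, 30))
    cls <- classify_gene(p, "bladder", params)
    detected <- p[["bladder"]] >= params$detection_cutoff
    expect_equal(
      as.character(cls$category) == "tissue_enriched",
      detected && cls$ts_score >= params$fold_factor
    )
  }
})

test_that("category tallies match a loop oracle and percentages round as printed", {
  withr::local_seed(3)
  rows <- random_classification(500)
  counts <- category_counts(rows)
  for (cc in spec_categories()) {
    manual <- 0
    for (i in seq_len(nrow(rows))) {
      if (as.character(rows$category[i]) == cc) manual <- manual + 1
    }
    expect_equal(counts$n[counts$category == cc], manual)
  }
  expect_equal(elevated_total(counts), elevated_total(rows))

  expect_equal(percent_reported(c(90, 8874), 20344), c(0.4, 44))
})
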