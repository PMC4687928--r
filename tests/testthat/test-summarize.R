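test_that("pool fractions partition the target-tissue transcript pool", {
  te <- tibble::tibble(
    gene_id = c("g1", "g2"),
    bladder = c(3, 7), t1 = c(1, 1), t2 = c(1, 1)
  )
  rows <- random_classification(2, tissues = c("bladder", "t1", "t2"))
  rows$gene_id <- te$gene_id
  rows$category <- category_factor(c("tissue_enriched", "expressed_in_all"))
  rows$group_tissues <- list(NULL, NULL)

  pf <- pool_fractions(te, rows, "bladder")
  expect_equal(pf$fraction[pf$category == "tissue_enriched"], 0.3)
  expect_equal(pf$fraction[pf$category == "expressed_in_all"], 0.7)
  expect_equal(sum(pf$fraction), 1, tolerance = 1e-12)

  rows$category <- category_factor(rep("mixed", 2))
  pf1 <- pool_fractions(te, rows, "bladder")
  expect_equal(pf1$fraction[pf1$category == "mixed"], 1)

  expect_error(
    pool_fractions(te[2:1, ], rows, "bladder"),
    class = "tissuespec_consistency_error"
  )

  te$bladder <- c(0, 0)
  expect_warning(pf0 <- pool_fractions(te, rows, "bladder"), "zero")
  expect_equal(sum(pf0$fraction), 0)
})

test_that("pool fractions equal brute-force per-category sums and sum to one", {
  withr::local_seed(8)
  n <- 200
  te <- tibble::tibble(gene_id = sprintf("g%03d", 1:n), bladder = runif(n, 0, 50),
                       t01 = runif(n), t02 = runif(n))
  rows <- random_classification(n, tissues = names(te)[-1])
  rows$gene_id <- te$gene_id
  pf <- pool_fractions(te, rows, "bladder")
  total <- sum(te$bladder)
  for (cc in spec_categories()) {
    s <- 0
    for (i in seq_len(n)) {
      if (as.character(rows$category[i]) == cc) s <- s + te$bladder[i]
    }
    expect_equal(pf$fraction[pf$category == cc], s / total, tolerance = 1e-12)
  }
  expect_equal(sum(pf$fraction), 1, tolerance = 1e-9)
})

test_that("spearman_matrix handles duplicates, reversals and constant columns", {
  withr::local_seed(21)
  x <- tibble::tibble(
    gene_id = sprintf("g%d", 1:50),
    a = runif(50, 0, 100)
  )
  x$b <- x$a                       # duplicated column
  x$c <- max(x$a) + 1 - x$a        # exactly reversed ranks
  cc <- spearman_matrix(x)
  expect_equal(cc["a", "b"], 1)
  expect_equal(cc["a", "c"], -1)
  expect_equal(diag(cc), c(a = 1, b = 1, c = 1))

  x$d <- 5
  expect_warning(cc2 <- spearman_matrix(x), "Constant")
  expect_true(is.na(cc2["a", "d"]))
  expect_equal(cc2["d", "d"], 1)
})

test_that("spearman_matrix matches a from-scratch rank-then-Pearson oracle", {
  withr::local_seed(99)
  n <- 200
  x <- tibble::as_tibble(as.data.frame(matrix(rlnorm(n * 5, 2, 1.5), nrow = n)))
  names(x) <- sprintf("s%d", 1:5)
  x$s3[1:20] <- x$s1[1:20] # inject ties across and within columns
  x <- cbind(tibble::tibble(gene_id = sprintf("g%03d", 1:n)), x)

  cc <- spearman_matrix(x)
  oracle <- spearman_oracle(log2(as.matrix(x[-1]) + 1))
  expect_lt(max(abs(cc - oracle)), 1e-12)
  expect_equal(cc, t(cc))

  # invariant under a strictly monotone transform of the values
  y <- x
  y[-1] <- lapply(y[-1], function(v) v^1.7 + 3)
  expect_lt(max(abs(spearman_matrix(y) - cc)), 1e-12)
})

test_that("the tissue-sharing network tallies exact group combinations", {
  rows <- random_classification(6)
  rows$category <- category_factor(c(rep("group_enriched", 6)))
  rows$group_tissues <- list(
    c("bladder", "esophagus"), c("bladder", "esophagus"), c("bladder", "esophagus"),
    c("bladder", "skin"), c("bladder", "skin"),
    c("bladder", "esophagus", "skin")
  )
  net <- build_network(rows)
  expect_equal(nrow(net$groups), 3)
  eso <- net$groups[net$groups$combo_id == "bladder;esophagus", ]
  expect_equal(eso$n_genes, 3L)
  expect_equal(eso$node_size, sqrt(3))
  expect_equal(eso$node_size^2, 3)
  expect_equal(sum(net$groups$n_genes), 6)
  # tissue degree = number of combinations it belongs to
  expect_equal(sum(net$edges$tissue == "bladder"), 3)
  expect_equal(sum(net$edges$tissue == "skin"), 2)

  none <- random_classification(4)
  none$category <- category_factor(rep("mixed", 4))
  none$group_tissues <- list(NULL, NULL, NULL, NULL)
  empty <- build_network(none)
  expect_equal(nrow(empty$groups), 0)
  expect_equal(nrow(empty$edges), 0)
})

test_that("network gene counts sum to the group-enriched total on random data", {
  withr::local_seed(17)
  rows <- random_classification(300)
  net <- build_network(rows)
  expect_equal(
    sum(net$groups$n_genes),
    sum(as.character(rows$category) == "group_enriched")
  )
})

test_that("networks export to GraphML and read back with attributes", {
  dir <- withr::local_tempdir()
  rows <- random_classification(10)
  rows$category <- category_factor(rep("group_enriched", 10))
  rows$group_tissues <- rep(list(c("bladder", "esophagus")), 10)
  net <- build_network(rows)
  path <- file.path(dir, "net.graphml")
  write_network_graphml(net, path)
  g <- igraph::read_graph(path, format = "graphml")
  expect_equal(igraph::vcount(g), 3) # 2 tissues + 1 combination
  kinds <- igraph::vertex_attr(g, "kind")
  expect_equal(sort(kinds), c("group", "tissue", "tissue"))
  expect_equal(igraph::vertex_attr(g, "count")[kinds == "group"], 10)
})

test_that("top elevated report orders by TS score with printed rounding", {
  rows <- random_classification(5)
  rows$category <- category_factor(c(
    "tissue_enriched", "tissue_enhanced", "group_enriched", "mixed", "tissue_enhanced"
  ))
  rows$group_tissues <- list(NULL, NULL, c("bladder", "esophagus"), NULL, NULL)
  rows$ts_score <- c(38.57, 4.68, 4.62, 99, 2.31)
  rows$target_fpkm <- c(54.2, 8.4, 26.1, 1, 15.5)

  rep5 <- top_elevated_report(rows, n = 10)
  expect_equal(nrow(rep5), 4) # mixed gene excluded, n capped
  expect_equal(rep5$ts_score, c(38.6, 4.7, 4.6, 2.3))
  expect_equal(rep5$target_fpkm[1], 54)
  expect_equal(rep5$group_tissues[3], "bladder;esophagus")

  withr::local_seed(4)
  rnd <- random_classification(200)
  out <- top_elevated_report(rnd, n = 50)
  elev <- rnd[as.character(rnd$category) %in% elevated_categories(), ]
  oracle <- elev[order(-elev$ts_score, elev$gene_id), ][1:50, ]
  expect_equal(out$gene_id, oracle$gene_id)
})
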