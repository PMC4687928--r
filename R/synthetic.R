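#' Configuration for the synthetic FPKM generator
#'
#' Describes a replicate-bearing multi-tissue FPKM study with genes planted
#' in each specificity category. Defaults emulate the 32-tissue, duplicate
#' design of large multi-tissue expression atlases: 100 genes per category,
#' a 1-FPKM detection limit with 5-fold rules, multiplicative log-normal
#' replicate noise, and a safety margin of 2 on every planted rule so that
#' moderate noise does not flip category calls.
#'
#' @param n_tissues Number of tissues (>= 9 so groups of up to `group_max`
#'   leave outsiders).
#' @param replicates_per_tissue Samples per tissue.
#' @param genes_per_category Named integer vector giving the number of genes
#'   to plant per category (names from [spec_categories()]); default 100
#'   each.
#' @param margin Multiplicative slack (>= 1) applied to every planted rule:
#'   planted enriched genes sit at `margin * fold_factor` times the other
#'   tissues, planted below-cutoff values sit at `cutoff / margin`, and so
#'   on.
#' @param noise_sigma Standard deviation of the log-normal replicate noise;
#'   each replicate is the tissue mean times `exp(N(0, noise_sigma^2))`.
#' @param baseline_log_mean,baseline_log_sd Natural-log mean and sd of the
#'   log-normal baseline expression level (default median 10 FPKM).
#' @param seed Integer seed; generation is fully deterministic given the
#'   configuration.
#' @param target_tissue Name of the target tissue.
#' @param params [classification_params()] the generator plants against.
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(n_tissues = 32L,
                             replicates_per_tissue = 2L,
                             genes_per_category = NULL,
                             margin = 2,
                             noise_sigma = 0.1,
                             baseline_log_mean = log(10),
                             baseline_log_sd = 1,
                             seed = 1L,
                             target_tissue = "bladder",
                             params = classification_params()) {
  params <- as_classification_params(params)
  n_tissues <- as.integer(n_tissues)
  replicates_per_tissue <- as.integer(replicates_per_tissue)
  if (is.na(n_tissues) || n_tissues < 9L) {
    abort_config("`n_tissues` must be at least 9.")
  }
  if (is.na(replicates_per_tissue) || replicates_per_tissue < 1L) {
    abort_config("`replicates_per_tissue` must be at least 1.")
  }
  if (!is.numeric(margin) || margin < 1) {
    abort_config("`margin` must be >= 1.")
  }
  if (!is.numeric(noise_sigma) || noise_sigma < 0) {
    abort_config("`noise_sigma` must be >= 0.")
  }
  if (n_tissues <= params$group_max + 1L) {
    abort_config("`n_tissues` must exceed `group_max` + 1.")
  }

  gpc <- rep(100L, 7L)
  names(gpc) <- spec_categories()
  if (!is.null(genes_per_category)) {
    if (is.null(names(genes_per_category)) ||
        !all(names(genes_per_category) %in% spec_categories())) {
      abort_config("`genes_per_category` must be named with category names.")
    }
    gpc[] <- 0L
    gpc[names(genes_per_category)] <- as.integer(genes_per_category)
  }
  if (any(is.na(gpc)) || any(gpc < 0)) {
    abort_config("`genes_per_category` entries must be non-negative integers.")
  }

  cfg <- structure(
    list(
      n_tissues = n_tissues,
      replicates_per_tissue = replicates_per_tissue,
      genes_per_category = gpc,
      margin = margin,
      noise_sigma = noise_sigma,
      baseline_log_mean = baseline_log_mean,
      baseline_log_sd = baseline_log_sd,
      seed = as.integer(seed),
      target_tissue = target_tissue,
      params = params
    ),
    class = "generator_config"
  )
  check_generator_feasibility(cfg)
  cfg
}

# The planted constructions only work when the study geometry leaves room
# for them; fail early with an explanation rather than emit data that the
# classifier is guaranteed to relabel.
check_generator_feasibility <- function(cfg) {
  p <- cfg$params
  f <- p$fold_factor
  c_max <- p$group_max
  # Tissue-enhanced construction: group_max companion tissues at
  # v = (n_tissues/(f*margin) - 1) * target / group_max must break the
  # enriched rule, i.e. f * v > target, which needs
  # n_tissues > margin * (f + group_max).
  if (cfg$genes_per_category[["tissue_enhanced"]] > 0 &&
      cfg$n_tissues <= cfg$margin * (f + c_max)) {
    abort_config(paste0(
      "Infeasible config: planting tissue-enhanced genes at margin ",
      cfg$margin, " needs n_tissues > margin * (fold_factor + group_max) = ",
      cfg$margin * (f + c_max), ", got ", cfg$n_tissues,
      ". Lower `margin` or add tissues."
    ))
  }
  # Mixed construction needs a detected-tissue count that breaks both the
  # group rule (> group_max) and the enhanced rule (> 1.5 * 1.5 * nt / f),
  # while leaving at least one undetected tissue.
  if (cfg$genes_per_category[["mixed"]] > 0 &&
      mixed_min_detected(cfg) > cfg$n_tissues - 1L) {
    abort_config(paste0(
      "Infeasible config: mixed genes need between ", mixed_min_detected(cfg),
      " and ", cfg$n_tissues - 1L, " detected tissues."
    ))
  }
  # Noise can only be guaranteed not to flip a planted rule when the margin
  # dominates it.
  if (cfg$noise_sigma > 0 && log(cfg$margin) < 2 * cfg$noise_sigma) {
    abort_config(paste0(
      "Infeasible config: noise_sigma = ", cfg$noise_sigma,
      " is too large relative to margin = ", cfg$margin,
      " (need log(margin) >= 2 * noise_sigma to bound rule flips)."
    ))
  }
  invisible(cfg)
}

mixed_min_detected <- function(cfg) {
  max(
    cfg$params$group_max + 1L,
    as.integer(ceiling(2.25 * cfg$n_tissues / cfg$params$fold_factor))
  )
}

#' Generate a synthetic FPKM study with planted category truth
#'
#' Builds per-gene tissue-mean profiles that satisfy their planted
#' category's rule with multiplicative slack `margin`, then draws
#' replicate-level values as `mean * exp(N(0, noise_sigma^2))`. Zero means
#' stay exactly zero. At `noise_sigma = 0` every planted gene is recovered
#' by [classify_specificity()] by construction.
#'
#' Planted constructions (cutoff q, fold f, margin m):
#' tissue-enriched genes put the target at `m * f * max(others)` with all
#' other tissues detected; group-enriched genes give a random group of
#' `group_min`-`group_max` tissues a common level `m * f * max(outsiders)`;
#' tissue-enhanced genes hold `group_max` companion tissues at a level that
#' defeats the enriched and every group rule while the target sits at
#' exactly `m * f` times the all-tissue mean; expressed-in-all genes vary
#' within 1.5-fold around a detected baseline; mixed genes are detected in
#' a random strict subset large enough to defeat the group and enhanced
#' rules; not-detected genes sit below `q / m`.
#'
#' @param config A [generator_config()].
#' @return A list of class `fpkm_simulation` with elements `expression`
#'   (an [fpkm_matrix()]), `truth` (tibble `gene_id`, `category`,
#'   `group_tissues`) and `config`.
#' @examples
#' sim <- simulate_fpkm(generator_config(
#'   genes_per_category = c(tissue_enriched = 3, expressed_in_all = 3),
#'   noise_sigma = 0, seed = 7
#' ))
#' sim$truth
#' @export
simulate_fpkm <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  check_generator_feasibility(config)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  }
  set.seed(config$seed)

  p <- config$params
  nt <- config$n_tissues
  q <- p$detection_cutoff
  f <- p$fold_factor
  m <- config$margin
  blm <- config$baseline_log_mean
  bls <- config$baseline_log_sd
  tissues <- c(config$target_tissue, sprintf("tissue%02d", seq_len(nt - 1L)))
  target <- config$target_tissue
  oth_idx <- 2:nt

  gpc <- config$genes_per_category
  total <- sum(gpc)
  means <- matrix(0, nrow = total, ncol = nt, dimnames = list(NULL, tissues))
  gene_ids <- character(total)
  truth_cat <- character(total)
  truth_groups <- vector("list", total)

  tag <- c(
    tissue_enriched = "ENR", group_enriched = "GRP", tissue_enhanced = "ENH",
    expressed_in_all = "ALL", mixed = "MIX",
    not_detected_target = "NDT", not_detected_any = "NDA"
  )
  row <- 0L
  baseline <- function(n) pmax(rlnorm(n, blm, bls), m * q)

  for (cat in spec_categories()) {
    k <- gpc[[cat]]
    if (k == 0L) next
    idx <- row + seq_len(k)
    gene_ids[idx] <- sprintf("%s%04d", tag[[cat]], seq_len(k))
    truth_cat[idx] <- cat

    if (cat == "tissue_enriched") {
      oth <- matrix(baseline(k * (nt - 1L)), nrow = k)
      means[idx, oth_idx] <- oth
      means[idx, 1L] <- m * f * row_max(oth)
    } else if (cat == "group_enriched") {
      sizes <- resample(p$group_min:p$group_max, k)
      for (i in seq_len(k)) {
        g <- c(1L, resample(oth_idx, sizes[i] - 1L, replace = FALSE))
        outs <- setdiff(seq_len(nt), g)
        means[idx[i], outs] <- runif(length(outs), 0.2 * q, 0.8 * q)
        means[idx[i], g] <- m * f * max(means[idx[i], outs])
        truth_groups[[idx[i]]] <- sort(tissues[g])
      }
    } else if (cat == "tissue_enhanced") {
      beta <- (nt / (f * m) - 1) / p$group_max
      tv <- pmax(rlnorm(k, blm + 1, bls), f * m * q)
      for (i in seq_len(k)) {
        comp <- resample(oth_idx, p$group_max, replace = FALSE)
        means[idx[i], 1L] <- tv[i]
        means[idx[i], comp] <- beta * tv[i]
      }
    } else if (cat == "expressed_in_all") {
      b <- baseline(k)
      means[idx, ] <- b * matrix(runif(k * nt, 1, 1.5), nrow = k)
    } else if (cat == "mixed") {
      s_min <- mixed_min_detected(config)
      sizes <- resample(s_min:(nt - 1L), k)
      b <- baseline(k)
      for (i in seq_len(k)) {
        det <- c(1L, resample(oth_idx, sizes[i] - 1L, replace = FALSE))
        und <- setdiff(seq_len(nt), det)
        means[idx[i], det] <- b[i] * runif(length(det), 1, 1.5)
        means[idx[i], und] <- runif(length(und), 0, q / (2 * m))
      }
    } else if (cat == "not_detected_target") {
      means[idx, 1L] <- runif(k, 0, q / (2 * m))
      means[idx, oth_idx] <- baseline(k) *
        matrix(runif(k * (nt - 1L), 1, 1.5), nrow = k)
    } else if (cat == "not_detected_any") {
      means[idx, ] <- matrix(runif(k * nt, 0, q / (2 * m)), nrow = k)
    }
    row <- row + k
  }

  reps <- config$replicates_per_tissue
  values <- tibble(gene_id = gene_ids)
  sample_ids <- character(0)
  sample_tissues <- character(0)
  for (t in seq_len(nt)) {
    for (r in seq_len(reps)) {
      sid <- paste0(tissues[t], "_r", r)
      noise <- if (config$noise_sigma > 0) {
        exp(rnorm(total, 0, config$noise_sigma))
      } else {
        rep(1, total)
      }
      values[[sid]] <- means[, t] * noise
      sample_ids <- c(sample_ids, sid)
      sample_tissues <- c(sample_tissues, tissues[t])
    }
  }

  structure(
    list(
      expression = fpkm_matrix(
        values,
        tibble(sample_id = sample_ids, tissue = sample_tissues)
      ),
      truth = tibble(
        gene_id = gene_ids,
        category = category_factor(truth_cat),
        group_tissues = truth_groups
      ),
      config = config
    ),
    class = "fpkm_simulation"
  )
}

#' @export
print.fpkm_simulation <- function(x, ...) {
  cat(
    "<fpkm_simulation>", nrow(x$truth), "genes x", x$config$n_tissues,
    "tissues x", x$config$replicates_per_tissue, "replicates",
    "(noise_sigma =", x$config$noise_sigma,
    ", margin =", x$config$margin, ")\n"
  )
  invisible(x)
}

#' Write a simulated study to TSV files
#'
#' Emits the replicate matrix, the sample map and the planted truth so that
#' recovery tests can run file-level, exercising the readers too.
#'
#' @param sim An `fpkm_simulation`.
#' @param dir Output directory (created if needed).
#' @return Named character vector of the three file paths, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  stopifnot(inherits(sim, "fpkm_simulation"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    matrix = file.path(dir, "matrix.tsv"),
    samples = file.path(dir, "samples.tsv"),
    truth = file.path(dir, "truth.tsv")
  )
  write_fpkm_matrix(sim$expression, paths[["matrix"]], paths[["samples"]])
  readr::write_tsv(
    tibble(
      gene_id = sim$truth$gene_id,
      category = as.character(sim$truth$category),
      group_tissues = vapply(
        sim$truth$group_tissues,
        function(g) paste(sort(g %||% character()), collapse = ";"),
        character(1)
      )
    ),
    paths[["truth"]], progress = FALSE
  )
  invisible(paths)
}

#' @rdname write_simulation
#' @param path Path of a truth TSV written by [write_simulation()].
#' @export
read_truth_table <- function(path) {
  raw <- readr::read_tsv(
    path,
    col_types = readr::cols(.default = readr::col_character()),
    show_col_types = FALSE, progress = FALSE
  )
  gt <- ifelse(is.na(raw$group_tissues), "", raw$group_tissues)
  tibble(
    gene_id = raw$gene_id,
    category = category_factor(raw$category),
    group_tissues = lapply(
      gt, function(s) if (nzchar(s)) strsplit(s, ";", fixed = TRUE)[[1]] else NULL
    )
  )
}

#' Fraction of genes whose planted category was recovered
#'
#' Compares a classification against planted truth: a gene counts as
#' recovered when its assigned category equals the planted one and, for
#' group-enriched genes, the assigned tissue group equals the planted group
#' as a set.
#'
#' @param truth Truth tibble (`gene_id`, `category`, `group_tissues`).
#' @param rows Classification tibble over the same genes.
#' @return Fraction in [0, 1].
#' @export
recovery_score <- function(truth, rows) {
  if (!setequal(truth$gene_id, rows$gene_id) ||
      anyDuplicated(truth$gene_id) || anyDuplicated(rows$gene_id)) {
    abort_consistency("`truth` and `rows` must cover exactly the same genes.")
  }
  j <- match(truth$gene_id, rows$gene_id)
  cat_ok <- as.character(truth$category) == as.character(rows$category[j])
  grp_ok <- mapply(
    function(a, b) setequal(a %||% character(), b %||% character()),
    truth$group_tissues, rows$group_tissues[j]
  )
  ok <- cat_ok & (as.character(truth$category) != "group_enriched" | grp_ok)
  mean(ok)
}
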