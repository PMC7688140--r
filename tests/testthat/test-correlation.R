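# Correlation screening, permutation significance, partial correlations and
# the reporting breakdowns.

test_that("duplicate expression samples are averaged on the log scale", {
  E <- matrix(c(2^4 - 1, 2^6 - 1,    # one gene, two duplicate samples
                2^3 - 1, 2^3 - 1), nrow = 2, byrow = TRUE,
              dimnames = list(c("g1", "g2"), c("s1", "s2")))
  meta <- data.frame(sample_id = c("s1", "s2"), slide_id = c("w1", "w1"))
  out <- resolve_duplicates(E, meta)
  expect_identical(colnames(out), "w1")
  expect_equal(out["g1", "w1"], 5)     # mean of log values 4 and 6
  expect_equal(out["g2", "w1"], 3)
})

test_that("duplicate resolution is the identity without duplicates and matches a mean oracle on triplicates", {
  set.seed(2)
  E <- matrix(runif(12, 0, 100), 3, 4,
              dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
  meta <- data.frame(sample_id = paste0("s", 1:4),
                     slide_id = paste0("w", 1:4))
  expect_equal(unname(resolve_duplicates(E, meta)), unname(log2(1 + E)))
  meta3 <- data.frame(sample_id = paste0("s", 1:4),
                      slide_id = c("w1", "w1", "w1", "w2"))
  out <- resolve_duplicates(E, meta3)
  expect_equal(out[, "w1"], rowMeans(log2(1 + E[, 1:3])))
})

test_that("gene filtering keeps the boundary and drops just-below genes", {
  meta <- data.frame(gene = c("ZIC4-like", "HHEX-like", "low"),
                     tissue_of_max = "brain",
                     max_median = c(7.0, 6.84, 2.0))
  expect_identical(gene_filter(meta, 7), "ZIC4-like")
  expect_identical(gene_filter(meta, 0), meta$gene)
})

test_that("gene_meta reports per-tissue medians and the arg-max tissue", {
  set.seed(3)
  x <- matrix(rnorm(40, 5), 4, 10,
              dimnames = list(paste0("g", 1:4), paste0("w", 1:10)))
  tissue <- rep(c("a", "b"), each = 5)
  gm <- gene_meta(x, tissue)
  for (g in 1:4) {
    meds <- c(a = median(x[g, 1:5]), b = median(x[g, 6:10]))
    expect_equal(gm$medians[g, ], meds)
    expect_identical(gm$meta$tissue_of_max[g], names(which.max(meds)))
    expect_equal(gm$meta$max_median[g], max(meds))
  }
})

test_that("Pearson screening matches the textbook two-pass formula and exact cases", {
  set.seed(4)
  f <- matrix(rnorm(40), 10, 4, dimnames = list(paste0("w", 1:10), paste0("0_", 0:3)))
  g <- matrix(rnorm(30), 3, 10, dimnames = list(paste0("g", 1:3), paste0("w", 1:10)))
  g[1, ] <- 2 * f[, 1] + 3                      # exact linear map
  r <- correlate(g, f)
  expect_equal(r["g1", "0_0"], 1, tolerance = 1e-12)
  two_pass <- function(a, b) {
    sum((a - mean(a)) * (b - mean(b))) /
      sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  }
  for (i in 1:3) for (j in 1:4) {
    expect_equal(r[i, j], two_pass(g[i, ], f[, j]), tolerance = 1e-12)
  }
})

test_that("worked 4-sample vectors match hand-computed Pearson", {
  g <- matrix(c(1, 3, 4, 9), 1, dimnames = list("g", paste0("w", 1:4)))
  f <- matrix(c(2, 5, 5, 10), 4, 1, dimnames = list(paste0("w", 1:4), "0_0"))
  expect_equal(correlate(g, f)[1, 1],
               stats::cor(c(1, 3, 4, 9), c(2, 5, 5, 10)), tolerance = 1e-12)
})

test_that("null correlations are small at large n and degenerate inputs give NA", {
  set.seed(5)
  n <- 1000
  g <- matrix(rnorm(n), 1, n, dimnames = list("g", paste0("w", 1:n)))
  f <- matrix(rnorm(n), n, 1, dimnames = list(paste0("w", 1:n), "0_0"))
  expect_lt(abs(correlate(g, f)[1, 1]), 0.1)
  f_const <- matrix(1, n, 1, dimnames = dimnames(f))
  expect_true(is.na(correlate(g, f_const)[1, 1]))
  expect_error(correlate(g[, 1:2, drop = FALSE], f[1:2, , drop = FALSE]),
               "at least 3")
})

test_that("pair selection counts pairs, genes, features and tissues as planted", {
  r <- matrix(0, 3, 4, dimnames = list(c("g1", "g2", "g3"),
                                       c("0_0", "0_1", "1_0", "1_1")))
  r["g1", c("0_0", "0_1", "1_0")] <- c(0.85, -0.9, 0.82)
  r["g2", c("1_0", "1_1")] <- c(0.95, 0.81)
  meta <- data.frame(gene = c("g1", "g2", "g3"),
                     tissue_of_max = c("liver", "testis", "liver"),
                     max_median = c(11, 12, 1))
  sel <- select_significant(r, 0.8, meta, E_T = 10)
  expect_identical(unname(sel$counts), c(5L, 2L, 4L, 2L))
  # signed mode drops the negative pair
  sel_signed <- select_significant(r, 0.8, meta, E_T = 10, use_abs = FALSE)
  expect_identical(unname(sel_signed$counts["pairs"]), 4L)
  # empty input
  sel0 <- select_significant(r * 0 + 0.1, 0.8, meta)
  expect_identical(unname(sel0$counts), c(0L, 0L, 0L, 0L))
})

test_that("selection counts are monotone in both thresholds", {
  set.seed(6)
  r <- matrix(runif(200, -1, 1), 20, 10,
              dimnames = list(paste0("g", 1:20), paste0("0_", 1:10)))
  meta <- data.frame(gene = paste0("g", 1:20), tissue_of_max = "t",
                     max_median = runif(20, 0, 15))
  prev <- NULL
  for (rt in c(0.9, 0.8, 0.7, 0.6)) {
    cur <- select_significant(r, rt, meta, E_T = 7)$counts
    if (!is.null(prev)) expect_true(all(cur >= prev))
    prev <- cur
  }
  prev <- NULL
  for (et in c(12, 9, 6, 0)) {
    cur <- select_significant(r, 0.7, meta, E_T = et)$counts
    if (!is.null(prev)) expect_true(all(cur >= prev))
    prev <- cur
  }
})

test_that("the permutation p of a perfect correlation is exactly 1/1001", {
  set.seed(7)
  g <- rnorm(50)
  out <- permutation_test(g, 2 * g + 1, N = 1000, seed = 1)
  expect_equal(out$p, 1 / 1001)
  expect_false(out$degenerate)
  expect_lt(out$p, 1e-3)
})

test_that("degenerate permutation inputs are flagged with p = 1", {
  out <- permutation_test(rep(1, 10), rnorm(10), N = 100, seed = 1)
  expect_true(out$degenerate)
  expect_equal(out$p, 1)
})

test_that("permutation p-values are reproducible given the seed", {
  g <- rnorm(30); f <- rnorm(30)
  expect_identical(permutation_test(g, f, N = 200, seed = 9)$p,
                   permutation_test(g, f, N = 200, seed = 9)$p)
})

test_that("Fisher transform has its closed-form values and domain", {
  expect_equal(fisher_z(0), 0)
  expect_equal(fisher_z(0.5), 0.5493061, tolerance = 1e-6)
  expect_equal(fisher_z(0.5), atanh(0.5))
  expect_error(fisher_z(1), "\\|r\\| < 1")
})

test_that("reproducibility of identical correlation vectors is 1", {
  set.seed(8)
  r <- runif(50, -0.9, 0.9)
  out <- reproducibility(r, r)
  expect_equal(out$r_scale, 1)
  expect_equal(out$z_scale, 1)
  # noisy second vector: agreement below 1 but positive
  out2 <- reproducibility(r, tanh(atanh(r) + rnorm(50, 0, 0.2)))
  expect_lt(out2$r_scale, 1)
  expect_gt(out2$r_scale, 0.5)
})

test_that("with a single tissue the partial correlation equals the plain correlation", {
  set.seed(9)
  g <- rnorm(40); f <- 0.5 * g + rnorm(40)
  pc <- partial_correlation(g, f, rep("t", 40))
  expect_equal(pc$r, stats::cor(g, f), tolerance = 1e-12)
  expect_equal(pc$p, stats::cor.test(g, f)$p.value, tolerance = 1e-10)
})

test_that("group centering equals explicit residualisation on the tissue design", {
  set.seed(10)
  n <- 60
  tissue <- sample(c("a", "b", "c"), n, replace = TRUE)
  g <- rnorm(n) + as.integer(factor(tissue))
  f <- rnorm(n) + 2 * as.integer(factor(tissue))
  pc <- partial_correlation(g, f, tissue)
  rg <- stats::residuals(stats::lm(g ~ factor(tissue)))
  rf <- stats::residuals(stats::lm(f ~ factor(tissue)))
  expect_equal(pc$r, stats::cor(rg, rf), tolerance = 1e-10)
})

test_that("tissue-mean shifts without within-group signal are conditionally independent", {
  set.seed(11)
  flags <- replicate(25, {
    n <- 300
    tissue <- rep(c("a", "b", "c"), each = 100)
    mu <- c(a = 0, b = 3, c = -2)[tissue]
    g <- mu + rnorm(n)
    f <- 2 * mu + rnorm(n)
    pc <- partial_correlation(g, f, tissue)
    c(small_r = abs(pc$r) < 0.15, not_rejected = pc$p > 0.01)
  })
  expect_gte(mean(flags["small_r", ]), 0.95)
  expect_gte(mean(flags["not_rejected", ]), 0.95)
})

test_that("dependency patterns flag planted indirect pairs and spare direct ones", {
  set.seed(12)
  n <- 300
  tissue <- rep(c("a", "b", "c"), each = 100)
  mu <- c(a = 0, b = 3, c = -2)[tissue]
  u <- rnorm(n)
  log_expr <- rbind(MRK = mu + rnorm(n, 0, 0.7),
                    DIR = u + rnorm(n, 0, 0.5))
  colnames(log_expr) <- paste0("w", 1:n)
  features <- cbind("5_0" = 2 * mu + rnorm(n, 0, 1),
                    "5_1" = u + rnorm(n, 0, 0.5))
  rownames(features) <- colnames(log_expr)
  pairs <- data.frame(gene = c("MRK", "DIR"), feature = c("5_0", "5_1"),
                      r = c(0.9, 0.8), tissue_of_max = "b")
  dp <- dependency_patterns(pairs, log_expr, features,
                            stats::setNames(tissue, colnames(log_expr)),
                            alpha = 0.01)
  expect_true(dp$pairs$gtf_indirect[dp$pairs$gene == "MRK"])
  expect_false(dp$pairs$gtf_indirect[dp$pairs$gene == "DIR"])
  # degenerate threshold: no finite p-value reaches it, so nothing is flagged
  dp0 <- dependency_patterns(pairs, log_expr, features,
                             stats::setNames(tissue, colnames(log_expr)),
                             alpha = Inf)
  expect_false(any(dp0$pairs$gtf_indirect))
})

test_that("layer breakdown counts unique genes per layer, stacked by tissue", {
  pairs <- data.frame(
    gene = c("g1", "g1", "g2", "g3", "g3"),
    feature = c("29_1", "29_7", "29_2", "12_0", "29_9"),
    r = c(0.9, 0.85, 0.8, 0.95, 0.7),
    tissue_of_max = c("liver", "liver", "liver", "testis", "testis"))
  bd <- layer_tissue_breakdown(pairs)
  expect_identical(bd$n_genes[bd$layer == 29 & bd$tissue == "liver"], 2L)
  expect_identical(bd$n_genes[bd$layer == 29 & bd$tissue == "testis"], 1L)
  expect_identical(bd$n_genes[bd$layer == 12 & bd$tissue == "testis"], 1L)
  # a gene hitting several layers counts once per layer
  expect_gte(sum(bd$n_genes), length(unique(pairs$gene)))
  # single-layer table has a single layer bin
  bd29 <- layer_tissue_breakdown(pairs[grepl("^29_", pairs$feature), ])
  expect_identical(unique(bd29$layer), 29L)
})

test_that("annotation subsetting reports each gene's best feature, grouped and sorted", {
  pairs <- data.frame(
    gene = c("g1", "g1", "g2", "g3"),
    feature = c("3_1", "29_5", "7_0", "1_1"),
    r = c(0.7, 0.9, 0.8, 0.75),
    tissue_of_max = c("liver", "liver", "liver", "brain"))
  rep1 <- annotation_subset(pairs, c("g1", "g3"))
  expect_identical(rep1$gene, c("g3", "g1"))         # grouped by tissue
  expect_identical(rep1$feature[rep1$gene == "g1"], "29_5")
  expect_equal(rep1$r[rep1$gene == "g1"], 0.9)
  expect_identical(nrow(annotation_subset(pairs, "absent")), 0L)
  # within-tissue ordering is by descending correlation
  rep2 <- annotation_subset(pairs, c("g1", "g2"))
  expect_identical(rep2$gene, c("g1", "g2"))
})
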