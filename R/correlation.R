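# Genome-wide gene-feature correlation screening: log2(1+E) transform,
# duplicate-sample resolution, expression filtering, Pearson screening with
# permutation significance, Fisher-z reproducibility across datasets,
# partial-correlation conditional-independence analysis and the reporting
# breakdowns (per-layer gene counts, annotation-restricted tables).

#' log2(1 + E) transform of non-negative expression values
#'
#' @param E Non-negative expression matrix or vector.
#' @return `log2(1 + E)`.
#' @export
log_expression <- function(E) {
  if (any(E < 0)) stop("expression values must be non-negative")
  log2(1 + E)
}

#' Resolve duplicate expression samples to one column per slide
#'
#' Samples mapping to the same slide are averaged on the `log2(1+E)` scale.
#' The result is the log-scale genes-by-slides matrix used everywhere
#' downstream.
#'
#' @param expression Raw genes x samples matrix (non-negative).
#' @param sample_meta Data frame with `sample_id` and `slide_id`; rows must
#'   cover the matrix columns.
#' @return Log2-scale genes x slides matrix, one column per slide.
#' @export
resolve_duplicates <- function(expression, sample_meta) {
  stopifnot(all(colnames(expression) %in% sample_meta$sample_id))
  x <- log_expression(expression)
  slide <- sample_meta$slide_id[match(colnames(x), sample_meta$sample_id)]
  out <- t(rowsum(t(x), slide) / as.vector(table(slide)[sort(unique(slide))]))
  out[, unique(slide), drop = FALSE]
}

#' Per-gene expression summary: tissue medians and tissue of maximal expression
#'
#' @param log_expr Log2-scale genes x slides matrix.
#' @param tissue Character vector of tissue labels, one per slide column.
#' @return List with `medians` (genes x tissues matrix of per-tissue medians)
#'   and `meta` (data frame: gene, tissue_of_max, max_median).
#' @export
gene_meta <- function(log_expr, tissue) {
  stopifnot(ncol(log_expr) == length(tissue))
  tis <- sort(unique(tissue))
  med <- vapply(tis, function(tt) {
    apply(log_expr[, tissue == tt, drop = FALSE], 1L, stats::median)
  }, numeric(nrow(log_expr)))
  top <- max.col(med, ties.method = "first")
  list(medians = med,
       meta = data.frame(gene = rownames(log_expr),
                         tissue_of_max = tis[top],
                         max_median = med[cbind(seq_len(nrow(med)), top)],
                         stringsAsFactors = FALSE, row.names = NULL))
}

#' Filter genes by maximal median expression
#'
#' Keeps genes whose highest per-tissue median of `log2(1+E)` is at least
#' `E_T`; genes below the threshold in every tissue are excluded from the
#' correlation screen.
#'
#' @param meta The `meta` data frame from [gene_meta()].
#' @param E_T Log2 expression threshold (0 keeps everything).
#' @return Character vector of retained gene ids.
#' @export
gene_filter <- function(meta, E_T) {
  meta$gene[meta$max_median >= E_T]
}

#' Pairwise gene-feature Pearson correlations
#'
#' Correlates every gene's log2 expression with every feature over the slides
#' shared by both matrices (at least 3 required). Constant genes or features
#' yield `NA` entries, which all counting functions exclude.
#'
#' @param log_expr Log2-scale genes x slides matrix.
#' @param features Slides x features matrix (rownames = slide ids).
#' @return Correlation matrix genes x features.
#' @export
correlate <- function(log_expr, features) {
  shared <- intersect(colnames(log_expr), rownames(features))
  if (length(shared) < 3L) stop("need at least 3 shared slides")
  suppressWarnings(
    stats::cor(t(log_expr[, shared, drop = FALSE]),
               features[shared, , drop = FALSE]))
}

#' Select significantly correlated gene-feature pairs and count them
#'
#' Pairs with `|r| >= R_T` (or `r >= R_T` with `use_abs = FALSE`) among the
#' genes retained by [gene_filter()]. Unique tissues are counted through each
#' gene's tissue of maximal expression.
#'
#' @param r Correlation matrix genes x features.
#' @param R_T Correlation threshold in (0, 1).
#' @param meta `meta` data frame from [gene_meta()] (used for the expression
#'   filter and tissue attribution).
#' @param E_T Expression threshold passed to [gene_filter()].
#' @param use_abs Use `|r|` (default) or signed `r`.
#' @return List with `pairs` (data frame gene, feature, r, tissue_of_max) and
#'   `counts` (pairs, genes, features, tissues).
#' @export
select_significant <- function(r, R_T, meta, E_T = 0, use_abs = TRUE) {
  stopifnot(R_T > 0, R_T < 1)
  keep_genes <- intersect(rownames(r), gene_filter(meta, E_T))
  r <- r[keep_genes, , drop = FALSE]
  stat <- if (use_abs) abs(r) else r
  hit <- which(!is.na(stat) & stat >= R_T, arr.ind = TRUE)
  pairs <- data.frame(
    gene = rownames(r)[hit[, 1L]],
    feature = colnames(r)[hit[, 2L]],
    r = r[hit],
    stringsAsFactors = FALSE)
  pairs$tissue_of_max <- meta$tissue_of_max[match(pairs$gene, meta$gene)]
  pairs <- pairs[order(-abs(pairs$r)), , drop = FALSE]
  rownames(pairs) <- NULL
  list(pairs = pairs,
       counts = c(pairs = nrow(pairs),
                  genes = length(unique(pairs$gene)),
                  features = length(unique(pairs$feature)),
                  tissues = length(unique(pairs$tissue_of_max))))
}

#' Permutation test for one gene-feature correlation
#'
#' Permutes the sample labels of the gene vector `N` times and counts
#' permuted correlations at least as extreme (in absolute value) as the
#' observed one, with the add-one correction
#' `p = (1 + #{|r_perm| >= |r_obs|}) / (N + 1)`; the smallest attainable
#' p-value at `N = 1000` is therefore `1/1001`. Degenerate (constant) inputs
#' return `p = 1` with `degenerate = TRUE`.
#'
#' @param g,f Paired numeric vectors (same length, n >= 3).
#' @param N Number of permutations.
#' @param seed Integer seed.
#' @return List with `r` (observed), `p`, `degenerate`.
#' @export
permutation_test <- function(g, f, N = 1000L, seed = 1L) {
  stopifnot(length(g) == length(f), length(g) >= 3L)
  if (stats::sd(g) == 0 || stats::sd(f) == 0) {
    return(list(r = NA_real_, p = 1, degenerate = TRUE))
  }
  r_obs <- stats::cor(g, f)
  set.seed(seed)
  n <- length(g)
  G <- vapply(seq_len(N), function(i) g[sample.int(n)], numeric(n))
  r_perm <- as.vector(stats::cor(G, f))
  p <- (1 + sum(abs(r_perm) >= abs(r_obs))) / (N + 1)
  list(r = r_obs, p = p, degenerate = FALSE)
}

#' Fisher z-transform of correlation coefficients
#'
#' @param r Correlations with `|r| < 1`.
#' @return `atanh(r)`.
#' @export
fisher_z <- function(r) {
  if (any(abs(r) >= 1, na.rm = TRUE)) stop("fisher_z() requires |r| < 1")
  atanh(r)
}

#' Reproducibility of gene-feature correlations across two datasets
#'
#' Pearson correlation between two vectors of gene-feature correlations
#' computed on different sample sets (e.g. validation vs test), on the raw
#' r scale and on the Fisher-z scale. Pairs with `NA` or `|r| = 1` in either
#' vector are dropped.
#'
#' @param r_a,r_b Correlation vectors over the same (gene, feature) index.
#' @return List with `r_scale` and `z_scale` agreement.
#' @export
reproducibility <- function(r_a, r_b) {
  stopifnot(length(r_a) == length(r_b))
  ok <- is.finite(r_a) & is.finite(r_b) & abs(r_a) < 1 & abs(r_b) < 1
  list(r_scale = stats::cor(r_a[ok], r_b[ok]),
       z_scale = stats::cor(atanh(r_a[ok]), atanh(r_b[ok])))
}

#' Partial correlation of gene and feature given tissue
#'
#' Centres both vectors within tissue groups (identical to residualising on
#' the tissue one-hot design) and correlates the residuals. The
#' conditional-independence p-value uses
#' `t = r * sqrt((n - 2 - k) / (1 - r^2))` with `k = #tissues - 1` indicator
#' covariates, two-sided. With a single tissue this reduces to the plain
#' correlation and test.
#'
#' @param g,f Paired numeric vectors.
#' @param tissue Tissue label per sample.
#' @return List with `r` (partial correlation), `p` (CI test p-value) and
#'   `df` (residual degrees of freedom).
#' @export
partial_correlation <- function(g, f, tissue) {
  stopifnot(length(g) == length(f), length(g) == length(tissue))
  tissue <- as.character(tissue)
  gc <- g - stats::ave(g, tissue)
  fc <- f - stats::ave(f, tissue)
  n <- length(g)
  k <- length(unique(tissue)) - 1L
  df <- n - 2L - k
  if (df < 1L || stats::sd(gc) == 0 || stats::sd(fc) == 0) {
    return(list(r = NA_real_, p = 1, df = df))
  }
  r <- stats::cor(gc, fc)
  if (abs(r) >= 1) return(list(r = r, p = 0, df = df))
  tstat <- r * sqrt(df / (1 - r^2))
  list(r = r, p = 2 * stats::pt(-abs(tstat), df), df = df)
}

# conditional independence of a scalar x and the categorical tissue given a
# scalar covariate: F-test on the tissue indicator block after removing z
.ci_categorical <- function(x, tissue, z) {
  d <- data.frame(x = x, tissue = factor(tissue), z = z)
  if (nlevels(d$tissue) < 2L) return(1)
  fit0 <- stats::lm(x ~ z, data = d)
  fit1 <- stats::lm(x ~ z + tissue, data = d)
  a <- stats::anova(fit0, fit1)
  p <- a[["Pr(>F)"]][2L]
  if (is.na(p)) 1 else p
}

#' Classify indirect dependency patterns of significant pairs
#'
#' For each significant (gene, feature) pair, three conditional-independence
#' tests decide which indirect configurations are compatible with the data:
#' `g-t-f` when gene and feature are independent given tissue (partial
#' correlation test not rejected at `alpha`), `f-g-t` when feature and tissue
#' are independent given the gene, and `g-f-t` when gene and tissue are
#' independent given the feature. The tissue-as-outcome tests use a joint
#' F-test on the tissue indicator block after removing the scalar covariate.
#'
#' @param pairs Pair table from [select_significant()].
#' @param log_expr Log2-scale genes x slides matrix.
#' @param features Slides x features matrix.
#' @param tissue Named (by slide) or slide-ordered tissue labels.
#' @param alpha Significance threshold of the CI tests (default 0.01).
#' @return List with `pairs` (augmented with partial_r, ci_p, and logical
#'   flags gtf_indirect, fgt_indirect, gft_indirect) and `counts`.
#' @export
dependency_patterns <- function(pairs, log_expr, features, tissue,
                                alpha = 0.01) {
  shared <- intersect(colnames(log_expr), rownames(features))
  if (!is.null(names(tissue))) tissue <- tissue[shared]
  stopifnot(length(tissue) == length(shared))
  out <- pairs
  out$partial_r <- NA_real_
  out$ci_p <- NA_real_
  out$fgt_p <- NA_real_
  out$gft_p <- NA_real_
  for (i in seq_len(nrow(pairs))) {
    g <- log_expr[pairs$gene[i], shared]
    f <- features[shared, pairs$feature[i]]
    pc <- partial_correlation(g, f, tissue)
    out$partial_r[i] <- pc$r
    out$ci_p[i] <- pc$p
    out$fgt_p[i] <- .ci_categorical(f, tissue, g)
    out$gft_p[i] <- .ci_categorical(g, tissue, f)
  }
  out$gtf_indirect <- out$ci_p >= alpha
  out$fgt_indirect <- out$fgt_p >= alpha
  out$gft_indirect <- out$gft_p >= alpha
  list(pairs = out,
       counts = c(pairs = nrow(out),
                  gtf = sum(out$gtf_indirect),
                  fgt = sum(out$fgt_indirect),
                  gft = sum(out$gft_indirect)))
}

#' Per-layer counts of correlated genes, broken down by tissue
#'
#' Aggregates the significant pairs of each feature layer and counts the
#' unique genes, stacked by each gene's tissue of maximal expression. A gene
#' correlated with features in several layers contributes to each of them.
#'
#' @param pairs Pair table from [select_significant()] (needs
#'   `tissue_of_max`).
#' @return Data frame with `layer`, `tissue`, `n_genes`.
#' @export
layer_tissue_breakdown <- function(pairs) {
  if (nrow(pairs) == 0L) {
    return(data.frame(layer = integer(), tissue = character(),
                      n_genes = integer()))
  }
  layer <- parse_feature_id(pairs$feature)$layer
  key <- unique(data.frame(layer = layer, gene = pairs$gene,
                           tissue = pairs$tissue_of_max,
                           stringsAsFactors = FALSE))
  agg <- stats::aggregate(gene ~ layer + tissue, data = key, FUN = length)
  names(agg)[names(agg) == "gene"] <- "n_genes"
  agg[order(agg$layer, agg$tissue), , drop = FALSE]
}

#' Annotation-restricted report of best-correlated features per gene
#'
#' Restricts the pair table to annotated genes and reports, per gene, only
#' its best-correlated feature (largest `|r|`), grouped by tissue of maximal
#' expression and sorted by descending correlation within tissue.
#'
#' @param pairs Pair table from [select_significant()].
#' @param annotations Data frame with a `gene` column (and optionally flag
#'   columns), or a character vector of annotated genes.
#' @param meta Optional `meta` from [gene_meta()] to add `max_median`.
#' @return Data frame: gene, tissue_of_max, (max_median), feature, r.
#' @export
annotation_subset <- function(pairs, annotations, meta = NULL) {
  genes <- if (is.data.frame(annotations)) annotations$gene else annotations
  sub <- pairs[pairs$gene %in% genes, , drop = FALSE]
  if (nrow(sub) == 0L) {
    return(data.frame(gene = character(), tissue_of_max = character(),
                      feature = character(), r = numeric()))
  }
  sub <- sub[order(-abs(sub$r)), ]
  best <- sub[!duplicated(sub$gene), , drop = FALSE]
  if (!is.null(meta)) {
    best$max_median <- meta$max_median[match(best$gene, meta$gene)]
  }
  best <- best[order(best$tissue_of_max, -best$r), ]
  rownames(best) <- NULL
  best[, c("gene", "tissue_of_max",
           intersect("max_median", names(best)), "feature", "r")]
}
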