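# The synthetic paired-data generator and its planted ground truth.

test_that("tissue images are deterministic per seed and empty at zero density", {
  lat <- list(cell_radius = 10, cell_density = 40, palette_hue = 0)
  a <- make_tissue_image(1, lat, size = 128, seed = 5)
  b <- make_tissue_image(1, lat, size = 128, seed = 5)
  expect_identical(a, b)
  c <- make_tissue_image(1, lat, size = 128, seed = 6)
  expect_false(identical(a, c))
  empty <- make_tissue_image(1, list(cell_radius = 10, cell_density = 0,
                                     palette_hue = 0), size = 128, seed = 1)
  expect_equal(tissue_fraction(empty), 0)
})

test_that("doubling the cell radius roughly quadruples the mean disk area", {
  # sparse density so disks rarely overlap; area oracle = stained pixels/cells
  area_per_cell <- function(radius) {
    lat <- list(cell_radius = radius, cell_density = 1.5, palette_hue = 0)
    img <- make_tissue_image(1, lat, size = 512, seed = 9)
    n_cells <- round(1.5 * 512^2 / 1e4)
    sum(tissue_fraction(img) * 512^2) / n_cells
  }
  ratio <- area_per_cell(12) / area_per_cell(6)
  expect_gt(ratio, 3)
  expect_lt(ratio, 5)
})

test_that("direct genes hit their planted latent correlation", {
  set.seed(40)
  n <- 200
  lat <- data.frame(slide_id = sprintf("w%03d", 1:n),
                    class = rep(1:2, each = n / 2),
                    tissue = rep(c("a", "b"), each = n / 2),
                    cell_radius = rnorm(n, 10, 2),
                    cell_density = rnorm(n, 40, 5),
                    palette_hue = rnorm(n, 0, 0.02))
  # noiseless direct gene: correlation with its latent is exactly 1
  specs0 <- default_gene_specs(1, 0, 0, n_classes = 2, rho = 1 - 1e-12)
  ex0 <- make_expression(lat, specs0, seed = 1, duplicate_fraction = 0)
  expect_gt(stats::cor(ex0$log_expression[1, ], lat$cell_radius), 0.999999)
  # planted rho = 0.9: empirical correlation within +/- 0.05 in most seeds
  specs <- default_gene_specs(3, 0, 0, n_classes = 2, rho = 0.9)
  hits <- replicate(20, {
    sd <- sample.int(1e6, 1)
    ex <- make_expression(lat, specs, seed = sd, duplicate_fraction = 0)
    r <- stats::cor(ex$log_expression[1, ], lat$cell_radius)
    abs(r - 0.9) <= 0.05
  })
  expect_gte(mean(hits), 0.8)   # nominal 0.95 with binomial slack at 20 reps
})

test_that("null genes stay uncorrelated with every latent", {
  set.seed(41)
  n <- 200
  lat <- data.frame(slide_id = sprintf("w%03d", 1:n),
                    class = 1L, tissue = "a",
                    cell_radius = rnorm(n, 10, 2),
                    cell_density = rnorm(n, 40, 5),
                    palette_hue = rnorm(n, 0, 0.02))
  specs <- default_gene_specs(0, 0, 5, n_classes = 1)
  ok <- replicate(10, {
    ex <- make_expression(lat, specs, seed = sample.int(1e6, 1),
                          duplicate_fraction = 0)
    all(abs(stats::cor(t(ex$log_expression),
                       lat[, c("cell_radius", "cell_density", "palette_hue")])) < 0.2)
  })
  expect_gte(mean(ok), 0.9)
})

test_that("marker genes separate their class and are latent-independent within class", {
  set.seed(42)
  n <- 300
  lat <- data.frame(slide_id = sprintf("w%03d", 1:n),
                    class = rep(1:3, each = 100),
                    tissue = rep(c("a", "b", "c"), each = 100),
                    cell_radius = rnorm(n, 10, 2),
                    cell_density = rnorm(n, 40, 5),
                    palette_hue = rnorm(n, 0, 0.02))
  specs <- default_gene_specs(0, 3, 0, n_classes = 3)
  ex <- make_expression(lat, specs, seed = 2, duplicate_fraction = 0)
  x <- ex$log_expression["MRK01", ]
  expect_gt(mean(x[lat$class == 1]) - mean(x[lat$class != 1]), 3)
  in_class <- lat$class == 1
  expect_lt(abs(stats::cor(x[in_class], lat$cell_radius[in_class])), 0.3)
})

test_that("planted dependency structure separates markers from direct genes under CI testing", {
  # scalar-level check of the generator contract at a sample size where the
  # conditional-independence tests have power: features are the (noisy)
  # latents themselves, so marker genes are indirect (g-t-f) by construction
  # and direct genes are not
  set.seed(43)
  n <- 300
  # latents without class bases here, so the only class-driven features are
  # the marker ones and the direct/indirect pair sets do not overlap
  lat <- data.frame(slide_id = sprintf("w%03d", 1:n),
                    class = rep(1:3, each = 100),
                    tissue = rep(c("a", "b", "c"), each = 100),
                    cell_radius = rnorm(n, 10, 2),
                    cell_density = rnorm(n, 50, 8),
                    palette_hue = rnorm(n, 0.4, 0.05))
  specs <- default_gene_specs(6, 6, 0, n_classes = 3)
  ex <- make_expression(lat, specs, seed = 3, duplicate_fraction = 0)
  z <- function(v) (v - mean(v)) / sd(v)
  features <- cbind("1_0" = z(lat$cell_radius) + rnorm(n, 0, 0.3),
                    "1_1" = z(lat$cell_density) + rnorm(n, 0, 0.3),
                    "1_2" = z(lat$palette_hue) + rnorm(n, 0, 0.3),
                    "2_0" = (lat$class == 1) * 2 + rnorm(n, 0, 0.5),
                    "2_1" = (lat$class == 2) * 2 + rnorm(n, 0, 0.5),
                    "2_2" = (lat$class == 3) * 2 + rnorm(n, 0, 0.5))
  rownames(features) <- lat$slide_id
  colnames(ex$log_expression) <- lat$slide_id
  r <- correlate(ex$log_expression, features)
  meta <- data.frame(gene = rownames(r), tissue_of_max = "a", max_median = 10)
  sel <- select_significant(r, 0.6, meta)
  expect_gt(nrow(sel$pairs), 0)
  dp <- dependency_patterns(sel$pairs, ex$log_expression, features,
                            stats::setNames(lat$tissue, lat$slide_id),
                            alpha = 0.01)
  type <- specs$type[match(dp$pairs$gene, specs$gene)]
  marker_rate <- mean(dp$pairs$gtf_indirect[type == "tissue_marker"])
  direct_rate <- mean(dp$pairs$gtf_indirect[type == "direct"])
  expect_gte(marker_rate, 3 * max(direct_rate, 1e-9))
})

test_that("the default recipe yields the expected dataset arithmetic", {
  ds <- small_dataset()    # 2 classes x 10 slides, 512px, 18 genes
  expect_identical(nrow(ds$slide_manifest), 20L)
  expect_identical(nrow(ds$gene_truth), 18L)
  counts <- table(ds$slide_manifest$split)
  expect_identical(as.integer(counts[c("train", "validation", "test")]),
                   c(12L, 4L, 4L))
  # every slide has at least one expression sample; ~10% have duplicates
  expect_true(all(ds$slide_manifest$slide_id %in% ds$sample_meta$slide_id))
  expect_identical(nrow(ds$sample_meta), 22L)
  # ground truth covers every gene in the expression matrix
  expect_setequal(rownames(ds$expression), ds$gene_truth$gene)
  # the log transform round-trips exactly through the raw scale
  expect_equal(log_expression(ds$expression),
               log_expression(2^log_expression(ds$expression) - 1),
               tolerance = 1e-12)
})

test_that("dataset generation is reproducible for a fixed master seed", {
  d1 <- generate_dataset(n_classes = 2, slides_per_class = 3, image_size = 256,
                         gene_specs = default_gene_specs(2, 2, 2, n_classes = 2),
                         seed = 77, dir = withr::local_tempdir())
  d2 <- generate_dataset(n_classes = 2, slides_per_class = 3, image_size = 256,
                         gene_specs = default_gene_specs(2, 2, 2, n_classes = 2),
                         seed = 77, dir = withr::local_tempdir())
  expect_identical(d1$latents, d2$latents)
  expect_identical(d1$expression, d2$expression)
  expect_identical(d1$slide_manifest$split, d2$slide_manifest$split)
  expect_identical(read_slide_image(d1$slide_manifest$path[1]),
                   read_slide_image(d2$slide_manifest$path[1]))
})
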