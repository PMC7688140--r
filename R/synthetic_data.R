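# Synthetic paired histology/expression data with planted ground truth.
#
# Slides are disk-texture images: randomly placed "cells" (coloured disks on a
# white background). Three continuous per-slide latents -- cell radius, cell
# density and palette hue -- each combine a class-specific base value
# (class-discriminative) with within-class variation, and drive the
# expression of "direct" genes. "Tissue marker" genes track class identity
# only (the indirect g-t-f configuration) and "null" genes track nothing.
# The statistical structure, not visual realism, is what the downstream
# analysis assumes.

#' Default class palette and latent regimes for synthetic tissues
#'
#' @param n_classes Number of tissue classes (>= 2).
#' @return Data frame with one row per class: `class`, `tissue` (label),
#'   `hue`, `sat`, `val`, `radius` (mean cell radius, px), `density`
#'   (mean cells per 1e4 px^2), and within-class standard deviations
#'   `radius_sd`, `density_sd`, `hue_sd`.
#' @export
default_class_palette <- function(n_classes = 4L) {
  stopifnot(n_classes >= 2L)
  k <- seq_len(n_classes)
  data.frame(
    class = k,
    tissue = sprintf("tissue_%d", k),
    hue = (k - 1) / n_classes,
    sat = 0.55,
    val = 0.75,
    radius = 8 + 2 * ((k - 1) %% 4),          # 8, 10, 12, 14 px
    # density per 1e4 px^2 targets ~80% disk coverage (1 - exp(-d*pi*r^2/1e4))
    # so tiles sit comfortably above the 50% tissue filter in every class
    density = round(16000 / (pi * (8 + 2 * ((k - 1) %% 4))^2)),
    radius_sd = 1.0,
    density_sd = 3,
    # within-class hue spread: large enough that colour-sensitive channel
    # sums can recover the latent at desk-scale sample sizes, small enough
    # to stay visually within the class palette
    hue_sd = 0.05)
}

# offsets (as linear-index deltas) of a filled disk of integer radius r
.disk_cache <- new.env(parent = emptyenv())
.disk_offsets <- function(r, H) {
  key <- paste(r, H, sep = "_")
  hit <- .disk_cache[[key]]
  if (!is.null(hit)) return(hit)
  s <- seq.int(-r, r)
  g <- expand.grid(dh = s, dw = s)
  g <- g[g$dh^2 + g$dw^2 <= r^2, ]
  off <- g$dh + g$dw * H
  .disk_cache[[key]] <- off
  off
}

#' Render one synthetic tissue image
#'
#' Draws `round(cell_density * H * W / 1e4)` disks with radii jittered around
#' `cell_radius` and colours around the `palette_hue` latent (hue on the 0-1
#' circle), on a white background. Deterministic given `seed`.
#'
#' @param class Class index (row of `palette`).
#' @param latents List or one-row data frame with `cell_radius`,
#'   `cell_density`, `palette_hue`.
#' @param size Image edge length in pixels.
#' @param seed Integer seed.
#' @param palette Class palette from [default_class_palette()].
#' @return RGB array `[size, size, 3]` in `[0, 1]`.
#' @export
make_tissue_image <- function(class, latents, size = 1024L, seed = 1L,
                              palette = default_class_palette()) {
  stopifnot(size >= 2L)
  pal <- palette[palette$class == class, ]
  stopifnot(nrow(pal) == 1L)
  set.seed(seed)
  H <- as.integer(size)
  n_cells <- max(0L, as.integer(round(latents$cell_density * H * H / 1e4)))
  img <- rep(1, H * H * 3L)   # white background
  if (n_cells > 0L) {
    radii <- pmax(2L, as.integer(round(
      latents$cell_radius * stats::runif(n_cells, 0.8, 1.2))))
    rmax <- max(radii)
    # centres keep a margin so disks never cross the border
    ch <- sample.int(H - 2L * rmax, n_cells, replace = TRUE) + rmax
    cw <- sample.int(H - 2L * rmax, n_cells, replace = TRUE) + rmax
    hue <- (latents$palette_hue + stats::rnorm(n_cells, 0, 0.005)) %% 1
    val <- pmin(pmax(pal$val + stats::rnorm(n_cells, 0, 0.05), 0), 1)
    cols <- t(grDevices::col2rgb(grDevices::hsv(hue, pal$sat, val))) / 255
    HW <- H * H
    for (i in seq_len(n_cells)) {
      idx <- (ch[i] + (cw[i] - 1L) * H) + .disk_offsets(radii[i], H)
      img[idx] <- cols[i, 1]
      img[idx + HW] <- cols[i, 2]
      img[idx + 2L * HW] <- cols[i, 3]
    }
  }
  dim(img) <- c(H, H, 3L)
  img
}

#' Default gene specification table
#'
#' Direct genes track one of the three visual latents with a stated
#' theoretical latent-expression correlation `rho` (slope signs alternate);
#' tissue-marker genes are shifted up in one class; null genes are noise.
#'
#' @param n_direct,n_marker,n_null Gene counts per type.
#' @param n_classes Number of classes markers are spread over.
#' @param rho Theoretical correlation between a direct gene's log expression
#'   and its (standardised) target latent.
#' @return Data frame, one row per gene: `gene`, `type`, `target_latent`,
#'   `marker_class`, `slope`, `intercept`, `sigma`, `rho`.
#' @export
default_gene_specs <- function(n_direct = 20L, n_marker = 20L, n_null = 20L,
                               n_classes = 4L, rho = 0.9) {
  latents <- c("cell_radius", "cell_density", "palette_hue")
  rows <- list()
  if (n_direct > 0L) {
    slope <- rep(c(1, -1), length.out = n_direct)
    sigma <- abs(slope) * sqrt(1 / rho^2 - 1)
    rows$direct <- data.frame(
      gene = sprintf("DIR%02d", seq_len(n_direct)), type = "direct",
      target_latent = rep(latents, length.out = n_direct),
      marker_class = NA_integer_, slope = slope, intercept = 7,
      sigma = sigma, rho = rho * sign(slope))
  }
  if (n_marker > 0L) {
    rows$marker <- data.frame(
      gene = sprintf("MRK%02d", seq_len(n_marker)), type = "tissue_marker",
      target_latent = NA_character_,
      marker_class = rep(seq_len(n_classes), length.out = n_marker),
      slope = NA_real_, intercept = 5, sigma = 0.5, rho = NA_real_)
  }
  if (n_null > 0L) {
    rows$null <- data.frame(
      gene = sprintf("NUL%02d", seq_len(n_null)), type = "null",
      target_latent = NA_character_, marker_class = NA_integer_,
      slope = NA_real_, intercept = 7, sigma = 1, rho = NA_real_)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Simulate expression for a set of slides
#'
#' Builds log2-scale expression `x` per gene and slide -- direct genes
#' `x = intercept + slope * z(latent) + noise`, markers
#' `x = intercept + 4 * [class == marker_class] + noise`, nulls
#' `x = intercept + noise` -- then inverts to raw counts `E = 2^x - 1`
#' (clamping `x` at 0), so the pipeline's `log2(1 + E)` transform is an exact
#' round trip. A fraction of slides receive a duplicate expression sample
#' with fresh noise.
#'
#' @param latent_table Data frame with `slide_id`, `class` and the latent
#'   columns named in the gene specs.
#' @param gene_specs From [default_gene_specs()].
#' @param seed Integer seed.
#' @param duplicate_fraction Fraction of slides with a duplicate sample.
#' @return List with `expression` (raw genes x samples matrix),
#'   `sample_meta` (sample_id, slide_id, tissue) and `log_expression`.
#' @export
make_expression <- function(latent_table, gene_specs, seed = 1L,
                            duplicate_fraction = 0.1) {
  set.seed(seed)
  n <- nrow(latent_table)
  n_dup <- as.integer(round(duplicate_fraction * n))
  dup_idx <- if (n_dup > 0L) sort(sample.int(n, n_dup)) else integer(0)
  cols <- c(seq_len(n), dup_idx)              # slide index per sample column
  sample_id <- sprintf("%s.s%d", latent_table$slide_id[cols],
                       stats::ave(cols, cols, FUN = seq_along))
  zscore <- function(v) (v - mean(v)) / stats::sd(v)
  zl <- list(cell_radius = zscore(latent_table$cell_radius),
             cell_density = zscore(latent_table$cell_density),
             palette_hue = zscore(latent_table$palette_hue))
  x <- matrix(0, nrow(gene_specs), length(cols),
              dimnames = list(gene_specs$gene, sample_id))
  for (g in seq_len(nrow(gene_specs))) {
    sp <- gene_specs[g, ]
    mu <- if (sp$type == "direct") {
      sp$intercept + sp$slope * zl[[sp$target_latent]][cols]
    } else if (sp$type == "tissue_marker") {
      sp$intercept + 4 * (latent_table$class[cols] == sp$marker_class)
    } else {
      rep(sp$intercept, length(cols))
    }
    x[g, ] <- pmax(0, mu + stats::rnorm(length(cols), 0, sp$sigma))
  }
  meta <- data.frame(sample_id = sample_id,
                     slide_id = latent_table$slide_id[cols],
                     tissue = latent_table$tissue[cols],
                     stringsAsFactors = FALSE)
  list(expression = 2^x - 1, log_expression = x, sample_meta = meta)
}

#' Generate a full synthetic paired dataset
#'
#' Default desk-scale recipe: 4 classes, 30 slides per class, 1024x1024
#' images (four 512-pixel tiles each) and 60 genes (20 direct, 20 tissue
#' markers, 20 null). Slide images are written as PNG files under `dir`
#' (they are too large to keep in memory all at once); everything else is
#' returned in memory. Fully deterministic given `seed`.
#'
#' @param n_classes,slides_per_class,image_size Recipe parameters.
#' @param gene_specs Gene specification table; default
#'   [default_gene_specs()] matched to `n_classes`.
#' @param seed Master seed; per-slide seeds are derived from it.
#' @param duplicate_fraction Fraction of slides with duplicate expression
#'   samples (default 0.1).
#' @param dir Output directory for slide PNGs.
#' @param split_fractions Slide-level train/validation/test fractions.
#' @return List with `slide_manifest` (slide_id, path, tissue, split),
#'   `latents`, `expression` (raw), `sample_meta`, `gene_truth`, `palette`.
#' @export
generate_dataset <- function(n_classes = 4L, slides_per_class = 30L,
                             image_size = 1024L, gene_specs = NULL,
                             seed = 1L, duplicate_fraction = 0.1,
                             dir = file.path(tempdir(), "histotx_synth"),
                             split_fractions = c(0.6, 0.2, 0.2)) {
  stopifnot(n_classes >= 2L)
  palette <- default_class_palette(n_classes)
  if (is.null(gene_specs)) gene_specs <- default_gene_specs(n_classes = n_classes)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  n <- n_classes * slides_per_class
  set.seed(seed)
  cls <- rep(seq_len(n_classes), each = slides_per_class)
  latents <- data.frame(
    slide_id = sprintf("SYN%03d", seq_len(n)),
    class = cls,
    tissue = palette$tissue[cls],
    cell_radius = palette$radius[cls] + stats::rnorm(n, 0, palette$radius_sd[cls]),
    cell_density = palette$density[cls] + stats::rnorm(n, 0, palette$density_sd[cls]),
    palette_hue = palette$hue[cls] + stats::rnorm(n, 0, palette$hue_sd[cls]),
    stringsAsFactors = FALSE)
  latents$cell_radius <- pmax(3, latents$cell_radius)
  latents$cell_density <- pmax(5, latents$cell_density)
  paths <- character(n)
  for (i in seq_len(n)) {
    img <- make_tissue_image(cls[i], latents[i, ], size = image_size,
                             seed = seed * 1000L + i, palette = palette)
    paths[i] <- file.path(dir, paste0(latents$slide_id[i], ".png"))
    write_image(img, paths[i])
  }
  expr <- make_expression(latents, gene_specs, seed = seed + 1L,
                          duplicate_fraction = duplicate_fraction)
  manifest <- data.frame(slide_id = latents$slide_id, path = paths,
                         tissue = latents$tissue, stringsAsFactors = FALSE)
  manifest$split <- split_slides(manifest, fractions = split_fractions,
                                 seed = seed + 2L)$split[manifest$slide_id]
  truth <- gene_specs[, c("gene", "type", "target_latent", "marker_class", "rho")]
  list(slide_manifest = manifest, latents = latents,
       expression = expr$expression, sample_meta = expr$sample_meta,
       gene_truth = truth, palette = palette, gene_specs = gene_specs,
       seed = seed, dir = dir)
}
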