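# Slide tiling: non-overlapping 512x512 grid extraction, tissue-fraction
# filtering of near-background tiles, and preparation of model inputs
# (bilinear rescale to 224x224 + ImageNet channel normalisation).
#
# Images are arrays [H, W, 3] with values in [0, 1]. The input raster is
# assumed to be at the target magnification already; pyramid-level selection
# belongs to the reader adapter, not here.

IMAGENET_MEAN <- c(0.485, 0.456, 0.406)
IMAGENET_SD <- c(0.229, 0.224, 0.225)

#' Read a slide image from PNG or TIFF
#'
#' @param path Image file path (`.png`, `.tif`/`.tiff`).
#' @return Array `[H, W, 3]` of doubles in `[0, 1]`.
#' @export
read_slide_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- if (ext == "png") {
    png::readPNG(path)
  } else if (ext %in% c("tif", "tiff")) {
    if (!requireNamespace("tiff", quietly = TRUE)) {
      stop("reading TIFF slides requires the 'tiff' package")
    }
    tiff::readTIFF(path)
  } else {
    stop("unsupported image format: ", ext)
  }
  if (length(dim(img)) == 2L) img <- array(rep(img, 3L), c(dim(img), 3L))
  if (dim(img)[3] > 3L) img <- img[, , 1:3, drop = FALSE]  # drop alpha
  img
}

#' Write an RGB array to PNG
#'
#' @param img Array `[H, W, 3]` in `[0, 1]` (values are clamped).
#' @param path Output path.
#' @export
write_image <- function(img, path) {
  png::writePNG(pmin(pmax(img, 0), 1), path)
  invisible(path)
}

#' Extract non-overlapping grid tiles from a slide image
#'
#' The slide is cut into `tile_size` x `tile_size` windows on a regular grid
#' anchored at the top-left pixel; partial windows at the right/bottom edges
#' (non-square remainders) are discarded, so an image yields
#' `floor(W/T) * floor(H/T)` tiles. Grid coordinates are 0-based with
#' half-open pixel windows, row-major order.
#'
#' @param image Array `[H, W, 3]`, or a `SlideRecord`-style list with
#'   elements `image`, `slide_id`, `tissue`.
#' @param tile_size Tile edge length in pixels (default 512).
#' @param slide_id,tissue Optional metadata attached to each tile.
#' @return List of tiles; each tile is a list with `pixels`, `grid_x`,
#'   `grid_y`, `slide_id`, `label` and (once computed) `tissue_fraction`.
#' @export
extract_tiles <- function(image, tile_size = 512L, slide_id = NA_character_,
                          tissue = NA_character_) {
  if (is.list(image) && !is.null(image$image)) {
    slide_id <- image$slide_id %||% slide_id
    tissue <- image$tissue %||% tissue
    image <- image$image
  }
  stopifnot(length(dim(image)) == 3L, dim(image)[3] == 3L, tile_size >= 1L)
  d <- dim(image)
  nx <- d[2] %/% tile_size   # columns
  ny <- d[1] %/% tile_size   # rows
  if (nx == 0L || ny == 0L) return(list())
  tiles <- vector("list", nx * ny)
  k <- 0L
  for (gy in seq_len(ny) - 1L) {        # row-major: x varies fastest
    for (gx in seq_len(nx) - 1L) {
      k <- k + 1L
      px <- image[gy * tile_size + seq_len(tile_size),
                  gx * tile_size + seq_len(tile_size), , drop = FALSE]
      tiles[[k]] <- list(pixels = px, grid_x = gx, grid_y = gy,
                         slide_id = slide_id, label = tissue)
    }
  }
  tiles
}

#' Fraction of tile pixels classified as tissue
#'
#' A pixel counts as background when all three channels are at least
#' `background_brightness` (near-white, as left by slide scanners outside the
#' section); tissue fraction is the complement. The brightness rule is a
#' simple reproducible criterion; the threshold is exposed.
#'
#' @param tile A tile from [extract_tiles()] or a raw `[H, W, 3]` array.
#' @param background_brightness Background threshold on the 0-255 scale
#'   (default 220).
#' @return Fraction in `[0, 1]`.
#' @export
tissue_fraction <- function(tile, background_brightness = 220) {
  px <- if (is.list(tile)) tile$pixels else tile
  thr <- background_brightness / 255
  mn <- pmin(px[, , 1], px[, , 2], px[, , 3])
  mean(mn < thr)
}

#' Filter tiles by minimum tissue fraction
#'
#' Keeps tiles whose tissue fraction is at least `min_fraction`; tiles with
#' strictly less are removed. Fractions are computed (and memoised on the
#' tile) if absent.
#'
#' @param tiles List of tiles.
#' @param min_fraction Minimum tissue fraction kept (default 0.5).
#' @param background_brightness Passed to [tissue_fraction()].
#' @return Filtered list of tiles, each carrying `tissue_fraction`.
#' @export
filter_tiles <- function(tiles, min_fraction = 0.5,
                         background_brightness = 220) {
  tiles <- lapply(tiles, function(tl) {
    if (is.null(tl$tissue_fraction)) {
      tl$tissue_fraction <- tissue_fraction(tl, background_brightness)
    }
    tl
  })
  keep <- vapply(tiles, function(tl) tl$tissue_fraction >= min_fraction,
                 logical(1))
  tiles[keep]
}

# separable bilinear resize of one channel matrix to size out_h x out_w,
# pixel-centre aligned (same convention as standard image libraries)
.bilinear_channel <- function(m, out_h, out_w) {
  in_h <- nrow(m); in_w <- ncol(m)
  map <- function(n_out, n_in) {
    pos <- (seq_len(n_out) - 0.5) * n_in / n_out - 0.5
    lo <- pmin(pmax(floor(pos), 0), n_in - 1)
    hi <- pmin(lo + 1, n_in - 1)
    w <- pos - lo
    list(lo = lo + 1, hi = hi + 1, w = pmin(pmax(w, 0), 1))
  }
  mh <- map(out_h, in_h); mw <- map(out_w, in_w)
  rows <- m[mh$lo, , drop = FALSE] * (1 - mh$w) + m[mh$hi, , drop = FALSE] * mh$w
  rows[, mw$lo, drop = FALSE] * rep(1 - mw$w, each = out_h) +
    rows[, mw$hi, drop = FALSE] * rep(mw$w, each = out_h)
}

#' Resize an RGB array with bilinear interpolation
#'
#' @param img Array `[H, W, 3]`.
#' @param out_h,out_w Output size in pixels.
#' @return Resized array `[out_h, out_w, 3]`.
#' @export
resize_bilinear <- function(img, out_h, out_w) {
  out <- array(0, c(out_h, out_w, dim(img)[3]))
  for (c in seq_len(dim(img)[3])) {
    out[, , c] <- .bilinear_channel(img[, , c], out_h, out_w)
  }
  out
}

#' Prepare a tile as a normalised model input
#'
#' Bilinearly rescales a square tile to `input_size` (default 224) and applies
#' the standard ImageNet per-channel normalisation
#' `(value - mean_k) / sd_k` on the 0-1 scale.
#'
#' @param tile A tile from [extract_tiles()] or a square `[S, S, 3]` array.
#' @param input_size Output edge length (default 224).
#' @return Normalised array `[input_size, input_size, 3]`.
#' @export
prepare_input <- function(tile, input_size = 224L) {
  px <- if (is.list(tile)) tile$pixels else tile
  d <- dim(px)
  if (d[1] != d[2]) stop("prepare_input() expects a square tile, got ",
                         d[1], "x", d[2])
  if (d[1] != input_size) px <- resize_bilinear(px, input_size, input_size)
  for (c in 1:3) {
    px[, , c] <- (px[, , c] - IMAGENET_MEAN[c]) / IMAGENET_SD[c]
  }
  px
}

#' Invert the ImageNet input normalisation
#'
#' @param x Normalised array `[H, W, 3]`.
#' @return RGB array on the 0-1 scale (clamped).
#' @export
denormalize_input <- function(x) {
  for (c in 1:3) {
    x[, , c] <- x[, , c] * IMAGENET_SD[c] + IMAGENET_MEAN[c]
  }
  pmin(pmax(x, 0), 1)
}

#' Tile every slide of a manifest
#'
#' Convenience wrapper running [extract_tiles()] + [filter_tiles()] over a
#' slide manifest and returning a tile manifest.
#'
#' @param manifest Data frame with columns `slide_id`, `path`, `tissue` (and
#'   optionally `split`).
#' @param tile_size,min_fraction,background_brightness Tiling parameters.
#' @param out_dir Optional directory; when given, kept tiles are written as
#'   `{slide_id}_{gx}_{gy}.png`.
#' @return List with `tiles` (list of kept tiles across slides) and
#'   `manifest` (data frame: slide_id, grid_x, grid_y, tissue_fraction,
#'   label, and `path` when written).
#' @export
tile_slides <- function(manifest, tile_size = 512L, min_fraction = 0.5,
                        background_brightness = 220, out_dir = NULL) {
  stopifnot(all(c("slide_id", "path", "tissue") %in% names(manifest)))
  all_tiles <- list()
  rows <- list()
  for (i in seq_len(nrow(manifest))) {
    img <- read_slide_image(manifest$path[i])
    tiles <- extract_tiles(img, tile_size, manifest$slide_id[i],
                           manifest$tissue[i])
    tiles <- filter_tiles(tiles, min_fraction, background_brightness)
    for (tl in tiles) {
      path <- NA_character_
      if (!is.null(out_dir)) {
        path <- file.path(out_dir, sprintf("%s_%d_%d.png", tl$slide_id,
                                           tl$grid_x, tl$grid_y))
        write_image(tl$pixels, path)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        slide_id = tl$slide_id, grid_x = tl$grid_x, grid_y = tl$grid_y,
        tissue_fraction = tl$tissue_fraction, label = tl$label, path = path,
        stringsAsFactors = FALSE)
    }
    all_tiles <- c(all_tiles, tiles)
  }
  list(tiles = all_tiles,
       manifest = if (length(rows)) do.call(rbind, rows) else
         data.frame(slide_id = character(), grid_x = integer(),
                    grid_y = integer(), tissue_fraction = numeric(),
                    label = character(), path = character()))
}
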