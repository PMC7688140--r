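# Quantification of the location-invariant features f_lz: forward
# propagation with activation capture, spatial aggregation per channel
# (f_lz(X) = sum over x,y of Y_lzxy(X)^p), and summation over a slide's
# tiles (f_lz(W) = sum over tiles X of f_lz(X)).

#' Feature vector of one prepared tile
#'
#' Runs the tile through the network in inference mode, captures the
#' activation array of every feature-part layer and aggregates each channel
#' over its spatial positions with exponent `p` (default 1, the plain
#' spatial sum). Non-integer `p` is rejected on layers that can produce
#' negative activations.
#'
#' @param model A `histotx_model` built from an architecture with a
#'   feature-part layer table (e.g. `"tiny"`).
#' @param tile_input Prepared input array (see [prepare_input()]).
#' @param p Aggregation exponent (>= 1).
#' @return Named numeric vector over all enumerated feature ids `"l_z"`.
#' @export
tile_features <- function(model, tile_input, p = 1) {
  stopifnot(p >= 1)
  flayers <- model$feature_layers
  if (is.null(flayers)) stop("model carries no feature-part layer table")
  if (p != as.integer(p) && any(!flayers$nonneg_output)) {
    stop("non-integer p is undefined on layers with negative activations")
  }
  n_feat_layers <- nrow(flayers)
  fw <- nn_forward(model, tile_input, capture = TRUE, upto = n_feat_layers)
  out <- lapply(seq_len(n_feat_layers), function(i) {
    a <- fw$acts[[i]]
    if (p != 1) a <- a^p
    v <- apply(a, 3L, sum)
    names(v) <- paste0(flayers$index[i], "_", seq_along(v) - 1L)
    v
  })
  unlist(out[flayers$eligible], use.names = TRUE)
}

#' Slide feature vector: sum of its tile feature vectors
#'
#' @param tile_feature_vectors List of (or matrix of row-wise) per-tile
#'   feature vectors of identical layout.
#' @return Per-feature sum across tiles.
#' @export
slide_features <- function(tile_feature_vectors) {
  if (is.matrix(tile_feature_vectors)) {
    stopifnot(nrow(tile_feature_vectors) >= 1L)
    return(colSums(tile_feature_vectors))
  }
  stopifnot(length(tile_feature_vectors) >= 1L)
  Reduce(`+`, tile_feature_vectors)
}

#' Build the samples-by-features matrix over a set of slides
#'
#' For every slide: tile the image, drop low-tissue tiles, prepare each kept
#' tile, quantify its features and sum over tiles. Slides whose tiles are all
#' filtered away are dropped with a warning. Deterministic given the model
#' weights.
#'
#' @param model A trained `histotx_model`.
#' @param slide_manifest Data frame with `slide_id`, `path`, `tissue`.
#' @param p Aggregation exponent.
#' @param tile_size,min_fraction Tiling parameters (see [filter_tiles()]).
#' @param tile_level Also return the per-tile feature matrix.
#' @return List with `features` (matrix slides x features, rownames =
#'   slide_id), and when `tile_level = TRUE` also `tile_features` plus
#'   `tile_info` (slide_id, grid_x, grid_y per row).
#' @export
build_feature_matrix <- function(model, slide_manifest, p = 1,
                                 tile_size = 512L, min_fraction = 0.5,
                                 tile_level = FALSE) {
  rows <- list()
  trows <- list()
  tinfo <- list()
  for (i in seq_len(nrow(slide_manifest))) {
    sid <- slide_manifest$slide_id[i]
    img <- read_slide_image(slide_manifest$path[i])
    tiles <- filter_tiles(extract_tiles(img, tile_size, slide_id = sid),
                          min_fraction)
    if (length(tiles) == 0L) {
      warning("slide '", sid, "' has no tiles above the tissue threshold; dropped")
      next
    }
    tf <- lapply(tiles, function(tl) {
      tile_features(model, prepare_input(tl$pixels), p = p)
    })
    rows[[sid]] <- slide_features(tf)
    if (tile_level) {
      for (j in seq_along(tiles)) {
        trows[[length(trows) + 1L]] <- tf[[j]]
        tinfo[[length(tinfo) + 1L]] <- data.frame(
          slide_id = sid, grid_x = tiles[[j]]$grid_x,
          grid_y = tiles[[j]]$grid_y, stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0L) stop("no slide produced any usable tile")
  features <- do.call(rbind, rows)
  out <- list(features = features)
  if (tile_level) {
    out$tile_features <- do.call(rbind, trows)
    out$tile_info <- do.call(rbind, tinfo)
  }
  out
}

#' Write / read a feature matrix as TSV with "l_z" column headers
#'
#' @param features Matrix with slide_id rownames.
#' @param path TSV path.
#' @return `read_feature_matrix` returns the matrix.
#' @export
write_feature_matrix <- function(features, path) {
  df <- data.frame(slide_id = rownames(features), features,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_matrix
#' @export
read_feature_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}
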