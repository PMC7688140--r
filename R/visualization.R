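# Feature visualization: guided backpropagation of a feature scalar onto an
# input tile, input-free activation maximization by regularised gradient
# ascent, and selection of representative high-activation tiles.
#
# The feature scalar visualised is the aggregated f_lz (spatial sum, p = 1),
# the same quantity that is correlated with gene expression.

# resolve a feature reference to (engine layer position, channel+1)
.resolve_feature <- function(model, feature) {
  if (is.character(feature)) feature <- unlist(parse_feature_id(feature))
  layer0 <- as.integer(feature[1])
  chan0 <- as.integer(feature[2])
  pos <- layer0 + 1L
  if (pos > length(model$layers)) {
    stop("feature layer ", layer0, " is beyond the network depth")
  }
  list(pos = pos, chan = chan0 + 1L)
}

#' Guided backpropagation of a feature onto an input image
#'
#' Backpropagates the feature scalar `f_lz` (spatial sum of channel `z` in
#' layer `l`) to the input pixels. At every ReLU the propagated gradient is
#' zeroed both where the forward input was non-positive and where the
#' incoming gradient is negative; all other layers use their standard
#' gradients. On a network without ReLUs this equals the plain gradient.
#'
#' @param model A `histotx_model`.
#' @param feature Feature id `"l_z"` or an integer pair `(layer, channel)`
#'   (both 0-based; the layer indexes `model$layers`).
#' @param input Prepared input array.
#' @param guided Set `FALSE` for the plain gradient.
#' @return Gradient array shaped like `input` (class `histotx_gradient`).
#' @export
guided_backprop <- function(model, feature, input, guided = TRUE) {
  fr <- .resolve_feature(model, feature)
  fw <- nn_forward(model, input, keep_cache = TRUE, upto = fr$pos)
  act <- fw$out
  if (length(dim(act)) != 3L || fr$chan > dim(act)[3]) {
    stop("channel ", fr$chan - 1L, " not present at layer ", fr$pos - 1L)
  }
  dy <- array(0, dim(act))
  dy[, , fr$chan] <- 1
  bw <- nn_backward(model, fw$cache, dy, from = fr$pos, guided = guided,
                    need_param_grads = FALSE, need_input_grad = TRUE)
  structure(bw$dx, class = "histotx_gradient")
}

#' Render a signed gradient image as displayable RGB
#'
#' Affine rescale centred at mid-gray: zero gradient maps to 0.5 and the
#' largest absolute value to the range limits, so sign symmetry is preserved.
#' An all-zero gradient renders uniform mid-gray.
#'
#' @param grad Gradient array from [guided_backprop()].
#' @return RGB array in `[0, 1]`.
#' @export
render_gradient <- function(grad) {
  grad <- unclass(grad)
  stopifnot(all(is.finite(grad)))
  m <- max(abs(grad))
  if (m == 0) return(array(0.5, dim(grad)))
  0.5 + grad / (2 * m)
}

#' Configuration for activation maximization
#'
#' @param steps Number of ascent steps.
#' @param step_size Step length in normalised input space.
#' @param seed Seed for the random initial image and jitter.
#' @param jitter Maximum circular pixel shift applied each step.
#' @param blur_every,blur_sigma Gaussian blur regulariser cadence and width.
#' @param l2_weight Weight decay pulling pixels toward zero.
#' @return A `histotx_synth_config` list.
#' @export
synth_image_config <- function(steps = 256L, step_size = 0.05, seed = 7L,
                               jitter = 2L, blur_every = 4L, blur_sigma = 0.5,
                               l2_weight = 1e-4) {
  stopifnot(steps >= 1L)
  structure(list(steps = as.integer(steps), step_size = step_size,
                 seed = as.integer(seed), jitter = as.integer(jitter),
                 blur_every = as.integer(blur_every), blur_sigma = blur_sigma,
                 l2_weight = l2_weight),
            class = "histotx_synth_config")
}

.circular_shift <- function(x, dh, dw) {
  d <- dim(x)
  if (dh != 0) x <- x[(seq_len(d[1]) - 1L - dh) %% d[1] + 1L, , , drop = FALSE]
  if (dw != 0) x <- x[, (seq_len(d[2]) - 1L - dw) %% d[2] + 1L, , drop = FALSE]
  x
}

.feature_value <- function(model, x, fr) {
  act <- nn_forward(model, x, upto = fr$pos)$out
  sum(act[, , fr$chan])
}

#' Synthesize an input image maximizing a feature
#'
#' Gradient ascent on the aggregated feature scalar from a random normal
#' initial image, with the usual regularisers: per-step random circular
#' jitter, periodic Gaussian blur, L2 shrinkage, and clamping to the
#' normalised range of valid 8-bit inputs. Deterministic given the config
#' seed. Aborts if the ascent produces non-finite values.
#'
#' @param model A `histotx_model`.
#' @param feature Feature id `"l_z"` or `(layer, channel)` pair.
#' @param config A [synth_image_config()].
#' @param input_size Image edge length (default the model input, 224).
#' @return List with `image` (normalised), `rgb` (de-normalised `[0,1]`),
#'   `trajectory` (feature value per step), `initial_value`, `final_value`.
#' @export
activation_maximization <- function(model, feature,
                                    config = synth_image_config(),
                                    input_size = 224L) {
  fr <- .resolve_feature(model, feature)
  lo <- (0 - IMAGENET_MEAN) / IMAGENET_SD
  hi <- (1 - IMAGENET_MEAN) / IMAGENET_SD
  set.seed(config$seed)
  x <- array(stats::rnorm(input_size * input_size * 3L, 0, 0.1),
             c(input_size, input_size, 3L))
  initial_value <- .feature_value(model, x, fr)
  trajectory <- numeric(config$steps)
  for (step in seq_len(config$steps)) {
    if (config$jitter > 0L) {
      sh <- sample.int(2L * config$jitter + 1L, 2L) - config$jitter - 1L
      x <- .circular_shift(x, sh[1], sh[2])
    }
    fw <- nn_forward(model, x, keep_cache = TRUE, upto = fr$pos)
    dy <- array(0, dim(fw$out))
    dy[, , fr$chan] <- 1
    bw <- nn_backward(model, fw$cache, dy, from = fr$pos,
                      need_param_grads = FALSE, need_input_grad = TRUE)
    g <- bw$dx / (sqrt(mean(bw$dx^2)) + 1e-8)
    x <- (x + config$step_size * g) * (1 - config$l2_weight)
    if (config$blur_every > 0L && step %% config$blur_every == 0L) {
      for (c in 1:3) {
        x[, , c] <- EBImage::gblur(x[, , c], sigma = config$blur_sigma)
      }
    }
    for (c in 1:3) x[, , c] <- pmin(pmax(x[, , c], lo[c]), hi[c])
    trajectory[step] <- .feature_value(model, x, fr)
    if (!all(is.finite(x))) {
      stop("activation maximization diverged at step ", step,
           " (non-finite pixels); reduce step_size")
    }
  }
  list(image = x, rgb = denormalize_input(x), trajectory = trajectory,
       initial_value = initial_value,
       final_value = trajectory[config$steps])
}

#' Select representative high-activation tiles for a feature
#'
#' Top-`k` tiles by tile-level feature value, subject to at most
#' `per_slide_cap` tiles from any one slide. Ties are broken
#' deterministically by tile identity (slide_id, grid_y, grid_x).
#'
#' @param tile_features Tiles x features matrix.
#' @param tile_info Data frame (one row per tile) with `slide_id`, `grid_x`,
#'   `grid_y`.
#' @param feature Feature id (column of `tile_features`).
#' @param k Number of tiles to select.
#' @param per_slide_cap Maximum tiles per slide.
#' @return `tile_info` rows of the selected tiles, with a `value` column,
#'   in descending value order.
#' @export
select_representative_tiles <- function(tile_features, tile_info, feature,
                                        k = 8L, per_slide_cap = 2L) {
  stopifnot(feature %in% colnames(tile_features),
            nrow(tile_features) == nrow(tile_info))
  v <- tile_features[, feature]
  ord <- order(-v, tile_info$slide_id, tile_info$grid_y, tile_info$grid_x)
  taken <- integer(0)
  per_slide <- table(character(0))
  count <- stats::setNames(integer(0), character(0))
  for (i in ord) {
    sid <- tile_info$slide_id[i]
    used <- if (sid %in% names(count)) count[[sid]] else 0L
    if (used >= per_slide_cap) next
    taken <- c(taken, i)
    count[sid] <- used + 1L
    if (length(taken) >= k) break
  }
  out <- tile_info[taken, , drop = FALSE]
  out$value <- v[taken]
  rownames(out) <- NULL
  out
}
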