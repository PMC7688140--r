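# Minimal dense CNN engine: forward propagation with activation capture,
# reverse-mode gradients (standard and guided through ReLUs), and SGD updates.
# Convolutions are evaluated as im2col patch-matrix products so the heavy
# lifting happens in BLAS. Arrays are [height, width, channel] doubles.

# im2col index matrices are deterministic functions of the padded geometry;
# cache them per (Hp, Wp, C, k, stride) since the same shapes recur every tile.
.idx_cache <- new.env(parent = emptyenv())

conv_patch_index <- function(Hp, Wp, C, k, stride) {
  key <- paste(Hp, Wp, C, k, stride, sep = "_")
  hit <- .idx_cache[[key]]
  if (!is.null(hit)) return(hit)
  outH <- (Hp - k) %/% stride + 1L
  outW <- (Wp - k) %/% stride + 1L
  base_h <- (seq_len(outH) - 1L) * stride            # varies fastest
  base_w <- (seq_len(outW) - 1L) * stride
  base <- rep(base_h, times = outW) + rep(base_w, each = outH) * Hp
  off <- expand.grid(dh = seq_len(k), dw = seq_len(k), cc = seq_len(C))
  offset <- off$dh + (off$dw - 1L) * Hp + (off$cc - 1L) * Hp * Wp
  idx <- outer(base, offset, "+")
  storage.mode(idx) <- "integer"
  out <- list(idx = idx, idxvec = as.vector(idx), J = length(offset),
              outH = outH, outW = outW)
  .idx_cache[[key]] <- out
  out
}

pad_image <- function(x, pad) {
  if (pad == 0L) return(x)
  d <- dim(x)
  xp <- array(0, c(d[1] + 2L * pad, d[2] + 2L * pad, d[3]))
  xp[pad + seq_len(d[1]), pad + seq_len(d[2]), ] <- x
  xp
}

conv_forward <- function(layer, x) {
  d <- dim(x)
  stopifnot(d[3] == layer$in_ch)
  xp <- pad_image(x, layer$pad)
  dp <- dim(xp)
  g <- conv_patch_index(dp[1], dp[2], dp[3], layer$k, layer$stride)
  P <- xp[g$idxvec]
  dim(P) <- c(length(P) %/% g$J, g$J)
  Y <- P %*% layer$W
  Y <- Y + matrix(layer$b, nrow(Y), length(layer$b), byrow = TRUE)
  dim(Y) <- c(g$outH, g$outW, layer$out_ch)
  list(y = Y, cache = list(P = P, in_dim = d, pad_dim = dp, geom = g))
}

conv_backward <- function(layer, cache, dy, need_param_grads = TRUE,
                          need_input_grad = TRUE) {
  g <- cache$geom
  L <- nrow(g$idx)
  dYm <- matrix(dy, L, layer$out_ch)
  out <- list()
  if (need_param_grads) {
    out$dW <- crossprod(cache$P, dYm)
    out$db <- colSums(dYm)
  }
  if (need_input_grad) {
    dP <- dYm %*% t(layer$W)
    dxp <- numeric(prod(cache$pad_dim))
    # within one patch-offset column the target positions are distinct,
    # so column-wise scatter-add is exact
    for (j in seq_len(ncol(g$idx))) {
      jj <- g$idx[, j]
      dxp[jj] <- dxp[jj] + dP[, j]
    }
    dim(dxp) <- cache$pad_dim
    p <- layer$pad
    d <- cache$in_dim
    out$dx <- if (p > 0L) dxp[p + seq_len(d[1]), p + seq_len(d[2]), , drop = FALSE] else dxp
    dim(out$dx) <- d
  }
  out
}

pool_forward <- function(x, p, kind = c("max", "avg")) {
  kind <- match.arg(kind)
  d <- dim(x)
  stopifnot(d[1] %% p == 0L, d[2] %% p == 0L)
  best <- NULL
  winner <- NULL
  sid <- 0L
  for (j in seq_len(p)) for (i in seq_len(p)) {
    sid <- sid + 1L
    sub <- x[seq.int(i, d[1], p), seq.int(j, d[2], p), , drop = FALSE]
    if (is.null(best)) {
      best <- sub
      if (kind == "max") winner <- array(1L, dim(sub))
    } else if (kind == "max") {
      upd <- sub > best
      best[upd] <- sub[upd]
      winner[upd] <- sid
    } else {
      best <- best + sub
    }
  }
  if (kind == "avg") best <- best / (p * p)
  list(y = best, winner = winner, in_dim = d)
}

pool_backward <- function(cache, dy, p, kind) {
  d <- cache$in_dim
  dx <- array(0, d)
  sid <- 0L
  for (j in seq_len(p)) for (i in seq_len(p)) {
    sid <- sid + 1L
    if (kind == "max") {
      sub <- array(0, dim(dy))
      m <- cache$winner == sid
      sub[m] <- dy[m]
      dx[seq.int(i, d[1], p), seq.int(j, d[2], p), ] <- sub
    } else {
      dx[seq.int(i, d[1], p), seq.int(j, d[2], p), ] <- dy / (p * p)
    }
  }
  dx
}

#' Instantiate a trainable network from an architecture specification
#'
#' Materialises weight tensors for every parametric layer of an architecture
#' built by [build_architecture()]. Convolution and linear weights use
#' He-style normal initialisation scaled by fan-in; biases start at zero.
#' Only desk-scale architectures (the bundled `"tiny"` network or custom layer
#' lists) are practical to instantiate on a CPU; the catalog entries for the
#' published large architectures are intended for counting, not training.
#'
#' @param arch An architecture object from [build_architecture()], or a raw
#'   list of layer descriptors.
#' @param seed Integer seed controlling weight initialisation.
#' @return An object of class `histotx_model`: the layer list with weights
#'   attached, plus the architecture metadata needed for feature indexing.
#' @export
instantiate_model <- function(arch, seed = 1L) {
  layers <- if (inherits(arch, "histotx_architecture")) arch$instantiable else arch
  if (is.null(layers)) {
    stop("architecture '", arch$name, "' has no instantiable layer list; ",
         "only desk-scale architectures can be materialised")
  }
  set.seed(seed)
  layers <- lapply(layers, function(ly) {
    if (ly$kind == "conv") {
      fan_in <- ly$k * ly$k * ly$in_ch
      ly$W <- matrix(stats::rnorm(fan_in * ly$out_ch, sd = sqrt(2 / fan_in)),
                     fan_in, ly$out_ch)
      ly$b <- numeric(ly$out_ch)
    } else if (ly$kind == "linear") {
      ly$W <- matrix(stats::rnorm(ly$d_in * ly$d_out, sd = sqrt(2 / ly$d_in)),
                     ly$d_in, ly$d_out)
      ly$b <- numeric(ly$d_out)
    }
    ly
  })
  structure(
    list(layers = layers,
         name = if (inherits(arch, "histotx_architecture")) arch$name else "custom",
         num_classes = if (inherits(arch, "histotx_architecture")) arch$num_classes else NA_integer_,
         input_size = attr(layers, "input_size") %||%
           (if (inherits(arch, "histotx_architecture")) arch$input_size else NULL),
         feature_layers = if (inherits(arch, "histotx_architecture")) arch$layers else NULL),
    class = "histotx_model")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Forward propagation with optional activation capture
#'
#' Runs an image through a [instantiate_model()] network. With
#' `capture = TRUE` the output array of every layer is retained, which is how
#' the location-invariant features f_lz are quantified downstream.
#'
#' @param model A `histotx_model`.
#' @param x Input array `[H, W, C]` (already normalised).
#' @param train Logical; enables dropout sampling.
#' @param capture Keep every layer's output activation array.
#' @param keep_cache Keep the intermediates needed for a backward pass.
#' @param upto Stop after this layer index (1-based into `model$layers`).
#' @return A list with `out` (final output: class scores once the head is
#'   reached), `acts` (per-layer activations when captured) and `cache`.
#' @export
nn_forward <- function(model, x, train = FALSE, capture = FALSE,
                       keep_cache = FALSE, upto = NULL) {
  layers <- model$layers
  n <- if (is.null(upto)) length(layers) else upto
  acts <- if (capture) vector("list", n) else NULL
  cache <- if (keep_cache) vector("list", n) else NULL
  for (i in seq_len(n)) {
    ly <- layers[[i]]
    if (ly$kind == "conv") {
      cf <- conv_forward(ly, x)
      x <- cf$y
      if (keep_cache) cache[[i]] <- cf$cache
    } else if (ly$kind == "relu") {
      mask <- x > 0
      if (keep_cache) cache[[i]] <- list(mask = mask)
      x <- x * mask
    } else if (ly$kind == "maxpool") {
      pf <- pool_forward(x, ly$p, "max")
      x <- pf$y
      if (keep_cache) cache[[i]] <- pf
    } else if (ly$kind == "avgpool") {
      pf <- pool_forward(x, ly$p, "avg")
      x <- pf$y
      if (keep_cache) cache[[i]] <- pf
    } else if (ly$kind == "flatten") {
      if (keep_cache) cache[[i]] <- list(in_dim = dim(x))
      x <- as.numeric(x)
    } else if (ly$kind == "dropout") {
      if (train && ly$rate > 0) {
        keep <- stats::rbinom(length(x), 1L, 1 - ly$rate) / (1 - ly$rate)
        if (keep_cache) cache[[i]] <- list(keep = keep)
        x <- x * keep
      } else if (keep_cache) cache[[i]] <- list(keep = NULL)
    } else if (ly$kind == "linear") {
      xv <- as.numeric(x)
      if (keep_cache) cache[[i]] <- list(xv = xv)
      x <- drop(xv %*% ly$W) + ly$b
    } else {
      stop("unknown layer kind: ", ly$kind)
    }
    if (capture) acts[[i]] <- x
  }
  list(out = x, acts = acts, cache = cache)
}

#' Reverse-mode gradients through the network
#'
#' Backpropagates a gradient seeded at any layer down to the parameters and
#' (optionally) the input pixels. `guided = TRUE` applies the guided rule at
#' every ReLU: the propagated gradient is zeroed both where the forward input
#' was non-positive and where the incoming gradient is negative.
#'
#' @param model A `histotx_model`.
#' @param cache Cache list from `nn_forward(..., keep_cache = TRUE)`.
#' @param dy Gradient seed, shaped like the output of layer `from`.
#' @param from Layer index the seed applies to (default: last layer run).
#' @param guided Use the guided ReLU masking rule.
#' @param need_param_grads Accumulate weight/bias gradients.
#' @param need_input_grad Propagate all the way to the input image.
#' @return A list with `dx` (input gradient, if requested) and `grads`
#'   (per-layer lists with `dW`/`db` for parametric layers).
#' @export
nn_backward <- function(model, cache, dy, from = NULL, guided = FALSE,
                        need_param_grads = TRUE, need_input_grad = FALSE) {
  layers <- model$layers
  if (is.null(from)) from <- max(which(!vapply(cache, is.null, logical(1))))
  grads <- vector("list", length(layers))
  for (i in seq.int(from, 1L)) {
    ly <- layers[[i]]
    last <- i == 1L
    want_dx <- need_input_grad || !last
    if (ly$kind == "conv") {
      g <- conv_backward(ly, cache[[i]], dy, need_param_grads, want_dx)
      if (need_param_grads) grads[[i]] <- list(dW = g$dW, db = g$db)
      if (!want_dx) return(list(dx = NULL, grads = grads))
      dy <- g$dx
    } else if (ly$kind == "relu") {
      dy <- dy * cache[[i]]$mask
      if (guided) dy <- dy * (dy > 0)
    } else if (ly$kind == "maxpool") {
      dy <- pool_backward(cache[[i]], dy, ly$p, "max")
    } else if (ly$kind == "avgpool") {
      dy <- pool_backward(cache[[i]], dy, ly$p, "avg")
    } else if (ly$kind == "flatten") {
      dim(dy) <- cache[[i]]$in_dim
    } else if (ly$kind == "dropout") {
      if (!is.null(cache[[i]]$keep)) dy <- dy * cache[[i]]$keep
    } else if (ly$kind == "linear") {
      if (need_param_grads) {
        grads[[i]] <- list(dW = outer(cache[[i]]$xv, dy), db = dy)
      }
      dy <- drop(ly$W %*% dy)
    }
  }
  list(dx = dy, grads = grads)
}

# softmax cross-entropy on a logit vector; returns loss, probs, dlogits
softmax_xent <- function(logits, label) {
  z <- logits - max(logits)
  p <- exp(z) / sum(exp(z))
  d <- p
  d[label] <- d[label] - 1
  list(loss = -log(max(p[label], 1e-12)), probs = p, dlogits = d)
}

# one momentum-SGD update in place; grads accumulated over a mini-batch
sgd_update <- function(model, grads, velocity, lr, momentum = 0.9,
                       weight_decay = 1e-4, batch_size = 1L) {
  for (i in seq_along(model$layers)) {
    g <- grads[[i]]
    if (is.null(g)) next
    ly <- model$layers[[i]]
    dW <- g$dW / batch_size + weight_decay * ly$W
    db <- g$db / batch_size
    if (is.null(velocity[[i]])) {
      velocity[[i]] <- list(W = dW * 0, b = db * 0)
    }
    velocity[[i]]$W <- momentum * velocity[[i]]$W + dW
    velocity[[i]]$b <- momentum * velocity[[i]]$b + db
    model$layers[[i]]$W <- ly$W - lr * velocity[[i]]$W
    model$layers[[i]]$b <- ly$b - lr * velocity[[i]]$b
  }
  list(model = model, velocity = velocity)
}

# element-wise add of two grad accumulators
accumulate_grads <- function(total, g) {
  if (is.null(total)) return(g)
  for (i in seq_along(g)) {
    if (is.null(g[[i]])) next
    if (is.null(total[[i]])) {
      total[[i]] <- g[[i]]
    } else {
      total[[i]]$dW <- total[[i]]$dW + g[[i]]$dW
      total[[i]]$db <- total[[i]]$db + g[[i]]$db
    }
  }
  total
}
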