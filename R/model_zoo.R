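# Architecture catalog: layer tables, feature enumeration and trainable
# parameter counts for the convolutional network families used in the
# histology classifier study, plus the desk-scale "tiny" network that this
# package can actually train on a CPU.
#
# A "feature" is one (layer, channel) pair l_z of the feature-extraction part.
# Conventions per family:
#   * AlexNet / VGG (+bn): every conv, batchnorm, ReLU and pooling layer of
#     the feature part contributes its channels (dropout appears only in
#     heads and carries no activation channels).
#   * ResNet34: only layers not skipped over by residual additions count:
#     the stem ReLU/maxpool and each block's post-addition ReLU.
#   * Inception v3: only elementary layers with non-negative outputs (ReLU,
#     max/avg pooling) off the auxiliary branch; concatenated block outputs
#     are redundant re-listings of their inputs and are not counted.

SUPPORTED_ARCHITECTURES <- c(
  "alexnet", "vgg11", "vgg13", "vgg16", "vgg19",
  "vgg11_bn", "vgg13_bn", "vgg16_bn", "vgg19_bn",
  "resnet34", "inception_v3", "vgg16_1fc", "vgg16_avg1fc", "tiny")

.layer_row <- function(kind, channels, nonneg = FALSE, aux = FALSE,
                       skipped = FALSE, eligible = TRUE) {
  data.frame(kind = kind, channels = as.integer(channels),
             nonneg_output = nonneg, on_aux_branch = aux,
             skipped = skipped, eligible = eligible,
             stringsAsFactors = FALSE)
}

.param_row <- function(name, count) {
  data.frame(name = name, count = as.numeric(count), stringsAsFactors = FALSE)
}

.finish_layers <- function(rows) {
  df <- do.call(rbind, rows)
  df$index <- seq_len(nrow(df)) - 1L
  df[, c("index", "kind", "channels", "nonneg_output", "on_aux_branch",
         "skipped", "eligible")]
}

# ---- VGG family -----------------------------------------------------------

.vgg_cfg <- list(
  vgg11 = c(64, "M", 128, "M", 256, 256, "M", 512, 512, "M", 512, 512, "M"),
  vgg13 = c(64, 64, "M", 128, 128, "M", 256, 256, "M", 512, 512, "M",
            512, 512, "M"),
  vgg16 = c(64, 64, "M", 128, 128, "M", 256, 256, 256, "M", 512, 512, 512,
            "M", 512, 512, 512, "M"),
  vgg19 = c(64, 64, "M", 128, 128, "M", 256, 256, 256, 256, "M", 512, 512,
            512, 512, "M", 512, 512, 512, 512, "M"))

.vgg_feature_part <- function(cfg, bn) {
  rows <- list()
  params <- list()
  in_ch <- 3L
  for (tok in cfg) {
    if (tok == "M") {
      rows[[length(rows) + 1L]] <- .layer_row("maxpool", in_ch, nonneg = TRUE)
    } else {
      out <- as.integer(tok)
      rows[[length(rows) + 1L]] <- .layer_row("conv", out)
      params[[length(params) + 1L]] <-
        .param_row(sprintf("conv%d_%d", in_ch, out), (9 * in_ch + 1) * out)
      if (bn) {
        rows[[length(rows) + 1L]] <- .layer_row("batchnorm", out)
        params[[length(params) + 1L]] <- .param_row("bn", 2 * out)
      }
      rows[[length(rows) + 1L]] <- .layer_row("relu", out, nonneg = TRUE)
      in_ch <- out
    }
  }
  list(layers = rows, params = params)
}

.vgg_head_params <- function(num_classes) {
  rbind(.param_row("fc1", 25088 * 4096 + 4096),
        .param_row("fc2", 4096 * 4096 + 4096),
        .param_row("fc3", 4096 * num_classes + num_classes))
}

# ---- AlexNet --------------------------------------------------------------

.alexnet_parts <- function(num_classes) {
  specs <- list(  # in, out, kernel
    c(3, 64, 11), c(64, 192, 5), c(192, 384, 3), c(384, 256, 3), c(256, 256, 3))
  pool_after <- c(1, 2, 5)
  rows <- list()
  params <- list()
  for (i in seq_along(specs)) {
    s <- specs[[i]]
    rows[[length(rows) + 1L]] <- .layer_row("conv", s[2])
    rows[[length(rows) + 1L]] <- .layer_row("relu", s[2], nonneg = TRUE)
    if (i %in% pool_after) {
      rows[[length(rows) + 1L]] <- .layer_row("maxpool", s[2], nonneg = TRUE)
    }
    params[[length(params) + 1L]] <-
      .param_row(sprintf("conv%d", i), (s[3]^2 * s[1] + 1) * s[2])
  }
  params[[length(params) + 1L]] <- .param_row("fc1", 9216 * 4096 + 4096)
  params[[length(params) + 1L]] <- .param_row("fc2", 4096 * 4096 + 4096)
  params[[length(params) + 1L]] <-
    .param_row("fc3", 4096 * num_classes + num_classes)
  list(layers = rows, params = params)
}

# ---- ResNet34 -------------------------------------------------------------

.resnet34_parts <- function(num_classes) {
  rows <- list(
    .layer_row("conv", 64, eligible = FALSE),
    .layer_row("batchnorm", 64, eligible = FALSE),
    .layer_row("relu", 64, nonneg = TRUE),
    .layer_row("maxpool", 64, nonneg = TRUE))
  params <- list(.param_row("conv1", 49 * 3 * 64), .param_row("bn1", 128))
  stages <- list(c(64, 3), c(128, 4), c(256, 6), c(512, 3))
  in_ch <- 64L
  for (s in stages) {
    out <- s[1]
    for (b in seq_len(s[2])) {
      down <- b == 1L && in_ch != out
      # internal block layers are skipped over by the residual addition
      rows <- c(rows, list(
        .layer_row("conv", out, skipped = TRUE, eligible = FALSE),
        .layer_row("batchnorm", out, skipped = TRUE, eligible = FALSE),
        .layer_row("relu", out, nonneg = TRUE, skipped = TRUE, eligible = FALSE),
        .layer_row("conv", out, skipped = TRUE, eligible = FALSE),
        .layer_row("batchnorm", out, skipped = TRUE, eligible = FALSE),
        .layer_row("residual-add", out, eligible = FALSE),
        .layer_row("relu", out, nonneg = TRUE)))
      params <- c(params, list(
        .param_row("block_conv1", 9 * in_ch * out), .param_row("bn", 2 * out),
        .param_row("block_conv2", 9 * out * out), .param_row("bn", 2 * out)))
      if (down) {
        params <- c(params, list(.param_row("down_conv", in_ch * out),
                                 .param_row("down_bn", 2 * out)))
      }
      in_ch <- out
    }
  }
  rows <- c(rows, list(.layer_row("avgpool", 512, nonneg = TRUE,
                                  eligible = FALSE)))
  params <- c(params, list(.param_row("fc", 512 * num_classes + num_classes)))
  list(layers = rows, params = params)
}

# ---- Inception v3 ---------------------------------------------------------

.inception_v3_parts <- function(num_classes) {
  rows <- list()
  params <- list()
  bconv <- function(in_ch, out, kh, kw, aux = FALSE) {
    rows[[length(rows) + 1L]] <<- .layer_row("conv", out, aux = aux,
                                             eligible = FALSE)
    rows[[length(rows) + 1L]] <<- .layer_row("batchnorm", out, aux = aux,
                                             eligible = FALSE)
    rows[[length(rows) + 1L]] <<- .layer_row("relu", out, nonneg = TRUE,
                                             aux = aux, eligible = !aux)
    params[[length(params) + 1L]] <<-
      .param_row(sprintf("conv%dx%d_%d_%d", kh, kw, in_ch, out),
                 kh * kw * in_ch * out + 2 * out)
  }
  pool <- function(kind, ch, aux = FALSE) {
    rows[[length(rows) + 1L]] <<- .layer_row(kind, ch, nonneg = TRUE,
                                             aux = aux, eligible = !aux)
  }
  concat <- function(ch) {
    rows[[length(rows) + 1L]] <<- .layer_row("concat", ch, nonneg = TRUE,
                                             eligible = FALSE)
  }
  # stem
  bconv(3, 32, 3, 3); bconv(32, 32, 3, 3); bconv(32, 64, 3, 3)
  pool("maxpool", 64)
  bconv(64, 80, 1, 1); bconv(80, 192, 3, 3)
  pool("maxpool", 192)
  inception_a <- function(in_ch, pf) {
    bconv(in_ch, 64, 1, 1)
    bconv(in_ch, 48, 1, 1); bconv(48, 64, 5, 5)
    bconv(in_ch, 64, 1, 1); bconv(64, 96, 3, 3); bconv(96, 96, 3, 3)
    pool("avgpool", in_ch); bconv(in_ch, pf, 1, 1)
    concat(224 + pf)
  }
  inception_a(192, 32); inception_a(256, 64); inception_a(288, 64)
  # grid reduction (B)
  bconv(288, 384, 3, 3)
  bconv(288, 64, 1, 1); bconv(64, 96, 3, 3); bconv(96, 96, 3, 3)
  pool("maxpool", 288)
  concat(768)
  inception_c <- function(c7) {
    bconv(768, 192, 1, 1)
    bconv(768, c7, 1, 1); bconv(c7, c7, 1, 7); bconv(c7, 192, 7, 1)
    bconv(768, c7, 1, 1); bconv(c7, c7, 7, 1); bconv(c7, c7, 1, 7)
    bconv(c7, c7, 7, 1); bconv(c7, 192, 1, 7)
    pool("avgpool", 768); bconv(768, 192, 1, 1)
    concat(768)
  }
  inception_c(128); inception_c(160); inception_c(160); inception_c(192)
  # auxiliary classifier branch (feature-ineligible)
  pool("avgpool", 768, aux = TRUE)
  bconv(768, 128, 1, 1, aux = TRUE); bconv(128, 768, 5, 5, aux = TRUE)
  params[[length(params) + 1L]] <-
    .param_row("aux_fc", 768 * num_classes + num_classes)
  # grid reduction (D)
  bconv(768, 192, 1, 1); bconv(192, 320, 3, 3)
  bconv(768, 192, 1, 1); bconv(192, 192, 1, 7); bconv(192, 192, 7, 1)
  bconv(192, 192, 3, 3)
  pool("maxpool", 768)
  concat(1280)
  inception_e <- function(in_ch) {
    bconv(in_ch, 320, 1, 1)
    bconv(in_ch, 384, 1, 1); bconv(384, 384, 1, 3); bconv(384, 384, 3, 1)
    bconv(in_ch, 448, 1, 1); bconv(448, 384, 3, 3); bconv(384, 384, 1, 3)
    bconv(384, 384, 3, 1)
    pool("avgpool", in_ch); bconv(in_ch, 192, 1, 1)
    concat(2048)
  }
  inception_e(1280); inception_e(2048)
  pool("avgpool", 2048)
  params[[length(params) + 1L]] <-
    .param_row("fc", 2048 * num_classes + num_classes)
  list(layers = rows, params = params)
}

# ---- tiny (desk-scale) ----------------------------------------------------

# Fixed three-block network: 224x224x3 input, a stem 2x average pool (halves
# the spatial grid so CPU training stays fast), then three conv/relu/maxpool
# blocks with 3x3 kernels (pad 1) and a linear head on the 7x7x32 map.
.tiny_channels <- c(8L, 16L, 32L)

.tiny_parts <- function(num_classes) {
  ch <- .tiny_channels
  # stem avgpool sees the (possibly negative) normalised input
  rows <- list(.layer_row("avgpool", 3L))
  params <- list()
  in_ch <- 3L
  for (i in seq_along(ch)) {
    rows <- c(rows, list(.layer_row("conv", ch[i]),
                         .layer_row("relu", ch[i], nonneg = TRUE),
                         .layer_row("maxpool", ch[i], nonneg = TRUE)))
    params[[length(params) + 1L]] <-
      .param_row(sprintf("conv%d", i), (9 * in_ch + 1) * ch[i])
    in_ch <- ch[i]
  }
  params[[length(params) + 1L]] <-
    .param_row("fc", 1568 * num_classes + num_classes)
  inst <- list(
    list(kind = "avgpool", p = 2L),
    list(kind = "conv", in_ch = 3L, out_ch = ch[1], k = 3L, stride = 1L, pad = 1L),
    list(kind = "relu"), list(kind = "maxpool", p = 4L),
    list(kind = "conv", in_ch = ch[1], out_ch = ch[2], k = 3L, stride = 1L, pad = 1L),
    list(kind = "relu"), list(kind = "maxpool", p = 2L),
    list(kind = "conv", in_ch = ch[2], out_ch = ch[3], k = 3L, stride = 1L, pad = 1L),
    list(kind = "relu"), list(kind = "maxpool", p = 2L),
    list(kind = "flatten"),
    list(kind = "linear", d_in = 1568L, d_out = as.integer(num_classes)))
  list(layers = rows, params = params, instantiable = inst)
}

#' Build a convolutional architecture specification
#'
#' Returns the ordered feature-part layer table, the trainable-parameter
#' inventory and (for desk-scale architectures) an instantiable layer list for
#' one of the supported convolutional network families, adapted to
#' `num_classes` output classes. The two bespoke single-head VGG16 variants
#' replace the usual three fully connected layers by dropout plus one linear
#' map (`vgg16_1fc`), optionally preceded by a global 7x7 average pool
#' (`vgg16_avg1fc`).
#'
#' @param name One of `r paste0('"', SUPPORTED_ARCHITECTURES, '"', collapse = ", ")`.
#' @param num_classes Number of output classes (default 39 tissue types).
#' @return An object of class `histotx_architecture` with elements `name`,
#'   `num_classes`, `layers` (feature-part layer table with 0-based `index`),
#'   `params` (trainable tensor inventory), `head` (description) and, for
#'   `"tiny"`, `instantiable` (layer descriptors for [instantiate_model()]).
#' @examples
#' arch <- build_architecture("vgg16", 39)
#' count_parameters(arch)
#' nrow(enumerate_features(arch))
#' @export
build_architecture <- function(name, num_classes = 39L) {
  if (!is.character(name) || length(name) != 1L ||
      !(name %in% SUPPORTED_ARCHITECTURES)) {
    stop("unknown architecture '", paste(name, collapse = ","),
         "'; supported: ", paste(SUPPORTED_ARCHITECTURES, collapse = ", "))
  }
  stopifnot(num_classes >= 2)
  num_classes <- as.integer(num_classes)
  inst <- NULL
  head <- ""
  if (name %in% c("vgg11", "vgg13", "vgg16", "vgg19",
                  "vgg11_bn", "vgg13_bn", "vgg16_bn", "vgg19_bn")) {
    base <- sub("_bn$", "", name)
    fp <- .vgg_feature_part(.vgg_cfg[[base]], bn = grepl("_bn$", name))
    layers <- .finish_layers(fp$layers)
    params <- rbind(do.call(rbind, fp$params), .vgg_head_params(num_classes))
    head <- "Linear(25088,4096); ReLU; Dropout(0.5); Linear(4096,4096); ReLU; Dropout(0.5); Linear(4096,C)"
  } else if (name == "vgg16_1fc") {
    fp <- .vgg_feature_part(.vgg_cfg$vgg16, bn = FALSE)
    layers <- .finish_layers(fp$layers)
    params <- rbind(do.call(rbind, fp$params),
                    .param_row("fc", 25088 * num_classes + num_classes))
    head <- "Dropout(0.5); Linear(25088,C)"
  } else if (name == "vgg16_avg1fc") {
    fp <- .vgg_feature_part(.vgg_cfg$vgg16, bn = FALSE)
    rows <- c(fp$layers, list(.layer_row("avgpool", 512, nonneg = TRUE)))
    layers <- .finish_layers(rows)
    params <- rbind(do.call(rbind, fp$params),
                    .param_row("fc", 512 * num_classes + num_classes))
    head <- "AvgPool2d(7x7); Dropout(0.5); Linear(512,C)"
  } else if (name == "alexnet") {
    ap <- .alexnet_parts(num_classes)
    layers <- .finish_layers(ap$layers)
    params <- do.call(rbind, ap$params)
    head <- "Dropout; Linear(9216,4096); ReLU; Dropout; Linear(4096,4096); ReLU; Linear(4096,C)"
  } else if (name == "resnet34") {
    rp <- .resnet34_parts(num_classes)
    layers <- .finish_layers(rp$layers)
    params <- do.call(rbind, rp$params)
    head <- "AvgPool; Linear(512,C)"
  } else if (name == "inception_v3") {
    ip <- .inception_v3_parts(num_classes)
    layers <- .finish_layers(ip$layers)
    params <- do.call(rbind, ip$params)
    head <- "Linear(2048,C) + auxiliary Linear(768,C)"
  } else if (name == "tiny") {
    tp <- .tiny_parts(num_classes)
    layers <- .finish_layers(tp$layers)
    params <- do.call(rbind, tp$params)
    inst <- tp$instantiable
    head <- "Linear(1568,C)"
  }
  rownames(params) <- NULL
  structure(list(name = name, num_classes = num_classes, layers = layers,
                 params = params, head = head, instantiable = inst,
                 input_size = c(224L, 224L, 3L)),
            class = "histotx_architecture")
}

#' Enumerate the location-invariant features f_lz of an architecture
#'
#' One feature per eligible (layer, channel) pair, identified by the string
#' `"l_z"` with the 0-based layer index `l` and channel `z`. Eligibility
#' follows the family conventions documented at the top of this file.
#'
#' @param spec A `histotx_architecture`, or a data frame of layers with at
#'   least a `channels` column (all rows eligible unless an `eligible`
#'   column says otherwise).
#' @return Data frame with columns `layer`, `channel` (both 0-based) and `id`.
#' @export
enumerate_features <- function(spec) {
  layers <- if (inherits(spec, "histotx_architecture")) spec$layers else spec
  stopifnot(is.data.frame(layers), "channels" %in% names(layers))
  if (is.null(layers$eligible)) layers$eligible <- TRUE
  if (is.null(layers$index)) layers$index <- seq_len(nrow(layers)) - 1L
  keep <- layers[layers$eligible, , drop = FALSE]
  n <- keep$channels
  out <- data.frame(
    layer = rep(keep$index, n),
    channel = unlist(lapply(n, function(k) seq_len(k) - 1L), use.names = FALSE))
  out$id <- paste0(out$layer, "_", out$channel)
  out
}

#' Parse feature ids of the form "l_z" back to (layer, channel)
#'
#' @param ids Character vector of feature ids, e.g. `"29_499"`.
#' @return Data frame with integer columns `layer` and `channel`.
#' @export
parse_feature_id <- function(ids) {
  parts <- strsplit(ids, "_", fixed = TRUE)
  bad <- lengths(parts) != 2L
  if (any(bad)) stop("malformed feature id(s): ", paste(ids[bad], collapse = ", "))
  data.frame(layer = as.integer(vapply(parts, `[`, "", 1L)),
             channel = as.integer(vapply(parts, `[`, "", 2L)))
}

#' Count trainable parameters
#'
#' For an architecture specification the count is the closed-form sum over the
#' declared weight and bias tensors; for an instantiated model it is the sum
#' of the materialised tensor lengths. The two agree by construction for the
#' desk-scale architectures.
#'
#' @param x A `histotx_architecture` or `histotx_model`.
#' @return Number of trainable scalars.
#' @export
count_parameters <- function(x) {
  if (inherits(x, "histotx_architecture")) return(sum(x$params$count))
  if (inherits(x, "histotx_model")) {
    return(sum(vapply(x$layers, function(ly) {
      length(ly$W %||% numeric(0)) + length(ly$b %||% numeric(0))
    }, numeric(1))))
  }
  stop("count_parameters() expects an architecture or model object")
}

#' @export
print.histotx_architecture <- function(x, ...) {
  cat(sprintf("<histotx architecture '%s', %d classes>\n", x$name, x$num_classes))
  cat(sprintf("  feature-part layers: %d\n", nrow(x$layers)))
  cat(sprintf("  features f_lz:       %d\n", nrow(enumerate_features(x))))
  cat(sprintf("  trainable params:    %s\n",
              format(count_parameters(x), big.mark = ",")))
  cat("  head:", x$head, "\n")
  invisible(x)
}
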