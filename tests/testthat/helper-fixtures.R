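# Shared fixtures: small networks and datasets built in code at test time.

# internal engine helpers exercised directly by the engine tests
softmax_xent <- histotx:::softmax_xent

# a micro conv net on small inputs, exercising every layer kind
micro_model <- function(input = 8L, in_ch = 2L, classes = 3L, seed = 42L) {
  layers <- list(
    list(kind = "conv", in_ch = in_ch, out_ch = 3L, k = 3L, stride = 1L, pad = 1L),
    list(kind = "relu"),
    list(kind = "maxpool", p = 2L),
    list(kind = "conv", in_ch = 3L, out_ch = 4L, k = 3L, stride = 1L, pad = 1L),
    list(kind = "relu"),
    list(kind = "avgpool", p = 2L),
    list(kind = "flatten"),
    list(kind = "linear", d_in = as.integer((input / 4)^2 * 4), d_out = classes))
  instantiate_model(layers, seed = seed)
}

# tiny-architecture model with its feature-layer table attached
tiny_model <- function(classes = 4L, seed = 1L) {
  instantiate_model(build_architecture("tiny", classes), seed = seed)
}

# deterministic RGB test image [h, w, 3]
test_image <- function(h, w, seed = 1L) {
  set.seed(seed)
  array(runif(h * w * 3), c(h, w, 3L))
}

# one-slide-per-row manifest for a set of images written to a temp dir
write_slide_set <- function(images, tissues, dir = withr::local_tempdir(),
                            .local_envir = parent.frame()) {
  if (missing(dir)) dir <- withr::local_tempdir(.local_envir = .local_envir)
  ids <- sprintf("SL%02d", seq_along(images))
  paths <- file.path(dir, paste0(ids, ".png"))
  for (i in seq_along(images)) write_image(images[[i]], paths[i])
  data.frame(slide_id = ids, path = paths, tissue = tissues,
             stringsAsFactors = FALSE)
}

# small synthetic paired dataset reused across pipeline-level tests
small_dataset <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- generate_dataset(
        n_classes = 2L, slides_per_class = 10L, image_size = 512L,
        gene_specs = default_gene_specs(6L, 6L, 6L, n_classes = 2L),
        seed = 7L, dir = file.path(tempdir(), "histotx_small_ds"))
    }
    cache
  }
})
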