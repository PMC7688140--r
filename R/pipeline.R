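# End-to-end orchestration: tile -> train -> quantify (test split) ->
# correlate (test split) -> dependency analysis, with split hygiene enforced
# at each hand-off. The correlation stage only ever sees test-split slides;
# the trainer refuses test tiles outright.

#' Prepare the model-ready tile set for the training stages
#'
#' Tiles and filters every slide of the manifest and prepares kept tiles as
#' normalised 224-pixel inputs. Test-split slides are excluded by default:
#' this function feeds the trainer.
#'
#' @param manifest Slide manifest (`slide_id`, `path`, `tissue`, `split`).
#' @param classes Class label vector defining the label index.
#' @param include_splits Splits to keep (default train + validation).
#' @param tile_size,min_fraction Tiling parameters.
#' @return List of tiles with `input`, `label` (integer), `slide_id`,
#'   `split`.
#' @export
prepare_tile_dataset <- function(manifest, classes,
                                 include_splits = c("train", "validation"),
                                 tile_size = 512L, min_fraction = 0.5) {
  keep <- manifest[manifest$split %in% include_splits, , drop = FALSE]
  out <- list()
  for (i in seq_len(nrow(keep))) {
    img <- read_slide_image(keep$path[i])
    tiles <- filter_tiles(extract_tiles(img, tile_size,
                                        slide_id = keep$slide_id[i],
                                        tissue = keep$tissue[i]),
                          min_fraction)
    for (tl in tiles) {
      out[[length(out) + 1L]] <- list(
        input = prepare_input(tl$pixels),
        label = match(keep$tissue[i], classes),
        slide_id = keep$slide_id[i],
        split = keep$split[i])
    }
  }
  out
}

#' Run the full histology-to-transcriptome analysis on a paired dataset
#'
#' Executes the stages in order on a dataset as produced by
#' [generate_dataset()] (or any dataset with the same shape): tile and
#' prepare the training/validation slides, train the tile classifier with
#' best-validation-epoch selection, quantify slide-level features on the
#' test split only, correlate them with log2 expression on the test split
#' only, run permutation tests on the selected pairs, and classify indirect
#' dependency patterns. The full configuration is stored in the run object
#' for provenance.
#'
#' @param dataset List with `slide_manifest`, `expression`, `sample_meta`.
#' @param arch_name Architecture to train (default `"tiny"`).
#' @param config A [train_config()].
#' @param R_T,E_T Correlation and expression thresholds for pair selection.
#' @param alpha CI-test significance threshold.
#' @param n_perm Permutations per selected pair (0 skips the stage).
#' @param p Feature aggregation exponent.
#' @param seed Seed for the permutation stage.
#' @return A `histotx_run` list: `model`, `train_log`, `test_eval`,
#'   `slide_eval`, `features`, `r`, `meta`, `screen` (pairs + counts),
#'   `patterns`, `config`.
#' @export
run_pipeline <- function(dataset, arch_name = "tiny",
                         config = train_config(epochs = 15L, batch_size = 16L),
                         R_T = 0.6, E_T = 0, alpha = 0.01, n_perm = 1000L,
                         p = 1, seed = 1L) {
  manifest <- dataset$slide_manifest
  stopifnot(all(c("slide_id", "path", "tissue", "split") %in% names(manifest)))
  classes <- sort(unique(manifest$tissue))

  arch <- build_architecture(arch_name, num_classes = length(classes))
  model <- instantiate_model(arch, seed = config$seed)

  tiles <- prepare_tile_dataset(manifest, classes)
  fit <- train_classifier(model, tiles, config)

  test_manifest <- manifest[manifest$split == "test", , drop = FALSE]
  test_tiles <- prepare_tile_dataset(manifest, classes,
                                     include_splits = "test")
  test_eval <- evaluate_tiles(fit$model, test_tiles, class_names = classes)

  slide_pred <- vapply(split(test_tiles,
                             vapply(test_tiles, `[[`, character(1), "slide_id")),
                       function(tl) predict_slide(fit$model, tl), integer(1))
  slide_truth <- match(test_manifest$tissue, classes)[
    match(names(slide_pred), test_manifest$slide_id)]
  slide_eval <- list(accuracy = mean(slide_pred == slide_truth),
                     predictions = slide_pred)

  fm <- build_feature_matrix(fit$model, test_manifest, p = p)

  log_expr <- resolve_duplicates(dataset$expression, dataset$sample_meta)
  test_ids <- intersect(colnames(log_expr), rownames(fm$features))
  log_expr <- log_expr[, test_ids, drop = FALSE]
  tissue <- manifest$tissue[match(test_ids, manifest$slide_id)]
  names(tissue) <- test_ids

  gm <- gene_meta(log_expr, tissue)
  r <- correlate(log_expr, fm$features)
  screen <- select_significant(r, R_T, gm$meta, E_T = E_T)

  if (n_perm > 0L && nrow(screen$pairs) > 0L) {
    set.seed(seed)
    perm_seeds <- sample.int(.Machine$integer.max, nrow(screen$pairs))
    screen$pairs$perm_p <- vapply(seq_len(nrow(screen$pairs)), function(i) {
      permutation_test(log_expr[screen$pairs$gene[i], test_ids],
                       fm$features[test_ids, screen$pairs$feature[i]],
                       N = n_perm, seed = perm_seeds[i])$p
    }, numeric(1))
    # Benjamini-Hochberg q-values: supplementary output beyond the fixed
    # threshold + permutation scheme
    screen$pairs$perm_q <- stats::p.adjust(screen$pairs$perm_p, "BH")
  }

  patterns <- if (nrow(screen$pairs) > 0L) {
    dependency_patterns(screen$pairs, log_expr, fm$features, tissue, alpha)
  } else {
    list(pairs = screen$pairs, counts = c(pairs = 0L, gtf = 0L,
                                          fgt = 0L, gft = 0L))
  }

  structure(list(
    model = fit$model, train_log = fit$log, best_epoch = fit$best_epoch,
    test_eval = test_eval, slide_eval = slide_eval,
    features = fm$features, r = r, meta = gm$meta,
    screen = screen, patterns = patterns,
    classes = classes,
    config = list(arch = arch_name, train = config, R_T = R_T, E_T = E_T,
                  alpha = alpha, n_perm = n_perm, p = p, seed = seed)),
    class = "histotx_run")
}

#' @export
print.histotx_run <- function(x, ...) {
  cat("<histotx run>\n")
  cat(sprintf("  classifier: %s, best epoch %d, test tile accuracy %.3f, slide accuracy %.3f\n",
              x$config$arch, x$best_epoch, x$test_eval$accuracy,
              x$slide_eval$accuracy))
  cat(sprintf("  screen: %d pairs (|r| >= %.2f), %d genes, %d features\n",
              x$screen$counts["pairs"], x$config$R_T,
              x$screen$counts["genes"], x$screen$counts["features"]))
  cat(sprintf("  indirect g-t-f: %d of %d pairs at alpha = %.2f\n",
              x$patterns$counts["gtf"], x$patterns$counts["pairs"],
              x$config$alpha))
  invisible(x)
}
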