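# Slide-level dataset splitting, tile-classifier training with a step
# learning-rate schedule, best-validation-epoch model selection, tile- and
# slide-level (majority vote) evaluation, and merging of similar classes.

#' Training configuration
#'
#' Defaults follow the study schedule: 90 epochs, initial learning rate 0.01
#' divided by 10 every 30 epochs, momentum SGD (momentum 0.9, weight decay
#' 1e-4) on softmax cross-entropy.
#'
#' @param epochs Number of epochs (>= 1).
#' @param lr0 Initial learning rate.
#' @param lr_decay_factor,lr_decay_every Step schedule: divide by
#'   `lr_decay_factor` every `lr_decay_every` epochs.
#' @param batch_size Mini-batch size.
#' @param momentum,weight_decay SGD parameters.
#' @param seed Seed for shuffling and any dropout sampling.
#' @return A `histotx_train_config` list.
#' @export
train_config <- function(epochs = 90L, lr0 = 0.01, lr_decay_factor = 10,
                         lr_decay_every = 30L, batch_size = 40L,
                         momentum = 0.9, weight_decay = 1e-4, seed = 1L) {
  stopifnot(epochs >= 1L, lr0 > 0)
  structure(list(epochs = as.integer(epochs), lr0 = lr0,
                 lr_decay_factor = lr_decay_factor,
                 lr_decay_every = as.integer(lr_decay_every),
                 batch_size = as.integer(batch_size), momentum = momentum,
                 weight_decay = weight_decay, seed = as.integer(seed)),
            class = "histotx_train_config")
}

#' Learning rate at a (0-based) epoch under the step schedule
#'
#' @param epoch 0-based epoch index.
#' @param config A [train_config()].
#' @return Learning rate.
#' @export
lr_at_epoch <- function(epoch, config) {
  config$lr0 / config$lr_decay_factor^(epoch %/% config$lr_decay_every)
}

#' Stratified slide-level train/validation/test split
#'
#' Slides (never tiles) are randomly assigned within each tissue so that the
#' per-tissue counts match the fractions by largest remainder. A tissue with
#' fewer than 3 slides is assigned entirely to the training split, with a
#' warning. Deterministic given `seed`.
#'
#' @param slides Data frame with columns `slide_id` and `tissue`.
#' @param fractions Train/validation/test fractions summing to 1.
#' @param seed Integer seed.
#' @return List with `split` (named character vector slide_id -> split) and
#'   `assignment` (data frame slide_id, tissue, split).
#' @export
split_slides <- function(slides, fractions = c(0.6, 0.2, 0.2), seed = 1L) {
  stopifnot(all(c("slide_id", "tissue") %in% names(slides)),
            length(fractions) == 3L, abs(sum(fractions) - 1) < 1e-8)
  set.seed(seed)
  names(fractions) <- c("train", "validation", "test")
  out <- character(nrow(slides))
  names(out) <- slides$slide_id
  for (tis in unique(slides$tissue)) {
    ids <- slides$slide_id[slides$tissue == tis]
    n <- length(ids)
    if (n < 3L) {
      warning("tissue '", tis, "' has only ", n,
              " slide(s); assigning all to train")
      out[ids] <- "train"
      next
    }
    base <- floor(n * fractions)
    rem <- n - sum(base)
    if (rem > 0L) {
      frac <- n * fractions - base
      base[order(frac, decreasing = TRUE)[seq_len(rem)]] <-
        base[order(frac, decreasing = TRUE)[seq_len(rem)]] + 1L
    }
    ids <- sample(ids)
    out[ids] <- rep(names(fractions), times = base)
  }
  list(split = out,
       assignment = data.frame(slide_id = slides$slide_id,
                               tissue = slides$tissue,
                               split = out[slides$slide_id],
                               stringsAsFactors = FALSE, row.names = NULL))
}

# forward a list of tiles, returning the class-score matrix [n, K]
.score_tiles <- function(model, tiles) {
  t(vapply(tiles, function(tl) nn_forward(model, tl$input)$out,
           numeric(model$layers[[length(model$layers)]]$d_out)))
}

#' Train a tile classifier
#'
#' Momentum-SGD minimisation of softmax cross-entropy under the step
#' learning-rate schedule in `config`. After every epoch, tile accuracy on
#' the validation tiles is logged; the returned model is the checkpoint from
#' the epoch with the best validation accuracy (earliest epoch on ties).
#' Tiles carrying a `split == "test"` are refused: the test split must never
#' reach training or model selection.
#'
#' @param model A `histotx_model` (see [instantiate_model()]).
#' @param tiles List of tiles; each needs `input` (prepared array), `label`
#'   (integer class in `1..K`) and `split` (`"train"` or `"validation"`).
#' @param config A [train_config()].
#' @return List with `model` (best checkpoint), `log` (per-epoch data frame:
#'   epoch, lr, train_loss, val_accuracy), `best_epoch` (0-based).
#' @export
train_classifier <- function(model, tiles, config = train_config()) {
  splits <- vapply(tiles, function(tl) tl$split %||% "train", character(1))
  if (any(splits == "test")) {
    stop("test-split tiles must not be passed to train_classifier()")
  }
  tr <- tiles[splits == "train"]
  va <- tiles[splits == "validation"]
  if (length(tr) == 0L) stop("empty training split")
  labels_tr <- vapply(tr, `[[`, integer(1), "label")
  labels_va <- vapply(va, `[[`, integer(1), "label")
  set.seed(config$seed)
  velocity <- vector("list", length(model$layers))
  log_rows <- vector("list", config$epochs)
  best <- list(acc = -Inf, model = model, epoch = NA_integer_)
  for (epoch in seq_len(config$epochs) - 1L) {
    lr <- lr_at_epoch(epoch, config)
    ord <- sample(length(tr))
    total_loss <- 0
    for (start in seq(1L, length(ord), by = config$batch_size)) {
      idx <- ord[start:min(start + config$batch_size - 1L, length(ord))]
      grads <- NULL
      for (i in idx) {
        fw <- nn_forward(model, tr[[i]]$input, train = TRUE, keep_cache = TRUE)
        sx <- softmax_xent(fw$out, labels_tr[i])
        total_loss <- total_loss + sx$loss
        bw <- nn_backward(model, fw$cache, sx$dlogits,
                          need_input_grad = FALSE)
        grads <- accumulate_grads(grads, bw$grads)
      }
      upd <- sgd_update(model, grads, velocity, lr,
                        momentum = config$momentum,
                        weight_decay = config$weight_decay,
                        batch_size = length(idx))
      model <- upd$model
      velocity <- upd$velocity
    }
    val_acc <- if (length(va)) {
      mean(max.col(.score_tiles(model, va)) == labels_va)
    } else NA_real_
    log_rows[[epoch + 1L]] <- data.frame(
      epoch = epoch, lr = lr, train_loss = total_loss / length(tr),
      val_accuracy = val_acc)
    if (!is.na(val_acc) && val_acc > best$acc) {   # strict >: earliest wins
      best <- list(acc = val_acc, model = model, epoch = epoch)
    }
  }
  if (is.infinite(best$acc)) best <- list(acc = NA_real_, model = model,
                                          epoch = config$epochs - 1L)
  list(model = best$model, log = do.call(rbind, log_rows),
       best_epoch = best$epoch, best_val_accuracy = best$acc)
}

#' Tile-level evaluation: accuracy and confusion matrix
#'
#' @param model A trained `histotx_model`.
#' @param tiles List of tiles with `input` and `label` (integer `1..K`).
#' @param class_names Optional class labels for the confusion dimnames.
#' @return List with `accuracy`, `confusion` (rows = truth, cols =
#'   prediction) and `predictions` (integer vector).
#' @export
evaluate_tiles <- function(model, tiles, class_names = NULL) {
  stopifnot(length(tiles) >= 1L)
  scores <- .score_tiles(model, tiles)
  K <- ncol(scores)
  pred <- max.col(scores)
  truth <- vapply(tiles, `[[`, integer(1), "label")
  if (is.null(class_names)) class_names <- as.character(seq_len(K))
  cm <- table(factor(truth, levels = seq_len(K), labels = class_names),
              factor(pred, levels = seq_len(K), labels = class_names))
  list(accuracy = mean(pred == truth), confusion = unclass(cm),
       predictions = pred)
}

#' Slide-level prediction by majority vote over tiles
#'
#' The slide class is the modal tile-level argmax class. Ties are broken by
#' the largest summed softmax score across the slide's tiles, then by lowest
#' class index.
#'
#' @param model A trained `histotx_model`.
#' @param slide_tiles Tiles of one slide (each with `input`).
#' @return Integer class index.
#' @export
predict_slide <- function(model, slide_tiles) {
  if (length(slide_tiles) == 0L) stop("predict_slide() needs at least one tile")
  scores <- .score_tiles(model, slide_tiles)
  probs <- t(apply(scores, 1L, function(z) {
    e <- exp(z - max(z)); e / sum(e)
  }))
  if (nrow(scores) == 1L) probs <- matrix(probs, 1L)
  pred <- max.col(scores)
  votes <- tabulate(pred, nbins = ncol(scores))
  top <- which(votes == max(votes))
  if (length(top) == 1L) return(top)
  sums <- colSums(probs)[top]
  top[order(-sums, top)][1L]
}

#' The five groups of histologically similar tissues merged in reporting
#'
#' Merging these five groups reduces the 39 tissue classes to 33.
#'
#' @return List of character vectors of tissue labels.
#' @export
similar_tissue_groups <- function() {
  list(
    c("Artery - Aorta", "Artery - Coronary", "Artery - Tibial"),
    c("Colon - Sigmoid", "Colon - Transverse"),
    c("Esophagus - Gastroesophageal Junction", "Esophagus - Muscularis"),
    c("Heart - Atrial Appendage", "Heart - Left Ventricle"),
    c("Skin - Not Sun Exposed", "Skin - Sun Exposed"))
}

#' Merge groups of similar classes in a label vector
#'
#' Each group of labels becomes a single class named by joining the group
#' members with `"/"`. Groups must be disjoint. Labels not in any group are
#' unchanged; an empty group list is the identity.
#'
#' @param labels Character vector (or factor) of class labels.
#' @param groups List of character vectors.
#' @return Character vector of relabelled classes.
#' @export
merge_classes <- function(labels, groups = list()) {
  labels <- as.character(labels)
  if (length(groups)) {
    members <- unlist(groups)
    if (anyDuplicated(members)) stop("merge groups must be disjoint")
    for (grp in groups) {
      labels[labels %in% grp] <- paste(grp, collapse = "/")
    }
  }
  labels
}

#' Collapse a confusion matrix after merging classes
#'
#' @param confusion Square count matrix with identical row/col labels.
#' @param groups List of character vectors of labels to merge.
#' @return The collapsed confusion matrix.
#' @export
merge_confusion <- function(confusion, groups = list()) {
  lab <- merge_classes(rownames(confusion), groups)
  m <- rowsum(confusion, lab)
  t(rowsum(t(m), lab))
}

#' Accuracy implied by a confusion matrix
#'
#' @param confusion Count matrix, rows = truth, cols = prediction.
#' @return Fraction of counts on the diagonal.
#' @export
accuracy_from_confusion <- function(confusion) {
  sum(diag(as.matrix(confusion))) / sum(confusion)
}
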