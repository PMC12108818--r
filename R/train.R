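# Training loop (AdamW + cosine annealing), evaluation with
# confidence-threshold flagging, and Grad-CAM explanation.

#' Cosine-annealed learning rate
#'
#' `lr(t) = lr0 * (lrf + (1 - lrf) * (1 + cos(pi * t / T)) / 2)`,
#' stepped per epoch: starts at `lr0` and decays to the floor
#' `lrf * lr0`.
#'
#' @param t epoch index in `[0, T]`
#' @param T total epochs
#' @param lr0 initial learning rate (default 5e-4)
#' @param lrf floor scaling factor (default 0.2)
#' @return learning rate at `t`
#' @export
lr_schedule <- function(t, T, lr0 = 5e-4, lrf = 0.2) {
  if (T <= 0) stop("T must be positive")
  if (any(t < 0 | t > T)) stop("t must lie in [0, T]")
  lr0 * (lrf + (1 - lrf) * (1 + cos(pi * t / T)) / 2)
}

#' Training configuration
#'
#' Defaults follow the WHA-Net recipe: AdamW with weight decay 0.02,
#' batch size 64, initial learning rate 5e-4, cosine annealing with
#' floor factor 0.2, cross-entropy loss, 256 px inputs.
#'
#' @param epochs training epochs (default 100)
#' @param batch_size minibatch size
#' @param lr initial learning rate
#' @param lrf cosine floor factor
#' @param weight_decay AdamW decoupled weight decay
#' @param input_size square input resolution
#' @param augment apply online augmentation (random resized crop +
#'   horizontal flip) to training batches
#' @param seed integer seed controlling shuffling, augmentation and
#'   initialization
#' @return a `wha_train_config` list
#' @export
train_config <- function(epochs = 100L, batch_size = 64L, lr = 5e-4,
                         lrf = 0.2, weight_decay = 0.02,
                         input_size = 256L, augment = TRUE, seed = 1L) {
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), lr = lr, lrf = lrf,
                 weight_decay = weight_decay,
                 input_size = as.integer(input_size), augment = augment,
                 seed = as.integer(seed)),
            class = "wha_train_config")
}

# cross-entropy on logits; returns loss and gradient
softmax_xent <- function(logits, y_idx) {
  p <- row_softmax(logits)
  n <- nrow(logits)
  ll <- -log(pmax(p[cbind(seq_len(n), y_idx)], 1e-12))
  g <- p
  g[cbind(seq_len(n), y_idx)] <- g[cbind(seq_len(n), y_idx)] - 1
  list(loss = mean(ll), grad = g / n)
}

#' Load manifest images into a batch array
#'
#' @param manifest a `fundus_manifest`
#' @param split which split to load
#' @param size resize target (plain resize, evaluation path)
#' @return list with `x` (`(size,size,3,N)` array) and `y` (integer
#'   labels, 0-based in Normal/ODE/PPE order)
#' @export
load_split <- function(manifest, split, size = 256L) {
  rows <- which(manifest$split == split)
  if (!length(rows)) stop("empty split: ", split)
  x <- array(0, c(size, size, 3, length(rows)))
  for (i in seq_along(rows)) {
    img <- png::readPNG(manifest$path[rows[i]])
    if (!identical(dim(img)[1:2], c(size, size)))
      img <- augment_online(img, out_size = size, train = FALSE)
    x[, , , i] <- img[, , 1:3]
  }
  list(x = x, y = match(manifest$label[rows], FUNDUS_CLASSES) - 1L)
}

#' Train a model
#'
#' Seeded end-to-end training with AdamW, per-epoch cosine annealing and
#' cross-entropy loss. Tracks per-epoch training loss and validation
#' macro (one-vs-rest) accuracy; the returned model carries the weights
#' of the best validation epoch (ties resolved to the earlier epoch).
#'
#' @param model a `wha_model`
#' @param train_data,val_data lists with `x` (`(H,W,3,N)` array) and `y`
#'   (0-based integer labels), e.g. from [load_split()]
#' @param cfg a [train_config()]
#' @param verbose print per-epoch progress
#' @return an object of class `wha_fit`: list with `model`, `history`
#'   tibble (`epoch`, `lr`, `train_loss`, `val_macro_acc`),
#'   `best_epoch`, `config`
#' @export
train <- function(model, train_data, val_data, cfg = train_config(),
                  verbose = TRUE) {
  n <- dim(train_data$x)[4]
  if (n == 0 || dim(val_data$x)[4] == 0) stop("empty split")
  set.seed(cfg$seed)
  opt <- optim_adamw(model, lr = cfg$lr, weight_decay = cfg$weight_decay)
  hist <- vector("list", cfg$epochs)
  best_acc <- -Inf; best_sd <- NULL; best_epoch <- NA_integer_
  for (ep in seq_len(cfg$epochs)) {
    lr <- lr_schedule(ep - 1L, cfg$epochs, cfg$lr, cfg$lrf)
    ord <- sample.int(n)
    losses <- c()
    for (b in seq(1, n, by = cfg$batch_size)) {
      idx <- ord[b:min(b + cfg$batch_size - 1L, n)]
      xb <- train_data$x[, , , idx, drop = FALSE]
      if (cfg$augment) {
        for (j in seq_along(idx))
          xb[, , , j] <- augment_online(xb[, , , j],
                                        seed = fold_seed(cfg$seed,
                                                         ep * 100003L + idx[j]),
                                        out_size = dim(xb)[1])
      }
      logits <- layer_forward(model, xb, training = TRUE)
      ce <- softmax_xent(logits, train_data$y[idx] + 1L)
      zero_grads(model)
      layer_backward(model, ce$grad)
      opt <- optim_step(opt, lr = lr)
      losses <- c(losses, ce$loss)
    }
    recompute_bn_stats(model, train_data$x, cfg$batch_size)
    val <- evaluate(model, val_data)
    acc <- val$metrics$macro[["accuracy"]]
    hist[[ep]] <- tibble::tibble(epoch = ep, lr = lr,
                                 train_loss = mean(losses),
                                 val_macro_acc = acc)
    if (acc > best_acc) {
      best_acc <- acc; best_sd <- state_dict(model); best_epoch <- ep
    }
    if (verbose)
      message(sprintf("epoch %3d  lr %.2e  loss %.4f  val macro acc %.4f",
                      ep, lr, mean(losses), acc))
  }
  load_state_dict(model, best_sd)
  structure(list(model = model, history = do.call(rbind, hist),
                 best_epoch = best_epoch, config = cfg),
            class = "wha_fit")
}

#' @export
tidy.wha_fit <- function(x, ...) x$history

#' @export
glance.wha_fit <- function(object, ...) {
  h <- object$history
  tibble::tibble(epochs = nrow(h), best_epoch = object$best_epoch,
                 best_val_macro_acc = max(h$val_macro_acc),
                 final_train_loss = h$train_loss[nrow(h)])
}

#' Evaluate a model on a labelled split
#'
#' Deterministic inference (no augmentation, eval-mode normalization).
#' Samples whose maximum softmax confidence falls below `threshold` are
#' flagged for clinical review ("low diagnostic confidence").
#'
#' @param model a `wha_model` or `wha_fit`
#' @param data list with `x` and `y` as in [train()]
#' @param threshold confidence threshold in `[0,1]` (default 0.95)
#' @param batch_size inference batch size
#' @return an object of class `wha_eval`: list with `metrics`
#'   (`wha_metrics`), `confusion`, `prob` matrix, `pred`/`truth`
#'   vectors, `flagged` tibble
#' @export
evaluate <- function(model, data, threshold = 0.95, batch_size = 64L) {
  if (inherits(model, "wha_fit")) model <- model$model
  n <- dim(data$x)[4]
  if (n == 0) stop("empty split")
  probs <- matrix(0, n, model$cfg$classes)
  for (b in seq(1, n, by = batch_size)) {
    idx <- b:min(b + batch_size - 1L, n)
    probs[idx, ] <- predict_proba(model, data$x[, , , idx, drop = FALSE])
  }
  colnames(probs) <- model$cfg$class_names
  pred <- max.col(probs, ties.method = "first") - 1L
  cm <- confusion_matrix(data$y, pred, classes = model$cfg$class_names)
  conf <- probs[cbind(seq_len(n), pred + 1L)]
  flagged <- tibble::tibble(
    index = which(conf < threshold),
    confidence = conf[conf < threshold],
    predicted = model$cfg$class_names[pred[conf < threshold] + 1L]
  )
  structure(list(metrics = classification_metrics(cm), confusion = cm,
                 prob = probs, pred = pred, truth = data$y,
                 confidence = conf, flagged = flagged,
                 threshold = threshold),
            class = "wha_eval")
}

#' @export
print.wha_eval <- function(x, ...) {
  print(x$metrics)
  cat(sprintf("%d / %d samples below confidence %.2f\n",
              nrow(x$flagged), length(x$pred), x$threshold))
  invisible(x)
}

#' Recompute batch-norm statistics with frozen weights
#'
#' Running a few frozen-weight forward passes over the training data and
#' averaging the per-batch moments gives exact population statistics for
#' the current weights ("precise BN"). With very few optimizer steps per
#' epoch the momentum-based running estimates lag far behind the weights
#' and make eval-mode predictions collapse; this removes that lag. Called
#' once per epoch by [train()] before validation.
#'
#' @param model a `wha_model`
#' @param x `(H,W,3,N)` training images
#' @param batch_size forward batch size
#' @return the model, invisibly (running statistics updated in place)
#' @export
recompute_bn_stats <- function(model, x, batch_size = 64L) {
  bns <- list()
  collect <- function(layer) {
    if (inherits(layer, "bn2d") || inherits(layer, "bnact"))
      bns[[length(bns) + 1L]] <<- layer
    for (ch in layer$children) collect(ch)
  }
  collect(model)
  n <- dim(x)[4]
  k <- 0L
  for (b in seq(1, n, by = batch_size)) {
    idx <- b:min(b + batch_size - 1L, n)
    if (length(idx) < 2L) next
    k <- k + 1L
    for (l in bns) l$momentum_save <- l$momentum
    for (l in bns) l$momentum <- 1 / k   # running = mean of batch stats
    invisible(layer_forward(model, x[, , , idx, drop = FALSE],
                            training = TRUE))
    for (l in bns) l$momentum <- l$momentum_save
  }
  invisible(model)
}

# freeze batch-norm statistics so a caching forward pass reproduces
# eval-mode outputs (used by Grad-CAM)
set_bn_frozen <- function(layer, frozen) {
  if (inherits(layer, "bn2d") || inherits(layer, "bnact"))
    layer$frozen_stats <- frozen
  for (ch in layer$children) set_bn_frozen(ch, frozen)
  invisible(layer)
}

#' Grad-CAM class activation heatmap
#'
#' Backpropagates the target-class score to a feature layer, averages
#' the gradients spatially into per-channel weights, rectifies the
#' weighted activation sum, upsamples bilinearly to the input size and
#' max-normalizes to `[0,1]` (an all-zero map is left as zeros).
#'
#' @param model a `wha_model` or `wha_fit`
#' @param image `(H,W,3)` array in `[0,1]`
#' @param target_class class index (0-based) or class name
#' @param target_layer name of the feature-stage layer to explain
#'   (default `"s6_amv"`, the last Agent-MViT stage)
#' @return a `wha_heatmap`: `H x W` matrix in `[0,1]` with attributes
#'   `class` and `score`
#' @export
grad_cam <- function(model, image, target_class,
                     target_layer = "s6_amv") {
  if (inherits(model, "wha_fit")) model <- model$model
  if (is.character(target_class)) {
    tc <- match(target_class, model$cfg$class_names)
    if (is.na(tc)) stop("unknown class: ", target_class)
  } else {
    tc <- as.integer(target_class) + 1L
    if (tc < 1 || tc > model$cfg$classes) stop("class index out of range")
  }
  feats <- model$children$features$children
  if (!target_layer %in% names(feats)) stop("unknown layer: ", target_layer)
  cc <- as_hwcn(image)
  set_bn_frozen(model, TRUE)
  on.exit(set_bn_frozen(model, FALSE))
  x <- whanet_standardize(cc$x)
  acts <- NULL
  for (nm in names(feats)) {
    x <- layer_forward(feats[[nm]], x, training = TRUE)
    if (nm == target_layer) acts <- x
  }
  h <- layer_forward(model$children$head_bn,
         layer_forward(model$children$head_conv, x, TRUE), TRUE)
  pooled <- t(layer_forward(model$children$gap, h, TRUE))
  logits <- layer_forward(model$children$classifier, pooled, TRUE)
  dlog <- matrix(0, 1, model$cfg$classes)
  dlog[1, tc] <- 1
  dpool <- t(layer_backward(model$children$classifier, dlog))
  dh <- layer_backward(model$children$gap, dpool)
  dx <- layer_backward(model$children$head_conv,
          layer_backward(model$children$head_bn, dh))
  post <- names(feats)[seq(match(target_layer, names(feats)) + 1L,
                           length(feats))]
  if (match(target_layer, names(feats)) == length(feats)) post <- character()
  for (nm in rev(post)) dx <- layer_backward(feats[[nm]], dx)
  # channel weights: spatial mean of the gradients
  d <- dim(acts)
  w <- colMeans(matrix(dx[, , , 1], d[1] * d[2], d[3]))
  cam <- matrix(matrix(acts[, , , 1], d[1] * d[2], d[3]) %*% w, d[1], d[2])
  cam <- pmax(cam, 0)
  up <- as.matrix(EBImage::resize(EBImage::Image(cam),
                                  w = dim(cc$x)[1], h = dim(cc$x)[2]))
  up <- pmax(up, 0)
  if (max(up) > 0) up <- up / max(up)
  structure(up, class = c("wha_heatmap", "matrix", "array"),
            heat_class = model$cfg$class_names[tc],
            score = logits[1, tc])
}
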