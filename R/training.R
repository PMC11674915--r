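#' Training configuration
#'
#' The reference training protocol: Adam over 100 epochs with batch size
#' 128, categorical cross-entropy, plateau learning-rate decay on validation
#' loss (factor 0.3, floor 1e-6), best-validation-accuracy checkpointing,
#' and no data augmentation. The initial learning rate (1e-3, the
#' optimizer's conventional default) and the plateau patience (5 epochs) are
#' unstated in the protocol and fixed here.
#'
#' @param epochs Training epochs.
#' @param batch_size Mini-batch size.
#' @param initial_lr Initial Adam learning rate.
#' @param plateau_factor Multiplicative learning-rate reduction on plateau.
#' @param plateau_min_lr Learning-rate floor.
#' @param plateau_patience Epochs of non-improving validation loss before a
#'   reduction.
#' @param seed Seed controlling batch shuffling.
#' @param image_size `(height, width)` to which inputs are resized; must
#'   match the model's input shape.
#' @return An object of class `train_config`.
#' @export
train_config <- function(epochs = 100L, batch_size = 128L, initial_lr = 1e-3,
                         plateau_factor = 0.3, plateau_min_lr = 1e-6,
                         plateau_patience = 5L, seed = 1L,
                         image_size = c(224L, 224L)) {
  if (plateau_min_lr > initial_lr)
    stop("plateau_min_lr must not exceed initial_lr", call. = FALSE)
  if (plateau_factor <= 0 || plateau_factor >= 1)
    stop("plateau_factor must lie in (0, 1)", call. = FALSE)
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 optimizer = "adam", initial_lr = initial_lr,
                 plateau_factor = plateau_factor,
                 plateau_min_lr = plateau_min_lr,
                 plateau_patience = as.integer(plateau_patience),
                 plateau_monitor = "val_loss",
                 checkpoint_monitor = "val_accuracy",
                 loss = "categorical_cross_entropy",
                 augmentation = FALSE, seed = as.integer(seed),
                 image_size = as.integer(image_size)),
            class = "train_config")
}

#' Preprocess an image for the network
#'
#' Bilinear resize to the target size, replication of grayscale input to 3
#' channels, and scaling to `[0, 1]`. No mean/variance standardization is
#' applied.
#'
#' @param image File path or `(H, W, C)` array.
#' @param size Target `(height, width)`.
#' @return Array `(size[1], size[2], 3)` with values in `[0, 1]`.
#' @export
preprocess <- function(image, size = c(224L, 224L)) {
  x <- if (is.character(image)) read_image(image) else image
  if (length(dim(x)) == 2L) dim(x) <- c(dim(x), 1L)
  d <- dim(x)
  if (d[1] != size[1] || d[2] != size[2])
    x <- bilinear_resize_cpp(x, d[1], d[2], d[3], size[1], size[2])
  if (dim(x)[3] == 1L) x <- array(x, c(size[1], size[2], 3L))
  x <- pmin(pmax(x, 0), 1)
  array(x, c(size[1], size[2], 3L))
}

# Stack a dataset index into a (H, W, 3, N) tensor plus 0-based labels.
load_tensor <- function(index, size) {
  n <- nrow(index)
  x <- array(0, c(size[1], size[2], 3L, n))
  for (i in seq_len(n)) x[, , , i] <- preprocess(index$path[i], size)
  list(x = x, y = index$class_index)
}

#' Plateau learning-rate update
#'
#' When validation loss has not improved for `plateau_patience` epochs, the
#' learning rate is multiplied by `plateau_factor` and clamped at
#' `plateau_min_lr`; otherwise it is unchanged.
#'
#' @param current_lr Current learning rate.
#' @param stale_epochs Epochs since the monitored loss last improved.
#' @param config A [train_config()].
#' @return The updated learning rate.
#' @export
plateau_update <- function(current_lr, stale_epochs, config = train_config()) {
  if (stale_epochs >= config$plateau_patience)
    max(current_lr * config$plateau_factor, config$plateau_min_lr)
  else current_lr
}

ce_loss_grad <- function(probs, y) {
  # probs: (K, N); y: 0-based labels
  n <- ncol(probs)
  ix <- cbind(y + 1L, seq_len(n))
  p <- pmax(probs[ix], 1e-12)
  dy <- matrix(0, nrow(probs), n)
  dy[ix] <- -1 / (n * p)
  list(loss = -mean(log(p)), grad = dy)
}

predict_batched <- function(model, x, batch = 32L, training = FALSE) {
  n <- dim(x)[4]
  out <- NULL
  for (s in seq(1L, n, by = batch)) {
    e <- min(s + batch - 1L, n)
    p <- predict(model, x[, , , s:e, drop = FALSE], training = training)
    out <- if (is.null(out)) p else cbind(out, p)
  }
  out
}

eval_loss_acc <- function(model, x, y, batch = 32L) {
  probs <- predict_batched(model, x, batch)
  ix <- cbind(y + 1L, seq_len(ncol(probs)))
  loss <- -mean(log(pmax(probs[ix], 1e-12)))
  pred <- max.col(t(probs), ties.method = "first") - 1L
  list(loss = loss, accuracy = mean(pred == y))
}

#' Train a model
#'
#' Mini-batch Adam with the plateau learning-rate schedule and
#' best-validation-accuracy checkpointing of the reference protocol. Batch
#' order is a pure function of `config$seed` (no augmentation), so runs are
#' reproducible. On completion the weights of the epoch with the highest
#' validation accuracy (ties: earliest epoch) are restored.
#'
#' @param model An `amdnet_model` whose softmax arity matches the class
#'   count.
#' @param partitions List with `train` and `val` `dataset_index` elements
#'   (as from [split_dataset()]).
#' @param config A [train_config()].
#' @param verbose Print per-epoch progress.
#' @return List with `model` (best checkpoint), `history` (data.frame with
#'   columns epoch, train_loss, train_accuracy, val_loss, val_accuracy,
#'   learning_rate).
#' @export
train <- function(model, partitions, config = train_config(),
                  verbose = FALSE) {
  stopifnot(inherits(model, "amdnet_model"))
  for (p in c("train", "val"))
    if (is.null(partitions[[p]]) || nrow(partitions[[p]]) == 0)
      stop("empty partition: ", p, call. = FALSE)
  size <- config$image_size
  if (size[1] != model$in_shape$height || size[2] != model$in_shape$width)
    stop("config image_size does not match the model input shape",
         call. = FALSE)
  tr <- load_tensor(partitions$train, size)
  va <- load_tensor(partitions$val, size)
  n <- dim(tr$x)[4]

  opt <- adam_init(model)
  lr <- config$initial_lr
  best_val <- -Inf
  best_w <- get_weights(model)
  best_bn <- get_bn_state(model)
  best_loss <- Inf
  stale <- 0L
  step <- 0L
  hist <- vector("list", config$epochs)

  for (epoch in seq_len(config$epochs)) {
    perm <- with_seed(config$seed + epoch, sample.int(n))
    ep_loss <- 0; ep_correct <- 0
    for (s in seq(1L, n, by = config$batch_size)) {
      e <- min(s + config$batch_size - 1L, n)
      ix <- perm[s:e]
      xb <- tr$x[, , , ix, drop = FALSE]
      yb <- tr$y[ix]
      zero_grads(model)
      probs <- nn_forward(model$net, xb, training = TRUE)
      lg <- ce_loss_grad(probs, yb)
      nn_backward(model$net, lg$grad)
      step <- step + 1L
      opt <- adam_step(model, opt, lr, step)
      ep_loss <- ep_loss + lg$loss * length(ix)
      pred <- max.col(t(probs), ties.method = "first") - 1L
      ep_correct <- ep_correct + sum(pred == yb)
    }
    clear_caches(model$net)
    vm <- eval_loss_acc(model, va$x, va$y)
    if (vm$accuracy > best_val) {
      best_val <- vm$accuracy
      best_w <- get_weights(model)
      best_bn <- get_bn_state(model)
    }
    if (vm$loss < best_loss - 1e-8) {
      best_loss <- vm$loss
      stale <- 0L
    } else {
      stale <- stale + 1L
    }
    new_lr <- plateau_update(lr, stale, config)
    if (new_lr < lr) stale <- 0L
    hist[[epoch]] <- data.frame(epoch = epoch, train_loss = ep_loss / n,
                                train_accuracy = ep_correct / n,
                                val_loss = vm$loss,
                                val_accuracy = vm$accuracy,
                                learning_rate = lr)
    lr <- new_lr
    if (verbose)
      message(sprintf(
        "epoch %3d  loss %.4f  acc %.3f  val_loss %.4f  val_acc %.3f  lr %g",
        epoch, ep_loss / n, ep_correct / n, vm$loss, vm$accuracy,
        hist[[epoch]]$learning_rate))
  }
  set_weights(model, best_w)
  set_bn_state(model, best_bn)
  clear_caches(model$net)
  list(model = model, history = do.call(rbind, hist))
}

#' Evaluate a model on a test partition
#'
#' Argmax predictions (ties broken toward the lowest class index) aggregated
#' into a confusion matrix and full metrics report.
#'
#' @param model A trained `amdnet_model`.
#' @param test A `dataset_index`.
#' @param image_size Input `(height, width)`; defaults to the model's input
#'   shape.
#' @return List with `confusion` ([confusion()] matrix) and `report`
#'   ([report()]).
#' @export
evaluate <- function(model, test,
                     image_size = c(model$in_shape$height,
                                    model$in_shape$width)) {
  stopifnot(inherits(test, "dataset_index"))
  if (nrow(test) == 0) stop("empty test partition", call. = FALSE)
  te <- load_tensor(test, image_size)
  probs <- predict_batched(model, te$x)
  pred <- max.col(t(probs), ties.method = "first") - 1L
  cls <- attr(test, "class_names")
  K <- max(length(cls), max(te$y) + 1L, nrow(probs))
  cm <- confusion(te$y, pred, K,
                  class_names = if (length(cls) == K) cls else NULL)
  list(confusion = cm, report = report(cm))
}

#' Write a training history as CSV
#'
#' Columns `epoch,train_loss,train_accuracy,val_loss,val_accuracy,`
#' `learning_rate`.
#'
#' @param history The `history` element of a [train()] result.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_history_csv <- function(history, path) {
  utils::write.csv(history, path, row.names = FALSE)
  invisible(path)
}

#' Plot training/validation convergence curves
#'
#' Accuracy and loss per epoch for training and validation, drawn with base
#' graphics (two panels).
#'
#' @param history A [train()] history data.frame.
#' @param path Optional PNG output path; when given, the plot is written
#'   there.
#' @return Invisibly, `history`.
#' @export
plot_history <- function(history, path = NULL) {
  draw <- function() {
    op <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
    on.exit(graphics::par(op))
    graphics::plot(history$epoch, history$train_accuracy, type = "l",
                   ylim = c(0, 1), xlab = "epoch", ylab = "accuracy",
                   main = "accuracy")
    graphics::lines(history$epoch, history$val_accuracy, lty = 2)
    graphics::legend("bottomright", c("train", "validation"), lty = 1:2,
                     bty = "n")
    yl <- range(c(history$train_loss, history$val_loss))
    graphics::plot(history$epoch, history$train_loss, type = "l", ylim = yl,
                   xlab = "epoch", ylab = "loss", main = "loss")
    graphics::lines(history$epoch, history$val_loss, lty = 2)
    graphics::legend("topright", c("train", "validation"), lty = 1:2,
                     bty = "n")
  }
  if (!is.null(path)) {
    grDevices::png(path, width = 900, height = 420)
    on.exit(grDevices::dev.off(), add = TRUE)
    draw()
  } else draw()
  invisible(history)
}
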