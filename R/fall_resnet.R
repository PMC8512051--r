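#' Network configuration for [fall_resnet()]
#'
#' @param channels feature-map widths of the four residual blocks. Each
#'   block halves the time resolution and (by default) doubles the channel
#'   count, the smallest standard residual layout that trains on a CPU.
#' @param kernel_width convolution kernel width (odd; default 3, i.e. the
#'   1x3 kernels the architecture is built from).
#' @param n_classes number of output classes (2: ADL vs fall).
#' @param learning_rate Adam learning rate (default 0.001).
#' @param max_epochs maximum training epochs (default 30).
#' @param batch_size mini-batch size (default 64).
#' @param seed integer seed controlling initialization and batch order.
#' @return a `net_config` list.
#' @export
net_config <- function(channels = c(16, 32, 64, 128), kernel_width = 3,
                       n_classes = 2, learning_rate = 0.001,
                       max_epochs = 30, batch_size = 64, seed = 0L) {
  if (kernel_width %% 2 != 1)
    stop_imbfall("`kernel_width` must be odd (zero 'same' padding)",
                 "imbfall_config_error")
  if (n_classes < 2)
    stop_imbfall("`n_classes` must be at least 2", "imbfall_config_error")
  assert_scalar_pos(learning_rate, "learning_rate", "imbfall_config_error")
  structure(list(channels = channels, kernel_width = as.integer(kernel_width),
                 n_classes = as.integer(n_classes),
                 learning_rate = learning_rate,
                 max_epochs = as.integer(max_epochs),
                 batch_size = as.integer(batch_size),
                 seed = as.integer(seed)),
            class = "net_config")
}

#' Fit a 1D residual-network fall classifier
#'
#' Trains a small residual convolutional network (four two-convolution
#' residual blocks with batch normalization and ReLU, global average
#' pooling and a softmax head) on labeled accelerometer windows, by
#' mini-batch Adam on the selected loss. The parameters of the epoch with
#' the lowest validation loss are returned.
#'
#' The fitted object predicts per-window posterior probabilities; turning
#' posteriors into fall decisions is the job of a [threshold_policy()]
#' (see [closed_form_threshold()] and [empirical_threshold()]), passed to
#' [predict.fall_resnet()].
#'
#' @param x a `split_corpus` (train and validation splits are used), or a
#'   `window_set`/array of training windows (then `y` and `validation`
#'   must be given).
#' @param y integer labels (0 = ADL, 1 = fall) when `x` is not a
#'   `split_corpus`.
#' @param validation list `list(x=, y=)` with validation windows/labels
#'   when `x` is not a `split_corpus`.
#' @param config a [net_config()].
#' @param loss `"cross_entropy"` (default), `"class_weight"`
#'   (inverse-frequency weighted cross-entropy, see [class_weights()]) or
#'   `"focal"` ([focal_loss()]).
#' @param gamma,alpha focal-loss parameters (used when
#'   `loss = "focal"`).
#' @return an object of class `fall_resnet` with components `params`
#'   (fitted weights), `history` (per-epoch train/validation loss and
#'   validation accuracy), `best_epoch`, `config`, `loss`, and the
#'   training class counts.
#' @examples
#' \donttest{
#' corpus <- sim_corpus(sim_config(n_adl = 12, n_fall = 4, master_seed = 1))
#' split <- split_corpus(window_corpus(corpus), seed = 1)
#' fit <- fall_resnet(split, config = net_config(max_epochs = 2, seed = 1))
#' predict(fit, split$test)[1:3, ]
#' }
#' @export
fall_resnet <- function(x, y = NULL, validation = NULL,
                        config = net_config(),
                        loss = c("cross_entropy", "class_weight", "focal"),
                        gamma = 2, alpha = 0.75) {
  loss <- match.arg(loss)
  if (inherits(x, "split_corpus")) {
    x_train <- x$train$x; y_train <- x$train$label
    x_val <- x$validation$x; y_val <- x$validation$label
  } else {
    if (inherits(x, "window_set")) { y <- y %||% x$label; x <- x$x }
    if (is.null(y) || is.null(validation))
      stop_imbfall("supply a split_corpus, or x, y and validation",
                   "imbfall_value_error")
    x_train <- x; y_train <- as.integer(y)
    xv <- validation$x
    if (inherits(xv, "window_set")) { x_val <- xv$x; y_val <- xv$label }
    else { x_val <- xv; y_val <- as.integer(validation$y) }
  }
  if (dim(x_train)[1] == 0L)
    stop_imbfall("empty training set", "imbfall_value_error")
  n_per_class <- tabulate(y_train + 1L, nbins = 2L)
  loss_spec <- switch(loss,
    cross_entropy = {
      if (any(n_per_class == 0L))
        warning("training data contain a single class; plain cross-entropy may be degenerate")
      list(type = "ce", weights = NULL)
    },
    class_weight = list(type = "ce", weights = class_weights(y_train)),
    focal = list(type = "focal", gamma = gamma, alpha = alpha))
  fit <- train_network(x_train, y_train, x_val, y_val, config, loss_spec)
  structure(list(params = fit$params, running = fit$running,
                 arch = fit$arch, history = fit$history,
                 best_epoch = fit$best_epoch,
                 best_val_loss = fit$best_val_loss,
                 config = config, loss = loss, loss_spec = loss_spec,
                 classes = c("adl", "fall"),
                 n_train = dim(x_train)[1], train_counts = n_per_class,
                 input_shape = dim(x_train)[-1]),
            class = "fall_resnet")
}

#' Posterior probabilities or thresholded classes from a fitted classifier
#'
#' @param object a fitted [fall_resnet()].
#' @param newdata a `window_set`, `split_corpus` split, or array
#'   `(n, timesteps, channels)` matching the training input shape.
#' @param type `"prob"` for the posterior matrix (columns `adl`, `fall`),
#'   `"class"` for 0/1 labels under `policy`.
#' @param policy a [threshold_policy()] used when `type = "class"`
#'   (default: the conventional 0.5 cutoff).
#' @param ... unused.
#' @return matrix of posteriors, or integer labels (1 = fall).
#' @export
predict.fall_resnet <- function(object, newdata, type = c("prob", "class"),
                                policy = threshold_policy(), ...) {
  type <- match.arg(type)
  x <- if (inherits(newdata, "window_set")) newdata$x else newdata
  if (length(dim(x)) != 3L ||
      !all(dim(x)[-1] == object$input_shape))
    stop_imbfall(sprintf("window shape (%s) does not match the trained input shape (%s)",
                         paste(dim(x)[-1], collapse = "x"),
                         paste(object$input_shape, collapse = "x")),
                 "imbfall_shape_error")
  p <- net_predict(x, object$params, object$arch, object$running)
  colnames(p) <- object$classes
  if (type == "prob") return(p)
  apply_threshold(p, policy)
}

#' @export
print.fall_resnet <- function(x, ...) {
  cat("1D residual-network fall classifier\n")
  cat(sprintf("  input %s windows; blocks: %s channels (stride-2 each)\n",
              paste(x$input_shape, collapse = " x "),
              paste(x$config$channels, collapse = "/")))
  cat(sprintf("  loss: %s; trained %d epoch(s), best validation loss %.4f at epoch %d\n",
              x$loss, nrow(x$history), x$best_val_loss, x$best_epoch))
  cat(sprintf("  train windows: %d ADL, %d fall (imbalance ratio %.2f)\n",
              x$train_counts[1], x$train_counts[2],
              x$train_counts[1] / max(x$train_counts[2], 1)))
  invisible(x)
}

#' @export
summary.fall_resnet <- function(object, ...) {
  npar <- sum(vapply(object$params, length, 0L))
  out <- list(n_parameters = npar, history = object$history,
              best_epoch = object$best_epoch,
              best_val_loss = object$best_val_loss,
              config = object$config, loss = object$loss,
              train_counts = object$train_counts)
  class(out) <- "summary.fall_resnet"
  out
}

#' @export
print.summary.fall_resnet <- function(x, ...) {
  cat(sprintf("fall_resnet: %d trainable parameters, loss = %s\n",
              x$n_parameters, x$loss))
  cat(sprintf("best epoch %d (validation loss %.4f)\n", x$best_epoch,
              x$best_val_loss))
  cat("\nTraining history:\n")
  print(x$history, row.names = FALSE)
  invisible(x)
}

#' @export
coef.fall_resnet <- function(object, ...) object$params

#' @export
plot.fall_resnet <- function(x, ...) {
  h <- x$history
  ylim <- range(c(h$train_loss, h$val_loss))
  plot(h$epoch, h$train_loss, type = "b", pch = 16, ylim = ylim,
       xlab = "epoch", ylab = "loss", ...)
  graphics::lines(h$epoch, h$val_loss, type = "b", pch = 1, lty = 2)
  graphics::abline(v = x$best_epoch, col = "grey60", lty = 3)
  graphics::legend("topright", c("train", "validation"), pch = c(16, 1),
                   lty = c(1, 2), bty = "n")
  invisible(x)
}
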