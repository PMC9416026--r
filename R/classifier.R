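# Compact residual CNN classifier.
#
# The fidelity protocol trains a from-scratch residual classifier on
# synthetic cubes and scores it on real ones.  The network is a small
# ResNet-style stack: a 3x3 stem, four residual blocks (three spatial
# halvings), global average pooling and a single logistic output for
# benign (0) vs malignant (1).  No pretrained weights are involved.

#' Residual classifier configuration
#'
#' @param width Stem channel count; block widths are `width`, `2*width`,
#'   `3*width`, `3*width`.
#' @param blocks Number of residual blocks (strides 2, 2, 2, then 1).
#' @param epochs Maximum training epochs.
#' @param batch_size Minibatch size.
#' @param lr Adam learning rate.
#' @param beta1,beta2 Adam moment coefficients.
#' @param l2_coeff L2 weight decay on convolution weights.
#' @param early_stop_acc Stop once training accuracy (eval mode) reaches
#'   this fraction (set above 1 to disable).
#' @param seed Seed for initialization and data order.
#' @param verbose Print one line per epoch.
#' @return An object of class `classifier_config`.
#' @export
classifier_config <- function(width = 16L, blocks = 4L, epochs = 50L,
                              batch_size = 32L, lr = 1e-3, beta1 = 0.9,
                              beta2 = 0.999, l2_coeff = 1e-5,
                              early_stop_acc = 1.0, seed = 1L,
                              verbose = FALSE) {
  if (!is_count(width) || width < 4) stop_config("width must be >= 4")
  if (!is_count(blocks) || blocks < 1 || blocks > 6)
    stop_config("blocks must be in 1..6")
  structure(list(width = as.integer(width), blocks = as.integer(blocks),
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), lr = lr,
                 beta1 = beta1, beta2 = beta2, l2_coeff = l2_coeff,
                 early_stop_acc = early_stop_acc, seed = as.integer(seed),
                 verbose = isTRUE(verbose)),
            class = "classifier_config")
}

build_classifier_net <- function(input_dim, config) {
  w <- config$width
  widths <- c(w, 2L * w, 3L * w, 3L * w, 3L * w, 3L * w)[seq_len(config$blocks)]
  strides <- c(2L, 2L, 2L, 1L, 1L, 1L)[seq_len(config$blocks)]
  net <- list(layer_conv(input_dim[3], w, 3L, 1L, 1L),
              layer_bn(w), layer_act("relu"))
  Cin <- w
  H <- input_dim[1]
  for (i in seq_len(config$blocks)) {
    s <- if (H <= 2L) 1L else strides[i]  # never collapse below 2x2
    net[[length(net) + 1L]] <- layer_resblock(Cin, widths[i], s)
    Cin <- widths[i]
    H <- conv_out_size(H, 3L, s, 1L)
  }
  net[[length(net) + 1L]] <- layer_gap()
  net[[length(net) + 1L]] <- layer_dense(Cin, 1L, init_sd = 0.05)
  net
}

classifier_stack <- function(cubes) {
  d <- dim(cubes[[1]]$data)
  X <- array(0, c(d, length(cubes)))
  for (i in seq_along(cubes)) {
    if (!all(dim(cubes[[i]]$data) == d))
      stop_dimension("all cubes must share the same shape")
    X[, , , i] <- 2 * cubes[[i]]$data - 1
  }
  X
}

classifier_logits <- function(net, X, batch = 64L, training = FALSE) {
  n <- dim(X)[4]
  out <- numeric(n)
  for (start in seq(1L, n, by = batch)) {
    idx <- start:min(n, start + batch - 1L)
    out[idx] <- as.vector(net_forward(net, X[, , , idx, drop = FALSE],
                                      training))
  }
  out
}

#' Fit the compact residual lesion classifier
#'
#' Trains from scratch with Adam on binary cross-entropy (malignant = 1),
#' stopping early once training accuracy reaches
#' `config$early_stop_acc`.
#'
#' @param cubes List of [hsi_cube()] of identical shape.
#' @param labels Optional class vector; defaults to the cube labels.
#' @param config A [classifier_config()].
#' @return An object of class `lesion_classifier` with a
#'   [predict.lesion_classifier()] method; `$train_accuracy` holds the
#'   final training-set accuracy in percent.
#' @examples
#' \donttest{
#' cubes <- make_phantom_dataset(
#'   phantom_params(height = 16, width = 16, bands = 8, seed = 1), 10, 10)
#' clf <- fit_lesion_classifier(cubes, config = classifier_config(
#'   width = 8, epochs = 5, seed = 1))
#' clf$train_accuracy
#' }
#' @export
fit_lesion_classifier <- function(cubes, labels = NULL,
                                  config = classifier_config()) {
  if (!length(cubes)) stop_data("empty training set")
  labels <- labels %||% vapply(cubes, function(cb) cb$label %||% NA_character_,
                               character(1))
  if (anyNA(labels)) stop_data("every training cube needs a class label")
  if (length(unique(labels)) < 2L)
    stop_data("both classes must be present in the training set")
  y <- as.numeric(labels == "malignant")
  X <- classifier_stack(cubes)
  d <- dim(X)
  net <- with_seed(stream_seed(config$seed, "classifier_init"),
                   build_classifier_net(d[1:3], config))
  n <- d[4]
  history <- data.frame(epoch = integer(), loss = numeric(),
                        accuracy = numeric())
  t_step <- 0L
  with_seed(stream_seed(config$seed, "classifier_train"), {
    for (ep in seq_len(config$epochs)) {
      perm <- sample.int(n)
      steps <- split(perm, ceiling(seq_along(perm) / config$batch_size))
      tot <- 0
      for (idx in steps) {
        net_zero_grads(net)
        logits <- as.vector(net_forward(net, X[, , , idx, drop = FALSE],
                                        training = TRUE))
        p <- 1 / (1 + exp(-logits))
        tot <- tot + binary_cross_entropy(p, y[idx]) * length(idx)
        g <- matrix((p - y[idx]) / length(idx), 1L)
        net_backward(net, g)
        t_step <- t_step + 1L
        adam_step(net, config$lr, t_step, config$beta1, config$beta2,
                  l2 = config$l2_coeff)
      }
      acc <- mean((classifier_logits(net, X) > 0) == (y == 1))
      history <- rbind(history, data.frame(epoch = ep, loss = tot / n,
                                           accuracy = acc))
      if (config$verbose)
        message(sprintf("classifier epoch %3d  loss %.4f  acc %.3f",
                        ep, tot / n, acc))
      if (acc >= config$early_stop_acc) break
    }
  })
  structure(list(net = net, config = config, classes = c("benign", "malignant"),
                 input_dim = d[1:3], history = history,
                 train_accuracy = 100 * history$accuracy[nrow(history)]),
            class = "lesion_classifier")
}

rebuild_classifier <- function(ck) {
  net <- with_seed(1L, build_classifier_net(ck$input_dim, ck$config))
  net_set_params(net, ck$params)
  structure(list(net = net, config = ck$config,
                 classes = ck$classes, input_dim = ck$input_dim,
                 history = ck$history, train_accuracy = ck$train_accuracy),
            class = "lesion_classifier")
}

#' @export
print.lesion_classifier <- function(x, ...) {
  cat(sprintf(
    "<lesion_classifier> %d residual blocks, width %d, %d epochs, train accuracy %.2f%%\n",
    x$config$blocks, x$config$width, nrow(x$history), x$train_accuracy))
  invisible(x)
}

#' Predict lesion classes
#'
#' @param object A fitted `lesion_classifier`.
#' @param cubes List of [hsi_cube()] matching the training shape.
#' @param type `"class"`, `"prob"` (malignant probability), `"logit"`, or
#'   `"features"` (penultimate global-average-pool activations, used as
#'   the optional learned embedding for Frechet distances).
#' @param ... Unused.
#' @return Character vector, numeric vector, or feature matrix.
#' @export
predict.lesion_classifier <- function(object, cubes,
                                      type = c("class", "prob", "logit",
                                               "features"), ...) {
  type <- match.arg(type)
  X <- classifier_stack(cubes)
  if (!all(dim(X)[1:3] == object$input_dim))
    stop_dimension("cube shape does not match the classifier input")
  if (type == "features") {
    # forward through everything but the final dense head
    n <- dim(X)[4]
    net <- object$net[-length(object$net)]
    feats <- NULL
    for (start in seq(1L, n, by = 64L)) {
      idx <- start:min(n, start + 63L)
      f <- net_forward(net, X[, , , idx, drop = FALSE], FALSE)
      feats <- cbind(feats, f)
    }
    return(t(feats))
  }
  logits <- classifier_logits(object$net, X)
  switch(type,
    logit = logits,
    prob = 1 / (1 + exp(-logits)),
    class = ifelse(logits > 0, "malignant", "benign"))
}
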