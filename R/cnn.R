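#' CNN architecture specification
#'
#' The posture network is a shallow two-block convolutional architecture:
#' conv(32 filters, 3x3, ReLU) -> 2x2 max pool -> conv(64 filters, 3x3,
#' ReLU) -> 2x2 max pool -> flatten -> dense(128, ReLU) -> dense(n_classes,
#' softmax), trained with Adam on the cross-entropy loss with early
#' stopping on validation loss. Convolutions use 'same' zero padding, so a
#' 32x32 dual-mat input flattens to 64 x 8 x 8 = 4096 features. A pooling
#' stage is skipped whenever the current spatial side is below 8, which
#' keeps the architecture applicable to the downsampled frames of the
#' resolution study (e.g. a 5x5 input flattens to 64 x 5 x 5 = 1600).
#'
#' @param input_channels input channels (2: seat and backrest stacked).
#' @param grid spatial side length of the input.
#' @param conv1_filters,conv2_filters filters in the two conv layers.
#' @param kernel convolution kernel side (3).
#' @param pool pooling window side (2).
#' @param dense_units width of the hidden dense layer.
#' @param n_classes output units (one per posture).
#' @param learning_rate,batch_size,max_epochs,early_stopping_patience
#'   Adam/early-stopping settings.
#' @param seed seed for weight initialization and batch shuffling.
#' @return An object of class `cnn_spec`.
#' @export
cnn_spec <- function(input_channels = 2L, grid = 32L, conv1_filters = 32L,
                     conv2_filters = 64L, kernel = 3L, pool = 2L,
                     dense_units = 128L, n_classes = 19L,
                     learning_rate = 1e-3, batch_size = 32L,
                     max_epochs = 100L, early_stopping_patience = 5L,
                     seed = 42L) {
  stopifnot(kernel == 3L, pool == 2L)  # the compiled kernels are 3x3 / 2x2
  structure(list(input_channels = as.integer(input_channels),
                 grid = as.integer(grid),
                 conv1_filters = as.integer(conv1_filters),
                 conv2_filters = as.integer(conv2_filters),
                 kernel = 3L, pool = 2L,
                 dense_units = as.integer(dense_units),
                 n_classes = as.integer(n_classes),
                 learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 early_stopping_patience = as.integer(early_stopping_patience),
                 seed = as.integer(seed)),
            class = "cnn_spec")
}

# spatial geometry implied by the spec (mirrors the compiled code)
cnn_geometry <- function(spec) {
  H <- spec$grid
  pool1 <- H >= 8
  H2 <- if (pool1) H %/% 2L else H
  pool2 <- H2 >= 8
  H3 <- if (pool2) H2 %/% 2L else H2
  list(H = H, H2 = H2, H3 = H3, pool1 = pool1, pool2 = pool2,
       flatten = spec$conv2_filters * H3 * H3)
}

#' Build an untrained CNN
#'
#' Instantiates the layer stack of [cnn_spec()] with He-initialized weights
#' drawn under the spec seed.
#'
#' @param spec a [cnn_spec()].
#' @return An object of class `sit_cnn` holding the weight tensors, the
#'   geometry and per-layer parameter counts.
#' @examples
#' net <- build_cnn(cnn_spec())
#' cnn_param_count(net)
#' @export
build_cnn <- function(spec = cnn_spec()) {
  stopifnot(inherits(spec, "cnn_spec"))
  g <- cnn_geometry(spec)
  C <- spec$input_channels
  f1 <- spec$conv1_filters; f2 <- spec$conv2_filters
  du <- spec$dense_units; K <- spec$n_classes
  he <- function(nr, nc, fan_in) {
    matrix(rnorm(nr * nc, 0, sqrt(2 / fan_in)), nr, nc)
  }
  weights <- with_seed(spec$seed, list(
    W1 = he(C * 9L, f1, C * 9L), b1 = rep(0, f1),
    W2 = he(f1 * 9L, f2, f1 * 9L), b2 = rep(0, f2),
    W3 = he(du, g$flatten, g$flatten), b3 = rep(0, du),
    W4 = matrix(rnorm(K * du, 0, sqrt(1 / du)), K, du), b4 = rep(0, K)
  ))
  counts <- c(conv1 = (C * 9L) * f1 + f1,
              conv2 = (f1 * 9L) * f2 + f2,
              dense1 = g$flatten * du + du,
              dense2 = du * K + K)
  structure(list(spec = spec, geometry = g, weights = weights,
                 param_counts = counts),
            class = "sit_cnn")
}

#' @rdname build_cnn
#' @param net a `sit_cnn`.
#' @export
cnn_param_count <- function(net) {
  stopifnot(inherits(net, "sit_cnn"))
  c(net$param_counts, total = sum(net$param_counts))
}

# features for the CNN: (C*H*H) x n, channel planes seat then back,
# column-major within each plane, normalized scale
cnn_features <- function(ds) {
  x <- dataset_features(ds)
  if (ds$scale == "raw") x <- x / 255
  t(x)
}

train_cnn <- function(train, val, spec) {
  classes <- levels(droplevels(train$labels))
  spec$n_classes <- length(classes)
  spec$grid <- train$resolution
  net <- build_cnn(spec)
  X <- cnn_features(train)
  y <- as.integer(factor(train$labels, levels = classes)) - 1L
  Xv <- cnn_features(val)
  yv <- as.integer(factor(val$labels, levels = classes)) - 1L
  if (anyNA(yv)) stop("validation split contains unregistered classes",
                      call. = FALSE)
  n <- ncol(X)
  perms <- with_seed(spec$seed + 1L,
                     vapply(seq_len(spec$max_epochs), function(e) sample.int(n),
                            integer(n)))
  fit <- cnn_train_cpp(X, y, Xv, yv, spec$input_channels, spec$grid,
                       net$weights, spec$learning_rate, spec$batch_size,
                       spec$max_epochs, spec$early_stopping_patience,
                       perms)
  list(weights = fit$weights, history = fit$history,
       best_epoch = fit$best_epoch, epochs_run = fit$epochs_run,
       spec = spec, classes = classes)
}

cnn_probabilities <- function(fit, ds) {
  p <- cnn_predict_cpp(fit$weights, cnn_features(ds),
                       fit$spec$input_channels, ds$resolution)
  p <- t(p)
  colnames(p) <- fit$classes
  p
}
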