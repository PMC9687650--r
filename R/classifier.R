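#' Layer specification of the CNN backbone
#'
#' @param kind One of `"conv1d"`, `"batchnorm"`, `"maxpool"`, `"dense"`,
#'   `"output"`.
#' @param kernel Kernel / pool width (where applicable).
#' @param units Channel count or dense width (where applicable).
#' @param stride Stride (where applicable).
#' @param activation Logical: ReLU after the layer (softmax for `"output"`).
#' @return An object of class `layer_spec`.
#' @export
layer_spec <- function(kind, kernel = NA_integer_, units = NA_integer_,
                       stride = NA_integer_, activation = FALSE) {
  kind <- match.arg(kind, c("conv1d", "batchnorm", "maxpool", "dense", "output"))
  for (v in c(kernel, units, stride)) {
    if (!is.na(v) && v < 1) stop_invalid("kernel/units/stride must be >= 1")
  }
  structure(list(kind = kind, kernel = kernel, units = units,
                 stride = stride, activation = activation),
            class = "layer_spec")
}

## closed-form output length of the conv/pool arithmetic (valid padding,
## floor division)
conv_out_len <- function(len, kernel, stride) (len - kernel) %/% stride + 1L

cnn_layer_table <- function(n_classes, dense_units) {
  list(layer_spec("conv1d", kernel = 50L, units = 128L, stride = 3L, activation = TRUE),
       layer_spec("batchnorm", units = 128L),
       layer_spec("maxpool", kernel = 2L, stride = 3L),
       layer_spec("conv1d", kernel = 8L, units = 32L, stride = 1L, activation = TRUE),
       layer_spec("batchnorm", units = 32L),
       layer_spec("maxpool", kernel = 2L, stride = 2L),
       layer_spec("conv1d", kernel = 5L, units = 512L, stride = 1L, activation = TRUE),
       layer_spec("conv1d", kernel = 3L, units = 128L, stride = 1L, activation = TRUE),
       layer_spec("dense", units = as.integer(dense_units), activation = TRUE),
       layer_spec("output", units = as.integer(n_classes)))
}

#' Build the 10-layer 1-D CNN beat classifier
#'
#' The fixed backbone used as feature extractor + classifier on fixed-length
#' beat vectors: conv1d(50, 128, stride 3) + ReLU; batch norm; max pool
#' (2, stride 3); conv1d(8, 32) + ReLU; batch norm; max pool (2, stride 2);
#' conv1d(5, 512) + ReLU; conv1d(3, 128) + ReLU; a fully connected layer;
#' and a softmax output layer. Convolutions use valid padding, pooling uses
#' floor division, so the shape arithmetic is exact.
#'
#' @param input_length Samples per input beat (must be long enough for the
#'   receptive field; 360 by default).
#' @param n_classes Number of output classes (`>= 2`).
#' @param dense_units Width of the fully connected layer (64 by default).
#' @return An object of class `cnn_classifier`: `spec` (10 [layer_spec()]s),
#'   `model` (instantiated network), `shapes` (per-stage lengths x channels),
#'   `input_length`, `n_classes`.
#' @examples
#' cnn <- build_cnn(360, 5)
#' length(cnn$spec) # 10
#' @export
build_cnn <- function(input_length, n_classes, dense_units = 64) {
  input_length <- as.integer(input_length)
  if (n_classes < 2) stop_invalid("n_classes must be >= 2")
  if (input_length < 50) stop_invalid("input_length must be >= 50 (first kernel)")
  spec <- cnn_layer_table(n_classes, dense_units)

  ## shape propagation with validity checks
  len <- input_length; ch <- 1L
  shapes <- list(c(len = len, ch = ch))
  for (l in spec) {
    if (l$kind == "conv1d") {
      if (len < l$kernel) stop_invalid("input too short for the receptive field")
      len <- conv_out_len(len, l$kernel, l$stride); ch <- l$units
    } else if (l$kind == "maxpool") {
      if (len < l$kernel) stop_invalid("input too short for the receptive field")
      len <- conv_out_len(len, l$kernel, l$stride)
    } else if (l$kind == "dense") {
      len <- l$units; ch <- 1L
    } else if (l$kind == "output") {
      len <- l$units
    }
    if (len < 1) stop_invalid("input too short for the receptive field")
    shapes <- c(shapes, list(c(len = len, ch = ch)))
  }

  flat <- shapes[[9]][["len"]] * shapes[[9]][["ch"]]
  model <- nn_init(list(
    nn_conv1d(50, 1, 128, 3, "relu"),
    nn_batchnorm(128),
    nn_maxpool(2, 3),
    nn_conv1d(8, 128, 32, 1, "relu"),
    nn_batchnorm(32),
    nn_maxpool(2, 2),
    nn_conv1d(5, 32, 512, 1, "relu"),
    nn_conv1d(3, 512, 128, 1, "relu"),
    nn_flatten(),
    nn_dense(flat, dense_units, "relu"),
    nn_dense(dense_units, n_classes, "softmax")))

  structure(list(spec = spec, model = model, shapes = shapes,
                 input_length = input_length, n_classes = as.integer(n_classes),
                 dense_units = as.integer(dense_units)),
            class = "cnn_classifier")
}

#' Total trainable parameter count of a built CNN
#'
#' @param cnn A [build_cnn()] result.
#' @return Integer parameter count (a pure function of `input_length`,
#'   `n_classes`, `dense_units`).
#' @export
cnn_parameter_count <- function(cnn) {
  sum(vapply(cnn$model$layers, function(l) {
    sum(vapply(nn_param_names(l), function(p) length(l[[p]]), numeric(1)))
  }, numeric(1)))
}

cnn_input_array <- function(cnn, x) {
  x <- as.matrix(x)
  if (ncol(x) != cnn$input_length) {
    stop_invalid("input has ", ncol(x), " samples; expected ", cnn$input_length)
  }
  array(x, c(nrow(x), ncol(x), 1L))
}

#' Forward pass of the CNN classifier
#'
#' @param object A `cnn_classifier`.
#' @param x Matrix of beats (one per row, `input_length` columns).
#' @param ... Unused.
#' @return A list with `probs` (rows sum to 1) and `labels` (0-based).
#' @export
predict.cnn_classifier <- function(object, x, ...) {
  p <- nn_forward(object$model, cnn_input_array(object, x), train = FALSE)$out
  list(probs = p, labels = max.col(p, ties.method = "first") - 1L)
}

#' Training configuration for the CNN classifier
#'
#' @param epochs Training epochs (0 leaves the model unchanged).
#' @param batch Minibatch size.
#' @param lr Learning rate of the adaptive-gradient (Adam) optimizer.
#' @param seed RNG seed; training is deterministic given it.
#' @return A list of class `classifier_config`.
#' @export
classifier_config <- function(epochs = 30, batch = 16, lr = 1e-3, seed = 1) {
  if (epochs < 0 || batch < 1 || lr <= 0) stop_invalid("invalid training config")
  structure(as.list(environment()), class = "classifier_config")
}

#' Train the CNN classifier
#'
#' Minibatch cross-entropy training with an adaptive-gradient optimizer;
#' deterministic given the config seed. Resample beats to the model's
#' `input_length` with [resample_beat()] before training if needed.
#'
#' @param cnn A [build_cnn()] result.
#' @param x Matrix of beats (rows), `input_length` columns.
#' @param y 0-based integer labels in `0:(n_classes - 1)`.
#' @param config A [classifier_config()].
#' @return The `cnn_classifier` with trained weights and a `loss_curve`
#'   field (mean training loss per epoch).
#' @export
train_classifier <- function(cnn, x, y, config = classifier_config()) {
  stopifnot(inherits(cnn, "cnn_classifier"))
  x <- as.matrix(x); y <- as.integer(y)
  if (nrow(x) != length(y)) stop_invalid("sample/label length mismatch")
  present <- sort(unique(y))
  if (length(present) < cnn$n_classes) {
    warning("degenerate split: ", cnn$n_classes - length(present),
            " class(es) absent from the training data")
  }
  if (config$epochs == 0) {
    cnn$loss_curve <- numeric(0)
    return(cnn)
  }
  with_seed(config$seed, {
    model <- cnn$model
    opt <- nn_opt_init(model, "adam", lr = config$lr)
    n <- nrow(x)
    curve <- numeric(config$epochs)
    for (e in seq_len(config$epochs)) {
      ord <- sample.int(n)
      losses <- numeric(0)
      for (start in seq(1, n, by = config$batch)) {
        idx <- ord[start:min(start + config$batch - 1, n)]
        xb <- cnn_input_array(cnn, x[idx, , drop = FALSE])
        fw <- nn_forward(model, xb, train = TRUE)
        model <- fw$model  # batchnorm running stats
        ce <- ce_loss(fw$out, one_hot(y[idx], cnn$n_classes))
        losses <- c(losses, ce$loss)
        bw <- nn_backward(model, fw$caches, ce$dprobs)
        st <- nn_opt_step(model, bw$grads, opt, sign = -1)
        model <- st$model; opt <- st$opt
      }
      curve[e] <- mean(losses)
    }
    cnn$model <- model
    cnn$loss_curve <- curve
    cnn
  })
}

#' Resample a beat vector to a fixed length
#'
#' Linear interpolation onto `input_length` equally spaced points, the
#' fixed-length representation the CNN consumes.
#'
#' @param samples Numeric beat samples.
#' @param input_length Target length (default 360).
#' @return Numeric vector of length `input_length`.
#' @export
resample_beat <- function(samples, input_length = 360) {
  n <- length(samples)
  if (n < 2) stop_invalid("beat must have at least 2 samples")
  stats::approx(seq_len(n), samples, n = input_length)$y
}
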