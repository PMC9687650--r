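## Minimal feed-forward engine: dense / conv1d / batchnorm / maxpool / flatten
## layers with manual backpropagation. Inputs are matrices (n x d) for dense
## stacks or arrays (n x length x channels) for convolutional stacks.
## Everything is deterministic given the RNG state at init/training time.

nn_dense <- function(units_in, units_out, activation = "linear") {
  stopifnot(units_in >= 1, units_out >= 1)
  activation <- match.arg(activation,
                          c("linear", "relu", "tanh", "sigmoid", "softmax"))
  list(type = "dense", units_in = units_in, units_out = units_out,
       activation = activation)
}

nn_conv1d <- function(kernel, ch_in, ch_out, stride = 1, activation = "relu") {
  stopifnot(kernel >= 1, ch_in >= 1, ch_out >= 1, stride >= 1)
  list(type = "conv1d", kernel = kernel, ch_in = ch_in, ch_out = ch_out,
       stride = stride, activation = activation)
}

nn_batchnorm <- function(channels, eps = 1e-5, momentum = 0.1) {
  list(type = "batchnorm", channels = channels, eps = eps, momentum = momentum)
}

nn_maxpool <- function(size = 2, stride = 2) {
  stopifnot(size >= 1, stride >= 1)
  list(type = "maxpool", size = size, stride = stride)
}

nn_flatten <- function() list(type = "flatten")

## Instantiate parameters for a list of layer specs. Uses the current RNG
## stream (callers wrap in with_seed for reproducibility).
nn_init <- function(layers) {
  for (i in seq_along(layers)) {
    l <- layers[[i]]
    if (l$type == "dense") {
      sd <- sqrt(2 / l$units_in)
      l$W <- matrix(stats::rnorm(l$units_in * l$units_out, sd = sd),
                    l$units_in, l$units_out)
      l$b <- numeric(l$units_out)
    } else if (l$type == "conv1d") {
      fan_in <- l$kernel * l$ch_in
      l$W <- matrix(stats::rnorm(fan_in * l$ch_out, sd = sqrt(2 / fan_in)),
                    fan_in, l$ch_out)
      l$b <- numeric(l$ch_out)
    } else if (l$type == "batchnorm") {
      l$gamma <- rep(1, l$channels)
      l$beta <- numeric(l$channels)
      l$run_mean <- numeric(l$channels)
      l$run_var <- rep(1, l$channels)
    }
    layers[[i]] <- l
  }
  structure(list(layers = layers), class = "distecg_nn")
}

nn_act <- function(z, activation) {
  switch(activation,
         linear = z,
         relu = pmax(z, 0),
         tanh = tanh(z),
         sigmoid = 1 / (1 + exp(-z)),
         softmax = {
           z <- z - apply(z, 1, max)
           e <- exp(z)
           e / rowSums(e)
         })
}

nn_act_grad <- function(dout, a, z, activation) {
  switch(activation,
         linear = dout,
         relu = dout * (z > 0),
         tanh = dout * (1 - a^2),
         sigmoid = dout * a * (1 - a),
         softmax = a * (dout - rowSums(dout * a)))
}

## im2col for conv1d: returns (n*out_len) x (kernel*ch_in), position-major blocks
conv_cols <- function(x, kernel, stride, out_len) {
  n <- dim(x)[1]; ch <- dim(x)[3]
  cols <- matrix(0, n * out_len, kernel * ch)
  for (t in seq_len(out_len)) {
    s <- (t - 1) * stride + 1
    patch <- x[, s:(s + kernel - 1), , drop = FALSE]
    dim(patch) <- c(n, kernel * ch)
    cols[((t - 1) * n + 1):(t * n), ] <- patch
  }
  cols
}

nn_forward <- function(model, x, train = TRUE) {
  caches <- vector("list", length(model$layers))
  for (i in seq_along(model$layers)) {
    l <- model$layers[[i]]
    if (l$type == "dense") {
      z <- sweep(x %*% l$W, 2, l$b, "+")
      a <- nn_act(z, l$activation)
      caches[[i]] <- list(x = x, z = z, a = a)
      x <- a
    } else if (l$type == "conv1d") {
      n <- dim(x)[1]; len <- dim(x)[2]
      if (len < l$kernel) {
        stop_invalid("input length ", len, " shorter than kernel ", l$kernel)
      }
      out_len <- (len - l$kernel) %/% l$stride + 1
      cols <- conv_cols(x, l$kernel, l$stride, out_len)
      zm <- sweep(cols %*% l$W, 2, l$b, "+")
      z <- array(zm, c(n, out_len, l$ch_out))
      a <- if (l$activation == "relu") pmax(z, 0) else z
      caches[[i]] <- list(dim_in = dim(x), cols = cols, z = z)
      x <- a
    } else if (l$type == "batchnorm") {
      conv_in <- length(dim(x)) == 3
      xm <- if (conv_in) {
        n <- dim(x)[1]; len <- dim(x)[2]
        matrix(x, n * len, dim(x)[3])
      } else x
      if (train) {
        mu <- colMeans(xm)
        v <- colMeans(sweep(xm, 2, mu)^2)
        model$layers[[i]]$run_mean <-
          (1 - l$momentum) * l$run_mean + l$momentum * mu
        model$layers[[i]]$run_var <-
          (1 - l$momentum) * l$run_var + l$momentum * v
      } else {
        mu <- l$run_mean
        v <- l$run_var
      }
      sd_inv <- 1 / sqrt(v + l$eps)
      xhat <- sweep(sweep(xm, 2, mu), 2, sd_inv, "*")
      out <- sweep(sweep(xhat, 2, l$gamma, "*"), 2, l$beta, "+")
      if (conv_in) dim(out) <- dim(x)
      caches[[i]] <- list(xhat = xhat, sd_inv = sd_inv, dim_in = dim(x),
                          conv_in = conv_in)
      x <- out
    } else if (l$type == "maxpool") {
      n <- dim(x)[1]; len <- dim(x)[2]; ch <- dim(x)[3]
      out_len <- (len - l$size) %/% l$stride + 1
      if (out_len < 1) stop_invalid("input length ", len, " too short for pool")
      a <- array(-Inf, c(n, out_len, ch))
      arg <- array(1L, c(n, out_len, ch))
      for (k in seq_len(l$size)) {
        idx <- (seq_len(out_len) - 1) * l$stride + k
        slice <- x[, idx, , drop = FALSE]
        upd <- slice > a
        a[upd] <- slice[upd]
        arg[upd] <- k
      }
      caches[[i]] <- list(dim_in = dim(x), arg = arg, out_len = out_len)
      x <- a
    } else if (l$type == "flatten") {
      caches[[i]] <- list(dim_in = dim(x))
      dim(x) <- c(dim(x)[1], prod(dim(x)[-1]))
    }
  }
  list(out = x, caches = caches, model = model)
}

## dout: gradient of the loss w.r.t. the model output. Returns per-layer
## parameter gradients plus the gradient w.r.t. the input.
nn_backward <- function(model, caches, dout) {
  grads <- vector("list", length(model$layers))
  for (i in rev(seq_along(model$layers))) {
    l <- model$layers[[i]]
    cc <- caches[[i]]
    if (l$type == "dense") {
      dz <- nn_act_grad(dout, cc$a, cc$z, l$activation)
      grads[[i]] <- list(W = crossprod(cc$x, dz), b = colSums(dz))
      dout <- tcrossprod(dz, l$W)
    } else if (l$type == "conv1d") {
      dz <- if (l$activation == "relu") dout * (cc$z > 0) else dout
      n <- dim(dz)[1]; out_len <- dim(dz)[2]
      dzm <- matrix(dz, n * out_len, l$ch_out)
      grads[[i]] <- list(W = crossprod(cc$cols, dzm), b = colSums(dzm))
      dcols <- tcrossprod(dzm, l$W)
      dx <- array(0, cc$dim_in)
      kch <- l$kernel * dim(dx)[3]
      for (t in seq_len(out_len)) {
        s <- (t - 1) * l$stride + 1
        block <- dcols[((t - 1) * n + 1):(t * n), , drop = FALSE]
        dim(block) <- c(n, l$kernel, dim(dx)[3])
        dx[, s:(s + l$kernel - 1), ] <-
          dx[, s:(s + l$kernel - 1), , drop = FALSE] + block
      }
      dout <- dx
    } else if (l$type == "batchnorm") {
      dm <- if (cc$conv_in) {
        matrix(dout, prod(cc$dim_in[1:2]), cc$dim_in[3])
      } else dout
      m <- nrow(dm)
      dgamma <- colSums(dm * cc$xhat)
      dbeta <- colSums(dm)
      dxhat <- sweep(dm, 2, l$gamma, "*")
      dx <- sweep(dxhat - matrix(colMeans(dxhat), m, ncol(dm), byrow = TRUE) -
                    sweep(cc$xhat, 2, colMeans(dxhat * cc$xhat), "*"),
                  2, cc$sd_inv, "*")
      grads[[i]] <- list(gamma = dgamma, beta = dbeta)
      if (cc$conv_in) dim(dx) <- cc$dim_in
      dout <- dx
    } else if (l$type == "maxpool") {
      dx <- array(0, cc$dim_in)
      n <- cc$dim_in[1]; ch <- cc$dim_in[3]
      for (k in seq_len(l$size)) {
        idx <- (seq_len(cc$out_len) - 1) * l$stride + k
        mask <- cc$arg == k
        contrib <- dout * mask
        dx[, idx, ] <- dx[, idx, , drop = FALSE] + contrib
      }
      dout <- dx
    } else if (l$type == "flatten") {
      dim(dout) <- cc$dim_in
    }
  }
  list(grads = grads, dinput = dout)
}

## ---- optimizers ------------------------------------------------------------

nn_param_names <- function(layer) {
  switch(layer$type,
         dense = c("W", "b"),
         conv1d = c("W", "b"),
         batchnorm = c("gamma", "beta"),
         character(0))
}

nn_opt_init <- function(model, method = c("sgd", "adam"),
                        lr = 1e-2, momentum = 0.9,
                        beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  method <- match.arg(method)
  slots <- lapply(model$layers, function(l) {
    nm <- nn_param_names(l)
    st <- lapply(nm, function(p) {
      v <- l[[p]] * 0
      if (method == "adam") list(m = v, v = v) else list(v = v)
    })
    names(st) <- nm
    st
  })
  list(method = method, lr = lr, momentum = momentum,
       beta1 = beta1, beta2 = beta2, eps = eps, t = 0L, slots = slots)
}

## sign = -1 for gradient descent (minimize), +1 for ascent (maximize)
nn_opt_step <- function(model, grads, opt, sign = -1) {
  opt$t <- opt$t + 1L
  for (i in seq_along(model$layers)) {
    nm <- nn_param_names(model$layers[[i]])
    for (p in nm) {
      g <- grads[[i]][[p]]
      if (is.null(g)) next
      if (opt$method == "sgd") {
        v <- opt$momentum * opt$slots[[i]][[p]]$v + g
        opt$slots[[i]][[p]]$v <- v
        model$layers[[i]][[p]] <- model$layers[[i]][[p]] + sign * opt$lr * v
      } else {
        s <- opt$slots[[i]][[p]]
        s$m <- opt$beta1 * s$m + (1 - opt$beta1) * g
        s$v <- opt$beta2 * s$v + (1 - opt$beta2) * g^2
        opt$slots[[i]][[p]] <- s
        mhat <- s$m / (1 - opt$beta1^opt$t)
        vhat <- s$v / (1 - opt$beta2^opt$t)
        model$layers[[i]][[p]] <- model$layers[[i]][[p]] +
          sign * opt$lr * mhat / (sqrt(vhat) + opt$eps)
      }
    }
  }
  list(model = model, opt = opt)
}

## ---- loss helpers ----------------------------------------------------------

one_hot <- function(y, n_classes) {
  y <- as.integer(y)
  if (any(y < 0L) || any(y >= n_classes)) {
    stop_invalid("labels must lie in 0..", n_classes - 1L)
  }
  m <- matrix(0, length(y), n_classes)
  m[cbind(seq_along(y), y + 1L)] <- 1
  m
}

## Cross-entropy of softmax probabilities against one-hot targets.
## Returns mean loss and the gradient w.r.t. the probability rows; when the
## final layer activation is softmax the combined backward pass yields the
## familiar (p - y)/n logit gradient.
ce_loss <- function(probs, y_onehot, weights = NULL) {
  p <- clamp01(probs)
  n <- nrow(p)
  per <- -rowSums(y_onehot * log(p))
  if (is.null(weights)) weights <- rep(1, n)
  loss <- sum(weights * per) / n
  dprobs <- -(y_onehot / p) * (weights / n)
  list(loss = loss, dprobs = dprobs, per_sample = per)
}
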