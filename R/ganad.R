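#' Logistic-mixture latent space
#'
#' The latent sampler of the auxiliary-domain GAN: a mixture of `N` logistic
#' components with weights `beta`, per-component deterministic locations
#' `gamma_i` and non-negative diagonal scales `delta_i` (dimension `K`).
#' A draw selects component `i` with probability `beta_i` and returns
#' `z = gamma_i + delta_i * sigma` with `sigma` i.i.d. standard logistic
#' noise per dimension (`latent = "gaussian"` switches the noise to standard
#' normal, kept as an ablation baseline).
#'
#' @param beta Mixture weight vector (non-negative, sums to 1).
#' @param gamma N x K matrix of component locations.
#' @param delta N x K matrix of non-negative component scales.
#' @param noise `"logistic"` (default) or `"gaussian"`.
#' @return An object of class `logistic_mixture`.
#' @export
logistic_mixture <- function(beta, gamma, delta, noise = c("logistic", "gaussian")) {
  gamma <- as.matrix(gamma); delta <- as.matrix(delta)
  if (any(beta < 0) || abs(sum(beta) - 1) > 1e-8) {
    stop_invalid("beta must be a probability vector")
  }
  if (length(beta) != nrow(gamma) || !all(dim(gamma) == dim(delta))) {
    stop_invalid("beta/gamma/delta dimensions are inconsistent")
  }
  if (any(delta < 0)) stop_invalid("delta entries must be non-negative")
  if (ncol(gamma) < 1) stop_invalid("latent dimension K must be >= 1")
  structure(list(beta = beta, gamma = gamma, delta = delta,
                 n_components = length(beta), K = ncol(gamma),
                 noise = match.arg(noise)),
            class = "logistic_mixture")
}

#' Sample from a logistic-mixture latent space
#'
#' @param mixture A [logistic_mixture()].
#' @param count Number of samples (`>= 1`).
#' @param seed Optional RNG seed (otherwise the session stream is used).
#' @return A list with `z` (count x K matrix), `components` (1-based chosen
#'   component per row), and `sigma` (the raw noise draws).
#' @examples
#' m <- logistic_mixture(1, matrix(c(1, 2), 1), matrix(0, 1, 2))
#' sample_latent(m, 3)$z
#' @export
sample_latent <- function(mixture, count, seed = NULL) {
  stopifnot(inherits(mixture, "logistic_mixture"))
  if (count < 1) stop_invalid("count must be >= 1")
  with_seed(seed, {
    comp <- sample.int(mixture$n_components, count, replace = TRUE,
                       prob = mixture$beta)
    sigma <- if (mixture$noise == "logistic") {
      matrix(stats::rlogis(count * mixture$K), count, mixture$K)
    } else {
      matrix(stats::rnorm(count * mixture$K), count, mixture$K)
    }
    z <- mixture$gamma[comp, , drop = FALSE] +
      mixture$delta[comp, , drop = FALSE] * sigma
    list(z = z, components = comp, sigma = sigma)
  })
}

check_scores <- function(p, what) {
  if (any(p <= 0) || any(p >= 1)) {
    stop_invalid(what, " scores must lie strictly inside (0, 1)")
  }
  p
}

#' Discriminator loss (minibatch value of the maximization objective)
#'
#' `mean(log d_real) + mean(log(1 - d_fake))`; the discriminator update
#' ascends this quantity. It is bounded above by 0, attained only in the
#' perfect-separation limit.
#'
#' @param d_real,d_fake Discriminator scores in the open interval (0, 1)
#'   (clamped at 1e-7 from the boundaries before use).
#' @return Scalar loss value.
#' @examples
#' discriminator_loss(0.5, 0.5) # 2 log 0.5
#' @export
discriminator_loss <- function(d_real, d_fake) {
  d_real <- check_scores(clamp01(d_real), "real")
  d_fake <- check_scores(clamp01(d_fake), "fake")
  mean(log(d_real)) + mean(log(1 - d_fake))
}

#' L2 generator regularizer over the mixture components
#'
#' `lambda * sum_i beta_i * ||1 - theta_i||^2`, where `theta_i` is the
#' learnable diagonal scale vector of the i-th latent component; the penalty
#' pulls every component scale toward one.
#'
#' @param beta Mixture weights.
#' @param theta N x K matrix of component scale vectors.
#' @param lambda_reg Regularization weight (`>= 0`).
#' @return Scalar penalty (non-negative; zero iff every `theta_i` is the
#'   all-ones vector or `lambda_reg = 0`).
#' @export
generator_regularizer <- function(beta, theta, lambda_reg) {
  if (lambda_reg < 0) stop_invalid("lambda_reg must be non-negative")
  theta <- as.matrix(theta)
  if (length(beta) != nrow(theta)) stop_invalid("beta/theta dimension mismatch")
  lambda_reg * sum(beta * rowSums((1 - theta)^2))
}

#' Generator loss with mixture regularization
#'
#' `mean(log(1 - d_fake)) + generator_regularizer(beta, theta, lambda_reg)`;
#' the generator update descends this quantity.
#'
#' @inheritParams generator_regularizer
#' @param d_fake Discriminator scores on generated samples, in (0, 1).
#' @return Scalar loss value.
#' @export
generator_loss <- function(d_fake, beta, theta, lambda_reg) {
  d_fake <- check_scores(clamp01(d_fake), "fake")
  mean(log(1 - d_fake)) + generator_regularizer(beta, theta, lambda_reg)
}

#' Training configuration for an auxiliary-domain GAN
#'
#' @param epochs Number of epochs `L`.
#' @param d_steps Discriminator steps `M` per epoch.
#' @param g_steps Generator steps `N` per epoch.
#' @param batch Minibatch size `p` (`>= 2`).
#' @param lambda_reg Generator regularization weight (`>= 0`).
#' @param lr_d,lr_g Learning rates of the discriminator / generator updates.
#' @param momentum SGD momentum.
#' @param n_components Latent mixture components.
#' @param latent_dim Latent dimension `K`.
#' @param hidden Hidden width of the generator/discriminator MLPs.
#' @param latent `"logistic"` (default) or `"gaussian"` (ablation baseline).
#' @param seed RNG seed; training is a pure function of data + config.
#' @return A list of class `gan_config`.
#' @export
gan_config <- function(epochs = 50, d_steps = 1, g_steps = 1, batch = 32,
                       lambda_reg = 0.01, lr_d = 0.05, lr_g = 0.05,
                       momentum = 0.5, n_components = 3, latent_dim = 4,
                       hidden = 16, latent = c("logistic", "gaussian"),
                       seed = 1) {
  if (epochs < 1 || d_steps < 1 || g_steps < 1) stop_invalid("counts must be >= 1")
  if (batch < 2) stop_invalid("batch must be >= 2")
  if (lambda_reg < 0) stop_invalid("lambda_reg must be non-negative")
  latent <- match.arg(latent)
  structure(as.list(environment()), class = "gan_config")
}

softmax_vec <- function(l) { e <- exp(l - max(l)); e / sum(e) }

#' Train a conditional GAN for one auxiliary domain
#'
#' Runs the two-player loop: per epoch, `d_steps` gradient-ascent updates of
#' the discriminator on `mean(log D(x, y)) + mean(log(1 - D(x, G(x, z))))`,
#' then `g_steps` gradient-descent updates of the generator on
#' `mean(log(1 - D(x, G(x, z))))` plus the mixture-scale regularizer. The
#' generator is conditioned on the class label (one-hot), so minority
#' classes can be oversampled at generation time. The mixture weights are
#' softmax-parameterized (so `beta` stays a probability vector) and the
#' component locations/scales are learned through the reparameterized latent
#' draw; stage 1 uses the distant source dataset, stage 2 the target dataset.
#'
#' @param x Numeric matrix of samples (rows) in data space.
#' @param y Integer class labels (0-based) conditioning the GAN.
#' @param stage 1 (source-built auxiliary domain) or 2 (target-built).
#' @param config A [gan_config()].
#' @param provenance Dataset identifier recorded on the result.
#' @return An object of class `auxiliary_gan`: generator, discriminator,
#'   fitted [logistic_mixture()], per-step `loss_trace` of length
#'   `epochs * (d_steps + g_steps)`, plus bookkeeping fields.
#' @export
train_auxiliary_gan <- function(x, y, stage = 1, config = gan_config(),
                                provenance = "") {
  x <- as.matrix(x)
  if (nrow(x) == 0) stop_invalid("dataset must be non-empty")
  if (length(y) != nrow(x)) stop_invalid("labels length mismatch")
  if (!stage %in% c(1, 2)) stop_invalid("stage must be 1 or 2")
  classes <- sort(unique(as.integer(y)))
  n_classes <- length(classes)
  y_idx <- match(as.integer(y), classes) - 1L
  d <- ncol(x)
  K <- config$latent_dim
  N <- config$n_components

  with_seed(config$seed, {
    G <- nn_init(list(nn_dense(n_classes + K, config$hidden, "tanh"),
                      nn_dense(config$hidden, d, "linear")))
    D <- nn_init(list(nn_dense(n_classes + d, config$hidden, "tanh"),
                      nn_dense(config$hidden, 1, "linear")))
    beta_logits <- numeric(N)
    gamma <- matrix(stats::rnorm(N * K, sd = 0.5), N, K)
    delta <- matrix(1, N, K)

    opt_d <- nn_opt_init(D, "sgd", lr = config$lr_d, momentum = config$momentum)
    opt_g <- nn_opt_init(G, "sgd", lr = config$lr_g, momentum = config$momentum)
    trace <- numeric(0)
    p <- min(config$batch, nrow(x))

    make_latent <- function() {
      logistic_mixture(softmax_vec(beta_logits), gamma, pmax(delta, 0),
                       noise = config$latent)
    }
    gen_fake <- function(pp) {
      yc <- y_idx[sample.int(nrow(x), pp, replace = TRUE)]
      lat <- sample_latent(make_latent(), pp)
      gin <- cbind(one_hot(yc, n_classes), lat$z)
      fw <- nn_forward(G, gin, train = TRUE)
      list(y = yc, lat = lat, gin = gin, fw = fw, xf = fw$out)
    }

    for (epoch in seq_len(config$epochs)) {
      for (j in seq_len(config$d_steps)) {
        idx <- sample.int(nrow(x), p, replace = nrow(x) < p)
        xr <- x[idx, , drop = FALSE]; yr <- y_idx[idx]
        fake <- gen_fake(p)
        din_r <- cbind(one_hot(yr, n_classes), xr)
        din_f <- cbind(one_hot(fake$y, n_classes), fake$xf)
        fw_r <- nn_forward(D, din_r); fw_f <- nn_forward(D, din_f)
        a_r <- 1 / (1 + exp(-fw_r$out)); a_f <- 1 / (1 + exp(-fw_f$out))
        trace <- c(trace, discriminator_loss(a_r, a_f))
        ## ascend: d/ds log(sigmoid(s)) = 1 - a ; d/ds log(1 - sigmoid(s)) = -a
        bw_r <- nn_backward(D, fw_r$caches, (1 - a_r) / p)
        bw_f <- nn_backward(D, fw_f$caches, -a_f / p)
        g_sum <- mapply(function(gr, gf) {
          if (is.null(gr)) return(NULL)
          mapply(function(a, b) a + b, gr, gf, SIMPLIFY = FALSE)
        }, bw_r$grads, bw_f$grads, SIMPLIFY = FALSE)
        st <- nn_opt_step(D, g_sum, opt_d, sign = +1)
        D <- st$model; opt_d <- st$opt
      }
      for (k in seq_len(config$g_steps)) {
        fake <- gen_fake(p)
        din_f <- cbind(one_hot(fake$y, n_classes), fake$xf)
        fw_f <- nn_forward(D, din_f)
        a_f <- 1 / (1 + exp(-fw_f$out))
        beta <- softmax_vec(beta_logits)
        trace <- c(trace, generator_loss(a_f, beta, pmax(delta, 0),
                                         config$lambda_reg))
        ## descend mean log(1 - D(fake)): d/ds = -a
        bw_d <- nn_backward(D, fw_f$caches, -a_f / p)
        dxf <- bw_d$dinput[, (n_classes + 1):(n_classes + d), drop = FALSE]
        bw_g <- nn_backward(G, fake$fw$caches, dxf)
        st <- nn_opt_step(G, bw_g$grads, opt_g, sign = -1)
        G <- st$model; opt_g <- st$opt
        ## latent parameter gradients through z = gamma_i + delta_i * sigma
        dz <- bw_g$dinput[, (n_classes + 1):(n_classes + K), drop = FALSE]
        dgam <- matrix(0, N, K); ddel <- matrix(0, N, K)
        for (i in seq_len(N)) {
          rows <- fake$lat$components == i
          if (any(rows)) {
            dgam[i, ] <- colSums(dz[rows, , drop = FALSE])
            ddel[i, ] <- colSums((dz * fake$lat$sigma)[rows, , drop = FALSE])
          }
        }
        ## regularizer lambda * sum beta_i ||1 - delta_i||^2
        ddel <- ddel + 2 * config$lambda_reg * beta * (pmax(delta, 0) - 1)
        r_i <- rowSums((1 - pmax(delta, 0))^2)
        dlog <- config$lambda_reg * beta * (r_i - sum(beta * r_i))
        gamma <- gamma - config$lr_g * dgam
        delta <- pmax(delta - config$lr_g * ddel, 0)
        beta_logits <- beta_logits - config$lr_g * dlog
      }
    }
    if (!all(is.finite(trace))) {
      cond <- errorCondition("GAN training diverged (non-finite loss)",
                             class = c("distecg_training_diverged", "error"))
      cond$trace <- trace
      stop(cond)
    }
    structure(list(generator = G, discriminator = D,
                   mixture = make_latent(), loss_trace = trace,
                   config = config, classes = classes,
                   n_classes = n_classes, data_dim = d, stage = stage,
                   provenance = provenance),
              class = "auxiliary_gan")
  })
}

#' Generate an auxiliary domain from a trained GAN
#'
#' Draws latent samples from the fitted mixture and passes them through the
#' generator under the requested condition labels; per-class output counts
#' follow the request exactly, which is how minority classes are oversampled.
#'
#' @param gan An [train_auxiliary_gan()] result.
#' @param conditions Either a vector of condition labels (one per requested
#'   sample) or a named count vector, e.g. `c("0" = 100, "1" = 50)`.
#' @param seed RNG seed for the latent draws.
#' @return An object of class `auxiliary_domain`: `x` (generated samples),
#'   `y` (condition labels), `stage`, `provenance`.
#' @export
generate_auxiliary_domain <- function(gan, conditions, seed = NULL) {
  stopifnot(inherits(gan, "auxiliary_gan"))
  if (!is.null(names(conditions)) && all(nzchar(names(conditions)))) {
    labels <- rep(as.integer(names(conditions)), as.integer(conditions))
  } else {
    labels <- as.integer(conditions)
  }
  if (!all(labels %in% gan$classes)) stop_invalid("unknown condition label")
  n <- length(labels)
  if (n == 0) {
    return(structure(list(x = matrix(0, 0, gan$data_dim), y = integer(0),
                          stage = gan$stage, provenance = gan$provenance),
                     class = "auxiliary_domain"))
  }
  with_seed(seed, {
    lat <- sample_latent(gan$mixture, n)
    gin <- cbind(one_hot(match(labels, gan$classes) - 1L, gan$n_classes), lat$z)
    xg <- nn_forward(gan$generator, gin, train = FALSE)$out
    structure(list(x = xg, y = labels, stage = gan$stage,
                   provenance = gan$provenance),
              class = "auxiliary_domain")
  })
}
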