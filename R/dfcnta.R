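#' Transfer batch: labeled source, labeled target, unlabeled target
#'
#' @param x_s,y_s Labeled source samples (matrix rows) and labels; may be
#'   empty.
#' @param x_l,y_l Labeled target samples and labels.
#' @param x_u Unlabeled target samples (may be empty / NULL).
#' @return An object of class `transfer_batch`.
#' @export
transfer_batch <- function(x_s = NULL, y_s = NULL, x_l, y_l, x_u = NULL) {
  as_mat <- function(m) if (is.null(m)) matrix(0, 0, 0) else as.matrix(m)
  x_s <- as_mat(x_s); x_l <- as_mat(x_l); x_u <- as_mat(x_u)
  y_s <- if (is.null(y_s)) integer(0) else as.integer(y_s)
  y_l <- as.integer(y_l)
  if (nrow(x_s) != length(y_s)) stop_invalid("source sample/label mismatch")
  if (nrow(x_l) != length(y_l)) stop_invalid("target sample/label mismatch")
  structure(list(x_s = x_s, y_s = y_s, x_l = x_l, y_l = y_l, x_u = x_u),
            class = "transfer_batch")
}

#' Virtual labeling rule
#'
#' Reserves one extra label `y_v` (appended after the real class set) that
#' lets a single discriminator act as both the marginal discriminator
#' (feature-only terms, paired with `y_v`) and the joint discriminator
#' (feature-label terms).
#'
#' @param classes The real class label set (0-based integers).
#' @return An object of class `virtual_labeling` with `y_v` and `classes`.
#' @export
virtual_labeling <- function(classes) {
  classes <- sort(unique(as.integer(classes)))
  structure(list(classes = classes, y_v = max(classes) + 1L),
            class = "virtual_labeling")
}

#' Assign the virtual label to unlabeled samples
#'
#' @param x_u Matrix of unlabeled samples (possibly 0 rows).
#' @param vlab A [virtual_labeling()].
#' @return A list with `x` and `y` (every row labeled `y_v`).
#' @export
assign_virtual_labels <- function(x_u, vlab) {
  stopifnot(inherits(vlab, "virtual_labeling"))
  x_u <- as.matrix(x_u)
  list(x = x_u, y = rep(vlab$y_v, nrow(x_u)))
}

#' Transfer hyperparameters
#'
#' The source-instance weights `phi` are the negative-transfer-avoidance
#' lever: with `phi_mode = "ones"` they are taken as given; with
#' `phi_mode = "grid"` a scalar broadcast weight is tuned by coarse grid
#' search (over `phi_grid`, which includes 0) against the cross-entropy on a
#' held-out slice of the labeled target data, so an unhelpful source is
#' down-weighted automatically.
#'
#' @param phi Per-source-sample non-negative weights (length 1 broadcasts to
#'   a per-dataset weight).
#' @param gamma_scale Scaling factor of the weighted source classification
#'   term (`>= 0`).
#' @param sigma_adv Adversarial weight of the min-max objective (`>= 0`).
#' @param phi_mode `"ones"` (use `phi` as given) or `"grid"` (tune a scalar
#'   phi by held-out grid search).
#' @param phi_grid Candidate scalar weights for `phi_mode = "grid"`
#'   (non-negative).
#' @return An object of class `transfer_hyper`.
#' @export
transfer_hyper <- function(phi = 1, gamma_scale = 1, sigma_adv = 0.1,
                           phi_mode = c("ones", "grid"),
                           phi_grid = c(0, 0.25, 0.5, 1)) {
  if (any(phi < 0)) stop_invalid("phi weights must be non-negative")
  if (gamma_scale < 0 || sigma_adv < 0) {
    stop_invalid("gamma_scale and sigma_adv must be non-negative")
  }
  phi_mode <- match.arg(phi_mode)
  if (length(phi_grid) < 1 || any(phi_grid < 0)) {
    stop_invalid("phi_grid must be a non-empty non-negative vector")
  }
  structure(list(phi = phi, gamma_scale = gamma_scale, sigma_adv = sigma_adv,
                 phi_mode = phi_mode, phi_grid = phi_grid),
            class = "transfer_hyper")
}

term_or_zero <- function(scores, flip, what) {
  if (length(scores) == 0) {
    message("empty batch part: ", what, " term contributes 0")
    return(0)
  }
  s <- check_scores(clamp01(scores), what)
  if (flip) mean(log(1 - s)) else mean(log(s))
}

#' Combined marginal/joint adversarial loss with a virtual label
#'
#' The four-term discriminator objective of the negative-transfer-avoidance
#' scheme: marginal terms pair features with the virtual label `y_v`
#' (unlabeled target vs. source), joint terms pair features with real labels
#' (labeled target vs. source):
#' `E log D(F(x_u), y_v) + E log(1 - D(F(x_s), y_v))
#'  + E log D(F(x_l), y_l) + E log(1 - D(F(x_s), y_s))`.
#' Empty batch parts contribute 0 (with a notice).
#'
#' @param feature_fn Function mapping a sample matrix to a feature matrix
#'   (use `identity` for raw features).
#' @param disc_fn Function `(features, labels) -> scores in (0, 1)`.
#' @param batch A [transfer_batch()].
#' @param vlab A [virtual_labeling()].
#' @param terms Optional logical list: `domain` enables the two marginal
#'   (`y_v`) terms, `joint` the two labeled terms (both default TRUE).
#' @return Scalar loss (maximized by the discriminator update).
#' @examples
#' b <- transfer_batch(x_s = matrix(0, 2, 1), y_s = c(0, 1),
#'                     x_l = matrix(0, 2, 1), y_l = c(0, 1),
#'                     x_u = matrix(0, 2, 1))
#' gan_loss(identity, function(f, y) rep(0.5, nrow(f)), b,
#'          virtual_labeling(0:1)) # 4 log 0.5
#' @export
gan_loss <- function(feature_fn, disc_fn, batch, vlab,
                     terms = list(domain = TRUE, joint = TRUE)) {
  stopifnot(inherits(batch, "transfer_batch"), inherits(vlab, "virtual_labeling"))
  total <- 0
  feat <- function(x) if (nrow(x) > 0) feature_fn(x) else x
  f_u <- feat(batch$x_u); f_s <- feat(batch$x_s); f_l <- feat(batch$x_l)
  if (isTRUE(terms$domain)) {
    total <- total +
      term_or_zero(if (nrow(f_u) > 0) disc_fn(f_u, rep(vlab$y_v, nrow(f_u))) else numeric(0),
                   FALSE, "marginal target") +
      term_or_zero(if (nrow(f_s) > 0) disc_fn(f_s, rep(vlab$y_v, nrow(f_s))) else numeric(0),
                   TRUE, "marginal source")
  }
  if (isTRUE(terms$joint)) {
    total <- total +
      term_or_zero(if (nrow(f_l) > 0) disc_fn(f_l, batch$y_l) else numeric(0),
                   FALSE, "joint target") +
      term_or_zero(if (nrow(f_s) > 0) disc_fn(f_s, batch$y_s) else numeric(0),
                   TRUE, "joint source")
  }
  total
}

#' Weighted classification loss over target and source parts
#'
#' Mean cross-entropy on the labeled target part plus
#' `gamma_scale * mean(phi * ce)` on the labeled source part, with
#' per-sample non-negative weights `phi` (length 1 broadcasts).
#'
#' @param feature_fn Function mapping samples to features.
#' @param classifier_fn Function mapping features to class-probability rows.
#' @param batch A [transfer_batch()] with non-empty labeled target part.
#' @param hyper A [transfer_hyper()].
#' @param n_classes Number of real classes (defaults to the labels seen).
#' @return Scalar loss (non-negative).
#' @export
weighted_class_loss <- function(feature_fn, classifier_fn, batch, hyper,
                                n_classes = NULL) {
  stopifnot(inherits(batch, "transfer_batch"), inherits(hyper, "transfer_hyper"))
  if (nrow(batch$x_l) == 0) stop_invalid("labeled target part must be non-empty")
  if (is.null(n_classes)) {
    n_classes <- max(c(batch$y_l, batch$y_s)) + 1L
  }
  p_l <- clamp01(classifier_fn(feature_fn(batch$x_l)))
  loss <- mean(-log(p_l[cbind(seq_len(nrow(p_l)), batch$y_l + 1L)]))
  if (nrow(batch$x_s) > 0 && hyper$gamma_scale > 0) {
    phi <- hyper$phi
    if (length(phi) == 1) phi <- rep(phi, nrow(batch$x_s))
    if (length(phi) != nrow(batch$x_s)) {
      stop_invalid("phi length must equal the source batch size")
    }
    p_s <- clamp01(classifier_fn(feature_fn(batch$x_s)))
    ce_s <- -log(p_s[cbind(seq_len(nrow(p_s)), batch$y_s + 1L)])
    loss <- loss + hyper$gamma_scale * mean(phi * ce_s)
  }
  loss
}

#' The min-max transfer objective
#'
#' `class_loss - sigma_adv * gan_loss`; minimized over the feature network
#' and classifier while the adversarial loss is separately maximized over
#' the discriminator.
#'
#' @param class_loss,gan_loss Scalars from [weighted_class_loss()] /
#'   [gan_loss()].
#' @param sigma_adv Adversarial weight (`>= 0`).
#' @return Scalar objective.
#' @export
dfcnta_objective <- function(class_loss, gan_loss, sigma_adv) {
  if (!is.finite(class_loss) || !is.finite(gan_loss)) {
    stop_invalid("losses must be finite")
  }
  class_loss - sigma_adv * gan_loss
}

#' Alternation schedule for one transfer stage
#'
#' @param rounds Alternation rounds.
#' @param n_D Discriminator ascent steps per round.
#' @param n_FC Feature/classifier descent steps per round.
#' @param lr Learning rate (SGD with momentum).
#' @param momentum Momentum coefficient.
#' @param hidden Feature-network hidden width.
#' @param feat_dim Feature dimension produced by the feature network.
#' @param hidden_d Discriminator hidden width.
#' @param seed RNG seed (network init is drawn from it).
#' @return A list of class `transfer_schedule`.
#' @export
transfer_schedule <- function(rounds = 60, n_D = 1, n_FC = 1, lr = 0.1,
                              momentum = 0.5, hidden = 16, feat_dim = 8,
                              hidden_d = 16, seed = 1) {
  if (rounds < 1 || n_D < 1 || n_FC < 1) stop_invalid("counts must be >= 1")
  structure(as.list(environment()), class = "transfer_schedule")
}

## build fresh F/C/D networks for a stage
init_transfer_nets <- function(d_in, n_classes, sched) {
  list(
    feature = nn_init(list(nn_dense(d_in, sched$hidden, "tanh"),
                           nn_dense(sched$hidden, sched$feat_dim, "tanh"))),
    classifier = nn_init(list(nn_dense(sched$feat_dim, n_classes, "softmax"))),
    discriminator = nn_init(list(
      nn_dense(sched$feat_dim + n_classes + 1L, sched$hidden_d, "tanh"),
      nn_dense(sched$hidden_d, 1, "linear")))
  )
}

## helpers exposing nn models through the functional loss interfaces
feature_fn_of <- function(Fnet) {
  function(x) nn_forward(Fnet, as.matrix(x), train = FALSE)$out
}
classifier_fn_of <- function(Cnet) {
  function(f) nn_forward(Cnet, as.matrix(f), train = FALSE)$out
}
disc_fn_of <- function(Dnet, n_lab) {
  function(f, y) {
    s <- nn_forward(Dnet, cbind(as.matrix(f), one_hot(y, n_lab)),
                    train = FALSE)$out
    as.numeric(1 / (1 + exp(-s)))
  }
}

#' Train one negative-transfer-avoidance stage
#'
#' Alternating optimization of the min-max objective: per round, `n_D`
#' gradient-ascent steps of the joint/marginal discriminator on the
#' adversarial loss, then `n_FC` descent steps of the feature network and
#' classifier on `class_loss - sigma_adv * gan_loss` (full-batch SGD with
#' momentum). With `sigma_adv = 0` and `gamma_scale = 0` the stage reduces
#' exactly to supervised training on the labeled target part.
#'
#' @param init Either `NULL` (fresh networks) or a list with `feature` and
#'   `classifier` networks carried over from a previous stage (the
#'   discriminator is always re-initialized).
#' @param source_data `NULL` or a list with `x`, `y` (labeled source).
#' @param target_data List with `x_l`, `y_l` (labeled target, non-empty) and
#'   optional `x_u` (unlabeled target).
#' @param hyper A [transfer_hyper()].
#' @param schedule A [transfer_schedule()].
#' @param n_classes Number of real classes shared by source and target.
#' @param terms Logical list of loss-term switches: `domain` (marginal
#'   discriminator terms), `feature` (adversarial term in the F update),
#'   `classifier` (weighted source classification term). All default TRUE;
#'   they realize the ablation variants.
#' @return An object of class `transfer_stage`: `feature`, `classifier`,
#'   `discriminator` networks plus a per-round `trace` matrix with columns
#'   `class_loss`, `gan_loss`, `objective`. With `phi_mode = "grid"` the
#'   selected scalar weight is recorded as `phi_selected`.
#' @export
train_transfer_stage <- function(init = NULL, source_data = NULL, target_data,
                                 hyper = transfer_hyper(),
                                 schedule = transfer_schedule(),
                                 n_classes = NULL,
                                 terms = list(domain = TRUE, feature = TRUE,
                                              classifier = TRUE)) {
  has_src <- !is.null(source_data) && nrow(as.matrix(source_data$x)) > 0
  grid_on <- identical(hyper$phi_mode, "grid") && has_src &&
    hyper$gamma_scale > 0 && isTRUE(terms$classifier) &&
    length(hyper$phi_grid) > 1 && length(hyper$phi) == 1
  if (!grid_on) {
    return(train_stage_core(init, source_data, target_data, hyper, schedule,
                            n_classes, terms))
  }
  ## coarse grid search for a scalar source weight on held-out target loss
  x_l <- as.matrix(target_data$x_l); y_l <- as.integer(target_data$y_l)
  held <- with_seed(schedule$seed, {
    idx <- unlist(lapply(split(seq_along(y_l), y_l), function(ix) {
      ix <- ix[sample.int(length(ix))]
      ix[seq_len(max(1L, floor(length(ix) / 4)))]
    }), use.names = FALSE)
    sort(idx)
  })
  keep <- setdiff(seq_along(y_l), held)
  if (length(keep) == 0 || length(unique(y_l[keep])) < length(unique(y_l))) {
    ## too little labeled target data to hold any out: fall back to phi as-is
    return(train_stage_core(init, source_data, target_data, hyper, schedule,
                            n_classes, terms))
  }
  inner_target <- list(x_l = x_l[keep, , drop = FALSE], y_l = y_l[keep],
                       x_u = target_data$x_u)
  score <- vapply(hyper$phi_grid, function(w) {
    h <- hyper; h$phi <- w; h$phi_mode <- "ones"
    st <- train_stage_core(init, source_data, inner_target, h, schedule,
                           n_classes, terms)
    p <- clamp01(predict(st, x_l[held, , drop = FALSE])$probs)
    mean(-log(p[cbind(seq_along(held), y_l[held] + 1L)]))
  }, numeric(1))
  best <- hyper$phi_grid[which.min(score)]
  h <- hyper; h$phi <- best; h$phi_mode <- "ones"
  out <- train_stage_core(init, source_data, target_data, h, schedule,
                          n_classes, terms)
  out$phi_selected <- best
  out$phi_scores <- stats::setNames(score, hyper$phi_grid)
  out
}

train_stage_core <- function(init = NULL, source_data = NULL, target_data,
                             hyper = transfer_hyper(),
                             schedule = transfer_schedule(),
                             n_classes = NULL,
                             terms = list(domain = TRUE, feature = TRUE,
                                          classifier = TRUE)) {
  x_l <- as.matrix(target_data$x_l); y_l <- as.integer(target_data$y_l)
  if (nrow(x_l) == 0) stop_invalid("labeled target data must be non-empty")
  x_u <- if (is.null(target_data$x_u)) matrix(0, 0, ncol(x_l)) else
    as.matrix(target_data$x_u)
  has_src <- !is.null(source_data) && nrow(as.matrix(source_data$x)) > 0
  x_s <- if (has_src) as.matrix(source_data$x) else matrix(0, 0, ncol(x_l))
  y_s <- if (has_src) as.integer(source_data$y) else integer(0)
  if (is.null(n_classes)) n_classes <- max(c(y_l, y_s)) + 1L
  vlab <- virtual_labeling(seq_len(n_classes) - 1L)
  n_lab <- n_classes + 1L

  phi <- hyper$phi
  if (length(phi) == 1) phi <- rep(phi, max(1, nrow(x_s)))
  if (has_src && length(phi) != nrow(x_s)) {
    stop_invalid("phi length must equal the number of source samples")
  }

  with_seed(schedule$seed, {
    nets <- init_transfer_nets(ncol(x_l), n_classes, schedule)
    if (!is.null(init)) {
      if (!is.null(init$feature)) nets$feature <- init$feature
      if (!is.null(init$classifier)) nets$classifier <- init$classifier
    }
    Fnet <- nets$feature; Cnet <- nets$classifier; Dnet <- nets$discriminator
    opt_f <- nn_opt_init(Fnet, "sgd", lr = schedule$lr, momentum = schedule$momentum)
    opt_c <- nn_opt_init(Cnet, "sgd", lr = schedule$lr, momentum = schedule$momentum)
    opt_d <- nn_opt_init(Dnet, "sgd", lr = schedule$lr, momentum = schedule$momentum)

    use_domain <- isTRUE(terms$domain)
    use_feature <- isTRUE(terms$feature)
    use_classifier <- isTRUE(terms$classifier) && hyper$gamma_scale > 0 && has_src
    sigma <- hyper$sigma_adv

    onehot_yv <- function(n) one_hot(rep(vlab$y_v, n), n_lab)
    trace <- matrix(NA_real_, schedule$rounds, 3,
                    dimnames = list(NULL, c("class_loss", "gan_loss", "objective")))

    ## adversarial forward over all parts; returns per-part D caches, scores
    gan_parts <- function(feats) {
      parts <- list()
      if (use_domain && nrow(feats$u) > 0) {
        parts$mu <- list(f = feats$u, oh = onehot_yv(nrow(feats$u)), flip = FALSE,
                         src = "u")
      }
      if (use_domain && nrow(feats$s) > 0) {
        parts$ms <- list(f = feats$s, oh = onehot_yv(nrow(feats$s)), flip = TRUE,
                         src = "s")
      }
      parts$jl <- list(f = feats$l, oh = one_hot(y_l, n_lab), flip = FALSE,
                       src = "l")
      if (nrow(feats$s) > 0) {
        parts$js <- list(f = feats$s, oh = one_hot(y_s, n_lab), flip = TRUE,
                         src = "s")
      }
      parts
    }

    for (round in seq_len(schedule$rounds)) {
      ## feature forward passes (current F) reused within the round
      fw_l <- nn_forward(Fnet, x_l)
      fw_s <- if (nrow(x_s) > 0) nn_forward(Fnet, x_s) else NULL
      fw_u <- if (nrow(x_u) > 0) nn_forward(Fnet, x_u) else NULL
      feats <- list(l = fw_l$out,
                    s = if (is.null(fw_s)) matrix(0, 0, schedule$feat_dim) else fw_s$out,
                    u = if (is.null(fw_u)) matrix(0, 0, schedule$feat_dim) else fw_u$out)

      ## --- discriminator ascent ---
      gl <- NA_real_
      for (j in seq_len(schedule$n_D)) {
        parts <- gan_parts(feats)
        gl <- 0
        grads_tot <- NULL
        for (pt in parts) {
          fwd <- nn_forward(Dnet, cbind(pt$f, pt$oh))
          a <- 1 / (1 + exp(-fwd$out))
          m <- nrow(pt$f)
          gl <- gl + if (pt$flip) mean(log(clamp01(1 - a))) else
            mean(log(clamp01(a)))
          dout <- if (pt$flip) -a / m else (1 - a) / m
          bw <- nn_backward(Dnet, fwd$caches, dout)
          grads_tot <- if (is.null(grads_tot)) bw$grads else
            mapply(function(g1, g2) mapply(`+`, g1, g2, SIMPLIFY = FALSE),
                   grads_tot, bw$grads, SIMPLIFY = FALSE)
        }
        st <- nn_opt_step(Dnet, grads_tot, opt_d, sign = +1)
        Dnet <- st$model; opt_d <- st$opt
      }

      ## --- feature / classifier descent ---
      cl <- NA_real_
      for (k in seq_len(schedule$n_FC)) {
        fw_l <- nn_forward(Fnet, x_l)
        fw_s <- if (nrow(x_s) > 0) nn_forward(Fnet, x_s) else NULL
        fw_u <- if (nrow(x_u) > 0) nn_forward(Fnet, x_u) else NULL
        feats <- list(l = fw_l$out,
                      s = if (is.null(fw_s)) matrix(0, 0, schedule$feat_dim) else fw_s$out,
                      u = if (is.null(fw_u)) matrix(0, 0, schedule$feat_dim) else fw_u$out)

        ## classification terms
        fw_cl <- nn_forward(Cnet, feats$l)
        y_l_oh <- one_hot(y_l, n_classes)
        ce_l <- ce_loss(fw_cl$out, y_l_oh)
        cl <- ce_l$loss
        bw_cl <- nn_backward(Cnet, fw_cl$caches, ce_l$dprobs)
        grads_c <- bw_cl$grads
        dfeat_l <- bw_cl$dinput
        dfeat_s <- if (nrow(feats$s) > 0) feats$s * 0 else NULL
        if (use_classifier) {
          fw_cs <- nn_forward(Cnet, feats$s)
          ce_s <- ce_loss(fw_cs$out, one_hot(y_s, n_classes),
                          weights = hyper$gamma_scale * phi)
          cl <- cl + ce_s$loss
          bw_cs <- nn_backward(Cnet, fw_cs$caches, ce_s$dprobs)
          grads_c <- mapply(function(g1, g2) mapply(`+`, g1, g2, SIMPLIFY = FALSE),
                            grads_c, bw_cs$grads, SIMPLIFY = FALSE)
          dfeat_s <- bw_cs$dinput
        }

        ## adversarial contribution to the feature gradient: F descends
        ## class_loss - sigma * gan_loss
        gl_now <- 0
        dfeat_u <- if (nrow(feats$u) > 0) feats$u * 0 else NULL
        parts <- gan_parts(feats)
        for (nm in names(parts)) {
          pt <- parts[[nm]]
          fwd <- nn_forward(Dnet, cbind(pt$f, pt$oh))
          a <- 1 / (1 + exp(-fwd$out))
          m <- nrow(pt$f)
          gl_now <- gl_now + if (pt$flip) mean(log(clamp01(1 - a))) else
            mean(log(clamp01(a)))
          if (use_feature && sigma > 0) {
            dgan_ds <- if (pt$flip) -a / m else (1 - a) / m
            bw <- nn_backward(Dnet, fwd$caches, -sigma * dgan_ds)
            dfeat_part <- bw$dinput[, seq_len(schedule$feat_dim), drop = FALSE]
            if (pt$src == "l") dfeat_l <- dfeat_l + dfeat_part
            if (pt$src == "s") dfeat_s <- dfeat_s + dfeat_part
            if (pt$src == "u") dfeat_u <- dfeat_u + dfeat_part
          }
        }
        gl <- gl_now

        ## backprop into F
        bw_fl <- nn_backward(Fnet, fw_l$caches, dfeat_l)
        grads_f <- bw_fl$grads
        if (!is.null(fw_s) && !is.null(dfeat_s)) {
          bw_fs <- nn_backward(Fnet, fw_s$caches, dfeat_s)
          grads_f <- mapply(function(g1, g2) mapply(`+`, g1, g2, SIMPLIFY = FALSE),
                            grads_f, bw_fs$grads, SIMPLIFY = FALSE)
        }
        if (!is.null(fw_u) && !is.null(dfeat_u) && use_feature && sigma > 0) {
          bw_fu <- nn_backward(Fnet, fw_u$caches, dfeat_u)
          grads_f <- mapply(function(g1, g2) mapply(`+`, g1, g2, SIMPLIFY = FALSE),
                            grads_f, bw_fu$grads, SIMPLIFY = FALSE)
        }
        st <- nn_opt_step(Cnet, grads_c, opt_c, sign = -1)
        Cnet <- st$model; opt_c <- st$opt
        st <- nn_opt_step(Fnet, grads_f, opt_f, sign = -1)
        Fnet <- st$model; opt_f <- st$opt
      }

      trace[round, ] <- c(cl, gl, dfcnta_objective(cl, gl, sigma))
      if (!all(is.finite(trace[round, ]))) {
        cond <- errorCondition("transfer stage diverged (non-finite loss)",
                               class = c("distecg_training_diverged", "error"))
        cond$trace <- trace[seq_len(round), , drop = FALSE]
        stop(cond)
      }
    }

    structure(list(feature = Fnet, classifier = Cnet, discriminator = Dnet,
                   trace = trace, hyper = hyper, schedule = schedule,
                   n_classes = n_classes, terms = terms),
              class = "transfer_stage")
  })
}

#' Predict class labels with a trained transfer stage
#'
#' @param object A `transfer_stage`.
#' @param x Sample matrix.
#' @param ... Unused.
#' @return A list with `probs` (rows sum to 1) and `labels` (0-based).
#' @export
predict.transfer_stage <- function(object, x, ...) {
  f <- nn_forward(object$feature, as.matrix(x), train = FALSE)$out
  p <- nn_forward(object$classifier, f, train = FALSE)$out
  list(probs = p, labels = max.col(p, ties.method = "first") - 1L)
}
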