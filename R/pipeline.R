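#' Ordered multi-source transfer scenario
#'
#' @param sources Ordered vector of source dataset ids (no repeats).
#' @param target Target dataset id.
#' @return An object of class `transfer_scenario`.
#' @export
transfer_scenario <- function(sources, target) {
  sources <- as.character(sources)
  if (length(sources) < 1) stop_invalid("at least one source required")
  if (anyDuplicated(sources)) stop_invalid("duplicate source ids")
  structure(list(sources = sources, target = as.character(target)),
            class = "transfer_scenario")
}

## all k-permutations of v in lexicographic order
k_permutations <- function(v, k) {
  if (k == 1) return(lapply(v, function(x) x))
  out <- list()
  for (i in seq_along(v)) {
    for (rest in k_permutations(v[-i], k - 1)) {
      out[[length(out) + 1]] <- c(v[i], rest)
    }
  }
  out
}

#' Enumerate ordered multi-source scenarios
#'
#' All ordered arrangements of every non-empty subset of the source ids,
#' crossed with each target, in deterministic lexicographic order (subset
#' size ascending, then lexicographic within size). With 4 sources this
#' yields `4 + 12 + 24 + 24 = 64` scenarios per target.
#'
#' @param source_ids Source dataset ids (non-empty).
#' @param target_ids Target dataset ids (non-empty).
#' @return A list of [transfer_scenario()] objects.
#' @examples
#' length(enumerate_scenarios(letters[1:4], "ecg")) # 64
#' @export
enumerate_scenarios <- function(source_ids, target_ids) {
  source_ids <- sort(unique(as.character(source_ids)))
  target_ids <- sort(unique(as.character(target_ids)))
  if (length(source_ids) < 1) stop_invalid("source set must be non-empty")
  if (length(target_ids) < 1) stop_invalid("target set must be non-empty")
  out <- list()
  for (tg in target_ids) {
    for (k in seq_along(source_ids)) {
      for (perm in k_permutations(source_ids, k)) {
        out[[length(out) + 1]] <- transfer_scenario(perm, tg)
      }
    }
  }
  out
}

#' Pipeline configuration with ablation switches
#'
#' The switches realize the ablation variants: disabling `use_ganad` removes
#' both GAN-built auxiliary domains (direct source-to-target transfer);
#' `use_domain_term` controls the marginal (virtual-label) discriminator
#' terms; `use_feature_term` the adversarial term in the feature update;
#' `use_classifier_term` the weighted source classification term. Enabling
#' all four reproduces the full configuration.
#'
#' @param use_ganad,use_domain_term,use_feature_term,use_classifier_term
#'   Logical ablation switches (all TRUE by default; at least one must stay
#'   enabled).
#' @param gan A [gan_config()] for the auxiliary-domain GANs.
#' @param hyper A [transfer_hyper()]; the pipeline default turns on the
#'   held-out grid search over the scalar source weight (`phi_mode =
#'   "grid"`), the instance-weighting half of negative-transfer avoidance.
#' @param schedule A [transfer_schedule()].
#' @param cv_k Cross-validation folds for the final stage (default 5).
#' @param aux_n Samples generated per auxiliary domain (balanced across
#'   condition classes, which oversamples minorities).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(use_ganad = TRUE, use_domain_term = TRUE,
                            use_feature_term = TRUE, use_classifier_term = TRUE,
                            gan = gan_config(),
                            hyper = transfer_hyper(phi_mode = "grid"),
                            schedule = transfer_schedule(), cv_k = 5,
                            aux_n = 120) {
  if (!any(use_ganad, use_domain_term, use_feature_term, use_classifier_term)) {
    stop_invalid("at least one loss component must remain enabled")
  }
  structure(as.list(environment()), class = "pipeline_config")
}

resolve_dataset <- function(registry, id) {
  if (!id %in% names(registry)) {
    stop(errorCondition(paste0("dataset id not in registry: ", id),
                        class = c("distecg_resolution_error", "error")))
  }
  d <- registry[[id]]
  list(x = as.matrix(d$x), y = as.integer(d$y))
}

balanced_conditions <- function(y, n_total) {
  cls <- sort(unique(y))
  per <- ceiling(n_total / length(cls))
  rep(cls, each = per)
}

stage_result <- function(stage, model, report) {
  structure(list(stage = stage, model = model, report = report),
            class = "stage_result")
}

terms_of <- function(config) {
  list(domain = config$use_domain_term, feature = config$use_feature_term,
       classifier = config$use_classifier_term)
}

sched_with_seed <- function(sched, seed) { sched$seed <- seed; sched }

#' Run the three-stage distant transfer for one scenario
#'
#' With auxiliary domains enabled, the pipeline (per source, in scenario
#' order) (i) trains a conditional GAN on the source dataset and transfers
#' source knowledge into the generated auxiliary domain 1; (ii) trains a GAN
#' on the target dataset and transfers auxiliary domain 1 into auxiliary
#' domain 2; (iii) transfers auxiliary domain 2 into the target under
#' stratified k-fold cross-validation. The feature extractor is carried
#' forward between stages and fine-tuned; the classifier head is
#' re-initialized whenever the label space changes. With `use_ganad = FALSE`
#' the pipeline reduces to direct negative-transfer-avoidance transfer from
#' the sources to the target (no GANs trained).
#'
#' @param scenario A [transfer_scenario()].
#' @param config A [pipeline_config()].
#' @param registry Named list mapping dataset ids to `list(x, y)`.
#' @param seed Integer seed controlling every stochastic step.
#' @return A list of class `distant_transfer_run`: `stages` (list of
#'   `stage_result`), `report` (final cross-validated [overall_report()]),
#'   `scenario`, and `n_gans_trained`.
#' @export
run_distant_transfer <- function(scenario, config, registry, seed = 1) {
  stopifnot(inherits(scenario, "transfer_scenario"),
            inherits(config, "pipeline_config"))
  target <- resolve_dataset(registry, scenario$target)
  sources <- lapply(scenario$sources, resolve_dataset, registry = registry)
  terms <- terms_of(config)
  hyper <- if (config$use_classifier_term) config$hyper else {
    h <- config$hyper; h$gamma_scale <- 0; h
  }
  if (!config$use_feature_term) hyper$sigma_adv <- 0

  stages <- list()
  carried <- NULL
  n_gans <- 0L

  if (config$use_ganad) {
    ## auxiliary domain 2: GAN on the target dataset
    gan2_cfg <- config$gan; gan2_cfg$seed <- seed + 211L
    gan2 <- train_auxiliary_gan(target$x, target$y, stage = 2, config = gan2_cfg,
                                provenance = scenario$target)
    n_gans <- n_gans + 1L
    aux2 <- generate_auxiliary_domain(
      gan2, balanced_conditions(target$y, config$aux_n), seed = seed + 311L)

    ## stage 1: per source, transfer into its GAN-built auxiliary domain
    aux1_x <- NULL; aux1_y <- NULL
    last_stage1 <- NULL
    for (i in seq_along(sources)) {
      src <- sources[[i]]
      gan1_cfg <- config$gan; gan1_cfg$seed <- seed + 100L + i
      gan1 <- train_auxiliary_gan(src$x, src$y, stage = 1, config = gan1_cfg,
                                  provenance = scenario$sources[i])
      n_gans <- n_gans + 1L
      aux1 <- generate_auxiliary_domain(
        gan1, balanced_conditions(src$y, config$aux_n), seed = seed + 400L + i)
      st1 <- train_transfer_stage(
        init = carried, source_data = list(x = src$x, y = src$y),
        target_data = list(x_l = aux1$x, y_l = aux1$y),
        hyper = hyper, schedule = sched_with_seed(config$schedule, seed + 500L + i),
        terms = terms)
      carried <- list(feature = st1$feature)
      last_stage1 <- st1
      aux1_x <- rbind(aux1_x, aux1$x); aux1_y <- c(aux1_y, aux1$y)
    }
    rep1 <- overall_report(aux1_y,
                           predict(last_stage1, aux1_x)$labels,
                           classes = sort(unique(aux1_y)))
    stages[[1]] <- stage_result(1L, last_stage1, rep1)

    ## stage 2: auxiliary domain 1 -> auxiliary domain 2
    st2 <- train_transfer_stage(
      init = carried, source_data = list(x = aux1_x, y = aux1_y),
      target_data = list(x_l = aux2$x, y_l = aux2$y),
      hyper = hyper, schedule = sched_with_seed(config$schedule, seed + 600L),
      terms = terms)
    carried <- list(feature = st2$feature)
    rep2 <- overall_report(aux2$y, predict(st2, aux2$x)$labels,
                           classes = sort(unique(aux2$y)))
    stages[[2]] <- stage_result(2L, st2, rep2)
    stage3_source <- list(x = aux2$x, y = aux2$y)
  } else {
    ## ablation: direct transfer, sources applied sequentially at stage 3
    stage3_source <- list(x = do.call(rbind, lapply(sources, `[[`, "x")),
                          y = unlist(lapply(sources, `[[`, "y")))
  }

  ## stage 3: transfer into the real target under k-fold CV
  folds <- kfold_split(nrow(target$x), k = config$cv_k, seed = seed,
                       labels = target$y)
  y_pred <- integer(nrow(target$x))
  fold_acc <- numeric(config$cv_k)
  last_model <- NULL
  for (f in seq_len(config$cv_k)) {
    test_idx <- folds$folds[[f]]
    train_idx <- setdiff(seq_len(nrow(target$x)), test_idx)
    st3 <- train_transfer_stage(
      init = carried,
      source_data = stage3_source,
      target_data = list(x_l = target$x[train_idx, , drop = FALSE],
                         y_l = target$y[train_idx],
                         x_u = target$x[train_idx, , drop = FALSE]),
      hyper = hyper,
      schedule = sched_with_seed(config$schedule, seed + 700L + f),
      terms = terms)
    pred <- predict(st3, target$x[test_idx, , drop = FALSE])$labels
    y_pred[test_idx] <- pred
    fold_acc[f] <- 100 * mean(pred == target$y[test_idx])
    last_model <- st3
  }
  report <- overall_report(target$y, y_pred, classes = sort(unique(target$y)))
  report$fold_accuracy <- fold_acc
  report$folds <- folds
  stages[[length(stages) + 1]] <- stage_result(3L, last_model, report)

  structure(list(stages = stages, report = report, scenario = scenario,
                 n_gans_trained = n_gans, seed = seed),
            class = "distant_transfer_run")
}

#' Target-only cross-validated baseline
#'
#' Trains the classifier on the target dataset alone (no source, no
#' adversarial term) under the same stratified k-fold assignment a transfer
#' run with the same seed uses, making paired comparisons valid.
#'
#' @param target_id Target dataset id.
#' @param config A [pipeline_config()].
#' @param registry Named list of datasets.
#' @param seed Integer seed (controls fold assignment and initialization).
#' @return A [overall_report()] with `fold_accuracy` and `folds` attached.
#' @export
run_baseline <- function(target_id, config, registry, seed = 1) {
  target <- resolve_dataset(registry, target_id)
  hyper0 <- transfer_hyper(phi = 1, gamma_scale = 0, sigma_adv = 0)
  folds <- kfold_split(nrow(target$x), k = config$cv_k, seed = seed,
                       labels = target$y)
  y_pred <- integer(nrow(target$x))
  fold_acc <- numeric(config$cv_k)
  for (f in seq_len(config$cv_k)) {
    test_idx <- folds$folds[[f]]
    train_idx <- setdiff(seq_len(nrow(target$x)), test_idx)
    st <- train_transfer_stage(
      init = NULL, source_data = NULL,
      target_data = list(x_l = target$x[train_idx, , drop = FALSE],
                         y_l = target$y[train_idx]),
      hyper = hyper0,
      schedule = sched_with_seed(config$schedule, seed + 700L + f))
    pred <- predict(st, target$x[test_idx, , drop = FALSE])$labels
    y_pred[test_idx] <- pred
    fold_acc[f] <- 100 * mean(pred == target$y[test_idx])
  }
  report <- overall_report(target$y, y_pred, classes = sort(unique(target$y)))
  report$fold_accuracy <- fold_acc
  report$folds <- folds
  report
}
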