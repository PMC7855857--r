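#' Training configuration
#'
#' Defaults reproduce the published protocol verbatim: 100 epochs, batch
#' size 64, RMSProp with learning rate 0.01 / smoothing 0.99 / epsilon 1e-8
#' (the conventional defaults of that optimizer family, pinned explicitly so
#' runs reproduce across library versions), weight decay 1e-5 on weight
#' matrices only, loss weights alpha = 0.2, beta = 1, gamma = 3, horizon
#' T = 36 months, best-validation-C model selection, and five-repeat
#' summaries.
#'
#' @param epochs number of passes over the training data.
#' @param batch_size mini-batch size (>= 2; batch normalization needs at
#'   least two rows).
#' @param learning_rate,rmsprop_smoothing,rmsprop_epsilon optimizer settings.
#' @param weight_decay L2 penalty rate applied to weight matrices only
#'   (never to biases or batch-norm scale/shift).
#' @param weights a [loss_weights()].
#' @param seed integer; the whole run (init handled separately, shuffling,
#'   dropout) is deterministic given the seed.
#' @param n_repeats default repeat count for [repeat_runs()].
#' @export
training_config <- function(epochs = 100L,
                            batch_size = 64L,
                            learning_rate = 0.01,
                            rmsprop_smoothing = 0.99,
                            rmsprop_epsilon = 1e-8,
                            weight_decay = 1e-5,
                            weights = loss_weights(),
                            seed = 1L,
                            n_repeats = 5L) {
  if (epochs < 1) stop_survnet("epochs must be >= 1")
  if (batch_size < 2) stop_survnet("batch_size must be >= 2")
  if (weight_decay < 0) stop_survnet("weight_decay must be nonnegative")
  structure(list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 optimizer = "rmsprop",
                 learning_rate = learning_rate,
                 rmsprop_smoothing = rmsprop_smoothing,
                 rmsprop_epsilon = rmsprop_epsilon,
                 weight_decay = weight_decay,
                 weights = weights, seed = as.integer(seed),
                 n_repeats = as.integer(n_repeats)),
            class = "training_config")
}

# Names of parameters that receive weight decay: weight matrices only.
decayed_params <- function(params) {
  names(params)[names(params) %in% c("We", "Wd", "W3", "wc", "wp")]
}

#' Train a SurvNet model
#'
#' Mini-batch RMSProp on the weighted multi-task objective, shuffling every
#' epoch. After each epoch the validation concordance index is computed from
#' the inference-mode gated prognosis index `p_x` (the deployed score), and
#' the parameter snapshot with the best validation C-index is returned
#' (first-attained on ties). Batches without any event skip the Cox term
#' (counted in the history); an epoch in which no batch had events is an
#' error. An incomplete final batch of size 1 is folded into the previous
#' batch.
#'
#' @param model an initialized `survnet_model`.
#' @param train_cohort,val_cohort `encoded_cohort`s sharing standardization
#'   stats.
#' @param config a [training_config()].
#' @param verbose print a line per 10 epochs.
#' @return list with `model` (selected snapshot, carrying the training
#'   stats) and `history` (data.frame of per-epoch losses and validation C,
#'   plus attributes `selected_epoch` and `best_val_cindex`).
#' @export
train_survnet <- function(model, train_cohort, val_cohort, config = training_config(),
                          verbose = FALSE) {
  stopifnot(inherits(model, "survnet_model"),
            inherits(train_cohort, "encoded_cohort"),
            inherits(val_cohort, "encoded_cohort"))
  if (sum(train_cohort$event) == 0) stop_survnet("training cohort has no events")
  n <- nrow(train_cohort$X)
  cfg <- config
  w <- cfg$weights

  # RMSProp state
  v_state <- lapply(model$params, function(p) p * 0)
  decay_set <- decayed_params(model$params)

  history <- data.frame(epoch = integer(0), cox = numeric(0),
                        classification = numeric(0), reconstruction = numeric(0),
                        total = numeric(0), val_cindex = numeric(0),
                        cox_batches_skipped = integer(0))
  best_c <- -Inf; best_model <- model; best_epoch <- NA_integer_

  with_seed(cfg$seed, {
    for (epoch in seq_len(cfg$epochs)) {
      perm <- sample.int(n)
      starts <- seq(1, n, by = cfg$batch_size)
      batches <- lapply(starts, function(st) perm[st:min(st + cfg$batch_size - 1, n)])
      nb <- length(batches)
      if (nb > 1 && length(batches[[nb]]) < 2) {
        batches[[nb - 1]] <- c(batches[[nb - 1]], batches[[nb]])
        batches[[nb]] <- NULL
      }
      ep_losses <- c(cox = 0, classification = 0, reconstruction = 0, total = 0)
      skipped <- 0L; used_cox <- 0L
      for (b in batches) {
        res <- survnet_loss_grads(model,
                                  train_cohort$X[b, , drop = FALSE],
                                  train_cohort$R[b, , drop = FALSE],
                                  train_cohort$time[b], train_cohort$event[b], w)
        model <- res$model
        if (res$cox_skipped) skipped <- skipped + 1L else used_cox <- used_cox + 1L
        g <- res$grads
        for (nm in names(model$params)) {
          gn <- g[[nm]]
          if (nm %in% decay_set && cfg$weight_decay > 0) {
            gn <- gn + cfg$weight_decay * model$params[[nm]]
          }
          v_state[[nm]] <- cfg$rmsprop_smoothing * v_state[[nm]] +
            (1 - cfg$rmsprop_smoothing) * gn^2
          model$params[[nm]] <- model$params[[nm]] -
            cfg$learning_rate * gn / (sqrt(v_state[[nm]]) + cfg$rmsprop_epsilon)
        }
        ep_losses <- ep_losses + c(res$losses$cox, res$losses$classification,
                                   res$losses$reconstruction, res$total)
      }
      if (used_cox == 0L) {
        stop_survnet("epoch ", epoch, ": no batch contained an event; ",
                     "increase batch size or check the cohort")
      }
      ep_losses <- ep_losses / length(batches)
      val_out <- survnet_forward(model, val_cohort$X, training = FALSE)
      val_c <- concordance_index(val_out$p_x, val_cohort$time, val_cohort$event)
      history[epoch, ] <- list(epoch, ep_losses[1], ep_losses[2], ep_losses[3],
                               ep_losses[4], val_c, skipped)
      if (val_c > best_c) {
        best_c <- val_c; best_model <- model; best_epoch <- epoch
      }
      if (verbose && epoch %% 10 == 0) {
        message(sprintf("epoch %3d  loss %.4f  val C %.4f", epoch, ep_losses[4], val_c))
      }
    }
  })
  best_model$stats <- train_cohort$stats
  attr(history, "selected_epoch") <- best_epoch
  attr(history, "best_val_cindex") <- best_c
  list(model = best_model, history = history)
}

#' Repeat training runs over independent seeds
#'
#' Trains `k` models from independent initializations, selects each by best
#' validation C-index, and evaluates the selected model on the test split —
#' the data behind a repeat-run boxplot. Run `i` derives its seed as
#' `seed + 1009 * (i - 1)`.
#'
#' @param arch a [survnet_arch()].
#' @param splits named list with `train`, `validation`, `test`
#'   `encoded_cohort`s (e.g. from [split_cohort()]).
#' @param config a [training_config()]; its `seed` anchors the seed ladder.
#' @param k number of repeats (default `config$n_repeats`).
#' @return list with `runs` (data.frame: run, seed, test_cindex,
#'   val_cindex, selected_epoch) and `summary` (median and quartiles of the
#'   test C-index).
#' @export
repeat_runs <- function(arch, splits, config = training_config(), k = config$n_repeats) {
  stopifnot(k >= 1)
  rows <- vector("list", k)
  for (i in seq_len(k)) {
    seed_i <- config$seed + 1009L * (i - 1L)
    run_cfg <- config; run_cfg$seed <- seed_i
    model <- init_model(arch, seed = seed_i)
    fit <- train_survnet(model, splits$train, splits$validation, run_cfg)
    test_out <- survnet_forward(fit$model, splits$test$X, training = FALSE)
    test_c <- concordance_index(test_out$p_x, splits$test$time, splits$test$event)
    rows[[i]] <- data.frame(run = i, seed = seed_i, test_cindex = test_c,
                            val_cindex = attr(fit$history, "best_val_cindex"),
                            selected_epoch = attr(fit$history, "selected_epoch"))
  }
  runs <- do.call(rbind, rows)
  qs <- stats::quantile(runs$test_cindex, c(0.25, 0.5, 0.75), names = FALSE)
  list(runs = runs,
       summary = data.frame(q1 = qs[1], median = qs[2], q3 = qs[3]))
}
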