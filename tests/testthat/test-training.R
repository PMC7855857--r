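# Small cohorts and short runs keep this file fast; the full published
# protocol is exercised end-to-end in test-acceptance.R.

make_splits <- function(n = 400, missing_rate = 0, seed = 41) {
  sim <- simulate_cohort(simulation_config(n = n, missing_rate = missing_rate,
                                           seed = seed))
  coh <- encode_cohort(sim$records, sim$schema)
  list(splits = split_cohort(coh, seed = seed), sim = sim)
}

test_that("one-epoch training yields a singleton history with selection at 1", {
  ms <- make_splits(200)
  cfg <- training_config(epochs = 1, seed = 3)
  fit <- train_survnet(init_model(survnet_arch(), 3), ms$splits$train,
                       ms$splits$validation, cfg)
  expect_equal(nrow(fit$history), 1)
  expect_equal(attr(fit$history, "selected_epoch"), 1)
  expect_equal(attr(fit$history, "best_val_cindex"), fit$history$val_cindex[1])
})

test_that("training is deterministic given the seed", {
  ms <- make_splits(200)
  cfg <- training_config(epochs = 3, seed = 8)
  f1 <- train_survnet(init_model(survnet_arch(), 8), ms$splits$train,
                      ms$splits$validation, cfg)
  f2 <- train_survnet(init_model(survnet_arch(), 8), ms$splits$train,
                      ms$splits$validation, cfg)
  expect_identical(f1$history, f2$history)
  expect_identical(f1$model$params, f2$model$params)
})

test_that("losses stay finite and the selected epoch attains the best validation C", {
  ms <- make_splits(300, missing_rate = 0.3)
  cfg <- training_config(epochs = 8, seed = 5)
  fit <- train_survnet(init_model(survnet_arch(), 5), ms$splits$train,
                       ms$splits$validation, cfg)
  expect_true(all(is.finite(fit$history$total)))
  sel <- attr(fit$history, "selected_epoch")
  expect_equal(fit$history$val_cindex[sel], max(fit$history$val_cindex))
  expect_equal(sel, which.max(fit$history$val_cindex))  # first-attained on ties
})

test_that("weight decay is wired: toggling it changes the trajectory, biases exempt", {
  ms <- make_splits(200)
  n_train <- length(ms$splits$train$time)
  # a single optimizer step (one epoch, one full-cohort batch): the raw
  # gradients coincide, so only decayed parameters may differ
  base <- training_config(epochs = 1, batch_size = n_train, seed = 9,
                          weight_decay = 0)
  wd <- training_config(epochs = 1, batch_size = n_train, seed = 9,
                        weight_decay = 0.1)
  f0 <- train_survnet(init_model(survnet_arch(), 9), ms$splits$train,
                      ms$splits$validation, base)
  f1 <- train_survnet(init_model(survnet_arch(), 9), ms$splits$train,
                      ms$splits$validation, wd)
  expect_false(identical(f0$model$params$We, f1$model$params$We))
  expect_false(identical(f0$model$params$W3, f1$model$params$W3))
  # batch-norm scale/shift and biases are exempt from decay
  expect_identical(f0$model$params$bn_gamma, f1$model$params$bn_gamma)
  expect_identical(f0$model$params$bn_beta, f1$model$params$bn_beta)
  expect_identical(f0$model$params$be, f1$model$params$be)
  expect_identical(f0$model$params$bp, f1$model$params$bp)
})

test_that("selected-model evaluation is repeatable in inference mode", {
  ms <- make_splits(200)
  cfg <- training_config(epochs = 2, seed = 12)
  fit <- train_survnet(init_model(survnet_arch(), 12), ms$splits$train,
                       ms$splits$validation, cfg)
  c1 <- concordance_index(survnet_forward(fit$model, ms$splits$test$X)$p_x,
                          ms$splits$test$time, ms$splits$test$event)
  c2 <- concordance_index(survnet_forward(fit$model, ms$splits$test$X)$p_x,
                          ms$splits$test$time, ms$splits$test$event)
  expect_identical(c1, c2)
})

test_that("training learns signal: validation C rises above chance", {
  ms <- make_splits(600, seed = 44)
  cfg <- training_config(epochs = 25, seed = 44)
  fit <- train_survnet(init_model(survnet_arch(), 44), ms$splits$train,
                       ms$splits$validation, cfg)
  expect_gt(attr(fit$history, "best_val_cindex"), 0.6)
})

test_that("repeat_runs returns one row per seed and a degenerate aggregate for k = 1", {
  ms <- make_splits(200)
  cfg <- training_config(epochs = 2, seed = 7)
  rr <- repeat_runs(survnet_arch(), ms$splits, cfg, k = 3)
  expect_equal(nrow(rr$runs), 3)
  expect_equal(length(unique(rr$runs$seed)), 3)
  rr1 <- repeat_runs(survnet_arch(), ms$splits, cfg, k = 1)
  expect_equal(rr1$summary$median, rr1$runs$test_cindex[1])
})

test_that("a training cohort with no events errors", {
  ms <- make_splits(200)
  dead <- ms$splits$train
  dead$event[] <- 0
  expect_error(train_survnet(init_model(survnet_arch(), 1), dead,
                             ms$splits$validation, training_config(epochs = 1)),
               "no events")
})
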